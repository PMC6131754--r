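tissue	human_enhancers	mouse_enhancers	human_eg	human_fce	human_rpe
BAT	35356	47267	17309	6566	11481
Cortex	27682	57310	13198	6070	8414
Heart	36003	61646	16789	8370	10844
Intestine	18581	48469	9296	3359	5926
Liver	37241	53162	21061	6125	10055
Lung	28932	61685	14576	5890	8466
Placenta	31221	61926	17925	5433	7863
Spleen	24152	38090	14245	3102	6805
Thymus	14722	35854	7735	2362	4625
Limb	40101	62557	19908	8501	11692
Leukemia	19907	36488	12797	1303	5807
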