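---
title: "Classifying enhancer reprogramming between two genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying enhancer reprogramming between two genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerReprog)
```

## The problem

Enhancers are distal regulatory elements that switch genes on in specific
tissues. When two mammalian genomes are compared, an enhancer whose
sequence survives in the other species may still be doing the same job, or
it may have been *reprogrammed*: the sequence is conserved but its tissue
activity has changed. This package classifies every tissue-labelled
enhancer of a reference species into three mutually exclusive categories:

* **FCE** — functionally conserved: the orthologous region is an enhancer
  in the same tissue set in the other species;
* **RPE** — reprogrammed: the orthologous region is an enhancer, but in at
  least one tissue in which the reference enhancer is not active;
* **EG** — gained: the enhancer has no alignable ortholog, or its ortholog
  shows no enhancer activity at all.

Downstream, the package quantifies two consequences of reprogramming: the
expression of genes whose locus hosts an RPE, and the turnover of
transcription-factor binding sites (TFBSs) inside orthologous enhancer
pairs.

## Classification procedure

All coordinates in the package are 0-based, half-open; every region
intersection uses a minimum-overlap threshold (default 50 bp). Inputs are
filtered first: peak-style enhancer calls are re-centred to fixed 1 kb
intervals, enhancers longer than 3 kb (stretch/super-enhancers) are
removed, and so are intervals with more than 75% soft-masked (repeat)
bases. Both filter thresholds are inclusive — the removal rules are
"longer than" and "more than", so a 3000 bp enhancer with exactly 75%
repeats stays. Repeat content is measured from lowercase bases in the
genome FASTA: soft-masking is the standard carrier of the repeat signal
and needs no extra track.

Each enhancer is projected through pairwise alignment chains
(`project_interval()`). Among chains overlapping the interval the single
best-scoring one is used — no chain stitching; ties break deterministically
by lower reference start, then chain id. Every reference base falling in
an aligned block maps to a query base; the ortholog is the minimal query
interval spanning the mapped bases. "Does not align" means zero mapped
bases; an enhancer projecting even one base proceeds to overlap testing,
where the 50 bp rule then decides functional overlap. We deliberately do
not introduce a second aligned-fraction threshold for enhancers — the
overlap rule is the only intersection criterion, and the mapped fraction
is exposed separately where sites are concerned (below).

Genome-wide classification gives RPE precedence over FCE: if the ortholog
overlaps destination enhancers both in shared and in novel tissues, the
enhancer is reprogrammed, because reprogramming is defined by activity in
a *partially or fully* different tissue set.

The tissue-pair variant (`classify_tissue_pair()`) works on two tissues at
a time: within each species the two tissues' shared enhancers are dropped
first, leaving tissue-exclusive subsets; exclusive source enhancers are
projected; same-tissue matches become FCEs and their destination partners
are removed; source leftovers overlapping the *other* tissue's destination
remainder are the enhancers reprogrammed from source tissue A to
destination tissue B. Two design points deserve a note:

* The "shared within species" step uses its own threshold
  (`share_min_bp`, default 1 bp — strictly non-overlapping subsets) rather
  than the tunable `min_overlap`. Keeping the exclusivity step fixed makes
  the procedure monotone in `min_overlap`: raising the cross-species
  threshold can only lose FCE and RPE calls, never manufacture them.
* FCE-matched destination enhancers are removed before the reprogramming
  intersection, so the three categories partition each tissue's input —
  no enhancer is counted both as conserved and reprogrammed.

## Binding-site turnover

Within an orthologous enhancer pair, each source-side motif hit is
assigned one of four categories by projecting it through the chain: a site
*maps* if at least `min_mapped_fraction` (default 0.5) of its bases
project. A mapped site over a destination hit of the same motif is
conserved (TFBSC); over a hit of a different motif, reused (TFBSR —
mutation has rewired the site for another factor); a site that does not
land on any destination hit but whose motif occurs elsewhere in the
destination enhancer is reshuffled (TFBSH); anything else is gained
(TFBSG). Precedence is TFBSC > TFBSR > TFBSH > TFBSG: positional mapping
evidence outranks mere presence. "Same factor" is operationalised as same
motif identifier. Gains are reference-relative; running the categoriser
with the two species swapped measures the other genome's gains.

Per-category densities (sites per kb) are pooled over all of a tissue
pair's reprogrammed enhancers and compared with the densities in the
functionally conserved enhancers of the pair's source tissue. Pooled
counts over pooled length are the default (per-enhancer means are
available); a verdict of "equal" means a relative difference within 1% —
without a tolerance, equality would be measure-zero for continuous
densities.

## Motif scanning and overrepresentation

The scanner is a log-odds position-weight-matrix scan of both strands.
Scores are `sum(log2(p'/b))` over motif positions, where `p'` is the
matrix probability with a small pseudocount mixed in proportionally to the
background `b`. Hit calling uses the *exact* word p-value: the full score
distribution over all words under the background, obtained by
position-wise convolution on a discretised score grid (0.01 bits by
default). Window scoring uses the same discretised matrix, so reported
p-values are exact on the grid; the test suite checks the scanner against
full enumeration of all `4^w` words. One consequence worth knowing: a
width-w motif can never achieve a p-value below `4^-w`, so very short
motifs are unreportable at stringent thresholds (the default threshold is
1e-4, sensible for widths of 6 and up).

Overrepresentation compares hit counts in a region set against controls
matched per region for length, GC (±0.02) and repeat content (±0.05),
sampled by rejection with stepwise tolerance doubling (each relaxation is
recorded; an unplaceable region is an error). The expectation is scaled by
total base pairs — `lambda = control_hits × region_bp / control_bp` — and
the p-value is the Poisson upper tail, Bonferroni-corrected over the
motifs tested (enrichment at adjusted p ≤ 0.05 by default). When controls
yield zero hits but regions do not, `lambda` is floored at 1e-9 and the
result flagged: such calls rest on no control information and should be
treated as qualitative. In sparse-hit regimes this floor makes a single
chance hit look significant — the type-I guarantees of the Poisson test
hold when expected hit counts are well above zero, which is how the null
simulations in the test suite are configured (longer regions, several
controls per region, permissive scan threshold).

## Gene loci and expression

A gene's locus extends from the midpoint of the upstream intergenic gap to
the midpoint of the downstream one (sequence ends close the first and last
locus), so loci tile each sequence exactly; overlapping genes get the
boundary at the midpoint of their overlap. Enhancers attach to loci by the
same 50 bp rule, a boundary-straddling enhancer to the larger-overlap side
(ties to the lower-coordinate locus). Expression is normalised per tissue
by the median over all genes. The reprogramming shift statistic for a
tissue pair (A→B) is the ratio of median expression (novel tissue B over
source tissue A) across genes whose locus hosts at least one of the pair's
RPEs, with a one-sided Wilcoxon rank-sum test (exact for small samples,
normal approximation with continuity correction otherwise — base R's
implementation, checked against explicit enumeration in the tests).
Single-enhancer-locus composition is tested per category with a two-sided
Fisher exact test on the 2×2 table (in/out of single-enhancer loci ×
in/out of category).

## The synthetic scenario generator

The full-scale inputs (chromatin-state enhancer calls, whole-genome
alignment nets, full motif libraries) are consumed, not computed, so the
package ships a generator that builds a complete two-species dataset with
planted truth for every stage. Both genomes are emitted from one colinear
segment plan, which makes the alignment chain exact by construction:

* background sequence is i.i.d. uniform ACGT; each inter-enhancer spacer
  carries one soft-masked run covering 20% of it, which exercises the
  repeat filter without a repeat model;
* a spacer is alignable with probability `alignment_coverage` (default
  0.7); alignable material can carry substitutions (never inside planted
  motif sites) and 1–5 bp indels (never inside enhancers);
* planted FCEs get an ortholog active in the same tissues; planted RPEs an
  ortholog active in at least one novel tissue; planted EGs are split
  50/50 between enhancers inside unalignable gaps and alignable enhancers
  with no destination activity. Default category mix: 2% FCE / 42% RPE /
  56% EG, the human-side breakdown reported for chromatin-state enhancer
  calls in 11-tissue human–mouse comparisons — the regime this pipeline is
  built for. Extra destination-only enhancers (30% of the
  source count) make the reverse-direction classification non-trivial;
* motif events are planted per orthologous pair at non-overlapping slots:
  conserved sites (same consensus, same aligned offset), reshuffled (same
  consensus, non-corresponding offsets), gained (source only — the
  destination keeps background there), reused (different consensus on each
  side at the same offset, i.e. only the site's bases are rewritten).
  Motifs are drawn without replacement within a pair and a gained site's
  motif never equals a destination-side motif, so planted categories are
  unambiguous. Default profiles give conserved enhancers mostly conserved
  sites and reprogrammed enhancers mostly gained ones. The motif library
  is synthetic: near-deterministic 8-mers with pairwise consensus Hamming
  distance ≥ 3, so at the default scan threshold only exact consensus
  words are hits;
* genes are laid out evenly with jitter along the source genome; every
  gene shares one log-normal baseline across tissues and species, and a
  gene whose locus hosts an RPE is shifted 1.4-fold in the tissue where
  that enhancer is active in each species (the lowest-coordinate RPE wins
  when a locus hosts several), before log-normal noise (sd 0.25).

One RNG stream, seeded from the config, drives every draw in a fixed
order: the same config is byte-reproducible. The generator refuses
infeasible packings up front.

What the generator does *not* emulate: realistic neutral evolution or
repeat families, motif degeneracy and cooperative binding, paralogy,
distance-dependent enhancer–gene assignment, and expression programmes
beyond a single planted fold. Passing tests therefore demonstrate that the
algorithms recover planted structure under controlled divergence, not that
they would resolve the far messier real data.

## Problem sizes and numerical choices

The reference scenario is 4 sequences × ~150 kb per species, 240 source
enhancers (~1 kb), 4 tissues, 10 motifs, 120 genes — small enough that the
full pipeline runs in seconds while every category and tissue pair stays
populated. The turnover analysis uses a variant with a larger conserved
fraction (30%) so per-pair FCE densities rest on more than a handful of
enhancers; at the study mix of 2% the control is a few enhancers and
verdicts are dominated by sampling noise, which is a property of the mix,
not of the method. Score discretisation is 0.01 bits; Wilcoxon switches to
the normal approximation above the exact-enumeration range; Fisher tests
are two-sided; Bonferroni is used wherever the study design calls for
family-wise control. Tie-breaks (equal-scoring chains, equal locus
overlap) are always resolved toward lower coordinates for determinism.

## Known limitations

Projection uses one chain per enhancer — fragmented orthology across
several chains is invisible. Site categories depend on scan completeness:
a destination hit missed at the threshold turns a conserved site into a
gain. The expression model assigns an enhancer to exactly one locus; real
enhancers skip genes and act across boundaries. Reprogramming direction is
not polarised against an outgroup: an RPE records difference, not which
lineage changed.
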