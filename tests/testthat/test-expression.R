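test_that("locus boundaries bisect intergenic gaps and tile the sequence", {
  genes <- data.frame(seq = "chr1", start = c(1000L, 4000L),
                      end = c(2000L, 5000L), gene = c("g1", "g2"))
  loci <- build_loci(genes, c(chr1 = 10000L))
  expect_equal(loci$locus_start, c(0, 3000))
  expect_equal(loci$locus_end, c(3000, 10000))
  # single gene owns the whole sequence
  l1 <- build_loci(genes[1, ], c(chr1 = 10000L))
  expect_equal(c(l1$locus_start, l1$locus_end), c(0, 10000))
  # three genes, gaps of 100 and 600 -> boundaries at gap midpoints
  g3 <- data.frame(seq = "chr1", start = c(0L, 600L, 1800L),
                   end = c(500L, 1200L, 2000L), gene = c("a", "b", "c"))
  l3 <- build_loci(g3, c(chr1 = 2500L))
  expect_equal(l3$locus_start, c(0, 550, 1500))
  expect_equal(l3$locus_end, c(550, 1500, 2500))
  expect_error(build_loci(g3, c(chr1 = 1900L)), "beyond")
})

test_that("loci tile each sequence with no overlap on random gene sets", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    start <- sort(sample(seq(0L, 90000L, by = 100L), n))
    genes <- data.frame(seq = "chrR", start = start, end = start + 80L,
                        gene = paste0("g", seq_len(n)))
    loci <- build_loci(genes, c(chrR = 100000L))
    expect_equal(loci$locus_start[1], 0)
    expect_equal(loci$locus_end[n], 100000)
    expect_equal(loci$locus_start[-1], loci$locus_end[-n])
    expect_true(all(loci$gene_start >= loci$locus_start - 1e-9))
  }
})

test_that("straddling enhancers go to the larger-overlap locus, ties low", {
  genes <- data.frame(seq = "chr1", start = c(1000L, 4000L),
                      end = c(2000L, 5000L), gene = c("g1", "g2"))
  loci <- build_loci(genes, c(chr1 = 10000L))  # boundary at 3000
  rec <- data.frame(seq = "chr1",
                    start = c(2800L, 2960L, 2950L, 9000L),
                    end = c(3100L, 3200L, 3050L, 9040L))
  li <- assign_to_loci(loci, rec)
  expect_equal(li[1], 1L)       # 200 bp left vs 100 right
  expect_equal(li[2], 2L)       # 40 left vs 200 right
  expect_equal(li[3], 1L)       # 50/50 tie -> lower locus
  expect_true(is.na(li[4]))     # 40 bp < 50 bp rule
})

test_that("median normalization scales columns independently and is idempotent", {
  m <- cbind(liver = c(1, 2, 3), heart = c(4, 4, 4))
  rownames(m) <- paste0("g", 1:3)
  n1 <- normalize_expression(m)
  expect_equal(unname(n1[, "liver"]), c(0.5, 1, 1.5))
  expect_equal(unname(n1[, "heart"]), c(1, 1, 1))
  expect_equal(normalize_expression(n1), n1)
  m0 <- cbind(t = c(0, 0, 0))
  rownames(m0) <- paste0("g", 1:3)
  expect_error(normalize_expression(m0), "zero")
})

test_that("a planted fold-change is recovered exactly at zero noise", {
  set.seed(66)
  genes <- sprintf("g%03d", 1:100)
  rpe_map <- data.frame(gene = genes[1:40], tissue_a = "liver", tissue_b = "heart")
  pe <- plant_expression(genes, rpe_map, c("liver", "heart"),
                         fold_change = 1.4, noise_sd = 0)
  sel <- pe$truth$gene[pe$truth$shifted]
  expect_equal(stats::median(pe$expression_b[sel, "heart"]) /
                 stats::median(pe$expression_b[sel, "liver"]), 1.4)
  expect_equal(stats::median(pe$expression_a[sel, "liver"]) /
                 stats::median(pe$expression_a[sel, "heart"]), 1.4)
  # fold 1, zero noise: all tissues identical per gene
  pe0 <- plant_expression(genes, rpe_map, c("liver", "heart"),
                          fold_change = 1, noise_sd = 0)
  expect_equal(pe0$expression_a[, "liver"], pe0$expression_a[, "heart"])
})

test_that("the shift test recovers 1.4x exactly and rejects at n = 100", {
  set.seed(67)
  # 100 genes, one RPE in each of the first 60 loci
  genes <- data.frame(seq = "chrE", start = seq(0L, by = 1000L, length.out = 100L),
                      end = seq(0L, by = 1000L, length.out = 100L) + 400L,
                      gene = sprintf("g%03d", 1:100))
  loci <- build_loci(genes, c(chrE = 100000L))
  rpe <- data.frame(seq = "chrE",
                    start = loci$locus_start[1:60] + 100L,
                    end = loci$locus_start[1:60] + 300L)
  rpe_map <- data.frame(gene = genes$gene[1:60], tissue_a = "liver",
                        tissue_b = "heart")
  pe <- plant_expression(genes$gene, rpe_map, c("liver", "heart"),
                         fold_change = 1.4, noise_sd = 0)
  sh <- rpe_expression_shift(rpe, loci, pe$expression_b, "liver", "heart",
                             normalize = FALSE)
  expect_equal(sh$fold_change, 1.4)
  expect_lt(sh$p_value, 0.05)
  expect_equal(sh$n_genes, 60)
  # identical expression in both tissues: fold 1, p ~ 0.5
  pe0 <- plant_expression(genes$gene, rpe_map[0, ], c("liver", "heart"),
                          fold_change = 1, noise_sd = 0)
  sh0 <- rpe_expression_shift(rpe, loci, pe0$expression_b, "liver", "heart",
                              normalize = FALSE)
  expect_equal(sh0$fold_change, 1)
  expect_gt(sh0$p_value, 0.4)
})

test_that("one-sided rank-sum p-values match exact enumeration for small n", {
  set.seed(68)
  for (rep in 1:12) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- round(stats::rlnorm(nx), 3); y <- round(stats::rlnorm(ny), 3)
    if (anyDuplicated(c(x, y))) next
    want <- oracle_wilcox_greater(x, y)
    got <- stats::wilcox.test(x, y, alternative = "greater")$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("locus bins report counts, expression and category fractions", {
  genes <- data.frame(seq = "chr1", start = c(1000L, 4000L, 7000L),
                      end = c(2000L, 5000L, 8000L), gene = c("g1", "g2", "g3"))
  loci <- build_loci(genes, c(chr1 = 10000L))
  rec <- data.frame(seq = "chr1",
                    start = c(500L, 700L, 3500L), end = c(650L, 900L, 3800L))
  rec$category <- c("RPE", "FCE", "RPE")
  expr <- cbind(liver = c(2, 4, 8))
  rownames(expr) <- genes$gene
  bins <- bin_by_enhancer_count(loci, rec, expr, "liver")
  b0 <- bins[bins$bin == 0, ]
  expect_equal(b0$n_genes, 1)            # g3 has no enhancer
  expect_true(is.na(b0$frac_rpe))
  b1 <- bins[bins$bin == 1, ]
  expect_equal(b1$frac_rpe, 1)
  b2 <- bins[bins$bin == 2, ]
  expect_equal(b2$frac_rpe, 0.5)
  expect_equal(b2$median_expression, 2)
})

test_that("a planted RPE-fraction trend across bins is recovered monotone", {
  # loci with 1..5 enhancers; RPE share grows with locus size
  set.seed(70)
  rows <- list(); genes <- list(); gpos <- 0L
  for (k in 1:5) {
    for (rep in 1:4) {
      genes[[length(genes) + 1L]] <- data.frame(
        seq = "chrM", start = gpos + 4000L, end = gpos + 4400L,
        gene = sprintf("g%d_%d", k, rep))
      for (e in seq_len(k)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = "chrM", start = gpos + 1000L * e, end = gpos + 1000L * e + 200L,
          category = if (e > 1) "RPE" else "FCE")  # RPE share (k-1)/k grows with k
      }
      gpos <- gpos + 10000L
    }
  }
  genes <- do.call(rbind, genes); rec <- do.call(rbind, rows)
  loci <- build_loci(genes, c(chrM = gpos))
  expr <- cbind(t1 = rep(1, nrow(genes))); rownames(expr) <- genes$gene
  bins <- bin_by_enhancer_count(loci, rec, expr, "t1")
  fr <- bins$frac_rpe[bins$bin > 0]
  expect_true(all(diff(fr) >= -1e-9))
})

test_that("seloci category make-up uses an exact hypergeometric test", {
  expect_equal(stats::fisher.test(matrix(c(3, 7, 12, 8), 2))$p.value,
               oracle_fisher2x2(3, 7, 12, 8), tolerance = 1e-9)
  # planted depletion of RPEs in single-enhancer loci
  set.seed(71)
  genes <- data.frame(seq = "chrS", start = seq(2000L, by = 10000L, length.out = 30L),
                      end = seq(2000L, by = 10000L, length.out = 30L) + 500L,
                      gene = sprintf("g%02d", 1:30))
  loci <- build_loci(genes, c(chrS = 300000L))
  rows <- list()
  for (i in seq_len(30)) {
    base <- loci$locus_start[i]
    if (i <= 15) {  # single-enhancer loci: never RPE
      rows[[length(rows) + 1L]] <- data.frame(seq = "chrS", start = base + 100L,
                                              end = base + 300L, category = "FCE")
    } else {        # multi-enhancer loci: mostly RPE
      for (e in 1:4)
        rows[[length(rows) + 1L]] <- data.frame(
          seq = "chrS", start = base + 500L * e, end = base + 500L * e + 200L,
          category = if (e == 1) "FCE" else "RPE")
    }
  }
  rec <- do.call(rbind, rows)
  out <- seloci_test(loci, rec)
  rpe <- out[out$category == "RPE", ]
  expect_lt(rpe$odds_ratio, 1)
  expect_lt(rpe$p_value, 0.05)
  expect_equal(rpe$frac_seloci, 0)
  # no single-enhancer locus -> absent result
  expect_null(seloci_test(loci[16:30, ], rec[rec$start >= loci$locus_start[16], ]))
})

test_that("uniformly spread categories give a null seloci result", {
  set.seed(72)
  genes <- data.frame(seq = "chrS", start = seq(2000L, by = 8000L, length.out = 40L),
                      end = seq(2000L, by = 8000L, length.out = 40L) + 500L,
                      gene = sprintf("g%02d", 1:40))
  loci <- build_loci(genes, c(chrS = 330000L))
  rows <- list()
  for (i in seq_len(40)) {
    base <- loci$locus_start[i]
    n_e <- if (i %% 2) 1L else 3L
    for (e in seq_len(n_e))
      rows[[length(rows) + 1L]] <- data.frame(
        seq = "chrS", start = base + 600L * e, end = base + 600L * e + 200L,
        category = sample(c("RPE", "FCE", "EG"), 1))
  }
  out <- seloci_test(loci, do.call(rbind, rows))
  # three simultaneous null tests: none should be strongly significant
  expect_true(all(out$p_value > 0.01))
  expect_true(all(out$odds_ratio > 0.2 & out$odds_ratio < 5))
})
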