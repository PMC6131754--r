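test_that("a consensus hit scores ~2 bits per position and is reported", {
  m <- fixed_motif("AAAA", id = "polyA")
  # for a width-4 motif the smallest exact p-value is 4^-4 ~ 0.0039, so the
  # threshold must sit above it for any hit to be reportable
  h <- scan_motif("AAAA", m, p_threshold = 0.005)
  expect_gte(nrow(h), 1)
  fwd <- h[h$strand == "+", ]
  expect_equal(fwd$score, 4 * log2((0.997 + 0.001 * 0.25) / 1.001 / 0.25),
               tolerance = 0.02)
  expect_equal(fwd$p_value, 1 / 256, tolerance = 1e-9)
  # a sequence without a strong window yields nothing
  expect_equal(nrow(scan_motif("CGCGCGCGCG", m, p_threshold = 0.005)), 0)
  # motif wider than sequence -> empty
  expect_equal(nrow(scan_motif("AA", m)), 0)
})

test_that("a palindromic motif hits the same interval on both strands", {
  m <- fixed_motif("AAACGTTT", id = "pal")  # its own reverse complement
  h <- scan_motif("GGAAACGTTTGG", m)
  expect_equal(nrow(h), 2)
  expect_equal(h$start, c(2L, 2L))
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(h$p_value[1], h$p_value[2])
})

test_that("windows containing N are skipped", {
  m <- fixed_motif("AAAA")
  h <- scan_motif("AANAAAAA", m)
  expect_true(all(h$start >= 3))
})

test_that("scanner equals the exhaustive word oracle for small widths", {
  set.seed(404)
  for (rep in 1:12) {
    w <- sample(4:6, 1)
    motif <- if (rep %% 2) random_motif(w, id = "MR") else
      fixed_motif(random_seq(w), id = "MC")
    s <- random_seq(sample(50:200, 1))
    thr <- sample(c(1e-2, 1e-3), 1)  # permissive so hits exist
    got <- scan_motif(s, motif, p_threshold = thr)
    want <- oracle_scan(s, motif, p_threshold = thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
    }
  }
})

test_that("non-uniform backgrounds shift p-values as the oracle predicts", {
  set.seed(17)
  bg <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  motif <- fixed_motif("AATT", background = bg)
  s <- random_seq(120)
  got <- scan_motif(s, motif, p_threshold = 5e-2)
  want <- oracle_scan(s, motif, p_threshold = 5e-2)
  expect_equal(got$start, want$start)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
})

test_that("matched controls honour their tolerance contract and determinism", {
  set.seed(8)
  genome <- c(chrM = paste0(random_seq(3000), tolower(random_seq(800)),
                            random_seq(3000)))
  regions <- data.frame(seq = "chrM", start = c(200L, 3100L), end = c(1200L, 3900L))
  gc_t <- gc_fraction(genome, regions)
  rep_t <- repeat_fraction(genome, regions)
  set.seed(99)
  ctl <- matched_controls(regions, genome, n_per_region = 2,
                          gc_tol = 0.05, repeat_tol = 0.10)
  expect_equal(nrow(ctl), 4)
  expect_equal(interval_length(ctl), rep(interval_length(regions), each = 2))
  for (k in seq_len(nrow(ctl))) {
    r <- ctl$region[k]
    tol_mult <- 2^ctl$relaxed[k]
    expect_lte(abs(ctl$gc[k] - gc_t[r]), 0.05 * tol_mult + 1e-12)
    expect_lte(abs(ctl$repeat_frac[k] - rep_t[r]), 0.10 * tol_mult + 1e-12)
    expect_false(any(intervals_overlap(ctl[rep(k, nrow(regions)), ], regions,
                                       min_bp = 1L)))
  }
  set.seed(99)
  ctl2 <- matched_controls(regions, genome, n_per_region = 2,
                           gc_tol = 0.05, repeat_tol = 0.10)
  expect_identical(ctl, ctl2)
  # degenerate tolerances accept any placement
  set.seed(1)
  free <- matched_controls(regions, genome, gc_tol = 1, repeat_tol = 1)
  expect_equal(free$relaxed, c(0L, 0L))
})

test_that("Poisson enrichment arithmetic matches closed forms", {
  # P(X >= 5 | lambda = 2) = 1 - e^-2 * (1 + 2 + 2 + 4/3 + 2/3) = 1 - 7 e^-2
  expect_equal(stats::ppois(4, 2, lower.tail = FALSE), 1 - 7 * exp(-2))
  genome <- c(chrE = paste(rep("ACGT", 2500), collapse = ""))
  motifs <- list(fixed_motif("AAAAAAAA", id = "M1"),
                 fixed_motif("CCCCCCCC", id = "M2"))
  regions <- data.frame(seq = "chrE", start = 0L, end = 400L)
  controls <- data.frame(seq = "chrE", start = c(1000L, 2000L), end = c(1400L, 2400L))
  enr <- motif_enrichment(regions, controls, genome, motifs)
  # the ACGT-repeat genome contains neither consensus: observed 0 -> p = 1
  expect_equal(enr$observed, c(0L, 0L))
  expect_equal(enr$p_value, c(1, 1))
  expect_false(any(enr$enriched))
  # Bonferroni is min(1, p * m)
  expect_equal(enr$p_adjusted, pmin(1, enr$p_value * 2))
})

test_that("a planted motif is called enriched against matched controls", {
  set.seed(123)
  genome_core <- random_seq(30000)
  motifs <- make_motif_library(4, width = 8)
  planted <- motif_consensus(motifs[[1]])
  # 10 regions x 3 planted sites of motif 1
  starts <- seq(500L, by = 2500L, length.out = 10L)
  g <- strsplit(genome_core, "")[[1]]
  for (s in starts) for (off in c(100L, 400L, 700L))
    g[(s + off + 1):(s + off + 8)] <- strsplit(planted, "")[[1]]
  genome <- c(chrP = paste(g, collapse = ""))
  regions <- data.frame(seq = "chrP", start = starts, end = starts + 1000L)
  set.seed(5)
  controls <- matched_controls(regions, genome, gc_tol = 0.2, repeat_tol = 1)
  enr <- motif_enrichment(regions, controls, genome, motifs)
  expect_true(enr$enriched[enr$motif_id == motifs[[1]]$motif_id])
  # an unplanted motif can only reach significance through the degenerate
  # zero-expectation floor (a chance hit with no control hits), never with
  # a real control estimate
  expect_false(any(enr$enriched[-1] & !enr$lambda_floored[-1]))
})

test_that("overrepresentation overlap percentages are plain set arithmetic", {
  expect_equal(tfbs_overlap_percentage(c("M1", "M2", "M3", "M4", "M5"),
                                       c("M1", "M2", "M3")), 60)
  expect_equal(tfbs_overlap_percentage(c("M1", "M2"), c("M3")), 0)
  expect_true(is.na(tfbs_overlap_percentage(character(), c("M1"))))
})

test_that("RPE-enriched motifs overlap the novel tissue's motif set, not the source's", {
  # plant one motif repertoire into heart-like regions and the RPE set,
  # and a disjoint repertoire into liver-like regions; the enriched-motif
  # overlap must point at the tissue the enhancers were reprogrammed to
  set.seed(777)
  lib <- make_motif_library(8, width = 8)
  heart_motifs <- lib[1:3]; liver_motifs <- lib[4:6]
  g <- strsplit(random_seq(60000), "")[[1]]
  plant <- function(g, starts, motifs) {
    for (s in starts) for (m in motifs) {
      off <- sample(0:900, 1)
      g[(s + off + 1):(s + off + 8)] <- strsplit(motif_consensus(m), "")[[1]]
    }
    g
  }
  rpe_starts <- seq(500L, by = 1600L, length.out = 12L)
  heart_starts <- seq(20500L, by = 1600L, length.out = 12L)
  liver_starts <- seq(40500L, by = 1600L, length.out = 12L)
  g <- plant(g, rpe_starts, heart_motifs)     # RPEs reprogrammed to heart
  g <- plant(g, heart_starts, heart_motifs)   # heart FCEs
  g <- plant(g, liver_starts, liver_motifs)   # liver FCEs
  genome <- c(chrF = paste(g, collapse = ""))
  reg <- function(st) data.frame(seq = "chrF", start = st, end = st + 1000L)
  enriched <- function(st) {
    r <- reg(st)
    ctl <- matched_controls(r, genome, gc_tol = 0.2, repeat_tol = 1)
    e <- motif_enrichment(r, ctl, genome, lib)
    e$motif_id[e$enriched]
  }
  rpe_set <- enriched(rpe_starts)
  heart_set <- enriched(heart_starts)
  liver_set <- enriched(liver_starts)
  ov_heart <- tfbs_overlap_percentage(rpe_set, heart_set)
  ov_liver <- tfbs_overlap_percentage(rpe_set, liver_set)
  expect_gt(ov_heart, ov_liver + 30)  # direction, with a wide margin
})
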