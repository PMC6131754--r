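id_chain <- function(n = 100000L, seq = "chrT") {
  b <- matrix(c(0L, 0L, n), 1, 3,
              dimnames = list(NULL, c("ref_start", "query_start", "size")))
  list(id = "1", score = 1, ref_seq = seq, ref_size = n, ref_start = 0L,
       ref_end = n, query_seq = seq, query_size = n, query_strand = "+",
       query_start = 0L, query_end = n, blocks = b)
}

test_that("peak re-centering yields fixed-width intervals with clipping", {
  x <- data.frame(seq = "chr1", start = 10400L, end = 10600L)
  out <- center_to_fixed_width(x, 1000L)
  expect_equal(out$start, 10000)
  expect_equal(out$end, 11000)
  expect_false(out$clipped)
  out <- center_to_fixed_width(data.frame(seq = "chr1", start = 0L, end = 10L), 1000L)
  expect_equal(out$start, 0)
  expect_equal(out$end, 505)
  expect_true(out$clipped)
  out <- center_to_fixed_width(data.frame(seq = "chr1", start = 5L, end = 6L), 1L)
  expect_equal(out$start, 5)
  expect_equal(out$end, 6)
})

test_that("filters remove long and repeat-rich enhancers, boundaries kept", {
  g <- c(chrF = paste0(paste(rep("A", 2000), collapse = ""),
                       paste(rep("a", 8000), collapse = "")))
  x <- data.frame(seq = "chrF",
                  start = c(0L, 0L, 1250L, 6000L),
                  end = c(3001L, 3000L, 4250L, 7000L))
  # row1: 3001 bp (too long); row2: 3000 bp, 1000/3000 repeats -> kept
  # row3: 3000 lowercase of 3000? [1250,4250): 750 upper + 2250 lower = 75% -> kept
  # row4: fully lowercase -> removed (repeat)
  out <- filter_enhancers(x, g)
  expect_equal(nrow(out$kept), 2)
  expect_equal(out$rejected$reason, c("length", "repeat"))
  expect_equal(out$kept$start, c(0L, 1250L))
})

test_that("the 50 bp overlap rule is a hard threshold", {
  a <- data.frame(seq = "chr1", start = 0L, end = 100L)
  expect_true(intervals_overlap(a, data.frame(seq = "chr1", start = 50L, end = 200L)))
  expect_false(intervals_overlap(a, data.frame(seq = "chr1", start = 51L, end = 200L)))
  expect_true(intervals_overlap(a, a))
  expect_false(intervals_overlap(a, data.frame(seq = "chr2", start = 0L, end = 100L)))
})

test_that("genome-wide classification follows the RPE-over-FCE precedence", {
  chains <- list(id_chain())
  rec <- enhancer_records(data.frame(
    seq = "chrT", start = c(1000L, 3000L, 5000L), end = c(2000L, 4000L, 6000L),
    tissue = "liver"))
  dst <- data.frame(seq = "chrT",
                    start = c(1000L, 3000L, 3100L),
                    end = c(2000L, 4000L, 4100L),
                    tissue = c("liver", "liver", "heart"))
  out <- classify_genome_wide(rec, dst, chains)
  expect_equal(out$category, c("FCE", "RPE", "EG"))
  expect_equal(out$reprogrammed_to[[2]], "heart")
  # unalignable enhancer -> EG
  rec2 <- enhancer_records(data.frame(seq = "chrU", start = 0L, end = 1000L,
                                      tissue = "liver"))
  out2 <- classify_genome_wide(rec2, dst, chains)
  expect_equal(out2$category, "EG")
  expect_equal(out2$aligned, 0L)
  # unknown destination tissue -> configuration error
  expect_error(classify_genome_wide(
    enhancer_records(data.frame(seq = "chrT", start = 0L, end = 100L,
                                tissue = "brainstem")), dst, chains),
    "brainstem")
})

test_that("tissue-pair algebra recovers a planted reprogramming event", {
  chains <- list(id_chain())
  # source tissue A: e1 FCE, e2 reprogrammed to B, e3 unalignable-by-absence
  a_src <- data.frame(seq = "chrT", start = c(1000L, 3000L, 20000L),
                      end = c(2000L, 4000L, 21000L))
  b_src <- data.frame(seq = "chrT", start = c(5000L, 7000L, 9000L),
                      end = c(6000L, 8000L, 10000L))
  a_dst <- data.frame(seq = "chrT", start = c(1000L, 5000L),
                      end = c(2000L, 6000L))
  b_dst <- data.frame(seq = "chrT", start = c(3000L, 7000L),
                      end = c(4000L, 8000L))
  r <- classify_tissue_pair(a_src, b_src, a_dst, b_dst, chains)
  expect_equal(r$a$category, c("FCE", "RPE", "EG"))
  # b_src[1] lands on the destination-A remainder: reprogrammed B -> A
  expect_equal(r$b$category, c("RPE", "FCE", "EG"))
  expect_equal(unname(r$counts["a_rpe"]), 1)
})

test_that("fully shared tissue sets leave nothing to classify", {
  chains <- list(id_chain())
  x <- data.frame(seq = "chrT", start = c(100L, 900L), end = c(800L, 1600L))
  r <- classify_tissue_pair(x, x, x, x, chains)
  expect_equal(nrow(r$a), 0)
  expect_equal(nrow(r$b), 0)
})

test_that("empty destination sets turn every alignable enhancer into an EG", {
  chains <- list(id_chain())
  a_src <- data.frame(seq = "chrT", start = 100L, end = 700L)
  b_src <- data.frame(seq = "chrT", start = 5000L, end = 5600L)
  none <- data.frame(seq = character(), start = integer(), end = integer())
  r <- classify_tissue_pair(a_src, b_src, none, none, chains)
  expect_equal(r$a$category, "EG")
  expect_equal(r$b$category, "EG")
})

test_that("tissue-pair classification equals brute-force enumeration", {
  set.seed(2024)
  for (rep in 1:60) {
    chains <- lapply(1:2, function(k) random_chain(id = as.character(k)))
    ns <- sample(0:8, 4, replace = TRUE)
    a_src <- random_intervals(ns[1]); b_src <- random_intervals(ns[2])
    a_dst <- random_intervals(ns[3]); b_dst <- random_intervals(ns[4])
    got <- classify_tissue_pair(a_src, b_src, a_dst, b_dst, chains)
    want <- oracle_tissue_pair(a_src, b_src, a_dst, b_dst, chains)
    expect_equal(got$a$category, want$a_cat)
    expect_equal(got$b$category, want$b_cat)
    # partition: every retained enhancer got exactly one category
    expect_true(all(got$a$category %in% c("FCE", "RPE", "EG")))
    expect_true(all(got$b$category %in% c("FCE", "RPE", "EG")))
  }
})

test_that("swapping the tissue order mirrors the reprogrammed sets", {
  set.seed(31)
  for (rep in 1:20) {
    chains <- list(random_chain())
    a_src <- random_intervals(6); b_src <- random_intervals(6)
    a_dst <- random_intervals(6); b_dst <- random_intervals(6)
    r1 <- classify_tissue_pair(a_src, b_src, a_dst, b_dst, chains)
    r2 <- classify_tissue_pair(b_src, a_src, b_dst, a_dst, chains)
    expect_equal(r1$counts[["a_rpe"]], r2$counts[["b_rpe"]])
    expect_equal(r1$counts[["b_fce"]], r2$counts[["a_fce"]])
    expect_equal(r1$a$category, r2$b$category)
  }
})

test_that("raising min_overlap never increases FCE or RPE counts", {
  set.seed(55)
  for (rep in 1:15) {
    chains <- list(random_chain())
    a_src <- random_intervals(8); b_src <- random_intervals(8)
    a_dst <- random_intervals(8); b_dst <- random_intervals(8)
    prev_f <- Inf; prev_r <- Inf
    for (mo in c(20L, 50L, 100L, 200L)) {
      r <- classify_tissue_pair(a_src, b_src, a_dst, b_dst, chains,
                                min_overlap = mo)
      f <- r$counts[["a_fce"]] + r$counts[["b_fce"]]
      rp <- r$counts[["a_rpe"]] + r$counts[["b_rpe"]]
      expect_lte(f, prev_f)
      expect_lte(rp, prev_r)
      prev_f <- f; prev_r <- rp
    }
  }
})

test_that("reprogramming rates follow the per-tissue count arithmetic", {
  rec <- enhancer_records(data.frame(
    seq = "chrT", start = c(0L, 100L, 200L, 300L) * 100L,
    end = c(0L, 100L, 200L, 300L) * 100L + 500L,
    tissue = c("liver", "liver", "liver", "heart")))
  rec$category <- c("RPE", "FCE", "RPE", "RPE")
  expect_equal(reprogramming_rate(rec, "liver"), 2 / 3)
  expect_equal(reprogramming_rate(rec, "heart"), 1)
  expect_true(is.na(reprogramming_rate(rec, "lung")))
  expect_equal(reprogramming_rate_from_counts(8414, 27682), 8414 / 27682)
})
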