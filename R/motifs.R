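BASES <- c("A", "C", "G", "T")

encode_dna <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], BASES)  # non-ACGT -> NA
  v
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Integer log-odds matrix on a discretised score grid.
# score(base b at position i) = log2( ((p_ib + pc*bg_b)/(1+pc)) / bg_b ),
# rounded to multiples of `resolution` bits. Both window scoring and the
# exact p-value distribution use the same discretised matrix, so p-values
# are exact on the grid.
motif_int_scores <- function(motif, resolution = 0.01) {
  p <- motif$matrix
  bg <- motif$background[BASES]
  pc <- motif$pseudocount
  adj <- sweep(p, 2, pc * bg, "+") / (1 + pc)
  lo <- log2(sweep(adj, 2, bg, "/"))
  round(lo / resolution)  # width x 4 integer matrix
}

# Exact distribution of the discretised score under the background:
# position-wise convolution. Returns list(min, pv) where pv[s - min + 1] =
# P(score >= s) for integer grid scores s.
motif_score_pvalues <- function(int_scores, background) {
  bg <- background[BASES]
  cur_vec <- 1; cur_min <- 0L
  for (i in seq_len(nrow(int_scores))) {
    s <- int_scores[i, ]
    new_min <- cur_min + min(s)
    new_len <- length(cur_vec) + (max(s) - min(s))
    nv <- numeric(new_len)
    for (b in 1:4) {
      off <- s[b] - min(s)
      idx <- seq_along(cur_vec) + off
      nv[idx] <- nv[idx] + cur_vec * bg[b]
    }
    cur_vec <- nv; cur_min <- new_min
  }
  pv <- rev(cumsum(rev(cur_vec)))
  pv <- pmin(pv, 1)
  list(min = cur_min, pv = pv)
}

pval_at <- function(pvd, s) {
  i <- s - pvd$min + 1L
  i <- pmin(pmax(i, 1L), length(pvd$pv))
  out <- pvd$pv[i]
  out[s > pvd$min + length(pvd$pv) - 1L] <- 0
  out[s < pvd$min] <- 1
  out
}

# score all windows of encoded sequence against an integer matrix
window_scores <- function(code, ism) {
  w <- nrow(ism); n <- length(code)
  if (n < w) return(integer(0))
  m <- n - w + 1L
  sc <- rep(0L, m)
  na <- rep(FALSE, m)
  for (j in seq_len(w)) {
    vj <- ism[j, ][code[j:(j + m - 1L)]]
    nas <- is.na(vj)
    if (any(nas)) { na <- na | nas; vj[nas] <- 0L }
    sc <- sc + vj
  }
  sc[na] <- NA_integer_
  sc
}

# per-motif scan cache: discretised matrices and exact p-value tables for
# both strands, computed once and reused across sequences
motif_scan_cache <- function(motif, resolution = 0.01) {
  w <- nrow(motif$matrix)
  ism <- motif_int_scores(motif, resolution)
  rc <- ism[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
  colnames(rc) <- BASES
  list(motif_id = motif$motif_id, w = w, resolution = resolution,
       mats = list("+" = ism, "-" = rc),
       pvds = list("+" = motif_score_pvalues(ism, motif$background),
                   "-" = motif_score_pvalues(rc, motif$background)))
}

scan_encoded <- function(code, cache, p_threshold, both_strands = TRUE) {
  w <- cache$w
  empty <- data.frame(start = integer(), end = integer(), motif_id = character(),
                      strand = character(), score = numeric(), p_value = numeric())
  if (length(code) < w) return(empty)
  out <- list()
  for (st in if (both_strands) c("+", "-") else "+") {
    sc <- window_scores(code, cache$mats[[st]])
    ok <- which(!is.na(sc))
    if (!length(ok)) next
    pv <- pval_at(cache$pvds[[st]], sc[ok])
    keep <- pv <= p_threshold
    hit <- ok[keep]
    if (!length(hit)) next
    out[[st]] <- data.frame(start = hit - 1L, end = hit - 1L + w,
                            motif_id = cache$motif_id, strand = st,
                            score = sc[hit] * cache$resolution,
                            p_value = pv[keep])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a sequence for occurrences of a motif
#'
#' Log-odds scan of both strands. A window is reported as a hit iff the
#' exact word-probability p-value of its score — computed from the full
#' score distribution over all words under the background, by
#' position-wise convolution on a discretised score grid — is at most
#' `p_threshold`. Windows containing non-ACGT characters are skipped.
#' Overlapping hits (including the same interval on both strands of a
#' palindromic motif) are all reported; no deduplication.
#'
#' @param sequence a single DNA string.
#' @param motif a motif model (see [read_meme()]).
#' @param p_threshold hit p-value threshold (default 1e-4).
#' @param both_strands scan the minus strand too (default TRUE).
#' @param resolution score grid resolution in bits (default 0.01).
#' @return data.frame of hits: `start`, `end` (0-based half-open on the
#'   forward strand), `motif_id`, `strand`, `score` (bits), `p_value`.
#' @export
scan_motif <- function(sequence, motif, p_threshold = 1e-4, both_strands = TRUE,
                       resolution = 0.01) {
  scan_encoded(encode_dna(sequence), motif_scan_cache(motif, resolution),
               p_threshold, both_strands)
}

#' Scan genomic regions with a motif library
#'
#' @param genome named character vector of sequences.
#' @param regions interval table; each region's sequence is scanned
#'   (uppercased, so soft-masking does not suppress hits).
#' @param motifs list of motif models.
#' @inheritParams scan_motif
#' @return data.frame of hits in genome coordinates with a `region` column
#'   (row index of the containing region).
#' @export
scan_regions <- function(genome, regions, motifs, p_threshold = 1e-4,
                         both_strands = TRUE, resolution = 0.01) {
  seqs <- interval_seq(genome, regions)
  caches <- lapply(motifs, motif_scan_cache, resolution = resolution)
  out <- list()
  for (r in seq_along(seqs)) {
    code <- encode_dna(seqs[r])
    for (m in caches) {
      h <- scan_encoded(code, m, p_threshold, both_strands)
      if (nrow(h)) {
        h$start <- h$start + regions$start[r]
        h$end <- h$end + regions$start[r]
        h$seq <- regions$seq[r]
        h$region <- r
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(seq = character(), start = integer(), end = integer(),
                      motif_id = character(), strand = character(),
                      score = numeric(), p_value = numeric(), region = integer()))
  res <- do.call(rbind, out)
  res <- res[, c("seq", "start", "end", "motif_id", "strand", "score",
                 "p_value", "region")]
  rownames(res) <- NULL
  res
}

#' Sample control regions matched on length, GC and repeat content
#'
#' For each input region, `n_per_region` random regions of identical length
#' are drawn (rejection sampling) whose GC fraction is within `gc_tol` and
#' repeat fraction within `repeat_tol` of the region's own values, and
#' which do not overlap any input region. If a region cannot be matched
#' within `max_attempts` draws, both tolerances are doubled (up to
#' `max_relax` times, each relaxation logged in the result); if placement
#' still fails an error names the region. Uses the global RNG stream —
#' call `set.seed()` for reproducibility.
#'
#' @param regions interval table.
#' @param genome soft-masked genome.
#' @param n_per_region controls per region (default 1).
#' @param gc_tol,repeat_tol matching tolerances (defaults 0.02, 0.05).
#' @param max_attempts rejection draws per tolerance level (default 1000).
#' @param max_relax tolerance doublings allowed (default 4).
#' @return interval table of controls with columns `region` (index of the
#'   matched input region), `gc`, `repeat_frac`, `relaxed` (number of
#'   doublings needed).
#' @export
matched_controls <- function(regions, genome, n_per_region = 1L, gc_tol = 0.02,
                             repeat_tol = 0.05, max_attempts = 1000L,
                             max_relax = 4L) {
  validate_intervals(regions)
  seq_len_v <- nchar(genome)
  gc_t <- gc_fraction(genome, regions)
  rep_t <- repeat_fraction(genome, regions)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    L <- regions$end[r] - regions$start[r]
    ok_seqs <- names(genome)[seq_len_v >= L]
    if (!length(ok_seqs)) stop("no sequence long enough for region ", r)
    wts <- (seq_len_v[ok_seqs] - L + 1)
    for (k in seq_len(n_per_region)) {
      placed <- FALSE
      for (relax in 0:max_relax) {
        g_tol <- gc_tol * 2^relax; r_tol <- repeat_tol * 2^relax
        for (att in seq_len(max_attempts)) {
          sq <- if (length(ok_seqs) == 1L) ok_seqs else sample(ok_seqs, 1L, prob = wts)
          st <- sample.int(seq_len_v[sq] - L + 1L, 1L) - 1L
          if (any(regions$seq == sq & regions$start < st + L & regions$end > st))
            next
          s <- substr(genome[[sq]], st + 1L, st + L)
          gcs <- nchar(gsub("[^GCgc]", "", s)) / L
          if (abs(gcs - gc_t[r]) > g_tol) next
          rps <- nchar(gsub("[^acgtn]", "", s)) / L
          if (abs(rps - rep_t[r]) <= r_tol) {
            out[[length(out) + 1L]] <- data.frame(
              seq = sq, start = st, end = st + L, region = r, gc = gcs,
              repeat_frac = rps, relaxed = relax)
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed)
        stop("could not place a matched control for region ", r,
             " even after relaxing tolerances")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif overrepresentation in regions vs matched controls
#'
#' Per motif, the observed count is the total number of hits in the
#' regions; the expectation is the control hit count scaled by total base
#' pairs, `lambda = control_hits * region_bp / control_bp`; the p-value is
#' the Poisson upper tail `P(X >= observed)`, Bonferroni-corrected over all
#' motifs tested. A zero lambda with a positive observed count is floored
#' at `lambda_floor` and flagged.
#'
#' @param regions,controls interval tables (controls from
#'   [matched_controls()]).
#' @param genome genome the intervals refer to.
#' @param motifs motif library.
#' @param p_threshold scan hit threshold (default 1e-4).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param lambda_floor floor for a degenerate zero expectation (1e-9).
#' @inheritParams scan_motif
#' @return data.frame: `motif_id`, `observed`, `expected`, `p_value`,
#'   `p_adjusted`, `enriched`, `lambda_floored`.
#' @export
motif_enrichment <- function(regions, controls, genome, motifs,
                             p_threshold = 1e-4, alpha = 0.05,
                             lambda_floor = 1e-9, resolution = 0.01) {
  ids <- vapply(motifs, `[[`, "", "motif_id")
  rh <- scan_regions(genome, regions, motifs, p_threshold, resolution = resolution)
  ch <- scan_regions(genome, controls, motifs, p_threshold, resolution = resolution)
  region_bp <- sum(interval_length(regions))
  control_bp <- sum(interval_length(controls))
  obs <- as.integer(table(factor(rh$motif_id, levels = ids)))
  ctl <- as.integer(table(factor(ch$motif_id, levels = ids)))
  lambda <- ctl * region_bp / control_bp
  floored <- lambda == 0 & obs > 0
  lambda[floored] <- lambda_floor
  p <- ifelse(obs == 0, 1, stats::ppois(obs - 1, lambda, lower.tail = FALSE))
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  data.frame(motif_id = ids, observed = obs, expected = ctl * region_bp / control_bp,
             p_value = p, p_adjusted = p_adj, enriched = p_adj <= alpha,
             lambda_floored = floored)
}

#' Percentage of overrepresented motifs shared with a reference set
#'
#' @param enriched_rpe character vector of motif ids overrepresented in the
#'   reprogrammed-enhancer set.
#' @param enriched_ref motif ids overrepresented in the reference set.
#' @return `100 * |intersection| / |enriched_rpe|`, or `NA` if
#'   `enriched_rpe` is empty.
#' @export
tfbs_overlap_percentage <- function(enriched_rpe, enriched_ref) {
  if (length(enriched_rpe) == 0L) return(NA_real_)
  100 * length(intersect(enriched_rpe, enriched_ref)) / length(unique(enriched_rpe))
}
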