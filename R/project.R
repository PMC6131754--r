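#' Project an interval through pairwise alignment chains
#'
#' Among the chains whose reference span overlaps the interval, the single
#' highest-scoring chain is used (no chain stitching); ties are broken by
#' lower reference start, then chain id. Every reference base of the
#' interval that falls inside an aligned block is mapped to its query base;
#' the result is the minimal query interval spanning the mapped bases,
#' together with the count of aligned bases. If no base maps, the interval
#' has no ortholog and `NULL` is returned — absence is a value, not an
#' error.
#'
#' @param interval a one-row interval table (or list with `seq`, `start`,
#'   `end`).
#' @param chains list of chains from [read_chain()].
#' @return `NULL`, or a list with `seq`, `start`, `end` (forward-strand,
#'   0-based half-open on the query), `aligned` (number of mapped bases),
#'   `strand` (query strand of the chain used) and `chain_id`.
#' @export
project_interval <- function(interval, chains) {
  s <- interval$seq[1]; a <- interval$start[1]; b <- interval$end[1]
  cand <- Filter(function(ch) ch$ref_seq == s && ch$ref_start < b && ch$ref_end > a,
                 chains)
  if (length(cand) == 0L) return(NULL)
  sc <- vapply(cand, `[[`, 0, "score")
  rs <- vapply(cand, `[[`, 0, "ref_start")
  id <- vapply(cand, `[[`, "", "id")
  best <- cand[[order(-sc, rs, id)[1]]]
  project_through_chain(a, b, best)
}

# map [a, b) through one chain; NULL if no base aligns
project_through_chain <- function(a, b, ch) {
  blk <- ch$blocks
  lo <- pmax(blk[, "ref_start"], a)
  hi <- pmin(blk[, "ref_start"] + blk[, "size"], b)
  keep <- hi > lo
  if (!any(keep)) return(NULL)
  lo <- lo[keep]; hi <- hi[keep]
  qb <- blk[keep, "query_start", drop = FALSE][, 1]
  rb <- blk[keep, "ref_start", drop = FALSE][, 1]
  sz <- blk[keep, "size", drop = FALSE][, 1]
  if (ch$query_strand == "-") {
    # within a block, ref base r maps to query_start + size - 1 - (r - ref_start)
    q_lo <- qb + (rb + sz) - hi
    q_hi <- qb + (rb + sz) - lo
  } else {
    q_lo <- qb + (lo - rb)
    q_hi <- qb + (hi - rb)
  }
  list(seq = ch$query_seq, start = min(q_lo), end = max(q_hi),
       aligned = sum(hi - lo), strand = ch$query_strand, chain_id = ch$id)
}

#' Project many intervals through chains
#'
#' @param x interval table.
#' @param chains list of chains.
#' @return data.frame with one row per input: `ortho_seq`, `ortho_start`,
#'   `ortho_end`, `aligned` (0 and `NA` coordinates when nothing maps),
#'   `ortho_strand`, `chain_id`.
#' @export
project_intervals <- function(x, chains) {
  validate_intervals(x)
  n <- nrow(x)
  out <- data.frame(ortho_seq = rep(NA_character_, n),
                    ortho_start = rep(NA_integer_, n),
                    ortho_end = rep(NA_integer_, n),
                    aligned = rep(0L, n),
                    ortho_strand = rep(NA_character_, n),
                    chain_id = rep(NA_character_, n))
  if (n == 0L) return(out)
  by_seq <- split(chains, vapply(chains, `[[`, "", "ref_seq"))
  for (i in seq_len(n)) {
    p <- project_interval(x[i, ], by_seq[[x$seq[i]]] %||% list())
    if (!is.null(p)) {
      out$ortho_seq[i] <- p$seq; out$ortho_start[i] <- p$start
      out$ortho_end[i] <- p$end; out$aligned[i] <- p$aligned
      out$ortho_strand[i] <- p$strand; out$chain_id[i] <- p$chain_id
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
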