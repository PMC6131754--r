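#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based, half-open: an interval
#' covers bases `start .. end - 1` and has length `end - start`.
#' Conversions to and from 1-based formats happen only at I/O boundaries.
#'
#' @param seq character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further per-interval columns (e.g. `tissue`, `id`), recycled.
#' @return a `data.frame` with columns `seq`, `start`, `end` and any extras.
#' @export
genomic_intervals <- function(seq, start, end, ...) {
  x <- data.frame(seq = as.character(seq), start = as.integer(start),
                  end = as.integer(end), ..., stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("seq", "start", "end") %in% names(x)))
  if (any(is.na(x$start) | is.na(x$end)))
    stop("interval coordinates must not be NA")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  invisible(x)
}

#' Interval lengths in base pairs
#' @param x an interval table.
#' @export
interval_length <- function(x) x$end - x$start

# internal: 0-based half-open table -> GRanges (1-based closed)
as_gr0 <- function(x) {
  GenomicRanges::GRanges(x$seq, IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Do two intervals overlap by at least `min_bp` bases?
#'
#' Overlap length is `min(a.end, b.end) - max(a.start, b.start)`;
#' intervals on different sequences never overlap. Vectorised over rows.
#'
#' @param a,b interval tables (recycled row-wise to a common length).
#' @param min_bp minimum overlap in bp (default 50, the intersection
#'   threshold used for every region-overlap decision in the pipeline).
#' @return logical vector.
#' @export
intervals_overlap <- function(a, b, min_bp = 50L) {
  stopifnot(min_bp >= 1)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  a$seq[ai] == b$seq[bi] & ov >= min_bp
}

#' Find all query/subject interval pairs overlapping by at least `min_bp`
#'
#' @param query,subject interval tables.
#' @param min_bp minimum overlap in bp.
#' @return data.frame with columns `query`, `subject` (row indices) and
#'   `overlap` (bp).
#' @export
find_interval_overlaps <- function(query, subject, min_bp = 50L) {
  stopifnot(min_bp >= 1)
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer(), overlap = integer()))
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(as_gr0(query), as_gr0(subject),
                                minoverlap = as.integer(min_bp)),
    warning = function(w) {
      # disjoint sequence name sets are a legitimate "no overlap" case
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) - pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, overlap = as.integer(ov))
}
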