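#' Categorise binding sites of an orthologous enhancer pair
#'
#' Each source-side motif hit is assigned one of four evolutionary
#' categories by projecting it through the alignment chain of the enhancer
#' pair:
#' \describe{
#'   \item{TFBSC (conserved)}{the site maps (at least `min_mapped_fraction`
#'     of its bases project) onto a destination hit of the same motif
#'     (>= 1 bp positional overlap after projection);}
#'   \item{TFBSR (reused)}{the site maps onto a destination hit of a
#'     different motif — mutations have rewired the site for another
#'     factor;}
#'   \item{TFBSH (reshuffled)}{the site does not overlap a destination hit
#'     positionally, but the same motif occurs elsewhere in the destination
#'     enhancer;}
#'   \item{TFBSG (gained)}{the motif has no occurrence in the destination
#'     enhancer (or, for an unmapped site, no occurrence anywhere in it).}
#' }
#' Precedence is TFBSC > TFBSR > TFBSH > TFBSG: mapping evidence outranks
#' mere presence. Gains are reference-relative — swapping source and
#' destination measures the destination side's gains.
#'
#' @param hits_src,hits_dst hit tables (as from [scan_regions()]) restricted
#'   to one orthologous enhancer pair; `hits_dst` coordinates are on the
#'   destination species.
#' @param chains alignment chains covering the pair (source as reference).
#' @param min_mapped_fraction fraction of site bases that must project for
#'   the site to count as mapped (default 0.5).
#' @return `hits_src` with an added `category` column; deterministic and
#'   independent of input row order.
#' @export
categorize_sites <- function(hits_src, hits_dst, chains, min_mapped_fraction = 0.5) {
  n <- nrow(hits_src)
  out <- hits_src
  out$category <- rep(NA_character_, n)
  if (n == 0L) return(out)
  dst_motifs <- unique(hits_dst$motif_id)
  for (i in seq_len(n)) {
    h <- hits_src[i, ]
    w <- h$end - h$start
    p <- project_interval(h, chains)
    mapped <- !is.null(p) && p$aligned / w >= min_mapped_fraction
    cat <- NA_character_
    if (mapped && nrow(hits_dst)) {
      pr <- data.frame(seq = p$seq, start = p$start, end = p$end)
      ov <- find_interval_overlaps(pr, hits_dst, min_bp = 1L)
      if (nrow(ov)) {
        same <- any(hits_dst$motif_id[ov$subject] == h$motif_id)
        cat <- if (same) "TFBSC" else "TFBSR"
      }
    }
    if (is.na(cat))
      cat <- if (h$motif_id %in% dst_motifs) "TFBSH" else "TFBSG"
    out$category[i] <- cat
  }
  out
}

#' Binding-site density in sites per kb
#'
#' @param n_sites number of sites.
#' @param length_bp enhancer length in bp (> 0).
#' @return `1000 * n_sites / length_bp`.
#' @export
site_density <- function(n_sites, length_bp) {
  stopifnot(all(length_bp > 0))
  1000 * n_sites / length_bp
}

SITE_CATEGORIES <- c("TFBSC", "TFBSH", "TFBSG", "TFBSR")

#' Pooled per-category site densities over a set of enhancer pairs
#'
#' @param categorized list of categorised hit tables (one per enhancer
#'   pair, from [categorize_sites()]).
#' @param lengths_bp source-enhancer lengths, parallel to `categorized`.
#' @param per_enhancer if TRUE return the mean of per-enhancer densities
#'   instead of pooled counts over pooled length (default FALSE: pooled).
#' @return named numeric vector of densities for TFBSC, TFBSH, TFBSG,
#'   TFBSR (sites per kb).
#' @export
category_densities <- function(categorized, lengths_bp, per_enhancer = FALSE) {
  stopifnot(length(categorized) == length(lengths_bp))
  counts <- vapply(categorized, function(h)
    as.integer(table(factor(h$category, levels = SITE_CATEGORIES))),
    integer(4))
  if (length(categorized) == 0L)
    return(stats::setNames(rep(NA_real_, 4), SITE_CATEGORIES))
  counts <- matrix(counts, nrow = 4)
  if (per_enhancer) {
    d <- sweep(counts, 2, lengths_bp, "/") * 1000
    stats::setNames(rowMeans(d), SITE_CATEGORIES)
  } else {
    stats::setNames(1000 * rowSums(counts) / sum(lengths_bp), SITE_CATEGORIES)
  }
}

#' Compare per-category site densities between RPEs and FCEs
#'
#' For each tissue pair and site category, the RPE density is judged
#' `"higher"`, `"lower"` or `"equal"` relative to the FCE density;
#' `"equal"` means a relative difference within `tolerance` (default 1%,
#' since exact equality is measure-zero for continuous densities).
#'
#' @param rpe_densities,fce_densities numeric matrices, tissue pairs in
#'   rows (rownames = pair ids) and the four categories in columns; rows
#'   must correspond. Pairs with any non-finite FCE density are skipped and
#'   listed in `skipped`.
#' @param tolerance relative-difference threshold for `"equal"`.
#' @return list with `verdicts` (tissue pair x category character matrix)
#'   and `summary` (fraction of tissue pairs with each verdict per
#'   category) and `skipped` (character vector of skipped pair ids).
#' @export
compare_rpe_fce <- function(rpe_densities, fce_densities, tolerance = 0.01) {
  stopifnot(identical(dim(rpe_densities), dim(fce_densities)))
  ok <- apply(is.finite(fce_densities) & is.finite(rpe_densities), 1, all)
  skipped <- rownames(rpe_densities)[!ok]
  r <- rpe_densities[ok, , drop = FALSE]
  f <- fce_densities[ok, , drop = FALSE]
  denom <- pmax(abs(f), .Machine$double.eps)
  rel <- (r - f) / denom
  verdict <- ifelse(abs(rel) <= tolerance, "equal",
                    ifelse(rel > 0, "higher", "lower"))
  summary <- sapply(colnames(verdict) %||% seq_len(ncol(verdict)), function(j) {
    v <- verdict[, j]
    c(higher = mean(v == "higher"), lower = mean(v == "lower"),
      equal = mean(v == "equal"))
  })
  list(verdicts = verdict, summary = summary, skipped = skipped)
}
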