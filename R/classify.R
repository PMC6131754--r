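#' Re-centre peak intervals to a fixed width
#'
#' Destination-species enhancer calls are distributed as peak locations;
#' each is replaced by a `width`-bp interval centred on the peak midpoint
#' (`floor((start + end) / 2)`). Intervals running past the sequence start
#' are clipped (and flagged), so their length may fall short of `width`.
#'
#' @param x interval table.
#' @param width target width in bp (default 1000).
#' @param seq_lengths optional named vector of sequence lengths for clipping
#'   at the right end.
#' @return interval table with re-centred coordinates and a logical
#'   `clipped` column.
#' @export
center_to_fixed_width <- function(x, width = 1000L, seq_lengths = NULL) {
  stopifnot(width >= 1)
  validate_intervals(x)
  centre <- (x$start + x$end) %/% 2L
  start <- centre - width %/% 2L
  end <- centre + as.integer(ceiling(width / 2))
  clipped <- start < 0L
  start[start < 0L] <- 0L
  if (!is.null(seq_lengths)) {
    lim <- seq_lengths[x$seq]
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  out <- x
  out$start <- as.integer(start); out$end <- as.integer(end)
  out$clipped <- clipped
  out
}

#' Filter enhancers on length and repeat content
#'
#' An enhancer is kept iff its length is at most `max_length` bp (stretch/
#' super-enhancers removed) and at most a fraction `max_repeat_fraction` of
#' its bases are soft-masked. Both thresholds are inclusive: the removal
#' rules are "longer than" and "more than", so exact boundary values stay.
#'
#' @param x interval table.
#' @param genome soft-masked genome (named character vector).
#' @param max_length maximum length in bp (default 3000).
#' @param max_repeat_fraction maximum repeat fraction (default 0.75).
#' @return list with `kept` (interval table) and `rejected` (interval table
#'   with a `reason` column, `"length"` or `"repeat"`).
#' @export
filter_enhancers <- function(x, genome, max_length = 3000L, max_repeat_fraction = 0.75) {
  validate_intervals(x)
  len_ok <- interval_length(x) <= max_length
  rep_frac <- repeat_fraction(genome, x)
  rep_ok <- rep_frac <= max_repeat_fraction
  keep <- len_ok & rep_ok
  rejected <- x[!keep, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(!len_ok[!keep], "length", "repeat")
  list(kept = x[keep, , drop = FALSE], rejected = rejected)
}

#' Collapse per-tissue enhancer sets into records with tissue sets
#'
#' The same interval listed under several tissues becomes one record active
#' in all of them (per-tissue tallies later re-count it once per tissue).
#'
#' @param x interval table with a `tissue` column.
#' @return interval table with a list-column `tissues` and an `id` column.
#' @export
enhancer_records <- function(x) {
  validate_intervals(x)
  stopifnot("tissue" %in% names(x))
  key <- paste(x$seq, x$start, x$end, sep = ":")
  tis <- lapply(split(x$tissue, key), function(t) sort(unique(t)))
  first <- !duplicated(key)
  out <- x[first, c("seq", "start", "end"), drop = FALSE]
  out$tissues <- unname(tis[key[first]])
  out$id <- paste0("enh_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Genome-wide FCE/RPE/EG classification
#'
#' Each source enhancer is projected to the other species through the best
#' overlapping chain and its ortholog overlapped (>= `min_overlap` bp) with
#' the destination per-tissue enhancer sets. Precedence:
#' \enumerate{
#'   \item no base projects: EG (no alignable ortholog);
#'   \item the ortholog overlaps a destination enhancer in at least one
#'     tissue in which the source enhancer is not active: RPE, with
#'     `reprogrammed_to` = those tissues;
#'   \item the ortholog overlaps destination enhancers only in shared
#'     tissues: FCE;
#'   \item the ortholog overlaps nothing: EG.
#' }
#'
#' @param records source records ([enhancer_records()] output: interval
#'   table with a `tissues` list-column).
#' @param dst destination enhancer table with a `tissue` column.
#' @param chains alignment chains (source as reference).
#' @param min_overlap minimum overlap in bp (default 50).
#' @return `records` with added columns: `category` (FCE/RPE/EG),
#'   `reprogrammed_to` (list-column), `ortho_seq`/`ortho_start`/`ortho_end`,
#'   `aligned`.
#' @export
classify_genome_wide <- function(records, dst, chains, min_overlap = 50L) {
  stopifnot(is.list(records$tissues), "tissue" %in% names(dst))
  src_tis <- unique(unlist(records$tissues))
  if (length(setdiff(src_tis, unique(dst$tissue))))
    stop("tissue label(s) absent from destination sets: ",
         paste(setdiff(src_tis, unique(dst$tissue)), collapse = ", "))
  proj <- project_intervals(records, chains)
  out <- cbind(records, proj[c("ortho_seq", "ortho_start", "ortho_end", "aligned")])
  n <- nrow(out)
  out$category <- rep("EG", n)
  out$reprogrammed_to <- rep(list(character()), n)
  has <- which(proj$aligned > 0L)
  if (length(has)) {
    pr <- data.frame(seq = proj$ortho_seq[has], start = proj$ortho_start[has],
                     end = proj$ortho_end[has])
    hits <- find_interval_overlaps(pr, dst, min_bp = min_overlap)
    tissues_hit <- lapply(split(dst$tissue[hits$subject], hits$query),
                          function(t) sort(unique(t)))
    for (k in names(tissues_hit)) {
      i <- has[as.integer(k)]
      novel <- setdiff(tissues_hit[[k]], out$tissues[[i]])
      if (length(novel)) {
        out$category[i] <- "RPE"
        out$reprogrammed_to[[i]] <- novel
      } else out$category[i] <- "FCE"
    }
  }
  out
}

#' Tissue-pair enhancer classification
#'
#' Implements the tissue-pair set algebra. For tissues A and B in the
#' source species and their orthologous destination tissues:
#' \enumerate{
#'   \item within each species, enhancers shared between the two tissues
#'     (overlapping by >= `share_min_bp`) are dropped, leaving the
#'     tissue-exclusive subsets A1/B1;
#'   \item A1/B1 of the source are projected through the chains; enhancers
#'     with no alignable ortholog are EGs;
#'   \item projected source enhancers overlapping (>= `min_overlap` bp) the
#'     same-tissue destination subset are FCEs; the matched destination
#'     enhancers are removed, leaving the destination remainders A2/B2;
#'   \item remaining projected source-A enhancers overlapping the
#'     destination-B remainder are reprogrammed (source tissue A ->
#'     destination tissue B), and symmetrically for source B;
#'   \item everything left joins the EGs.
#' }
#'
#' @param a_src,b_src source-species interval tables for tissues A and B.
#' @param a_dst,b_dst destination-species tables for the orthologous tissues.
#' @param chains alignment chains (source as reference).
#' @param min_overlap cross-species overlap threshold in bp (default 50).
#' @param share_min_bp within-species overlap (in bp) that marks an enhancer
#'   as shared between the two tissues in step 1 (default 1: the exclusive
#'   subsets are strictly non-overlapping).
#' @return list with per-enhancer tables `a` and `b` (the exclusive source
#'   subsets plus `category` and ortholog columns), the destination
#'   exclusive subsets `a1_dst`/`b1_dst`, index vectors of the destination
#'   rows matched as FCEs, and `counts`, a named summary.
#' @export
classify_tissue_pair <- function(a_src, b_src, a_dst, b_dst, chains,
                                 min_overlap = 50L, share_min_bp = 1L) {
  excl <- function(x, y) {
    if (nrow(x) == 0L || nrow(y) == 0L) return(x)
    sh <- unique(find_interval_overlaps(x, y, min_bp = share_min_bp)$query)
    x[setdiff(seq_len(nrow(x)), sh), , drop = FALSE]
  }
  a1s <- excl(a_src, b_src); b1s <- excl(b_src, a_src)
  a1d <- excl(a_dst, b_dst); b1d <- excl(b_dst, a_dst)

  side <- function(src1, same_dst) {
    n <- nrow(src1)
    res <- src1
    res$category <- rep("EG", n)
    proj <- project_intervals(src1, chains)
    res <- cbind(res, proj[c("ortho_seq", "ortho_start", "ortho_end", "aligned")])
    ali <- which(proj$aligned > 0L)
    fce_dst <- integer()
    if (length(ali)) {
      pr <- data.frame(seq = proj$ortho_seq[ali], start = proj$ortho_start[ali],
                       end = proj$ortho_end[ali])
      h1 <- find_interval_overlaps(pr, same_dst, min_bp = min_overlap)
      fce <- ali[unique(h1$query)]
      res$category[fce] <- "FCE"
      fce_dst <- sort(unique(h1$subject))
      rem <- setdiff(ali, fce)                       # alignable, not FCE
      res$.rem <- seq_len(n) %in% rem
    } else res$.rem <- rep(FALSE, n)
    list(res = res, fce_dst = fce_dst)
  }
  sa <- side(a1s, a1d)
  sb <- side(b1s, b1d)
  a2d_idx <- setdiff(seq_len(nrow(a1d)), sa$fce_dst)  # dst-A remainder after FCE matching
  b2d_idx <- setdiff(seq_len(nrow(b1d)), sb$fce_dst)

  cross <- function(res, cross_dst_rows) {
    rem <- which(res$.rem)
    if (length(rem) && nrow(cross_dst_rows)) {
      pr <- data.frame(seq = res$ortho_seq[rem], start = res$ortho_start[rem],
                       end = res$ortho_end[rem])
      h <- find_interval_overlaps(pr, cross_dst_rows, min_bp = min_overlap)
      res$category[rem[unique(h$query)]] <- "RPE"
    }
    res$.rem <- NULL
    res
  }
  a_res <- cross(sa$res, b1d[b2d_idx, , drop = FALSE])
  b_res <- cross(sb$res, a1d[a2d_idx, , drop = FALSE])

  list(a = a_res, b = b_res,
       a1_dst = a1d, b1_dst = b1d,
       fce_dst_a = sa$fce_dst, fce_dst_b = sb$fce_dst,
       counts = c(a_total = nrow(a_res), b_total = nrow(b_res),
                  a_fce = sum(a_res$category == "FCE"),
                  b_fce = sum(b_res$category == "FCE"),
                  a_rpe = sum(a_res$category == "RPE"),
                  b_rpe = sum(b_res$category == "RPE"),
                  a_eg = sum(a_res$category == "EG"),
                  b_eg = sum(b_res$category == "EG"),
                  a_shared_dropped = nrow(a_src) - nrow(a_res),
                  b_shared_dropped = nrow(b_src) - nrow(b_res)))
}

#' Cumulative reprogramming rate for one tissue
#'
#' The fraction of a tissue's classified enhancers that are RPEs.
#'
#' @param records classified records ([classify_genome_wide()] output).
#' @param tissue tissue label.
#' @return fraction in `[0, 1]`, or `NA` if no record is active in the
#'   tissue.
#' @export
reprogramming_rate <- function(records, tissue) {
  act <- vapply(records$tissues, function(t) tissue %in% t, TRUE)
  if (!any(act)) return(NA_real_)
  sum(records$category[act] == "RPE") / sum(act)
}

#' Reprogramming rate from published per-tissue count tables
#'
#' @param n_rpe number of RPEs in the tissue.
#' @param n_total number of classified enhancers in the tissue.
#' @return fraction `n_rpe / n_total`, or `NA` if `n_total` is zero.
#' @export
reprogramming_rate_from_counts <- function(n_rpe, n_total) {
  ifelse(n_total > 0, n_rpe / n_total, NA_real_)
}

#' Per-tissue enhancer category counts for an 11-tissue two-species study
#'
#' Published tally of enhancers assigned to 11 orthologous human and mouse
#' tissues, with the human-side breakdown into gains (EG), functionally
#' conserved (FCE) and reprogrammed (RPE) enhancers. Bundled as the input
#' for the per-tissue rate arithmetic.
#'
#' @return data.frame with columns `tissue`, `human_enhancers`,
#'   `mouse_enhancers`, `human_eg`, `human_fce`, `human_rpe`.
#' @export
tissue_enhancer_counts <- function() {
  path <- system.file("extdata", "tissue_enhancer_counts.tsv",
                      package = "enhancerReprog", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
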