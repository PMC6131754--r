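#' Build midpoint-bounded gene loci
#'
#' The boundary between two consecutive genes on a sequence sits at the
#' midpoint of the intergenic gap (half the distance between the end of a
#' gene and the start of the next); the first and last locus extend to the
#' sequence ends. Loci therefore tile each sequence exactly. If two
#' consecutive genes overlap, the boundary is placed at the midpoint of the
#' overlap.
#'
#' @param genes interval table with a `gene` column of unique ids.
#' @param seq_lengths named vector of sequence lengths.
#' @return data.frame: `gene`, `seq`, `gene_start`, `gene_end`,
#'   `locus_start`, `locus_end`.
#' @export
build_loci <- function(genes, seq_lengths) {
  validate_intervals(genes)
  stopifnot("gene" %in% names(genes), !anyDuplicated(genes$gene))
  if (any(genes$end > seq_lengths[genes$seq]))
    stop("gene beyond sequence length")
  out <- list()
  for (sq in unique(genes$seq)) {
    g <- genes[genes$seq == sq, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    if (n == 1L) {
      bounds <- c(0L, seq_lengths[[sq]])
    } else {
      mids <- as.integer(floor((g$end[-n] + g$start[-1]) / 2))
      bounds <- c(0L, mids, seq_lengths[[sq]])
    }
    out[[sq]] <- data.frame(gene = g$gene, seq = sq,
                            gene_start = g$start, gene_end = g$end,
                            locus_start = bounds[-length(bounds)],
                            locus_end = bounds[-1])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign enhancers to gene loci
#'
#' An enhancer belongs to a locus if it overlaps it by at least `min_bp`;
#' an enhancer straddling a boundary goes to the locus with the larger
#' overlap (ties to the lower-coordinate locus).
#'
#' @param loci loci table from [build_loci()].
#' @param records enhancer interval table.
#' @param min_bp minimum overlap (default 50).
#' @return integer vector, for each record the row index of its locus in
#'   `loci` (`NA` if none).
#' @export
assign_to_loci <- function(loci, records, min_bp = 50L) {
  lint <- data.frame(seq = loci$seq, start = loci$locus_start, end = loci$locus_end)
  ov <- find_interval_overlaps(records, lint, min_bp = min_bp)
  out <- rep(NA_integer_, nrow(records))
  if (nrow(ov)) {
    ov <- ov[order(ov$query, -ov$overlap, ov$subject), , drop = FALSE]
    first <- ov[!duplicated(ov$query), , drop = FALSE]
    out[first$query] <- first$subject
  }
  out
}

#' Median-normalize an expression table
#'
#' Each tissue column is divided by its median over all genes (missing
#' values ignored). Idempotent on tables whose columns already have
#' median 1.
#'
#' @param m gene-by-tissue numeric matrix.
#' @return matrix of the same shape.
#' @export
normalize_expression <- function(m) {
  stopifnot(is.matrix(m), nrow(m) > 0)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med) | med == 0))
    stop("zero or undefined median in tissue(s): ",
         paste(colnames(m)[!is.finite(med) | med == 0], collapse = ", "))
  sweep(m, 2, med, "/")
}

#' Expression shift at genes flanking reprogrammed enhancers
#'
#' Selects the genes whose locus contains at least one RPE of a given
#' tissue-pair reprogramming set and compares their expression between the
#' novel tissue B and the original tissue A: the statistic is the ratio of
#' median expression (B over A) and the p-value a one-sided Wilcoxon
#' rank-sum test of B > A.
#'
#' @param rpe_records interval table of the RPEs of the (A -> B) set.
#' @param loci loci table.
#' @param expression gene-by-tissue matrix (already normalized if desired).
#' @param tissue_a,tissue_b column names: original and novel tissue.
#' @param normalize median-normalize `expression` first (default TRUE).
#' @param min_bp locus-assignment overlap threshold.
#' @return list: `fold_change`, `p_value`, `n_genes`, `genes`, `reliable`
#'   (FALSE when fewer than 2 genes were selected).
#' @export
rpe_expression_shift <- function(rpe_records, loci, expression, tissue_a, tissue_b,
                                 normalize = TRUE, min_bp = 50L) {
  stopifnot(all(c(tissue_a, tissue_b) %in% colnames(expression)))
  if (normalize) expression <- normalize_expression(expression)
  li <- assign_to_loci(loci, rpe_records, min_bp = min_bp)
  genes <- unique(loci$gene[li[!is.na(li)]])
  genes <- genes[genes %in% rownames(expression)]
  xb <- expression[genes, tissue_b]
  xa <- expression[genes, tissue_a]
  keep <- is.finite(xa) & is.finite(xb)
  xa <- xa[keep]; xb <- xb[keep]
  n <- sum(keep)
  if (n == 0L)
    return(list(fold_change = NA_real_, p_value = NA_real_, n_genes = 0L,
                genes = character(), reliable = FALSE))
  fc <- stats::median(xb) / stats::median(xa)
  p <- if (n >= 2L)
    suppressWarnings(stats::wilcox.test(xb, xa, alternative = "greater",
                                        correct = TRUE)$p.value)
  else NA_real_
  list(fold_change = fc, p_value = p, n_genes = n, genes = genes[keep],
       reliable = n >= 2L)
}

#' Bin gene loci by enhancer count
#'
#' @param loci loci table.
#' @param records classified enhancer records (with `category`).
#' @param expression gene-by-tissue matrix.
#' @param tissue tissue whose expression to summarise.
#' @param max_bin loci with more enhancers than this are pooled into the
#'   top bin (default 20).
#' @param min_bp locus-assignment overlap threshold.
#' @return data.frame per bin: `bin`, `n_genes`, `median_expression`,
#'   `frac_rpe`, `frac_fce`, `frac_eg` (category fractions among the bin's
#'   enhancers; NA for the zero-enhancer bin).
#' @export
bin_by_enhancer_count <- function(loci, records, expression, tissue,
                                  max_bin = 20L, min_bp = 50L) {
  li <- assign_to_loci(loci, records, min_bp = min_bp)
  n_enh <- tabulate(li[!is.na(li)], nbins = nrow(loci))
  bin <- pmin(n_enh, max_bin)
  expr <- expression[, tissue][match(loci$gene, rownames(expression))]
  out <- list()
  for (b in sort(unique(bin))) {
    in_bin <- which(bin == b)
    cats <- records$category[!is.na(li) & bin[li] == b]
    nc <- length(cats)
    out[[length(out) + 1L]] <- data.frame(
      bin = b, n_genes = length(in_bin),
      median_expression = stats::median(expr[in_bin], na.rm = TRUE),
      frac_rpe = if (nc) mean(cats == "RPE") else NA_real_,
      frac_fce = if (nc) mean(cats == "FCE") else NA_real_,
      frac_eg = if (nc) mean(cats == "EG") else NA_real_,
      n_enhancers = nc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Category make-up of single-enhancer loci vs all loci
#'
#' For each enhancer category, a 2x2 table (enhancer in a single-enhancer
#' locus or not) x (enhancer of this category or not) is tested with a
#' two-sided Fisher exact test.
#'
#' @param loci loci table.
#' @param records classified enhancer records.
#' @param min_bp locus-assignment overlap threshold.
#' @return `NULL` if there is no single-enhancer locus, else a data.frame
#'   per category: `category`, `frac_seloci` (category fraction among
#'   single-enhancer-locus enhancers), `frac_all` (among all assigned
#'   enhancers), `odds_ratio`, `p_value`, plus counts.
#' @export
seloci_test <- function(loci, records, min_bp = 50L) {
  li <- assign_to_loci(loci, records, min_bp = min_bp)
  assigned <- which(!is.na(li))
  if (!length(assigned)) return(NULL)
  n_enh <- tabulate(li[assigned], nbins = nrow(loci))
  se_locus <- which(n_enh == 1L)
  if (!length(se_locus)) return(NULL)
  in_se <- li[assigned] %in% se_locus
  cats <- records$category[assigned]
  out <- lapply(c("RPE", "FCE", "EG"), function(cc) {
    is_cat <- cats == cc
    tab <- matrix(c(sum(in_se & is_cat), sum(in_se & !is_cat),
                    sum(!in_se & is_cat), sum(!in_se & !is_cat)), nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(category = cc,
               n_seloci = sum(in_se & is_cat), total_seloci = sum(in_se),
               n_all = sum(is_cat), total_all = length(cats),
               frac_seloci = mean(is_cat[in_se]), frac_all = mean(is_cat),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
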