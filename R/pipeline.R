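#' Invert alignment chains
#'
#' Swaps reference and query so projection can be run in the opposite
#' direction. Works for both query strands (the mapping of a chain is an
#' involution).
#'
#' @param chains list of chains.
#' @return list of chains with roles swapped.
#' @export
invert_chains <- function(chains) {
  lapply(chains, function(ch) {
    b <- ch$blocks[, c("query_start", "ref_start", "size"), drop = FALSE]
    colnames(b) <- c("ref_start", "query_start", "size")
    b <- b[order(b[, "ref_start"]), , drop = FALSE]
    list(id = ch$id, score = ch$score,
         ref_seq = ch$query_seq, ref_size = ch$query_size,
         ref_start = ch$query_start, ref_end = ch$query_end,
         query_seq = ch$ref_seq, query_size = ch$ref_size,
         query_strand = ch$query_strand,
         query_start = ch$ref_start, query_end = ch$ref_end,
         blocks = b)
  })
}

#' Per-tissue category counts shaped like a published tissue table
#'
#' One row per tissue with total, EG, FCE and RPE counts; an enhancer
#' active in several tissues is counted once in each.
#'
#' @param records classified records ([classify_genome_wide()] output).
#' @return data.frame: `tissue`, `n_enhancers`, `n_eg`, `n_fce`, `n_rpe`,
#'   `reprogramming_rate`.
#' @export
summarize_by_tissue <- function(records) {
  tis <- sort(unique(unlist(records$tissues)))
  rows <- lapply(tis, function(t) {
    act <- vapply(records$tissues, function(x) t %in% x, TRUE)
    cats <- records$category[act]
    data.frame(tissue = t, n_enhancers = sum(act),
               n_eg = sum(cats == "EG"), n_fce = sum(cats == "FCE"),
               n_rpe = sum(cats == "RPE"),
               reprogramming_rate = sum(cats == "RPE") / sum(act))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Tissue-pair reprogramming-rate matrix
#'
#' Runs the tissue-pair set algebra for every ordered pair of tissues and
#' reports the fraction of the source tissue's exclusive enhancers
#' reprogrammed to the destination tissue.
#'
#' @param bed_a,bed_b per-tissue interval tables (columns `seq`, `start`,
#'   `end`, `tissue`) for the source and destination species.
#' @param chains chains with the source species as reference.
#' @param min_overlap cross-species overlap threshold.
#' @return matrix; rows = source tissue A, columns = destination tissue B,
#'   entry = rate of (A -> B) reprogramming among A's exclusive enhancers
#'   (NA on the diagonal).
#' @export
reprogramming_rate_matrix <- function(bed_a, bed_b, chains, min_overlap = 50L) {
  tis <- sort(unique(bed_a$tissue))
  m <- matrix(NA_real_, length(tis), length(tis), dimnames = list(tis, tis))
  for (ta in tis) for (tb in tis) {
    if (ta == tb) next
    r <- classify_tissue_pair(bed_a[bed_a$tissue == ta, ],
                              bed_a[bed_a$tissue == tb, ],
                              bed_b[bed_b$tissue == ta, ],
                              bed_b[bed_b$tissue == tb, ],
                              chains, min_overlap = min_overlap)
    m[ta, tb] <- if (r$counts[["a_total"]] > 0)
      r$counts[["a_rpe"]] / r$counts[["a_total"]] else NA_real_
  }
  m
}

#' Binding-site turnover comparison between RPEs and FCEs of a scenario
#'
#' For every ordered tissue pair with at least `min_n` reprogrammed
#' enhancers, pools the per-site categories of the pair's RPEs into
#' per-category densities and compares them with the densities of the
#' functionally conserved enhancers active in the pair's source tissue.
#'
#' @param bundle a [simulate_scenario()] bundle.
#' @param use_truth_sites use the planted site truth table as the hit
#'   lists (zero scanning noise) instead of rescanning sequences.
#' @param p_threshold scan threshold when rescanning.
#' @param min_mapped_fraction see [categorize_sites()].
#' @param min_n minimum RPEs per tissue pair (default 3).
#' @param tolerance relative-difference tolerance for the "equal" verdict.
#' @return list as [compare_rpe_fce()], plus `rpe_densities`,
#'   `fce_densities`, `categorized` (per-enhancer categorised hits).
#' @export
tfbs_turnover_analysis <- function(bundle, use_truth_sites = TRUE,
                                   p_threshold = 1e-4,
                                   min_mapped_fraction = 0.5, min_n = 3L,
                                   tolerance = 0.01) {
  truth <- bundle$truth
  pairs_ok <- truth$category %in% c("FCE", "RPE") & !truth$b_only
  enh <- truth[pairs_ok, ]
  categorized <- vector("list", nrow(enh))
  names(categorized) <- enh$id
  for (k in seq_len(nrow(enh))) {
    e <- enh[k, ]
    if (use_truth_sites) {
      mt <- bundle$motif_truth
      mine <- mt[mt$enh_id == e$id, , drop = FALSE]
      src <- data.frame(seq = mine$a_seq, start = mine$a_start,
                        end = mine$a_end, motif_id = mine$motif_a)
      has_b <- !is.na(mine$b_start)
      dst <- data.frame(seq = mine$b_seq[has_b], start = mine$b_start[has_b],
                        end = mine$b_end[has_b], motif_id = mine$motif_b[has_b])
    } else {
      src <- scan_regions(bundle$genomes$a,
                          data.frame(seq = e$seq, start = e$start, end = e$end),
                          bundle$motifs, p_threshold)
      dst <- scan_regions(bundle$genomes$b,
                          data.frame(seq = e$b_seq, start = e$b_start, end = e$b_end),
                          bundle$motifs, p_threshold)
    }
    categorized[[k]] <- categorize_sites(src, dst, bundle$chains,
                                         min_mapped_fraction = min_mapped_fraction)
  }
  lens <- enh$end - enh$start
  pair_id <- ifelse(enh$category == "RPE",
                    paste(enh$pair_a, enh$pair_b, sep = "->"), NA)
  pairs <- sort(unique(stats::na.omit(pair_id)))
  pairs <- pairs[vapply(pairs, function(p) sum(pair_id == p, na.rm = TRUE) >= min_n, TRUE)]
  if (!length(pairs))
    return(list(verdicts = NULL, summary = NULL, skipped = character(),
                rpe_densities = NULL, fce_densities = NULL,
                categorized = categorized))
  rpe_d <- t(vapply(pairs, function(p) {
    i <- which(!is.na(pair_id) & pair_id == p)
    category_densities(categorized[i], lens[i])
  }, numeric(4)))
  fce_d <- t(vapply(pairs, function(p) {
    ta <- sub("->.*$", "", p)
    i <- which(enh$category == "FCE" &
                 vapply(strsplit(enh$tissues_a, ","), function(x) ta %in% x, TRUE))
    if (!length(i)) return(stats::setNames(rep(NA_real_, 4), SITE_CATEGORIES))
    category_densities(categorized[i], lens[i])
  }, numeric(4)))
  cmp <- compare_rpe_fce(rpe_d, fce_d, tolerance = tolerance)
  c(cmp, list(rpe_densities = rpe_d, fce_densities = fce_d,
              categorized = categorized))
}

#' Expression-shift tests for every reprogramming set of a scenario
#'
#' For each ordered tissue pair with reprogrammed enhancers, tests in the
#' destination species whether genes flanking the pair's RPEs are more
#' highly expressed in the novel tissue than in the source tissue, and
#' the mirrored comparison in the source species.
#'
#' @param bundle a [simulate_scenario()] bundle.
#' @param min_n minimum RPEs per pair (default 3).
#' @param normalize median-normalize the expression tables (default TRUE).
#' @return data.frame per pair: `tissue_a`, `tissue_b`, `n_rpe`,
#'   `fold_b`, `p_b` (destination species, novel vs source tissue),
#'   `fold_a`, `p_a` (source species, source vs novel tissue),
#'   `concordant` (both folds in the planted direction).
#' @export
expression_shift_analysis <- function(bundle, min_n = 3L, normalize = TRUE) {
  truth <- bundle$truth
  rpe <- truth[truth$category == "RPE" & !truth$b_only, ]
  if (!nrow(rpe)) return(NULL)
  key <- paste(rpe$pair_a, rpe$pair_b)
  out <- list()
  for (k in unique(key)) {
    sel <- rpe[key == k, ]
    if (nrow(sel) < min_n) next
    ta <- sel$pair_a[1]; tb <- sel$pair_b[1]
    sh_b <- rpe_expression_shift(sel, bundle$loci, bundle$expression$b,
                                 tissue_a = ta, tissue_b = tb,
                                 normalize = normalize)
    sh_a <- rpe_expression_shift(sel, bundle$loci, bundle$expression$a,
                                 tissue_a = tb, tissue_b = ta,
                                 normalize = normalize)
    out[[k]] <- data.frame(tissue_a = ta, tissue_b = tb, n_rpe = nrow(sel),
                           fold_b = sh_b$fold_change, p_b = sh_b$p_value,
                           fold_a = sh_a$fold_change, p_a = sh_a$p_value,
                           n_genes = sh_b$n_genes,
                           concordant = isTRUE(sh_b$fold_change > 1) &&
                             isTRUE(sh_a$fold_change > 1))
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the whole pipeline on a simulated scenario
#'
#' simulate -> filter -> classify (genome-wide both directions) ->
#' tissue-pair rate matrix -> binding-site turnover -> expression
#' analyses; writes every summary as TSV plus a run manifest. Any stage
#' failure aborts with the stage name; previously written outputs remain.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory.
#' @param use_truth_sites see [tfbs_turnover_analysis()].
#' @return (invisibly) a list with all in-memory results.
#' @export
run_scenario <- function(config, out_dir, use_truth_sites = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  bundle <- stage("simulate", simulate_scenario(config, file.path(out_dir, "data")))

  flt <- stage("filter", filter_enhancers(bundle$records_a, bundle$genomes$a))
  records <- flt$kept

  classified <- stage("classify",
                      classify_genome_wide(records, bundle$bed_b, bundle$chains))
  classified_b <- stage("classify_b", {
    recs_b <- enhancer_records(bundle$bed_b)
    classify_genome_wide(recs_b, bundle$bed_a, invert_chains(bundle$chains))
  })
  tab <- summarize_by_tissue(classified)
  tsv(tab, "tissue_summary_A.tsv")
  tsv(summarize_by_tissue(classified_b), "tissue_summary_B.tsv")
  out_cls <- classified
  out_cls$tissues <- vapply(out_cls$tissues, paste, "", collapse = ",")
  out_cls$reprogrammed_to <- vapply(out_cls$reprogrammed_to, paste, "", collapse = ",")
  tsv(out_cls, "classified_A.tsv")

  rates <- stage("rate_matrix",
                 reprogramming_rate_matrix(bundle$bed_a, bundle$bed_b, bundle$chains))
  tsv(data.frame(tissue_a = rownames(rates), rates, check.names = FALSE),
      "pair_rate_matrix.tsv")

  turn <- stage("tfbs_turnover",
                tfbs_turnover_analysis(bundle, use_truth_sites = use_truth_sites))
  if (!is.null(turn$rpe_densities)) {
    tsv(data.frame(pair = rownames(turn$rpe_densities), turn$rpe_densities,
                   check.names = FALSE), "rpe_site_density.tsv")
    tsv(data.frame(pair = rownames(turn$fce_densities), turn$fce_densities,
                   check.names = FALSE), "fce_site_density.tsv")
    tsv(data.frame(pair = rownames(turn$verdicts), turn$verdicts,
                   check.names = FALSE), "density_verdicts.tsv")
  }

  shifts <- stage("expression", expression_shift_analysis(bundle))
  if (!is.null(shifts)) tsv(shifts, "expression_shift.tsv")
  bins <- stage("bins", bin_by_enhancer_count(bundle$loci, classified,
                                              bundle$expression$a,
                                              tissue = bundle$tissues[1]))
  tsv(bins, "locus_bins.tsv")
  sel <- stage("seloci", seloci_test(bundle$loci, classified))
  if (!is.null(sel)) tsv(sel, "seloci.tsv")

  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(paste(names(config), vapply(config, function(v)
    paste(deparse(v), collapse = " "), ""), sep = " = "), cfg_path)
  manifest <- data.frame(
    key = c("package_version", "seed", "config_md5", "n_records_in",
            "n_records_kept", "n_rejected"),
    value = c(as.character(utils::packageVersion("enhancerReprog")),
              config$seed, unname(tools::md5sum(cfg_path)),
              nrow(bundle$records_a), nrow(records), nrow(flt$rejected)))
  tsv(manifest, "manifest.tsv")

  invisible(list(bundle = bundle, records = records, classified = classified,
                 classified_b = classified_b, tissue_summary = tab,
                 rates = rates, turnover = turn, shifts = shifts, bins = bins,
                 seloci = sel))
}
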