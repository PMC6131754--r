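#' Simulate a complete two-species dataset with planted ground truth
#'
#' Builds both genomes base by base from a colinear segment plan, so the
#' emitted alignment chain is exact by construction. Each species-A
#' enhancer is planted with a category drawn from
#' `config$category_fractions`:
#' \itemize{
#'   \item FCE: the ortholog is a species-B enhancer active in the same
#'     tissue set;
#'   \item RPE: the ortholog is a species-B enhancer active in at least one
#'     tissue absent from the A-side set;
#'   \item EG: half lie in unalignable gaps, half are alignable but have no
#'     enhancer at the orthologous position.
#' }
#' Binding-site events (conserved/gained/reshuffled/reused) are planted
#' into every FCE and RPE pair, with different event profiles for the two
#' categories; genes are laid out along species A, loci built by the
#' midpoint rule, and a `expression_fold_change` shift planted at genes
#' whose locus hosts an RPE. Deterministic given `config$seed` (one RNG
#' stream, sub-generators drawing in a fixed order).
#'
#' @param config a [scenario_config()].
#' @param out_dir if non-NULL, the dataset is also written there as
#'   standard files (FASTA, chain, BED, MEME, TSV), byte-reproducible for
#'   a given config.
#' @return a bundle list: `config`, `genomes` (named character vectors `a`,
#'   `b`), `seq_lengths`, `chains`, `truth` (per-enhancer table), `bed_a`,
#'   `bed_b` (per-tissue interval tables), `records_a` (collapsed A
#'   records), `motifs`, `motif_truth` (per-site table), `genes`, `loci`,
#'   `expression` (list `a`, `b`), `expression_truth`, `files`.
#' @export
simulate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(cfg$seed)
  tissues <- TISSUE_POOL[seq_len(cfg$n_tissues)]

  ## --- per-enhancer plan ------------------------------------------------
  n <- cfg$n_enhancers
  cat_lv <- c("FCE", "RPE", "EG")
  category <- sample(cat_lv, n, replace = TRUE, prob = cfg$category_fractions)
  eg_mode <- ifelse(category == "EG",
                    sample(c("gap", "no_ortholog"), n, replace = TRUE), NA)
  len <- sample(seq(cfg$enhancer_length_range[1], cfg$enhancer_length_range[2]),
                n, replace = TRUE)
  tissues_a <- lapply(seq_len(n), function(i) {
    k <- if (stats::runif(1) < cfg$multi_tissue_prob) 2L else 1L
    sort(sample(tissues, k))
  })
  tissues_b <- vector("list", n)
  pair_a <- pair_b <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (category[i] == "FCE") tissues_b[[i]] <- tissues_a[[i]]
    else if (category[i] == "RPE") {
      novel <- sample(setdiff(tissues, tissues_a[[i]]), 1L)
      keep_shared <- stats::runif(1) < 0.3
      tissues_b[[i]] <- sort(c(novel, if (keep_shared) tissues_a[[i]][1]))
      pair_a[i] <- tissues_a[[i]][1]
      pair_b[i] <- novel
    } else tissues_b[[i]] <- character()
  }
  n_bonly <- round(cfg$b_only_fraction * n)
  bonly_len <- sample(seq(cfg$enhancer_length_range[1], cfg$enhancer_length_range[2]),
                      n_bonly, replace = TRUE)
  bonly_tis <- lapply(seq_len(n_bonly), function(i) sample(tissues, 1L))

  chrom_of <- rep_len(seq_len(cfg$n_sequences), n)
  bonly_chrom <- rep_len(seq_len(cfg$n_sequences), n_bonly)
  motifs <- make_motif_library(cfg$n_motifs, cfg$motif_width)

  truth_rows <- list(); site_rows <- list(); chains <- list()
  genome_a <- character(cfg$n_sequences); genome_b <- character(cfg$n_sequences)
  names(genome_a) <- names(genome_b) <- paste0("chr", seq_len(cfg$n_sequences))

  for (cc in seq_len(cfg$n_sequences)) {
    chrom <- paste0("chr", cc)
    idx_a <- which(chrom_of == cc)
    idx_b <- which(bonly_chrom == cc)
    events <- c(lapply(idx_a, function(i) list(type = "A", i = i)),
                lapply(idx_b, function(i) list(type = "B", i = i)))
    events <- events[sample.int(length(events))]
    n_ev <- length(events)
    occupied <- sum(len[idx_a]) + sum(bonly_len[idx_b])
    mean_spacer <- (cfg$sequence_length - occupied) / (n_ev + 1L)
    if (mean_spacer < 120)
      stop("infeasible packing: ", n_ev, " enhancers do not fit in a ",
           cfg$sequence_length, " bp sequence")

    a_pieces <- character(); b_pieces <- character()
    pos_a <- 0L; pos_b <- 0L
    blocks <- list(); run <- NULL
    close_run <- function() {
      if (!is.null(run)) { blocks[[length(blocks) + 1L]] <<- run; run <<- NULL }
    }
    emit_aligned <- function(aseq, bseq) {
      nb <- nchar(aseq)
      if (nb == 0L) return(invisible())
      stopifnot(nchar(bseq) == nb)
      if (is.null(run)) run <<- c(pos_a, pos_b, 0L)
      run[3] <<- run[3] + nb
      a_pieces[length(a_pieces) + 1L] <<- aseq
      b_pieces[length(b_pieces) + 1L] <<- bseq
      pos_a <<- pos_a + nb; pos_b <<- pos_b + nb
    }
    emit_unaligned <- function(aseq, bseq) {
      close_run()
      if (nchar(aseq)) a_pieces[length(a_pieces) + 1L] <<- aseq
      if (nchar(bseq)) b_pieces[length(b_pieces) + 1L] <<- bseq
      pos_a <<- pos_a + nchar(aseq); pos_b <<- pos_b + nchar(bseq)
    }
    emit_spacer <- function() {
      ls <- max(60L, round(stats::runif(1, 0.6, 1.4) * mean_spacer))
      if (stats::runif(1) < cfg$alignment_coverage) {
        # alignable spacer, possibly broken by small indels
        k <- stats::rbinom(1, ls, cfg$indel_rate)
        cuts <- sort(sample.int(ls, min(k, ls)))
        prev <- 0L
        for (cut in c(cuts, ls)) {
          piece <- mask_repeats(random_dna(cut - prev), cfg$repeat_fraction)
          emit_aligned(piece, mutate_seq(piece, cfg$substitution_rate))
          prev <- cut
          if (cut < ls) {
            sz <- sample(1:5, 1L)
            if (stats::runif(1) < 0.5) emit_unaligned(random_dna(sz), "")
            else emit_unaligned("", random_dna(sz))
          }
        }
      } else {
        lb <- max(60L, round(stats::runif(1, 0.6, 1.4) * mean_spacer))
        emit_unaligned(mask_repeats(random_dna(ls), cfg$repeat_fraction),
                       mask_repeats(random_dna(lb), cfg$repeat_fraction))
      }
    }

    for (ev in events) {
      emit_spacer()
      if (ev$type == "A") {
        i <- ev$i
        bg <- random_dna(len[i])
        if (category[i] == "EG" && eg_mode[i] == "gap") {
          a_start <- pos_a
          emit_unaligned(bg, random_dna(sample(200:800, 1L)))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            id = paste0("A", i), seq = chrom, start = a_start,
            end = a_start + len[i],
            tissues_a = paste(tissues_a[[i]], collapse = ","),
            category = category[i], eg_mode = eg_mode[i],
            b_seq = NA, b_start = NA_integer_, b_end = NA_integer_,
            tissues_b = "", pair_a = NA, pair_b = NA, b_only = FALSE)
        } else {
          a_start <- pos_a; b_start <- pos_b
          if (category[i] %in% c("FCE", "RPE")) {
            prof <- if (category[i] == "FCE") cfg$motif_events$fce else cfg$motif_events$rpe
            counts <- vapply(prof, function(mu) stats::rpois(1, mu), 0L)
            b0 <- mutate_seq(bg, cfg$substitution_rate)
            pl <- plant_motif_events(bg, b0, motifs, counts)
            emit_aligned(pl$a_seq, pl$b_seq)
            if (nrow(pl$sites)) {
              s <- pl$sites
              s$enh_id <- paste0("A", i)
              s$a_seq <- chrom; s$b_chr <- chrom
              s$a_start <- s$a_start + a_start; s$a_end <- s$a_end + a_start
              s$b_start <- s$b_start + b_start; s$b_end <- s$b_end + b_start
              site_rows[[length(site_rows) + 1L]] <- s
            }
          } else {  # EG without ortholog enhancer: plain aligned copy
            emit_aligned(bg, mutate_seq(bg, cfg$substitution_rate))
          }
          has_b <- category[i] %in% c("FCE", "RPE")
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            id = paste0("A", i), seq = chrom, start = a_start,
            end = a_start + len[i],
            tissues_a = paste(tissues_a[[i]], collapse = ","),
            category = category[i], eg_mode = eg_mode[i],
            b_seq = if (has_b) chrom else NA,
            b_start = if (has_b) b_start else NA_integer_,
            b_end = if (has_b) b_start + len[i] else NA_integer_,
            tissues_b = paste(tissues_b[[i]], collapse = ","),
            pair_a = pair_a[i], pair_b = pair_b[i], b_only = FALSE)
        }
      } else {  # species-B-only enhancer in an unalignable insert
        i <- ev$i
        b_start <- pos_b + 150L
        emit_unaligned(random_dna(sample(100:300, 1L)),
                       paste0(random_dna(150L), random_dna(bonly_len[i]),
                              random_dna(150L)))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          id = paste0("B", i), seq = NA, start = NA_integer_, end = NA_integer_,
          tissues_a = "", category = "EG", eg_mode = "b_only",
          b_seq = chrom, b_start = b_start, b_end = b_start + bonly_len[i],
          tissues_b = paste(bonly_tis[[i]], collapse = ","),
          pair_a = NA, pair_b = NA, b_only = TRUE)
      }
    }
    emit_spacer()
    close_run()
    genome_a[chrom] <- paste(a_pieces, collapse = "")
    genome_b[chrom] <- paste(b_pieces, collapse = "")
    if (length(blocks)) {
      b <- do.call(rbind, blocks)
      colnames(b) <- c("ref_start", "query_start", "size")
      chains[[length(chains) + 1L]] <- list(
        id = as.character(cc), score = unname(sum(b[, "size"])),
        ref_seq = chrom, ref_size = unname(nchar(genome_a[chrom])),
        ref_start = unname(b[1, "ref_start"]),
        ref_end = unname(b[nrow(b), "ref_start"] + b[nrow(b), "size"]),
        query_seq = chrom, query_size = unname(nchar(genome_b[chrom])),
        query_strand = "+",
        query_start = unname(b[1, "query_start"]),
        query_end = unname(b[nrow(b), "query_start"] + b[nrow(b), "size"]),
        blocks = b)
    }
  }

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  motif_truth <- if (length(site_rows)) {
    mt <- do.call(rbind, site_rows)
    mt <- mt[, c("enh_id", "category", "motif_a", "motif_b",
                 "a_seq", "a_start", "a_end", "b_chr", "b_start", "b_end")]
    names(mt)[names(mt) == "b_chr"] <- "b_seq"
    rownames(mt) <- NULL
    mt
  } else NULL

  ## --- per-tissue BED tables -------------------------------------------
  ta <- truth[!truth$b_only, ]
  bed_a <- do.call(rbind, lapply(seq_len(nrow(ta)), function(r) {
    ts <- strsplit(ta$tissues_a[r], ",")[[1]]
    data.frame(seq = ta$seq[r], start = ta$start[r], end = ta$end[r], tissue = ts)
  }))
  tb <- truth[truth$tissues_b != "" & !is.na(truth$b_start), ]
  bed_b <- do.call(rbind, lapply(seq_len(nrow(tb)), function(r) {
    ts <- strsplit(tb$tissues_b[r], ",")[[1]]
    data.frame(seq = tb$b_seq[r], start = tb$b_start[r], end = tb$b_end[r],
               tissue = ts)
  }))
  if (is.null(bed_b))
    bed_b <- data.frame(seq = character(), start = integer(), end = integer(),
                        tissue = character())
  rownames(bed_a) <- rownames(bed_b) <- NULL

  ## --- genes, loci, expression -----------------------------------------
  seq_len_a <- nchar(genome_a)
  n_g_per <- round(cfg$n_genes * seq_len_a / sum(seq_len_a))
  gene_rows <- list()
  for (cc in seq_len(cfg$n_sequences)) {
    chrom <- paste0("chr", cc)
    ng <- n_g_per[cc]
    if (ng < 1) next
    L <- seq_len_a[[chrom]]
    stride <- L / ng
    mj <- max(0, (stride - cfg$gene_length) / 2 - 1)
    st <- round((seq_len(ng) - 1) * stride + (stride - cfg$gene_length) / 2 +
                  stats::runif(ng, -mj, mj) * 0.5)
    st <- pmax(0, pmin(st, L - cfg$gene_length))
    gene_rows[[cc]] <- data.frame(
      gene = sprintf("g_%s_%03d", chrom, seq_len(ng)), seq = chrom,
      start = as.integer(st), end = as.integer(st + cfg$gene_length))
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[, c("seq", "start", "end", "gene")]
  rownames(genes) <- NULL
  loci <- build_loci(genes, seq_len_a)

  rpe_truth <- truth[truth$category == "RPE" & !truth$b_only, ]
  rpe_map <- data.frame(gene = character(), tissue_a = character(),
                        tissue_b = character())
  if (nrow(rpe_truth)) {
    li <- assign_to_loci(loci, rpe_truth)
    ok <- !is.na(li)
    rt <- rpe_truth[ok, ]; lo <- li[ok]
    o <- order(lo, rt$start)
    rt <- rt[o, ]; lo <- lo[o]
    first <- !duplicated(lo)
    rpe_map <- data.frame(gene = loci$gene[lo[first]],
                          tissue_a = rt$pair_a[first],
                          tissue_b = rt$pair_b[first])
  }
  expr <- plant_expression(genes$gene, rpe_map, tissues,
                           fold_change = cfg$expression_fold_change,
                           noise_sd = cfg$expression_noise_sd)

  bundle <- list(config = cfg, genomes = list(a = genome_a, b = genome_b),
                 seq_lengths = list(a = nchar(genome_a), b = nchar(genome_b)),
                 chains = chains, truth = truth, bed_a = bed_a, bed_b = bed_b,
                 records_a = enhancer_records(bed_a), motifs = motifs,
                 motif_truth = motif_truth, genes = genes, loci = loci,
                 expression = list(a = expr$expression_a, b = expr$expression_b),
                 expression_truth = expr$truth, tissues = tissues,
                 files = NULL)
  if (!is.null(out_dir)) bundle$files <- write_scenario(bundle, out_dir)
  bundle
}

write_scenario <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  write_genome(bundle$genomes$a, f("speciesA.fa"))
  write_genome(bundle$genomes$b, f("speciesB.fa"))
  write_chain(bundle$chains, f("A_to_B.chain"))
  write_bed(bundle$bed_a, f("enhancers_A.bed"))
  write_bed(bundle$bed_b, f("enhancers_B.bed"))
  write_meme(bundle$motifs, f("motifs.meme"))
  write_bed(cbind(bundle$genes[, c("seq", "start", "end")],
                  tissue = bundle$genes$gene), f("genes.bed"))
  write_expression(bundle$expression$a, f("expression_A.tsv"))
  write_expression(bundle$expression$b, f("expression_B.tsv"))
  utils::write.table(bundle$truth, f("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bundle$motif_truth))
    utils::write.table(bundle$motif_truth, f("motif_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list.files(out_dir, full.names = TRUE)
}
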