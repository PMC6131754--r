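#' Scenario configuration for the two-species simulator
#'
#' Defaults define the reference scenario: category mix 2% functionally
#' conserved / 42% reprogrammed / 56% gained (the observed human-side
#' breakdown this pipeline is built to study), ~1 kb enhancers, four
#' tissues, no sequence divergence, a 1.4-fold planted expression shift at
#' genes flanking reprogrammed enhancers, and binding-site event profiles
#' that give conserved enhancers mostly conserved sites and reprogrammed
#' enhancers mostly gained sites.
#'
#' @param seed integer seed; every random draw of the simulator flows from
#'   this single stream.
#' @param n_sequences,sequence_length genome shape (target length per
#'   sequence in bp).
#' @param n_tissues number of paired tissues (max 8).
#' @param n_enhancers total enhancers in species A.
#' @param category_fractions named fractions for FCE, RPE, EG (sum to 1).
#' @param enhancer_length_range min/max enhancer length in bp.
#' @param alignment_coverage probability that an inter-enhancer spacer is
#'   alignable.
#' @param substitution_rate,indel_rate per-base divergence rates inside
#'   aligned material (substitutions never touch planted motif sites;
#'   indels occur in aligned spacers, not inside enhancers).
#' @param repeat_fraction fraction of each spacer soft-masked as one run.
#' @param motif_events named list with elements `fce` and `rpe`, each a
#'   named vector of expected (Poisson) per-enhancer counts for
#'   `conserved`, `gained`, `reshuffled`, `reused` sites.
#' @param n_motifs,motif_width motif library shape.
#' @param n_genes,gene_length gene annotation shape.
#' @param expression_fold_change planted shift at RPE-flanking genes.
#' @param expression_noise_sd log-scale multiplicative noise.
#' @param multi_tissue_prob probability an enhancer is active in two
#'   tissues instead of one.
#' @param b_only_fraction extra species-B-only enhancers, as a fraction of
#'   `n_enhancers`.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_sequences = 4L,
                            sequence_length = 150000L,
                            n_tissues = 4L,
                            n_enhancers = 240L,
                            category_fractions = c(fce = 0.02, rpe = 0.42, eg = 0.56),
                            enhancer_length_range = c(800L, 1200L),
                            alignment_coverage = 0.7,
                            substitution_rate = 0,
                            indel_rate = 0,
                            repeat_fraction = 0.2,
                            motif_events = list(
                              fce = c(conserved = 3, gained = 1, reshuffled = 1, reused = 0),
                              rpe = c(conserved = 1, gained = 3, reshuffled = 1, reused = 1)),
                            n_motifs = 10L,
                            motif_width = 8L,
                            n_genes = 120L,
                            gene_length = 1500L,
                            expression_fold_change = 1.4,
                            expression_noise_sd = 0.25,
                            multi_tissue_prob = 0.15,
                            b_only_fraction = 0.3) {
  stopifnot(abs(sum(category_fractions) - 1) < 1e-8,
            alignment_coverage > 0, alignment_coverage <= 1,
            n_tissues >= 2, n_tissues <= 8,
            length(enhancer_length_range) == 2,
            enhancer_length_range[1] <= enhancer_length_range[2])
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

TISSUE_POOL <- c("liver", "heart", "cortex", "lung", "spleen", "thymus",
                 "intestine", "placenta")

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate, protect = NULL) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  if (!is.null(protect)) idx <- setdiff(idx, protect)
  for (i in idx) v[i] <- sample(setdiff(BASES, toupper(v[i])), 1L)
  paste(v, collapse = "")
}

mask_repeats <- function(s, frac) {
  n <- nchar(s)
  k <- round(n * frac)
  if (k < 1 || n < 2) return(s)
  off <- sample.int(n - k + 1L, 1L)
  paste0(substr(s, 1, off - 1L),
         tolower(substr(s, off, off + k - 1L)),
         substr(s, off + k, n))
}

#' Consensus string of a motif
#' @param motif motif model.
#' @return character string of per-position most-probable bases.
#' @export
motif_consensus <- function(motif) {
  paste(BASES[apply(motif$matrix, 1, which.max)], collapse = "")
}

#' Generate a synthetic motif library
#'
#' `n` motifs of width `width` with distinct consensi (pairwise Hamming
#' distance >= 3, so at the default scan threshold only exact consensus
#' words are hits) and near-deterministic columns (0.97 on the consensus
#' base). Draws from the global RNG stream.
#'
#' @param n number of motifs.
#' @param width motif width.
#' @param pseudocount pseudocount stored on each model.
#' @return list of motif models.
#' @export
make_motif_library <- function(n, width = 8L, pseudocount = 0.001) {
  cons <- list()
  while (length(cons) < n) {
    cand <- sample(1:4, width, replace = TRUE)
    ok <- all(vapply(cons, function(c0) sum(c0 != cand) >= 3L, TRUE))
    if (ok) cons[[length(cons) + 1L]] <- cand
  }
  lapply(seq_len(n), function(i) {
    m <- matrix(0.01, nrow = width, ncol = 4, dimnames = list(NULL, BASES))
    m[cbind(seq_len(width), cons[[i]])] <- 0.97
    list(motif_id = sprintf("M%02d", i), matrix = m,
         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
         pseudocount = pseudocount)
  })
}

#' Plant binding-site evolutionary events into an orthologous enhancer pair
#'
#' Writes motif consensus strings into the two (same-length, aligned
#' base-for-base) enhancer sequences at non-overlapping slots:
#' conserved sites get the same consensus at the same offset in both;
#' reshuffled sites get the same consensus at non-corresponding offsets;
#' gained sites appear in A only; reused sites get one motif's consensus in
#' A and a different motif's at the same offset in B (the minimal edit that
#' switches the consensus, since only the site's bases are rewritten).
#' Motifs are drawn without replacement within the pair, and a gained
#' site's motif never equals any B-side motif, so scanning recovers the
#' planted categories exactly. If the enhancer cannot hold all requested
#' events, counts are trimmed and the shortfall reported.
#'
#' @param a_seq,b_seq enhancer sequences (equal length).
#' @param motifs motif library.
#' @param counts named integer vector: `conserved`, `gained`, `reshuffled`,
#'   `reused`.
#' @return list: `a_seq`, `b_seq` (edited), `sites` (data.frame with
#'   0-based `a_start`/`a_end`/`b_start`/`b_end` offsets within the
#'   enhancer, `motif_a`, `motif_b`, `category`), `skipped` (events
#'   dropped for lack of space or motifs).
#' @export
plant_motif_events <- function(a_seq, b_seq, motifs, counts) {
  stopifnot(nchar(a_seq) == nchar(b_seq))
  w <- nrow(motifs[[1]]$matrix)
  len <- nchar(a_seq)
  counts <- counts[c("conserved", "gained", "reshuffled", "reused")]
  counts[is.na(counts)] <- 0L
  empty_sites <- data.frame(a_start = integer(), a_end = integer(),
                            b_start = integer(), b_end = integer(),
                            motif_a = character(), motif_b = character(),
                            category = character())
  if (len < w)
    return(list(a_seq = a_seq, b_seq = b_seq, sites = empty_sites,
                skipped = sum(counts)))
  slots <- seq(0L, len - w, by = w + 4L)
  need <- function(ct) ct["conserved"] + ct["gained"] + 2L * ct["reshuffled"] + ct["reused"]
  n_motif_need <- function(ct) ct["conserved"] + ct["gained"] + ct["reshuffled"] + 2L * ct["reused"]
  skipped <- 0L
  while (need(counts) > length(slots) || n_motif_need(counts) > length(motifs)) {
    i <- which.max(counts)
    counts[i] <- counts[i] - 1L
    skipped <- skipped + 1L
  }
  nc <- counts["conserved"]; ng <- counts["gained"]
  nh <- counts["reshuffled"]; nr <- counts["reused"]
  tot_slots <- need(counts)
  pick <- slots[sample.int(length(slots), tot_slots)]
  ids <- vapply(motifs, `[[`, "", "motif_id")
  m_pick <- ids[sample.int(length(ids), n_motif_need(counts))]
  # carve up slots / motifs
  take <- function(n) { out <- pick[seq_len(n)]; pick <<- pick[-seq_len(n)]; out }
  mtake <- function(n) { out <- m_pick[seq_len(n)]; m_pick <<- m_pick[-seq_len(n)]; out }
  rows <- list()
  cons_of <- function(id) motif_consensus(motifs[[match(id, ids)]])
  write_at <- function(s, off, word) {
    paste0(substr(s, 1, off), word, substr(s, off + nchar(word) + 1L, nchar(s)))
  }
  if (nc > 0) for (k in seq_len(nc)) {
    off <- take(1); m <- mtake(1); word <- cons_of(m)
    a_seq <- write_at(a_seq, off, word); b_seq <- write_at(b_seq, off, word)
    rows[[length(rows) + 1L]] <- data.frame(a_start = off, a_end = off + w,
      b_start = off, b_end = off + w, motif_a = m, motif_b = m,
      category = "TFBSC")
  }
  if (nr > 0) for (k in seq_len(nr)) {
    off <- take(1); m <- mtake(2)
    a_seq <- write_at(a_seq, off, cons_of(m[1]))
    b_seq <- write_at(b_seq, off, cons_of(m[2]))
    rows[[length(rows) + 1L]] <- data.frame(a_start = off, a_end = off + w,
      b_start = off, b_end = off + w, motif_a = m[1], motif_b = m[2],
      category = "TFBSR")
  }
  if (nh > 0) for (k in seq_len(nh)) {
    off_a <- take(1); off_b <- take(1); m <- mtake(1); word <- cons_of(m)
    a_seq <- write_at(a_seq, off_a, word); b_seq <- write_at(b_seq, off_b, word)
    rows[[length(rows) + 1L]] <- data.frame(a_start = off_a, a_end = off_a + w,
      b_start = off_b, b_end = off_b + w, motif_a = m, motif_b = m,
      category = "TFBSH")
  }
  if (ng > 0) for (k in seq_len(ng)) {
    off <- take(1); m <- mtake(1)
    a_seq <- write_at(a_seq, off, cons_of(m))
    rows[[length(rows) + 1L]] <- data.frame(a_start = off, a_end = off + w,
      b_start = NA_integer_, b_end = NA_integer_, motif_a = m,
      motif_b = NA_character_, category = "TFBSG")
  }
  sites <- if (length(rows)) do.call(rbind, rows) else empty_sites
  list(a_seq = a_seq, b_seq = b_seq, sites = sites, skipped = skipped)
}

#' Plant expression values with a shift at RPE-flanking genes
#'
#' Every gene gets one log-normal baseline shared by both species and all
#' tissues. A gene whose locus hosts a reprogrammed enhancer (taking the
#' lowest-coordinate RPE when a locus hosts several) is shifted by
#' `fold_change` in the tissue where the enhancer is active in each
#' species: tissue A in species A, the novel tissue B in species B. All
#' cells then receive independent log-normal noise of sd `noise_sd`.
#'
#' @param genes character vector of gene ids.
#' @param rpe_map data.frame with columns `gene`, `tissue_a`, `tissue_b`
#'   (at most one row per gene).
#' @param tissues character vector of tissue names (columns).
#' @param fold_change multiplicative shift (1 = none).
#' @param noise_sd log-scale noise sd (0 = none).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @return list: `expression_a`, `expression_b` (gene x tissue matrices),
#'   `truth` (data.frame `gene`, `shifted`, `tissue_a`, `tissue_b`).
#' @export
plant_expression <- function(genes, rpe_map, tissues, fold_change = 1.4,
                             noise_sd = 0.25, baseline_meanlog = 3,
                             baseline_sdlog = 1) {
  stopifnot(!anyDuplicated(rpe_map$gene))
  n <- length(genes)
  base <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
  ea <- matrix(base, n, length(tissues), dimnames = list(genes, tissues))
  eb <- ea
  hit <- match(rpe_map$gene, genes)
  ok <- !is.na(hit)
  if (any(ok)) {
    ia <- cbind(hit[ok], match(rpe_map$tissue_a[ok], tissues))
    ib <- cbind(hit[ok], match(rpe_map$tissue_b[ok], tissues))
    ea[ia] <- ea[ia] * fold_change
    eb[ib] <- eb[ib] * fold_change
  }
  if (noise_sd > 0) {
    ea <- ea * matrix(stats::rlnorm(length(ea), 0, noise_sd), nrow(ea))
    eb <- eb * matrix(stats::rlnorm(length(eb), 0, noise_sd), nrow(eb))
  }
  truth <- data.frame(gene = genes, shifted = genes %in% rpe_map$gene[ok],
                      tissue_a = rpe_map$tissue_a[match(genes, rpe_map$gene)],
                      tissue_b = rpe_map$tissue_b[match(genes, rpe_map$gene)])
  list(expression_a = ea, expression_b = eb, truth = truth)
}
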