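# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain loops straight from definitions, so the
# vectorised implementations in the package are checked against code that
# shares none of their structure.

ov_len <- function(s1, a1, b1, s2, a2, b2) {
  if (s1 != s2) return(0L)
  max(0L, min(b1, b2) - max(a1, a2))
}

# per-base projection through the best chain (literal loop)
oracle_project <- function(seq, start, end, chains) {
  cand <- list()
  for (ch in chains)
    if (ch$ref_seq == seq && ch$ref_start < end && ch$ref_end > start)
      cand[[length(cand) + 1L]] <- ch
  if (!length(cand)) return(NULL)
  sc <- sapply(cand, `[[`, "score")
  rs <- sapply(cand, `[[`, "ref_start")
  id <- sapply(cand, `[[`, "id")
  best <- cand[[order(-sc, rs, id)[1]]]
  qpos <- integer()
  for (r in start:(end - 1L)) {
    for (k in seq_len(nrow(best$blocks))) {
      b <- best$blocks[k, ]
      if (r >= b["ref_start"] && r < b["ref_start"] + b["size"]) {
        q <- if (best$query_strand == "-")
          b["query_start"] + b["size"] - 1L - (r - b["ref_start"])
        else b["query_start"] + (r - b["ref_start"])
        qpos <- c(qpos, q)
      }
    }
  }
  if (!length(qpos)) return(NULL)
  list(seq = best$query_seq, start = min(qpos), end = max(qpos) + 1L,
       aligned = length(qpos))
}

# tissue-pair classification from first principles (loops over all pairs)
oracle_tissue_pair <- function(a_src, b_src, a_dst, b_dst, chains,
                               min_overlap = 50L, share_min_bp = 1L) {
  shared <- function(x, y) {
    out <- logical(nrow(x))
    for (i in seq_len(nrow(x))) for (j in seq_len(max(nrow(y), 0L))) {
      if (ov_len(x$seq[i], x$start[i], x$end[i],
                 y$seq[j], y$start[j], y$end[j]) >= share_min_bp)
        out[i] <- TRUE
    }
    out
  }
  a1s <- a_src[!shared(a_src, b_src), , drop = FALSE]
  b1s <- b_src[!shared(b_src, a_src), , drop = FALSE]
  a1d <- a_dst[!shared(a_dst, b_dst), , drop = FALSE]
  b1d <- b_dst[!shared(b_dst, a_dst), , drop = FALSE]
  one_side <- function(src1, same_dst) {
    cat <- rep("EG", nrow(src1))
    proj <- vector("list", nrow(src1))
    dst_used <- logical(nrow(same_dst))
    for (i in seq_len(nrow(src1))) {
      p <- oracle_project(src1$seq[i], src1$start[i], src1$end[i], chains)
      proj[i] <- list(p)
      if (is.null(p)) next
      for (j in seq_len(max(nrow(same_dst), 0L))) {
        if (ov_len(p$seq, p$start, p$end, same_dst$seq[j], same_dst$start[j],
                   same_dst$end[j]) >= min_overlap) {
          cat[i] <- "FCE"
          dst_used[j] <- TRUE
        }
      }
    }
    list(cat = cat, proj = proj, dst_used = dst_used)
  }
  sa <- one_side(a1s, a1d)
  sb <- one_side(b1s, b1d)
  a2d <- a1d[!sa$dst_used, , drop = FALSE]
  b2d <- b1d[!sb$dst_used, , drop = FALSE]
  cross <- function(s, cross_dst) {
    for (i in seq_along(s$cat)) {
      if (s$cat[i] != "EG" || is.null(s$proj[[i]])) next
      p <- s$proj[[i]]
      for (j in seq_len(max(nrow(cross_dst), 0L))) {
        if (ov_len(p$seq, p$start, p$end, cross_dst$seq[j], cross_dst$start[j],
                   cross_dst$end[j]) >= min_overlap)
          s$cat[i] <- "RPE"
      }
    }
    s$cat
  }
  list(a = a1s, b = b1s,
       a_cat = cross(sa, b2d), b_cat = cross(sb, a2d))
}

# full-enumeration motif scan: every window scored against the discretised
# matrix, p-value from an explicit sum over all 4^w words
oracle_scan <- function(sequence, motif, p_threshold = 1e-4, resolution = 0.01) {
  w <- nrow(motif$matrix)
  bg <- motif$background[c("A", "C", "G", "T")]
  score_mats <- list("+" = enhancerReprog:::motif_int_scores(motif, resolution))
  m <- score_mats[["+"]]
  mrc <- m[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
  colnames(mrc) <- c("A", "C", "G", "T")
  score_mats[["-"]] <- mrc
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  hits <- list()
  for (st in c("+", "-")) {
    ism <- score_mats[[st]]
    wscore <- integer(nrow(words))
    wprob <- numeric(nrow(words))
    for (k in seq_len(nrow(words))) {
      wscore[k] <- sum(ism[cbind(seq_len(w), words[k, ])])
      wprob[k] <- prod(bg[words[k, ]])
    }
    chars <- strsplit(toupper(sequence), "")[[1]]
    code <- match(chars, c("A", "C", "G", "T"))
    n <- length(code)
    for (i in seq_len(max(n - w + 1L, 0L))) {
      win <- code[i:(i + w - 1L)]
      if (anyNA(win)) next
      s <- sum(ism[cbind(seq_len(w), win)])
      p <- sum(wprob[wscore >= s])
      if (p <= p_threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + w, motif_id = motif$motif_id,
          strand = st, score = s * resolution, p_value = p)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(), motif_id = character(),
                      strand = character(), score = numeric(), p_value = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact one-sided rank-sum p-value P(sum of x-ranks >= observed) by
# enumerating all group assignments
oracle_wilcox_greater <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  obs <- sum(r[seq_along(x)])
  sets <- utils::combn(length(all_v), length(x))
  cnt <- 0L
  for (j in seq_len(ncol(sets))) if (sum(r[sets[, j]]) >= obs) cnt <- cnt + 1L
  cnt / ncol(sets)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  probs <- sapply(supp, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k))
  p_obs <- probs[supp == a]
  sum(probs[probs <= p_obs + 1e-12])
}

# --- random fixture builders ------------------------------------------------

# a random single-sequence chain with gaps on both sides
random_chain <- function(id = "1", seq = "chrT", max_blocks = 5L,
                         score = NULL) {
  nb <- sample(1:max_blocks, 1)
  rpos <- sample(0:200, 1); qpos <- sample(0:200, 1)
  blocks <- matrix(0L, nb, 3,
                   dimnames = list(NULL, c("ref_start", "query_start", "size")))
  for (k in seq_len(nb)) {
    sz <- sample(20:400, 1)
    blocks[k, ] <- c(rpos, qpos, sz)
    rpos <- rpos + sz + sample(0:150, 1)
    qpos <- qpos + sz + sample(0:150, 1)
  }
  last <- unname(blocks[nb, ])
  list(id = id, score = if (is.null(score)) sample(100:10000, 1) else score,
       ref_seq = seq, ref_size = rpos + 500L,
       ref_start = unname(blocks[1, 1]), ref_end = last[1] + last[3],
       query_seq = seq, query_size = qpos + 500L, query_strand = "+",
       query_start = unname(blocks[1, 2]), query_end = last[2] + last[3],
       blocks = blocks)
}

random_intervals <- function(n, seq = "chrT", max_pos = 2000L,
                             len_range = c(60L, 250L), tissue = NULL) {
  if (n == 0L)
    return(data.frame(seq = character(), start = integer(), end = integer()))
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sample(0:(max_pos - max(len)), n, replace = TRUE)
  out <- data.frame(seq = seq, start = start, end = start + len)
  if (!is.null(tissue)) out$tissue <- tissue
  out
}

# a fixed synthetic motif: near-deterministic columns on a consensus
fixed_motif <- function(consensus, id = "MX", p = 0.997,
                        background = c(A = .25, C = .25, G = .25, T = .25)) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, length(b), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- p
  list(motif_id = id, matrix = m, background = background, pseudocount = 0.001)
}

random_motif <- function(width, id = "MR") {
  m <- matrix(stats::runif(width * 4), width, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m <- m / rowSums(m)
  list(motif_id = id, matrix = m,
       background = c(A = .25, C = .25, G = .25, T = .25), pseudocount = 0.001)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

small_scenario <- function(seed = 1, n_enhancers = 60L, ...) {
  scenario_config(seed = seed, n_sequences = 2L, sequence_length = 60000L,
                  n_enhancers = n_enhancers, n_genes = 40L, ...)
}
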