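#' Read a BED3/BED4 file of (optionally tissue-labelled) intervals
#'
#' BED is already 0-based half-open, so coordinates are taken verbatim.
#' Column 4, when present, is interpreted as a tissue label.
#'
#' @param path file path.
#' @return interval table with columns `seq`, `start`, `end` and, if the
#'   file has a name column, `tissue`; rows in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(seq = character(), start = integer(), end = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 tab-separated columns")
  seq <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L], " in ",
         path, ": non-numeric coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval on line ", bad[1L], " of ", path, ": start >= end")
  out <- data.frame(seq = seq, start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$tissue <- vapply(fields, `[`, "", 4L)
  out
}

#' Write intervals as BED
#'
#' @param x interval table; if `name_col` names an existing column it is
#'   written as BED column 4.
#' @param path output path.
#' @param name_col column to use for the BED name field (default
#'   `"tissue"`, then `"category"`, skipped if absent).
#' @export
write_bed <- function(x, path, name_col = intersect(c("tissue", "category"), names(x))[1]) {
  validate_intervals(x)
  cols <- list(x$seq, x$start, x$end)
  if (!is.na(name_col) && !is.null(name_col) && name_col %in% names(x))
    cols <- c(cols, list(x[[name_col]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC chain file of pairwise alignments
#'
#' Blocks are reconstructed by accumulating the `dt` (reference gap) and
#' `dq` (query gap) offsets of the alignment data lines. Negative-strand
#' query coordinates are converted to forward-strand half-open intervals at
#' read time; `query_strand` records the flip and within-block orientation
#' is handled by [project_interval()].
#'
#' @param path chain file path.
#' @return list of chains. Each chain is a list with `id`, `score`,
#'   `ref_seq`, `ref_size`, `ref_start`, `ref_end`, `query_seq`,
#'   `query_size`, `query_strand`, `query_start`, `query_end` (forward
#'   strand, 0-based half-open) and `blocks`, a matrix with columns
#'   `ref_start`, `query_start`, `size` (query starts forward-strand).
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "[ \t]+")[[1]]
    if (hdr[1] != "chain" || length(hdr) < 13L)
      stop("expected chain header at data line ", i, " of ", path)
    score <- as.numeric(hdr[2])
    ref_seq <- hdr[3]; ref_size <- as.integer(hdr[4])
    if (hdr[5] != "+") stop("reference strand must be '+' in chain format")
    ref_start <- as.integer(hdr[6]); ref_end <- as.integer(hdr[7])
    query_seq <- hdr[8]; query_size <- as.integer(hdr[9])
    query_strand <- hdr[10]
    q_start_s <- as.integer(hdr[11]); q_end_s <- as.integer(hdr[12])
    id <- hdr[13]
    blocks <- list()
    rpos <- ref_start; qpos <- q_start_s
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("unterminated chain ", id, " in ", path)
      tok <- strsplit(lines[i], "[ \t]+")[[1]]
      sz <- as.integer(tok[1])
      if (sz < 1L) stop("chain ", id, ": block size < 1")
      blocks[[length(blocks) + 1L]] <- c(rpos, qpos, sz)
      if (length(tok) == 1L) { rpos <- rpos + sz; qpos <- qpos + sz; i <- i + 1L; break }
      dt <- as.integer(tok[2]); dq <- as.integer(tok[3])
      rpos <- rpos + sz + dt; qpos <- qpos + sz + dq
      i <- i + 1L
    }
    if (rpos != ref_end || qpos != q_end_s)
      stop("chain ", id, ": block sizes inconsistent with header span")
    b <- do.call(rbind, blocks)
    colnames(b) <- c("ref_start", "query_start", "size")
    if (query_strand == "-") {
      # strand coords -> forward-strand start of each block
      b[, "query_start"] <- query_size - (b[, "query_start"] + b[, "size"])
      q_fwd <- c(query_size - q_end_s, query_size - q_start_s)
    } else q_fwd <- c(q_start_s, q_end_s)
    chains[[length(chains) + 1L]] <- list(
      id = id, score = score,
      ref_seq = ref_seq, ref_size = ref_size,
      ref_start = ref_start, ref_end = ref_end,
      query_seq = query_seq, query_size = query_size,
      query_strand = query_strand, query_start = q_fwd[1], query_end = q_fwd[2],
      blocks = b)
  }
  chains
}

#' Write chains in UCSC chain format
#' @param chains list of chains as returned by [read_chain()].
#' @param path output path.
#' @export
write_chain <- function(chains, path) {
  out <- character()
  for (ch in chains) {
    b <- ch$blocks
    qs <- b[, "query_start"]
    if (ch$query_strand == "-") {
      qs <- ch$query_size - (b[, "query_start"] + b[, "size"])
      o <- order(qs)  # strand coords increase along ref order already
      stopifnot(identical(o, seq_len(nrow(b))) || identical(o, rev(seq_len(nrow(b)))))
      q_start_s <- ch$query_size - ch$query_end
      q_end_s <- ch$query_size - ch$query_start
    } else {
      q_start_s <- ch$query_start; q_end_s <- ch$query_end
    }
    hdr <- paste("chain", format(ch$score, scientific = FALSE), ch$ref_seq,
                 ch$ref_size, "+", ch$ref_start, ch$ref_end, ch$query_seq,
                 ch$query_size, ch$query_strand, q_start_s, q_end_s, ch$id)
    n <- nrow(b)
    body <- character(n)
    for (k in seq_len(n)) {
      if (k < n) {
        dt <- b[k + 1L, "ref_start"] - (b[k, "ref_start"] + b[k, "size"])
        dq <- qs[k + 1L] - (qs[k] + b[k, "size"])
        body[k] <- paste(b[k, "size"], dt, dq)
      } else body[k] <- as.character(b[k, "size"])
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' @param path file path.
#' @param pseudocount probability mass mixed into each matrix cell before
#'   log-odds scoring (default 0.001).
#' @return list of motif models: `motif_id`, `matrix` (width x 4 probability
#'   matrix, columns A,C,G,T), `background` (length-4, from the file's
#'   "Background letter frequencies" block or uniform 0.25), `pseudocount`.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1L]), "[ \t]+")[[1]]
    v <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(v) <- tok[seq(1, length(tok), by = 2)]
    bg[names(v)] <- v
  }
  motif_at <- grep("^MOTIF", lines)
  motifs <- vector("list", length(motif_at))
  for (m in seq_along(motif_at)) {
    hdr <- strsplit(trimws(lines[motif_at[m]]), "[ \t]+")[[1]]
    motif_id <- hdr[2]
    lp <- grep("^letter-probability matrix", lines[motif_at[m]:length(lines)])[1]
    if (is.na(lp)) stop("motif ", motif_id, ": no letter-probability matrix")
    j <- motif_at[m] + lp - 1L
    rows <- list()
    k <- j + 1L
    while (k <= length(lines)) {
      tok <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
      if (length(tok) != 4L || anyNA(suppressWarnings(as.numeric(tok)))) break
      rows[[length(rows) + 1L]] <- as.numeric(tok)
      k <- k + 1L
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- c("A", "C", "G", "T")
    if (nrow(mat) < 4L) stop("motif ", motif_id, ": width < 4")
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > 1e-5))
      stop("motif ", motif_id, ": probability row ", which(abs(sums - 1) > 1e-5)[1],
           " does not sum to 1")
    motifs[[m]] <- list(motif_id = motif_id, matrix = mat, background = bg,
                        pseudocount = pseudocount)
  }
  motifs
}

#' Write motifs in MEME minimal format
#' @param motifs list of motif models (see [read_meme()]).
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  bg <- if (length(motifs)) motifs[[1]]$background else c(A = .25, C = .25, G = .25, T = .25)
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), "")
  for (m in motifs) {
    out <- c(out, paste("MOTIF", m$motif_id),
             sprintf("letter-probability matrix: alength= 4 w= %d", nrow(m$matrix)),
             apply(m$matrix, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                    r[1], r[2], r[3], r[4])), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene-by-tissue expression table
#'
#' Tab-separated, header row of tissue names, first column gene ids.
#' "NA" cells stay missing (`NA`), never coerced to zero.
#'
#' @param path file path.
#' @return numeric matrix, genes as rownames, tissues as colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a gene-by-tissue expression table
#' @param m numeric matrix with gene rownames and tissue colnames.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (soft-masked) FASTA genome
#'
#' Case is preserved: lowercase bases mark repeat-derived sequence and are
#' the repeat signal used by [repeat_fraction()] and the enhancer filter.
#'
#' @param path FASTA path.
#' @return a named character vector of sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome as FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome), path, width = 70L)
  invisible(path)
}

#' Extract interval sequences from a genome
#' @param genome named character vector (see [read_genome()]).
#' @param x interval table.
#' @param uppercase fold to uppercase (default TRUE; set FALSE to keep the
#'   soft-mask).
#' @return character vector of sequences.
#' @export
interval_seq <- function(genome, x, uppercase = TRUE) {
  validate_intervals(x)
  miss <- setdiff(unique(x$seq), names(genome))
  if (length(miss)) stop("sequence(s) not in genome: ", paste(miss, collapse = ", "))
  if (any(x$end > nchar(genome[x$seq])))
    stop("interval extends beyond sequence end")
  s <- unname(substring(genome[x$seq], x$start + 1L, x$end))
  if (uppercase) toupper(s) else s
}

#' Fraction of soft-masked (lowercase) bases per interval
#' @inheritParams interval_seq
#' @export
repeat_fraction <- function(genome, x) {
  s <- interval_seq(genome, x, uppercase = FALSE)
  low <- nchar(gsub("[^acgtn]", "", s))
  low / (x$end - x$start)
}

#' GC fraction per interval (case-insensitive)
#' @inheritParams interval_seq
#' @export
gc_fraction <- function(genome, x) {
  s <- interval_seq(genome, x, uppercase = TRUE)
  gc <- nchar(gsub("[^GC]", "", s))
  gc / (x$end - x$start)
}
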