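#' Construct a motif matrix
#'
#' A nucleotide count matrix describing a transcription-factor binding
#' motif, together with the pseudocount-regularized frequency matrix used
#' for likelihood-ratio scoring.
#'
#' @param motif_id Unique motif identifier.
#' @param counts Numeric w x 4 matrix of (possibly real-valued) base counts,
#'   columns in A,C,G,T order; w >= 4.
#' @param tf_name Cognate transcription-factor name; defaults to `motif_id`.
#' @param pseudocount Non-negative value added to every cell before
#'   normalization: `freq[i,b] = (counts[i,b] + pc) / (sum_b counts[i,b] + 4 pc)`.
#' @param source_format Provenance tag, `"jaspar_pfm"` or `"transfac_dialect"`.
#' @return A `motif_matrix` object (list with `motif_id`, `tf_name`, `width`,
#'   `counts`, `freq`, `source_format`).
#' @export
motif_matrix <- function(motif_id, counts, tf_name = motif_id,
                         pseudocount = 0.01,
                         source_format = c("jaspar_pfm", "transfac_dialect")) {
  source_format <- match.arg(source_format)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop_fmt("motif '%s': counts must have 4 columns", motif_id)
  if (nrow(counts) < 4L) stop_fmt("motif '%s': width %d < 4", motif_id, nrow(counts))
  if (any(counts < 0)) stop_fmt("motif '%s': negative counts", motif_id)
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  colnames(counts) <- BASES
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0)) {
    stop_fmt("motif '%s': zero total count at position %d with pseudocount 0",
             motif_id, which(rs == 0)[1])
  }
  freq <- (counts + pseudocount) / (rs + 4 * pseudocount)
  structure(list(motif_id = motif_id, tf_name = tf_name,
                 width = nrow(counts), counts = counts, freq = freq,
                 source_format = source_format),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix %s (TF %s), width %d, IC %.2f bits\n",
              x$motif_id, x$tf_name, x$width, motif_information(x)))
  invisible(x)
}

#' Total information content of a motif (bits)
#'
#' Sum over positions of `2 + sum_b f log2 f`, i.e. relative entropy against
#' the uniform base distribution.
#'
#' @param motif A `motif_matrix`.
#' @param per_column Return the per-column average instead of the total.
#' @export
motif_information <- function(motif, per_column = FALSE) {
  f <- motif$freq
  h <- ifelse(f > 0, f * log2(f), 0)
  ic <- sum(2 + rowSums(h))
  if (per_column) ic / motif$width else ic
}

#' Reverse-complement a motif matrix
#' @param motif A `motif_matrix`.
#' @export
reverse_complement_motif <- function(motif) {
  rc <- motif$counts[rev(seq_len(motif$width)), c(4, 3, 2, 1), drop = FALSE]
  colnames(rc) <- BASES
  out <- motif_matrix(motif$motif_id, rc, motif$tf_name,
                      pseudocount = 0, source_format = motif$source_format)
  # keep the caller's regularized frequencies rather than re-deriving them
  out$freq <- motif$freq[rev(seq_len(motif$width)), c(4, 3, 2, 1), drop = FALSE]
  colnames(out$freq) <- BASES
  out
}

#' Read a motif library
#'
#' Supports two plain-text dialects: JASPAR PFM (`>id name` header followed
#' by four base rows, optionally in `A [ ... ]` style) and a minimal
#' TRANSFAC-style flat file (`ID`, optional `BF`, a `P0`/`PO` column header,
#' numbered count rows, `//` terminator).  Anything else is a loud error
#' with a line number.
#'
#' @param path Motif file.
#' @param format `"jaspar_pfm"` or `"transfac_dialect"`.
#' @param pseudocount Passed to [motif_matrix()].
#' @return A `motif_library`: named list of `motif_matrix` objects.
#' @export
read_motif_library <- function(path, format = c("jaspar_pfm", "transfac_dialect"),
                               pseudocount = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("motif file not found: %s", path)
  lines <- readLines(path)
  motifs <- if (format == "jaspar_pfm") {
    parse_jaspar_pfm(lines, pseudocount)
  } else {
    parse_transfac(lines, pseudocount)
  }
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  if (anyDuplicated(ids)) {
    stop_fmt("duplicate motif_id: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(motifs) <- ids
  structure(motifs, class = "motif_library")
}

parse_number_row <- function(line, lineno) {
  # strip "A [" ... "]" decoration if present
  stripped <- sub("^\\s*[ACGT]\\s*\\[", "", line)
  stripped <- sub("\\]\\s*$", "", stripped)
  toks <- strsplit(trimws(stripped), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0 || anyNA(vals)) {
    stop_fmt("malformed matrix row at line %d: '%s'", lineno, line)
  }
  vals
}

parse_jaspar_pfm <- function(lines, pseudocount) {
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!startsWith(line, ">")) {
      stop_fmt("expected '>' header at line %d: '%s'", i, line)
    }
    toks <- strsplit(sub("^>", "", line), "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) >= 2) toks[2] else motif_id
    if (i + 4L > n) stop_fmt("truncated matrix block after line %d", i)
    rows <- lapply(seq_len(4), function(k) parse_number_row(lines[i + k], i + k))
    widths <- lengths(rows)
    if (length(unique(widths)) != 1) {
      stop_fmt("ragged matrix block for motif '%s' at line %d", motif_id, i)
    }
    counts <- t(do.call(rbind, rows))  # rows were per-base; transpose to w x 4
    motifs[[length(motifs) + 1L]] <-
      motif_matrix(motif_id, counts, tf_name, pseudocount, "jaspar_pfm")
    i <- i + 5L
  }
  motifs
}

parse_transfac <- function(lines, pseudocount) {
  motifs <- list()
  motif_id <- NULL; tf_name <- NULL; rows <- list()
  flush <- function(lineno) {
    if (is.null(motif_id)) stop_fmt("'//' with no open record at line %d", lineno)
    if (length(rows) == 0) stop_fmt("motif '%s' has no count rows", motif_id)
    counts <- do.call(rbind, rows)
    motif_matrix(motif_id, counts, tf_name %||% motif_id, pseudocount,
                 "transfac_dialect")
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (startsWith(line, "ID")) {
      if (!is.null(motif_id)) stop_fmt("nested ID without '//' at line %d", i)
      motif_id <- trimws(sub("^ID\\s*", "", line))
      if (motif_id == "") stop_fmt("empty ID at line %d", i)
      tf_name <- NULL; rows <- list()
    } else if (startsWith(line, "BF")) {
      tf_name <- trimws(sub("^BF\\s*", "", line))
    } else if (grepl("^P[O0]\\b", line)) {
      # column-header line; validated for A C G T order
      hdr <- strsplit(line, "\\s+")[[1]][-1]
      if (!identical(head(hdr, 4), BASES)) {
        stop_fmt("P0 header at line %d is not 'A C G T'", i)
      }
    } else if (line == "//") {
      motifs[[length(motifs) + 1L]] <- flush(i)
      motif_id <- NULL
    } else if (grepl("^[0-9]+\\s", line)) {
      if (is.null(motif_id)) stop_fmt("count row outside record at line %d", i)
      toks <- strsplit(line, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (anyNA(vals)) stop_fmt("malformed count row at line %d: '%s'", i, line)
      rows[[length(rows) + 1L]] <- vals
    } else {
      stop_fmt("unrecognized line %d in TRANSFAC dialect: '%s'", i, line)
    }
  }
  if (!is.null(motif_id)) stop_fmt("unterminated record '%s' (missing '//')", motif_id)
  motifs
}

#' Write a motif library as JASPAR-style PFMs
#' @param motifs A `motif_library`.
#' @param path Output path.
#' @export
write_motif_library <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$motif_id, m$tf_name), con)
    for (b in 1:4) {
      writeLines(paste(format(m$counts[, b], trim = TRUE), collapse = " "), con)
    }
  }
  invisible(path)
}
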