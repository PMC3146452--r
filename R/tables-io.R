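#' Construct a Ct matrix
#'
#' qPCR cycle-threshold values for a panel of miRNAs across samples, with
#' per-sample cell-type and donor annotations and a designated reference
#' miRNA (default hsa-let-7a) for delta-Ct normalization.
#'
#' @param values Numeric miRNA x sample matrix of Ct cycles; dimnames
#'   required.  `NA` marks undetermined wells.
#' @param cell_type Character vector, one cell-type label per sample column.
#' @param donor Character vector, one donor label per sample column.
#' @param reference Row name of the reference miRNA.
#' @return A `ct_matrix` object.
#' @export
ct_matrix <- function(values, cell_type, donor, reference = "hsa-let-7a") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fmt("Ct matrix needs row (miRNA) and column (sample) names")
  }
  if (length(cell_type) != ncol(values) || length(donor) != ncol(values)) {
    stop_fmt("cell_type/donor must have one entry per sample column")
  }
  if (!reference %in% rownames(values)) {
    stop_fmt("reference miRNA '%s' is not a row of the Ct matrix", reference)
  }
  structure(list(values = values,
                 samples = data.frame(sample_id = colnames(values),
                                      cell_type = as.character(cell_type),
                                      donor = as.character(donor),
                                      stringsAsFactors = FALSE),
                 reference = reference),
            class = "ct_matrix")
}

#' Read a Ct table from TSV
#'
#' First column `mirna_id`; remaining columns are samples named
#' `<cell_type>.<donor>` (the annotation convention used throughout the
#' package, e.g. `monocyte.D1`, `iDC.D2`).  Cell-type labels must not
#' contain a dot.
#'
#' @param path TSV file.
#' @param reference Reference miRNA id.
#' @return A `ct_matrix`.
#' @export
read_ct_table <- function(path, reference = "hsa-let-7a") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fmt("Ct table %s needs a mirna_id column plus samples", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]) & vals[[j]] != "NA")
      stop_fmt("non-numeric Ct in column '%s' of %s (row %d)",
               names(vals)[j], path, if (length(bad)) bad[1] else 1L)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  parts <- strsplit(colnames(m), ".", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop_fmt("sample column names must follow <cell_type>.<donor>: '%s'",
             colnames(m)[which(lengths(parts) < 2)[1]])
  }
  cell_type <- vapply(parts, `[`, character(1), 1L)
  donor <- vapply(parts, function(p) paste(p[-1], collapse = "."), character(1))
  ct_matrix(m, cell_type, donor, reference)
}

#' Write a Ct matrix as TSV (inverse of [read_ct_table()])
#' @param ct A `ct_matrix`.
#' @param path Output path.
#' @export
write_ct_table <- function(ct, path) {
  cn <- paste(ct$samples$cell_type, ct$samples$donor, sep = ".")
  df <- data.frame(mirna_id = rownames(ct$values), ct$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("mirna_id", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor presence table
#'
#' Two TSV columns: `tf` (gene symbol) and `call`.  Calls are case-folded
#' and must be one of present / marginal / absent (microarray
#' detection-call semantics: presence p < 0.01, marginal 0.01-0.02,
#' otherwise absent).
#'
#' @param path TSV file.
#' @return A `presence_table`: data.frame with columns `tf`, `call`.
#' @export
read_presence_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "call") %in% names(df))) {
    stop_fmt("presence table %s needs columns 'tf' and 'call'", path)
  }
  call <- tolower(trimws(df$call))
  bad <- setdiff(unique(call), c("present", "marginal", "absent"))
  if (length(bad)) {
    stop_fmt("unknown presence call(s) in %s: %s", path,
             paste(bad, collapse = ", "))
  }
  out <- data.frame(tf = as.character(df$tf), call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("presence_table", "data.frame")
  out
}

#' Read a miRNA-to-promoter locus table
#'
#' TSV with columns `mirna_id`, `promoter_id`.  Many-to-one and one-to-many
#' mappings are allowed (distinct genomic loci can produce one mature
#' miRNA, so the promoter count may exceed the miRNA count).
#'
#' @param path TSV file.
#' @return Data.frame with columns `mirna_id`, `promoter_id`.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "promoter_id") %in% names(df))) {
    stop_fmt("locus table %s needs columns 'mirna_id' and 'promoter_id'", path)
  }
  df[, c("mirna_id", "promoter_id")]
}

HIT_COLUMNS <- c("promoter_id", "start", "end", "motif_id", "instance_score",
                 "strand", "conservation_score")

empty_hits <- function() {
  data.frame(promoter_id = character(), start = integer(), end = integer(),
             motif_id = character(), instance_score = numeric(),
             strand = character(), conservation_score = numeric(),
             stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  hits[order(hits$promoter_id, hits$start, hits$motif_id), , drop = FALSE]
}

#' Write motif hits as a BED-like TSV
#'
#' 0-based half-open intervals in promoter coordinates: columns
#' promoter_id, start, end, motif_id, instance_score, strand,
#' conservation_score (empty when unset).  Rows are stably sorted by
#' (promoter_id, start, motif_id).
#'
#' @param hits Hit data.frame as produced by [scan_promoter()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  if (nrow(hits) > 0 && !"end" %in% names(hits)) {
    hits$end <- hits$start + hits$width
  }
  if (nrow(hits) == 0) hits <- empty_hits()
  if (!"conservation_score" %in% names(hits)) hits$conservation_score <- NA_real_
  hits <- sort_hits(hits[, HIT_COLUMNS, drop = FALSE])
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read motif hits written by [write_hits()]
#' @param path TSV file.
#' @export
read_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(promoter_id = "character",
                                  motif_id = "character",
                                  strand = "character"))
  if (!all(HIT_COLUMNS %in% names(df))) {
    stop_fmt("hit file %s is missing columns: %s", path,
             paste(setdiff(HIT_COLUMNS, names(df)), collapse = ", "))
  }
  df$width <- df$end - df$start
  df
}
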