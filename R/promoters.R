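#' Read promoter sequences from a FASTA file
#'
#' Promoters are oriented upstream regions (by convention 2 kb) ending
#' immediately 5' of a pre-miRNA start: position 0 is the most distal base
#' and position L-1 abuts the hairpin.  Sequences must already be oriented
#' 5'->3' on the pre-miRNA's strand; this reader performs no strand
#' manipulation.  Optional `mirna=` and `strand=` key=value tokens in the
#' FASTA description are picked up as annotations.
#'
#' @param path FASTA file path.
#' @param expected_length If non-NULL, every record must have exactly this
#'   length; a mismatch is an error naming the offending record.
#' @return A `promoter_set`: a data.frame with columns `promoter_id`,
#'   `mirna_id`, `sequence` (uppercase, alphabet A/C/G/T/N) and `strand`.
#' @export
read_promoter_fasta <- function(path, expected_length = NULL) {
  if (!file.exists(path)) stop_fmt("promoter FASTA not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- unname(toupper(as.character(ss)))
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_fmt("duplicate promoter_id in %s: %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  key_val <- function(header, key) {
    m <- regmatches(header, regexpr(paste0(key, "=\\S+"), header))
    if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
  }
  mirna <- vapply(headers, key_val, character(1), key = "mirna",
                  USE.NAMES = FALSE)
  strand <- vapply(headers, key_val, character(1), key = "strand",
                   USE.NAMES = FALSE)
  strand[is.na(strand)] <- "+"
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    if (n == 0) stop_fmt("record '%s' has empty sequence", ids[i])
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0) {
      stop_fmt("record '%s' has non-nucleotide character '%s' at offset %d",
               ids[i], substr(seqs[i], bad, bad), bad - 1L)
    }
    if (!is.null(expected_length) && n != expected_length) {
      stop_fmt("record '%s' has length %d, expected %d", ids[i], n,
               expected_length)
    }
  }
  out <- data.frame(promoter_id = ids, mirna_id = mirna, sequence = seqs,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Write promoter sequences to FASTA
#'
#' Inverse of [read_promoter_fasta()]; `mirna=` / `strand=` annotations are
#' carried in the description so the round trip is lossless.
#'
#' @param promoters A `promoter_set` data.frame.
#' @param path Output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  desc <- promoters$promoter_id
  has_mir <- !is.na(promoters$mirna_id)
  desc[has_mir] <- paste0(desc[has_mir], " mirna=", promoters$mirna_id[has_mir])
  desc <- paste0(desc, " strand=", promoters$strand)
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- desc
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

promoter_lengths <- function(promoters) {
  setNames(nchar(promoters$sequence), promoters$promoter_id)
}
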