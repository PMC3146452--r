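#' Read per-base conservation tracks from a fixedStep wiggle file
#'
#' The pipeline keys conservation in promoter space: each fixedStep block's
#' `chrom` field names a `promoter_id` and `start` is the 1-based offset
#' within that promoter (lifting genome-coordinate tracks into promoter
#' space is a preprocessing step outside this package).  Positions not
#' covered by any block are missing (`NA`).  Scores are posterior
#' probabilities of the conserved state, so values outside [0,1] are a hard
#' error, as is a block extending beyond its promoter.
#'
#' @param path Wiggle file (fixedStep or variableStep; fixedStep is what
#'   [write_conservation_wig()] emits).
#' @param promoters A `promoter_set`; tracks are aligned 1:1 with these
#'   sequences.
#' @return A `conservation_set`: named list (by promoter_id) of numeric
#'   vectors the length of each promoter, `NA` where missing.
#' @export
read_conservation_wig <- function(path, promoters) {
  if (!file.exists(path)) stop_fmt("wiggle file not found: %s", path)
  gr <- rtracklayer::import(path, format = "wig")
  lens <- promoter_lengths(promoters)
  tracks <- lapply(lens, function(L) rep(NA_real_, L))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  scores <- gr$score
  if (any(scores < 0 | scores > 1)) {
    stop_fmt("conservation score outside [0,1] in %s (first offender: %g)",
             path, scores[which(scores < 0 | scores > 1)[1]])
  }
  unknown <- setdiff(unique(chrom), names(tracks))
  if (length(unknown)) {
    stop_fmt("wiggle block for unknown promoter_id: %s",
             paste(unknown, collapse = ", "))
  }
  for (pid in unique(chrom)) {
    sel <- chrom == pid
    if (max(ends[sel]) > lens[[pid]]) {
      stop_fmt("wiggle block for '%s' extends to %d but promoter length is %d",
               pid, max(ends[sel]), lens[[pid]])
    }
    for (j in which(sel)) {
      tracks[[pid]][starts[j]:ends[j]] <- scores[j]
    }
  }
  structure(tracks, class = "conservation_set")
}

#' Write conservation tracks as fixedStep wiggle
#'
#' Missing (`NA`) stretches are omitted, splitting a promoter's track into
#' multiple fixedStep blocks; [read_conservation_wig()] restores the mask.
#'
#' @param tracks A `conservation_set` (named list of numeric vectors).
#' @param path Output path.
#' @param digits Decimal digits written per score.
#' @export
write_conservation_wig <- function(tracks, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pid in names(tracks)) {
    v <- tracks[[pid]]
    ok <- !is.na(v)
    if (!any(ok)) next
    runs <- rle(ok)
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      if (runs$values[k]) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=1", pid, pos), con)
        writeLines(formatC(v[pos:(pos + len - 1L)], digits = digits,
                           format = "f"), con)
      }
      pos <- pos + len
    }
  }
  invisible(path)
}
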