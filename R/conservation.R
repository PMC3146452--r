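#' Conservation score of one binding site
#'
#' The median of the per-base conservation scores over the site's interval
#' `[start, start + width)`.  Even-length medians use the midpoint mean.
#' Missing bases are dropped; if fewer than half the bases carry a score
#' the site is unscorable and `NA` is returned.
#'
#' @param start 0-based start of the site within the promoter.
#' @param width Site width.
#' @param track Numeric per-base score vector (NA = missing) for the
#'   site's promoter.
#' @return The site conservation score in [0,1], or `NA_real_`.
#' @export
site_conservation <- function(start, width, track) {
  if (start < 0 || start + width > length(track)) {
    stop_fmt("site [%d,%d) lies outside the %d-base track", start,
             start + width, length(track))
  }
  v <- track[(start + 1L):(start + width)]
  v <- v[!is.na(v)]
  if (length(v) < width / 2) return(NA_real_)
  median(v)
}

#' Attach conservation scores to motif hits
#'
#' @param hits Hit data.frame (with `start`, `width`, `promoter_id`).
#' @param tracks A `conservation_set`.
#' @return The hits with `conservation_score` filled in (`NA` where the
#'   site was unscorable).
#' @export
add_conservation <- function(hits, tracks) {
  if (nrow(hits) == 0) { hits$conservation_score <- numeric(0); return(hits) }
  missing_tracks <- setdiff(unique(hits$promoter_id), names(tracks))
  if (length(missing_tracks)) {
    stop_fmt("no conservation track for promoter(s): %s",
             paste(missing_tracks, collapse = ", "))
  }
  hits$conservation_score <- vapply(seq_len(nrow(hits)), function(i) {
    site_conservation(hits$start[i], hits$width[i],
                      tracks[[hits$promoter_id[i]]])
  }, numeric(1))
  hits
}

#' Percentile filter on hit conservation
#'
#' With `direction = "top"` (the default, i.e. retain the most conserved
#' `percentile` percent of sites), the threshold is the
#' `(100 - percentile)`-th percentile of the hit conservation scores and
#' hits scoring at or above it are retained, ties included.
#' `direction = "bottom"` reads the percentile literally as a lower-tail
#' cut.
#'
#' @param hits Hits with conservation scores.
#' @param percentile Percent of hits to retain (default 10).
#' @param direction `"top"` or `"bottom"`.
#' @return A `conserved_hits` list: `hits` (retained), `threshold` (the
#'   percentile threshold value, NA when no scorable hits), `percentile`,
#'   `direction`.
#' @export
conservation_percentile_filter <- function(hits, percentile = 10,
                                           direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  scorable <- hits[!is.na(hits$conservation_score), , drop = FALSE]
  if (nrow(scorable) == 0) {
    return(structure(list(hits = scorable, threshold = NA_real_,
                          percentile = percentile, direction = direction),
                     class = "conserved_hits"))
  }
  prob <- if (direction == "top") 1 - percentile / 100 else percentile / 100
  thr <- unname(quantile(scorable$conservation_score, prob))
  keep <- scorable$conservation_score >= thr
  structure(list(hits = scorable[keep, , drop = FALSE], threshold = thr,
                 percentile = percentile, direction = direction),
            class = "conserved_hits")
}

#' Random-block conservation null
#'
#' For each observed site, samples `n_blocks_per_hit` random intervals of
#' the same width uniformly from the same promoter (blocks may overlap
#' sites and each other) and scores their median conservation.  Reports
#' the fold `median(observed) / median(null)` and a two-sample Wilcoxon
#' rank-sum p-value between the two score sets.
#'
#' @param hits Hits with conservation scores.
#' @param tracks A `conservation_set`.
#' @param n_blocks_per_hit Random blocks drawn per observed site.
#' @param seed Optional seed.
#' @return List: fold, p, observed, null (the two score vectors).
#' @export
conservation_null_test <- function(hits, tracks, n_blocks_per_hit = 1,
                                   seed = NULL) {
  obs <- hits$conservation_score
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0) stop_fmt("no scorable observed sites")
  null_scores <- with_seed(seed, {
    out <- numeric(0)
    for (i in seq_len(nrow(hits))) {
      track <- tracks[[hits$promoter_id[i]]]
      w <- hits$width[i]
      n_start <- length(track) - w + 1L
      starts <- sample_int(n_start, n_blocks_per_hit, replace = TRUE) - 1L
      sc <- vapply(starts, site_conservation, numeric(1), width = w,
                   track = track)
      out <- c(out, sc[!is.na(sc)])
    }
    out
  })
  if (length(null_scores) == 0) stop_fmt("no scorable null blocks")
  fold <- median(obs) / median(null_scores)
  p <- suppressWarnings(wilcox.test(obs, null_scores)$p.value)
  list(fold = fold, p = p, observed = obs, null = null_scores)
}

#' Correlation between instance score and conservation
#'
#' Pearson correlation across hits between the motif instance score and
#' the site conservation score, with its two-sided p-value.  Zero variance
#' in either variable is flagged rather than propagated as NaN.
#'
#' @param hits Hits with both scores.
#' @return List: r, p, n, defined (FALSE when degenerate).
#' @export
score_conservation_correlation <- function(hits) {
  ok <- !is.na(hits$conservation_score) & !is.na(hits$instance_score)
  x <- hits$instance_score[ok]
  y <- hits$conservation_score[ok]
  if (length(x) < 3) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ctest <- cor.test(x, y, method = "pearson")
  list(r = unname(ctest$estimate), p = ctest$p.value, n = length(x),
       defined = TRUE)
}

#' Histogram of hit positions over upstream offsets
#'
#' Offsets are hit starts relative to the promoter's 3' end (the base
#' abutting the pre-miRNA): `offset = start - L`, so offsets lie in
#' `[-L, 0)` and the most proximal bin is `[-bin_size, 0)`.
#'
#' @param hits Hit data.frame.
#' @param bin_size Bin width in bp (default 100).
#' @param promoter_length L; either a single value or a named vector by
#'   promoter_id.
#' @return Data.frame: bin_start, bin_end (offsets, half-open), count.
#' @export
upstream_distribution <- function(hits, bin_size = 100,
                                  promoter_length = 2000) {
  L <- max(promoter_length)
  breaks <- seq(-L, 0, by = bin_size)
  if (breaks[length(breaks)] != 0) breaks <- c(breaks, 0)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1])
  if (nrow(hits) == 0) {
    out$count <- 0L
    return(out)
  }
  Lh <- if (length(promoter_length) > 1) {
    promoter_length[hits$promoter_id]
  } else rep(promoter_length, nrow(hits))
  offs <- hits$start - Lh
  out$count <- vapply(seq_len(nrow(out)), function(i) {
    sum(offs >= out$bin_start[i] & offs < out$bin_end[i])
  }, integer(1))
  out
}

#' Proximal clustering test
#'
#' Tests whether hits concentrate in the `window` bp immediately upstream
#' of the pre-miRNA.  A hit is proximal when its midpoint offset lies in
#' `[-window, 0)`; the one-sided exact binomial test compares the proximal
#' fraction against the uniform-placement expectation `window / L`.
#'
#' @param hits Hit data.frame.
#' @param window Proximal window in bp (default 500).
#' @param promoter_length L (single value or named vector by promoter_id).
#' @return List: proximal_fraction, p, n_hits, expected (window/L),
#'   defined (FALSE with zero hits).
#' @export
proximal_cluster_test <- function(hits, window = 500, promoter_length = 2000) {
  if (nrow(hits) == 0) {
    return(list(proximal_fraction = NA_real_, p = NA_real_, n_hits = 0L,
                expected = NA_real_, defined = FALSE))
  }
  Lh <- if (length(promoter_length) > 1) {
    promoter_length[hits$promoter_id]
  } else rep(promoter_length, nrow(hits))
  mid_off <- hits$start + hits$width / 2 - Lh
  prox <- mid_off >= -window & mid_off < 0
  # promoters shorter than the window are proximal throughout
  p0 <- min(1, window / max(promoter_length))
  bt <- binom.test(sum(prox), length(prox), p = p0, alternative = "greater")
  list(proximal_fraction = mean(prox), p = bt$p.value, n_hits = length(prox),
       expected = p0, defined = TRUE)
}
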