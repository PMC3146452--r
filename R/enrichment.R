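# qualify motifs within one promoter subset of a scan cache: a motif
# qualifies when its raw-score randomization p (inner draws from
# `draw_pool`) is at or below p_cutoff AND it has at least one qualifying
# hit in the subset.  `presence` lets the conserved variant substitute a
# conservation-filtered presence matrix.  Consumes `n_inner` inner draws
# from the current RNG stream; the null raw scores are evaluated with one
# indicator-matrix product over the cached per-sequence log terms.
.qualify_set <- function(cache, set_idx, p_cutoff, n_inner,
                         presence = cache$presence,
                         draw_pool = seq_len(ncol(cache$log_terms))) {
  LT <- cache$log_terms
  raw_obs <- rowSums(LT[, set_idx, drop = FALSE])
  k <- length(set_idx)
  idx <- vapply(seq_len(n_inner), function(j) {
    draw_pool[sample_int(length(draw_pool), k)]
  }, integer(k))
  Z <- matrix(0, ncol(LT), n_inner)
  Z[cbind(as.vector(idx), rep(seq_len(n_inner), each = k))] <- 1
  null_raw <- LT %*% Z                      # motifs x n_inner
  exceed <- rowSums(null_raw >= raw_obs)
  p <- (1 + exceed) / (1 + n_inner)
  has_hit <- rowSums(presence[, set_idx, drop = FALSE]) >= 1
  list(p = setNames(p, cache$motif_ids),
       qualifying = p <= p_cutoff & has_hit)
}

#' Motifs qualifying in a promoter set
#'
#' A motif qualifies when it is over-represented in the test set relative
#' to random equal-size promoter sets from the pool (randomization p at or
#' below `p_cutoff` on the subset-averaged raw score) and has at least one
#' hit at the instance-score threshold in the test set.  When conservation
#' tracks are supplied, hits are first restricted to conserved ones: the
#' conservation threshold is the top-`conservation_percentile` cut of the
#' test-set hit conservation scores.
#'
#' @param test_set A `promoter_set` (the set of interest).
#' @param pool A `promoter_set` used as the randomization background; test
#'   promoters not already in the pool are appended for scanning purposes
#'   but random sets are drawn from the pool only.
#' @param motifs A `motif_library`.
#' @param instance_threshold Instance-score cutoff for hits (default 6).
#' @param p_cutoff Over-representation p cutoff (default 0.05).
#' @param n_random_overrep Random sets per motif test (default 1000).
#' @param tracks Optional `conservation_set` switching on the conserved
#'   variant.
#' @param conservation_percentile Top-percentile retained (default 10).
#' @param seed Optional seed.
#' @return List: `qualifying` (motif ids), `overrep_p` (named vector),
#'   `hits` (qualifying hits within the test set, conservation-filtered
#'   when applicable), `conservation_threshold`, `rule` (descriptor).
#' @export
qualifying_motifs <- function(test_set, pool, motifs, instance_threshold = 6,
                              p_cutoff = 0.05, n_random_overrep = 1000,
                              tracks = NULL, conservation_percentile = 10,
                              seed = NULL) {
  if (length(motifs) == 0) stop_fmt("empty motif library")
  extra <- test_set[!test_set$promoter_id %in% pool$promoter_id, , drop = FALSE]
  scan_set <- rbind(pool, extra)
  background <- estimate_background(pool)
  cache <- scan_cache(motifs, scan_set, background, instance_threshold)
  test_idx <- match(test_set$promoter_id, scan_set$promoter_id)
  pool_idx <- seq_len(nrow(pool))
  cons_threshold <- NA_real_
  presence <- cache$presence
  hits_all <- cache$hits
  if (!is.null(tracks)) {
    hits_all <- add_conservation(hits_all, tracks)
    test_hits <- hits_all[hits_all$promoter_id %in% test_set$promoter_id, ,
                          drop = FALSE]
    filt <- conservation_percentile_filter(test_hits, conservation_percentile)
    cons_threshold <- filt$threshold
    hits_all <- hits_all[!is.na(hits_all$conservation_score) &
                           hits_all$conservation_score >= cons_threshold, ,
                         drop = FALSE]
    presence <- presence_matrix(hits_all, cache$motif_ids,
                                cache$promoter_ids)
  }
  # inner draws must come from the pool, not the augmented scan set
  q <- with_seed(seed, {
    .qualify_set(cache, test_idx, p_cutoff, n_random_overrep, presence,
                 draw_pool = pool_idx)
  })
  test_hits <- hits_all[hits_all$promoter_id %in% test_set$promoter_id &
                          hits_all$motif_id %in%
                            cache$motif_ids[q$qualifying], , drop = FALSE]
  list(qualifying = cache$motif_ids[q$qualifying], overrep_p = q$p,
       hits = test_hits, conservation_threshold = cons_threshold,
       rule = list(instance_threshold = instance_threshold,
                   p_cutoff = p_cutoff,
                   n_random_overrep = n_random_overrep,
                   conservation_percentile =
                     if (is.null(tracks)) NA_real_ else conservation_percentile))
}

presence_matrix <- function(hits, motif_ids, promoter_ids) {
  H <- matrix(FALSE, length(motif_ids), length(promoter_ids),
              dimnames = list(motif_ids, promoter_ids))
  if (nrow(hits) > 0) {
    H[cbind(match(hits$motif_id, motif_ids),
            match(hits$promoter_id, promoter_ids))] <- TRUE
  }
  H
}

count_matrix <- function(hits, motif_ids, promoter_ids) {
  C <- matrix(0L, length(motif_ids), length(promoter_ids),
              dimnames = list(motif_ids, promoter_ids))
  if (nrow(hits) > 0) {
    tab <- table(factor(hits$motif_id, motif_ids),
                 factor(hits$promoter_id, promoter_ids))
    C[] <- as.integer(tab)
  }
  C
}

#' Sharing profile of motifs across a promoter set
#'
#' For every motif, the number of distinct promoters in the set containing
#' at least one qualifying hit.  Motifs without hits are retained with
#' count 0.
#'
#' @param hits Hit data.frame (already restricted to qualifying hits).
#' @param promoter_ids The promoter set.
#' @param motif_ids Motifs to profile (default: those present in `hits`).
#' @return A `sharing_profile` data.frame: motif_id, n_promoters.
#' @export
sharing_profile <- function(hits, promoter_ids,
                            motif_ids = unique(hits$motif_id)) {
  hits <- hits[hits$promoter_id %in% promoter_ids, , drop = FALSE]
  n <- vapply(motif_ids, function(m) {
    length(unique(hits$promoter_id[hits$motif_id == m]))
  }, integer(1))
  out <- data.frame(motif_id = as.character(motif_ids), n_promoters = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sharing_profile", "data.frame")
  out
}

#' Motifs present in every promoter of the set
#'
#' @param profile A `sharing_profile`.
#' @param n_promoters Size of the promoter set (strict universality:
#'   `n_promoters_with_hit == n_promoters`).
#' @return Character vector of motif ids.
#' @export
common_motifs <- function(profile, n_promoters) {
  profile$motif_id[profile$n_promoters == n_promoters]
}

#' Summed sharing statistic T
#'
#' `T = sum over motifs of the number of promoters with at least one
#' qualifying hit` - equivalently `sum_k k * M_k` where `M_k` counts
#' motifs shared by exactly k promoters.
#'
#' @param profile A `sharing_profile`.
#' @return Integer T.
#' @export
shared_statistic <- function(profile) {
  as.integer(sum(profile$n_promoters))
}

#' Shared-motif enrichment of a promoter set against random sets
#'
#' Computes the sharing statistic T of the test set under the full
#' qualifying rule, then re-runs the identical rule (over-representation
#' re-tested within each set; conservation threshold held fixed at the
#' test-set value in the conserved variant) on `n_random` random draws of
#' equal cardinality from the pool, and reports the fold
#' `T_observed / median(T_random)` and the add-one-smoothed empirical
#' p-value.
#'
#' @param test_ids Promoter ids of the test set (must be in the pool).
#' @param pool A `promoter_set` (e.g. all miRNA promoters).
#' @param motifs A `motif_library`.
#' @param instance_threshold Instance-score cutoff (default 6).
#' @param p_cutoff Over-representation p cutoff (default 0.05); set to 1
#'   to count every motif with at least one hit.
#' @param n_random Random promoter sets (default 1000).
#' @param n_inner Inner randomizations for the per-set over-representation
#'   test (default 100; 0 disables the over-representation condition,
#'   leaving the hit condition only).
#' @param variant `"unfiltered"` or `"conserved"`.
#' @param tracks `conservation_set`, required for the conserved variant.
#' @param conservation_percentile Top-percentile retained (default 10);
#'   the threshold value is derived from the test set and then held fixed.
#' @param weight `"presence"` (a motif counts once per promoter; the
#'   default) or `"multiplicity"` (total hit count).
#' @param exclude_test Exclude test promoters from the random draws.
#' @param seed Optional seed; the entire randomization (observed inner
#'   draws, then per-outer-set draws) consumes one sequential stream, so
#'   results are reproducible and independent of any execution order.
#' @return An `enrichment_result` list: T_observed, T_random, fold,
#'   p_empirical, n_random, seed, qualifying (observed motif ids),
#'   profile (observed sharing profile), conservation_threshold, rule.
#' @export
promoter_set_enrichment <- function(test_ids, pool, motifs,
                                    instance_threshold = 6, p_cutoff = 0.05,
                                    n_random = 1000, n_inner = 100,
                                    variant = c("unfiltered", "conserved"),
                                    tracks = NULL,
                                    conservation_percentile = 10,
                                    weight = c("presence", "multiplicity"),
                                    exclude_test = FALSE, seed = NULL) {
  variant <- match.arg(variant)
  weight <- match.arg(weight)
  if (!all(test_ids %in% pool$promoter_id)) {
    stop_fmt("test promoter(s) not in pool: %s",
             paste(setdiff(test_ids, pool$promoter_id), collapse = ", "))
  }
  if (variant == "conserved" && is.null(tracks)) {
    stop_fmt("the conserved variant requires conservation tracks")
  }
  if (n_inner > 0 && 1 / (1 + n_inner) > p_cutoff) {
    warning(sprintf(
      "the smallest attainable over-representation p (1/%d) exceeds p_cutoff = %g; no motif can qualify",
      n_inner + 1L, p_cutoff), call. = FALSE)
  }
  k <- length(test_ids)
  if (nrow(pool) < k) stop_fmt("pool smaller than test set")
  background <- estimate_background(pool)
  cache <- scan_cache(motifs, pool, background, instance_threshold)
  cons_threshold <- NA_real_
  presence <- cache$presence
  hits_all <- cache$hits
  if (variant == "conserved") {
    hits_all <- add_conservation(hits_all, tracks)
    test_hits <- hits_all[hits_all$promoter_id %in% test_ids, , drop = FALSE]
    filt <- conservation_percentile_filter(test_hits, conservation_percentile)
    cons_threshold <- filt$threshold
    if (is.na(cons_threshold)) {
      hits_all <- hits_all[0, , drop = FALSE]
    } else {
      hits_all <- hits_all[!is.na(hits_all$conservation_score) &
                             hits_all$conservation_score >= cons_threshold, ,
                           drop = FALSE]
    }
    presence <- presence_matrix(hits_all, cache$motif_ids, cache$promoter_ids)
  }
  counts <- if (weight == "multiplicity") {
    count_matrix(hits_all, cache$motif_ids, cache$promoter_ids)
  } else NULL
  stat_of <- function(idx, qualifying) {
    if (!any(qualifying)) return(0L)
    if (weight == "presence") {
      as.integer(sum(presence[qualifying, idx, drop = FALSE]))
    } else {
      as.integer(sum(counts[qualifying, idx, drop = FALSE]))
    }
  }
  qualify <- function(idx) {
    if (n_inner == 0) {
      rowSums(presence[, idx, drop = FALSE]) >= 1
    } else {
      .qualify_set(cache, idx, p_cutoff, n_inner, presence)$qualifying
    }
  }
  test_idx <- match(test_ids, pool$promoter_id)
  draw_pool <- if (exclude_test) {
    setdiff(seq_len(nrow(pool)), test_idx)
  } else seq_len(nrow(pool))
  if (length(draw_pool) < k) stop_fmt("pool too small after excluding test set")
  res <- with_seed(seed, {
    qual_obs <- qualify(test_idx)
    T_obs <- stat_of(test_idx, qual_obs)
    T_rand <- integer(n_random)
    for (r in seq_len(n_random)) {
      idx <- draw_pool[sample_int(length(draw_pool), k)]
      T_rand[r] <- stat_of(idx, qualify(idx))
    }
    list(qual_obs = qual_obs, T_obs = T_obs, T_rand = T_rand)
  })
  med_rand <- median(res$T_rand)
  fold <- if (med_rand == 0) Inf else res$T_obs / med_rand
  p <- (1 + sum(res$T_rand >= res$T_obs)) / (1 + n_random)
  qual_ids <- cache$motif_ids[res$qual_obs]
  obs_hits <- hits_all[hits_all$promoter_id %in% test_ids &
                         hits_all$motif_id %in% qual_ids, , drop = FALSE]
  profile <- sharing_profile(obs_hits, test_ids, qual_ids)
  structure(list(T_observed = res$T_obs, T_random = res$T_rand,
                 fold = fold, fold_undefined = med_rand == 0,
                 p_empirical = p, n_random = n_random, seed = seed,
                 qualifying = qual_ids, profile = profile,
                 hits = obs_hits,
                 conservation_threshold = cons_threshold,
                 rule = list(instance_threshold = instance_threshold,
                             p_cutoff = p_cutoff, n_inner = n_inner,
                             variant = variant, weight = weight,
                             conservation_percentile =
                               if (variant == "conserved")
                                 conservation_percentile else NA_real_)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result (%s): T_observed = %d, median T_random = %.1f,\n  fold = %.3g, empirical p = %.4g (n_random = %d)\n",
    x$rule$variant, x$T_observed, median(x$T_random), x$fold,
    x$p_empirical, x$n_random))
  invisible(x)
}
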