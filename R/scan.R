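#' Background base composition for likelihood-ratio scoring
#'
#' Mononucleotide frequencies estimated from a promoter pool, with one
#' pseudo-observation per base so no frequency is zero.  Because scanning
#' works on both strands, frequencies are strand-symmetrized by default
#' (A with T, C with G pooled), which makes forward and reverse-complement
#' scans exactly mirror each other.
#'
#' @param promoters A `promoter_set`, or NULL for the uniform background.
#' @param pseudocount Pseudo-observations added per base.
#' @param symmetrize Pool complementary bases.
#' @return A `background` object: named frequency vector (A,C,G,T) with a
#'   `provenance` attribute.
#' @export
estimate_background <- function(promoters = NULL, pseudocount = 1,
                                symmetrize = TRUE) {
  if (is.null(promoters)) {
    return(structure(setNames(rep(0.25, 4), BASES), provenance = "uniform",
                     class = "background"))
  }
  all_seq <- paste(promoters$sequence, collapse = "")
  counts <- vapply(BASES, function(b) {
    lengths(regmatches(all_seq, gregexpr(b, all_seq, fixed = TRUE)))
  }, numeric(1))
  counts <- counts + pseudocount
  if (symmetrize) {
    at <- (counts["A"] + counts["T"]) / 2
    cg <- (counts["C"] + counts["G"]) / 2
    counts <- setNames(c(at, cg, cg, at), BASES)
  }
  structure(counts / sum(counts), provenance = "pool_estimated",
            class = "background")
}

#' Uniform background (each base 1/4)
#' @export
uniform_background <- function() estimate_background(NULL)

# integer-encode a sequence: A=1 C=2 G=3 T=4, N -> NA
encode_sequence <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], BASES)
  codes
}

# per-position log2 likelihood-ratio weights: w x 4 matrix
motif_log_weights <- function(motif, background) {
  lw <- log2(motif$freq)
  lw <- sweep(lw, 2, log2(as.numeric(background)), "-")
  lw
}

# log2 instance score at every valid start (length L-w+1), NA where the
# window contains N; vectorized over positions
position_scores <- function(motif, codes, background) {
  w <- motif$width
  L <- length(codes)
  if (w > L) return(numeric(0))
  lw <- motif_log_weights(motif, background)
  n_pos <- L - w + 1L
  scores <- numeric(n_pos)
  for (i in seq_len(w)) {
    scores <- scores + lw[i, ][codes[i:(i + n_pos - 1L)]]
  }
  scores
}

#' Instance score of a single window
#'
#' The log2 likelihood ratio of a w-mer under the motif frequency model
#' against the background base composition:
#' `log2( prod_i f_i(b_i) / prod_i q(b_i) )`.
#'
#' @param motif A `motif_matrix`.
#' @param window Character w-mer over A/C/G/T (N makes the window
#'   unscorable and returns `NA`).
#' @param background A `background` (default uniform).
#' @return The instance score (log2 scale), or `NA_real_` for windows
#'   containing N.
#' @export
likelihood_ratio <- function(motif, window, background = uniform_background()) {
  codes <- encode_sequence(toupper(window))
  if (length(codes) != motif$width) {
    stop_fmt("window length %d does not match motif width %d",
             length(codes), motif$width)
  }
  if (anyNA(codes)) return(NA_real_)
  lw <- motif_log_weights(motif, background)
  sum(lw[cbind(seq_len(motif$width), codes)])
}

#' Scan a promoter for high-scoring motif instances
#'
#' Every window on the forward strand, and (by default) every window whose
#' reverse complement matches on the minus strand, is scored; windows at or
#' above `threshold` become hits.  Windows containing N are skipped.
#' Coordinates are 0-based half-open in promoter space.
#'
#' @param motif A `motif_matrix`.
#' @param promoter One row of a `promoter_set` (or a list with
#'   `promoter_id` and `sequence`).
#' @param background A `background`.
#' @param threshold Minimum instance score (log2 likelihood ratio); the
#'   conventional cutoff 6 means a likelihood ratio of at least 64.
#' @param both_strands Scan the minus strand as well.
#' @return Hit data.frame: promoter_id, start, end, width, strand,
#'   motif_id, instance_score; sorted by start.
#' @export
scan_promoter <- function(motif, promoter, background = uniform_background(),
                          threshold = 6, both_strands = TRUE) {
  codes <- encode_sequence(promoter$sequence)
  fwd <- position_scores(motif, codes, background)
  keep_f <- which(!is.na(fwd) & fwd >= threshold)
  res <- list(data.frame(start = keep_f - 1L,
                         strand = rep("+", length(keep_f)),
                         instance_score = fwd[keep_f],
                         stringsAsFactors = FALSE))
  if (both_strands) {
    rev_scores <- position_scores(reverse_complement_motif(motif), codes,
                                  background)
    keep_r <- which(!is.na(rev_scores) & rev_scores >= threshold)
    res[[2]] <- data.frame(start = keep_r - 1L,
                           strand = rep("-", length(keep_r)),
                           instance_score = rev_scores[keep_r],
                           stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  data.frame(promoter_id = rep(promoter$promoter_id, nrow(hits)),
             start = hits$start, end = hits$start + motif$width,
             width = rep(motif$width, nrow(hits)), strand = hits$strand,
             motif_id = rep(motif$motif_id, nrow(hits)),
             instance_score = hits$instance_score,
             conservation_score = rep(NA_real_, nrow(hits)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a motif library over a promoter set
#'
#' @param motifs A `motif_library`.
#' @param promoters A `promoter_set`.
#' @inheritParams scan_promoter
#' @return One hit data.frame covering all motif/promoter pairs.
#' @export
scan_hits <- function(motifs, promoters, background = uniform_background(),
                      threshold = 6, both_strands = TRUE) {
  out <- list()
  for (m in motifs) {
    for (i in seq_len(nrow(promoters))) {
      out[[length(out) + 1L]] <-
        scan_promoter(m, promoters[i, ], background, threshold, both_strands)
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- cbind(empty_hits(), width = integer())
  rownames(hits) <- NULL
  hits
}

#' Per-sequence averaged likelihood ratio
#'
#' The arithmetic mean of the (linear-scale) likelihood ratio over all
#' scorable windows of a promoter, pooling both strands.  This is the
#' per-sequence statistic entering the subset-averaged raw score.
#'
#' @inheritParams scan_promoter
#' @return The mean likelihood ratio `s >= 0`.
#' @export
sequence_score <- function(motif, promoter, background = uniform_background(),
                           both_strands = TRUE) {
  codes <- encode_sequence(promoter$sequence)
  sc <- position_scores(motif, codes, background)
  if (both_strands) {
    sc <- c(sc, position_scores(reverse_complement_motif(motif), codes,
                                background))
  }
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0) {
    stop_fmt("promoter '%s' has no scorable windows for motif '%s'",
             promoter$promoter_id, motif$motif_id)
  }
  mean(2^sc)
}

#' Subset-averaged raw score of a promoter set
#'
#' Averages the per-sequence likelihood ratios over all subsets of the
#' sequence set (empty subset included): the average likelihood ratio is
#' `A = 2^-n * sum_{S subset} prod_{i in S} s_i = prod_i (1 + s_i)/2`,
#' evaluated in log space, and the raw score is `log2 A`.  A raw score
#' above zero signifies over-representation of the motif in the set.
#'
#' @param sequence_scores Vector of per-sequence averaged likelihood
#'   ratios, all `>= 0`.
#' @return The raw score (log2 scale).
#' @export
set_raw_score <- function(sequence_scores) {
  if (length(sequence_scores) < 1) stop_fmt("need at least one sequence score")
  if (any(sequence_scores < 0)) stop_fmt("sequence scores must be >= 0")
  sum(log2((1 + sequence_scores) / 2))
}

#' Randomization test for motif over-representation
#'
#' Compares the raw score of a test promoter set with raw scores of random
#' promoter sets of equal cardinality drawn without replacement from a
#' background pool.  The empirical p-value uses add-one smoothing,
#' `p = (1 + #{raw_random >= raw_observed}) / (1 + n_random)`, so its floor
#' at 1000 randomizations is about 0.001.
#'
#' @param motif A `motif_matrix`.
#' @param test_set A `promoter_set` (the sequences of interest).
#' @param pool A `promoter_set`, at least as large as the test set.
#' @param background A `background`; defaults to frequencies estimated from
#'   the pool.
#' @param n_random Number of random sets.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param pool_scores Optional precomputed per-sequence scores for the
#'   pool, as returned by [sequence_score()] per promoter, to avoid
#'   rescanning.
#' @return An `overrep_result` list: motif_id, raw_score, sequence_scores,
#'   n_random, p_value, raw_random.
#' @export
overrepresentation_test <- function(motif, test_set, pool,
                                    background = NULL, n_random = 1000,
                                    seed = NULL, pool_scores = NULL) {
  if (nrow(pool) < nrow(test_set)) {
    stop_fmt("pool (%d) is smaller than the test set (%d)",
             nrow(pool), nrow(test_set))
  }
  if (n_random < 1) stop_fmt("n_random must be >= 1")
  if (is.null(background)) background <- estimate_background(pool)
  s_test <- vapply(seq_len(nrow(test_set)), function(i) {
    sequence_score(motif, test_set[i, ], background)
  }, numeric(1))
  raw_obs <- set_raw_score(s_test)
  if (is.null(pool_scores)) {
    pool_scores <- vapply(seq_len(nrow(pool)), function(i) {
      sequence_score(motif, pool[i, ], background)
    }, numeric(1))
  }
  log_terms <- log2((1 + pool_scores) / 2)
  k <- nrow(test_set)
  raw_random <- with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      sum(log_terms[sample_int(length(log_terms), k)])
    }, numeric(1))
  })
  p <- (1 + sum(raw_random >= raw_obs)) / (1 + n_random)
  structure(list(motif_id = motif$motif_id, raw_score = raw_obs,
                 sequence_scores = s_test, n_random = n_random,
                 p_value = p, raw_random = raw_random),
            class = "overrep_result")
}

# Precompute, for a motif library over a promoter set, everything the
# set-level analyses reuse: per-sequence scores, their raw-score log terms,
# hit presence, and the full hit table.  All randomization layers index
# into this cache instead of rescanning.
scan_cache <- function(motifs, promoters, background, threshold = 6) {
  n_m <- length(motifs)
  n_p <- nrow(promoters)
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  S <- matrix(0, n_m, n_p, dimnames = list(ids, promoters$promoter_id))
  hits_list <- vector("list", n_m * n_p)
  codes_list <- lapply(promoters$sequence, encode_sequence)
  for (mi in seq_len(n_m)) {
    motif <- motifs[[mi]]
    rc <- reverse_complement_motif(motif)
    for (pi in seq_len(n_p)) {
      codes <- codes_list[[pi]]
      fwd <- position_scores(motif, codes, background)
      rev_ <- position_scores(rc, codes, background)
      all_sc <- c(fwd, rev_)
      all_sc <- all_sc[!is.na(all_sc)]
      if (length(all_sc) == 0) {
        stop_fmt("promoter '%s' has no scorable windows for motif '%s'",
                 promoters$promoter_id[pi], motif$motif_id)
      }
      S[mi, pi] <- mean(2^all_sc)
      keep_f <- which(!is.na(fwd) & fwd >= threshold)
      keep_r <- which(!is.na(rev_) & rev_ >= threshold)
      n_hit <- length(keep_f) + length(keep_r)
      if (n_hit > 0) {
        hits_list[[(mi - 1L) * n_p + pi]] <- data.frame(
          promoter_id = rep(promoters$promoter_id[pi], n_hit),
          start = c(keep_f, keep_r) - 1L,
          end = c(keep_f, keep_r) - 1L + motif$width,
          width = rep(motif$width, n_hit),
          strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
          motif_id = rep(motif$motif_id, n_hit),
          instance_score = c(fwd[keep_f], rev_[keep_r]),
          conservation_score = rep(NA_real_, n_hit),
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, hits_list)
  if (is.null(hits)) hits <- cbind(empty_hits(), width = integer())
  rownames(hits) <- NULL
  H <- matrix(FALSE, n_m, n_p, dimnames = dimnames(S))
  if (nrow(hits) > 0) {
    H[cbind(match(hits$motif_id, ids),
            match(hits$promoter_id, promoters$promoter_id))] <- TRUE
  }
  list(motif_ids = ids, promoter_ids = promoters$promoter_id,
       seq_scores = S, log_terms = log2((1 + S) / 2), presence = H,
       hits = hits, threshold = threshold)
}
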