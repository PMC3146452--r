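# small in-code fixtures shared across test files

make_promoters <- function(seqs, ids = sprintf("P%d", seq_along(seqs))) {
  out <- data.frame(promoter_id = ids, mirna_id = NA_character_,
                    sequence = toupper(seqs), strand = "+",
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_set", "data.frame")
  out
}

random_promoters <- function(n, len, seed, gc = 0.5,
                             ids = sprintf("P%03d", seq_len(n))) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1)))
  make_promoters(seqs, ids)
}

# motif whose frequency matrix puts probability 1 - 3*eps on each base of
# `consensus`
consensus_motif <- function(consensus, id = "M1", eps = 1e-4) {
  bases <- strsplit(consensus, "")[[1]]
  freq <- t(vapply(bases, function(b) {
    v <- rep(eps, 4)
    v[match(b, c("A", "C", "G", "T"))] <- 1 - 3 * eps
    v
  }, numeric(4)))
  m <- mirprom::motif_matrix(id, freq * 1000, pseudocount = 0)
  m
}

uniform_motif <- function(width = 6, id = "MU") {
  mirprom::motif_matrix(id, matrix(25, width, 4), pseudocount = 0)
}

random_motif <- function(width, seed, id = "MR") {
  counts <- withr::with_seed(seed,
    matrix(stats::runif(width * 4, 0.5, 20), width, 4))
  mirprom::motif_matrix(id, counts, pseudocount = 0.01)
}

random_motif_library <- function(n, widths, seed, ic = c(0.8, 1.4)) {
  cfg <- mirprom::sim_config(seed = seed, n_motifs = n,
                             motif_widths = widths,
                             motif_information_bits = ic,
                             n_planted_motifs = 0)
  mirprom::gen_motif_library(cfg, seed = seed)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent log-space oracle for the instance score of one window
oracle_instance_score <- function(motif, window, q = rep(0.25, 4)) {
  codes <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  s <- 0
  for (i in seq_along(codes)) {
    s <- s + log2(motif$freq[i, codes[i]]) - log2(q[codes[i]])
  }
  unname(s)
}
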