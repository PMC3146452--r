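test_that("instance scores follow the likelihood-ratio product", {
  m <- consensus_motif("ACGT", eps = 0)
  # probability 1 on each consensus base over uniform background:
  # LR = (1/0.25)^4 = 256, log2 = 8
  expect_equal(likelihood_ratio(m, "ACGT"), 8)
  mu <- uniform_motif(6)
  expect_equal(likelihood_ratio(mu, "ACGTAC"), 0)
  expect_true(is.na(likelihood_ratio(mu, "ACGTNN")))
  expect_error(likelihood_ratio(mu, "ACG"), "length")
})

test_that("instance scores agree with a brute-force oracle", {
  m <- random_motif(8, seed = 101)
  windows <- withr::with_seed(202, vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
  }, character(1)))
  q <- c(0.3, 0.2, 0.2, 0.3)
  bg <- structure(setNames(q, c("A", "C", "G", "T")), class = "background")
  for (wd in windows) {
    expect_equal(likelihood_ratio(m, wd, bg), oracle_instance_score(m, wd, q),
                 tolerance = 1e-9)
  }
})

test_that("instance score is additive over concatenated half-motifs", {
  left <- random_motif(5, seed = 11, id = "L")
  right <- random_motif(6, seed = 12, id = "R")
  whole <- motif_matrix("LR", rbind(left$counts, right$counts),
                        pseudocount = 0.01)
  w1 <- "ACGTA"; w2 <- "GGTACC"
  expect_equal(likelihood_ratio(whole, paste0(w1, w2)),
               likelihood_ratio(left, w1) + likelihood_ratio(right, w2),
               tolerance = 1e-9)
})

test_that("scan_promoter finds planted sites on both strands", {
  site <- "ACGTACGTAC"
  m <- consensus_motif(site)
  base <- strrep("A", 2000)
  fwd <- base
  substr(fwd, 701, 710) <- site         # 0-based start 700
  substr(fwd, 301, 310) <- revcomp(site)  # 0-based start 300, minus strand
  prom <- make_promoters(fwd, "p1")[1, ]
  hits <- scan_promoter(m, prom, threshold = 6)
  expect_true(any(hits$start == 700 & hits$strand == "+"))
  expect_true(any(hits$start == 300 & hits$strand == "-"))
  expect_equal(hits$end, hits$start + 10L)
  expect_true(all(hits$instance_score >= 6))
  # at a near-perfect threshold only the two planted placements remain
  exact <- scan_promoter(m, prom, threshold = 15)
  expect_equal(exact$start, c(300L, 700L))
  expect_equal(exact$strand, c("-", "+"))
  expect_equal(nrow(scan_promoter(m, prom, threshold = Inf)), 0L)
})

test_that("scanning a reverse-complemented sequence mirrors hits", {
  prom <- random_promoters(1, 400, seed = 31)
  m <- random_motif(7, seed = 32)
  rc <- make_promoters(revcomp(prom$sequence), "P001")
  h1 <- scan_promoter(m, prom[1, ], threshold = 2)
  h2 <- scan_promoter(m, rc[1, ], threshold = 2)
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at start s maps to a - hit at start L - s - w
  key1 <- paste(400 - h1$start - 7, chartr("+-", "-+", h1$strand))
  key2 <- paste(h2$start, h2$strand)
  expect_setequal(key1, key2)
  expect_equal(sort(h1$instance_score), sort(h2$instance_score),
               tolerance = 1e-9)
})

test_that("windows containing N are skipped during scanning", {
  m <- consensus_motif("ACGTTCGT")  # non-palindromic consensus
  s <- strrep("G", 100)
  substr(s, 41, 48) <- "ACGTTCGT"
  substr(s, 60, 60) <- "N"
  prom <- make_promoters(s, "p")[1, ]
  hits <- scan_promoter(m, prom, threshold = 6)
  expect_equal(hits$start, 40L)
  # every window overlapping the N is absent even at threshold -Inf
  all_hits <- scan_promoter(m, prom, threshold = -Inf)
  expect_false(any(all_hits$start > 51 & all_hits$start < 60))
})

test_that("sequence_score is the mean likelihood ratio over windows", {
  mu <- uniform_motif(6)
  prom <- random_promoters(1, 200, seed = 5)
  expect_equal(sequence_score(mu, prom[1, ]), 1)

  # exhaustive enumeration oracle on a random motif
  m <- random_motif(8, seed = 77)
  bg <- uniform_background()
  lr <- c(
    vapply(1:(200 - 7), function(p) {
      2^likelihood_ratio(m, substr(prom$sequence, p, p + 7), bg)
    }, numeric(1)),
    vapply(1:(200 - 7), function(p) {
      2^likelihood_ratio(reverse_complement_motif(m),
                         substr(prom$sequence, p, p + 7), bg)
    }, numeric(1)))
  expect_equal(sequence_score(m, prom[1, ], bg), mean(lr), tolerance = 1e-9)

  allN <- make_promoters(strrep("N", 50), "n")
  expect_error(sequence_score(mu, allN[1, ]), "no scorable windows")
})

test_that("the raw score equals the subset-average identity and enumeration", {
  expect_equal(set_raw_score(1), 0)
  expect_equal(set_raw_score(c(1, 3)), 1)  # A = (2*4)/4 = 2
  s <- withr::with_seed(9, runif(10, 0, 5))
  # explicit enumeration over all 2^10 subsets, empty subset included
  total <- 0
  for (mask in 0:(2^10 - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:9)))
    total <- total + prod(s[sel])
  }
  expect_equal(set_raw_score(s), log2(total / 2^10), tolerance = 1e-9)
  expect_error(set_raw_score(numeric(0)))
  expect_error(set_raw_score(c(1, -0.1)), ">= 0")
})

test_that("raw score is symmetric, monotone and additive over copies", {
  s <- c(0.2, 1.7, 3.1, 0.9)
  expect_equal(set_raw_score(s), set_raw_score(rev(s)))
  bigger <- s; bigger[2] <- bigger[2] + 0.5
  expect_gt(set_raw_score(bigger), set_raw_score(s))
  expect_equal(set_raw_score(rep(2.5, 7)), 7 * log2(3.5 / 2),
               tolerance = 1e-12)
})

test_that("background columns matching the motif contribute zero score", {
  counts <- rbind(c(40, 0, 0, 0), c(10, 10, 10, 10), c(0, 0, 40, 0),
                  c(10, 10, 10, 10))
  m <- motif_matrix("m", counts, pseudocount = 0)
  # positions 2 and 4 are uniform: they contribute exactly 0 whatever the
  # base, so only the two consensus columns (2 bits each) remain
  for (w in c("AAGA", "ACGC", "AGGG", "ATGT")) {
    expect_equal(likelihood_ratio(m, w), 4, tolerance = 1e-12)
  }
})

test_that("overrepresentation test hits its p-value floor on planted sets", {
  site <- "ACGTTGCAGT"
  m <- consensus_motif(site)
  pool <- random_promoters(40, 300, seed = 21)
  test <- random_promoters(5, 300, seed = 22,
                           ids = sprintf("T%d", 1:5))
  for (i in 1:5) {
    for (at in c(11, 101, 201)) {
      substr(test$sequence[i], at, at + 9) <- site
    }
  }
  res <- overrepresentation_test(m, test, pool, n_random = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$raw_score, 0)
  expect_error(overrepresentation_test(m, pool, test), "smaller")
})

test_that("add-one smoothing keeps empirical p in (0, 1]", {
  mu <- uniform_motif(6)
  pool <- random_promoters(10, 100, seed = 3)
  res <- overrepresentation_test(mu, pool[1:2, ], pool, n_random = 1,
                                 seed = 4)
  # with one random draw p is 1/2 or 1; a uniform motif ties every set
  expect_true(res$p_value %in% c(0.5, 1))
  expect_equal(res$p_value, 1)  # ties count as >= observed
})
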