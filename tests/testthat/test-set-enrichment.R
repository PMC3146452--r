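fake_hits <- function(promoter_id, motif_id) {
  data.frame(promoter_id = promoter_id, start = 0L, end = 5L, width = 5L,
             motif_id = motif_id, instance_score = 7, strand = "+",
             conservation_score = NA_real_, stringsAsFactors = FALSE)
}

test_that("sharing profile counts distinct promoters per motif", {
  hits <- fake_hits(c("P1", "P1", "P3"), "m1")
  prof <- sharing_profile(hits, c("P1", "P2", "P3"), c("m1", "m2"))
  expect_equal(prof$n_promoters, c(2L, 0L))  # m2 retained with zero
  # brute-force nested-loop oracle on random placements
  set <- sprintf("P%d", 1:8)
  motifs <- sprintf("m%d", 1:6)
  hits2 <- withr::with_seed(44, fake_hits(
    sample(set, 60, replace = TRUE), sample(motifs, 60, replace = TRUE)))
  prof2 <- sharing_profile(hits2, set, motifs)
  for (m in motifs) {
    n <- 0L
    for (p in set) {
      found <- FALSE
      for (r in seq_len(nrow(hits2))) {
        if (hits2$motif_id[r] == m && hits2$promoter_id[r] == p) found <- TRUE
      }
      n <- n + found
    }
    expect_equal(prof2$n_promoters[prof2$motif_id == m], n)
  }
})

test_that("common motifs require strict universality", {
  prof <- sharing_profile(fake_hits(sprintf("P%d", 1:12), "m_all"),
                          sprintf("P%d", 1:12), c("m_all", "m_11"))
  prof$n_promoters[prof$motif_id == "m_11"] <- 11L
  expect_equal(common_motifs(prof, 12), "m_all")
  expect_equal(common_motifs(prof[0, ], 12), character(0))
})

test_that("the sharing statistic T equals both counting formulas", {
  prof <- data.frame(motif_id = c("a", "b", "c"), n_promoters = c(2L, 3L, 1L))
  expect_equal(shared_statistic(prof), 6L)
  expect_equal(shared_statistic(prof[0, ]), 0L)
  for (i in 1:100) {
    counts <- withr::with_seed(500 + i,
                               sample(0:12, 20, replace = TRUE))
    p <- data.frame(motif_id = sprintf("m%d", 1:20), n_promoters = counts)
    mk <- table(factor(counts, levels = 0:12))
    expect_equal(shared_statistic(p),
                 as.integer(sum(as.integer(names(mk)) * mk)))
  }
})

test_that("planted motifs qualify and an indifferent motif does not", {
  site <- "TTACGCGTAA"
  m_planted <- consensus_motif(site, id = "planted")
  m_absent <- consensus_motif("GGGGCCCCGG", id = "absent")
  lib <- structure(list(planted = m_planted, absent = m_absent),
                   class = "motif_library")
  pool <- random_promoters(40, 300, seed = 61)
  test_ids <- pool$promoter_id[1:6]
  for (i in 1:6) {
    substr(pool$sequence[i], 51, 60) <- site
    substr(pool$sequence[i], 151, 160) <- site
  }
  q <- qualifying_motifs(pool[1:6, ], pool, lib, n_random_overrep = 99,
                         seed = 9)
  expect_true("planted" %in% q$qualifying)
  expect_false("absent" %in% q$qualifying)
  expect_equal(unname(q$overrep_p["planted"]), 1 / 100)
  expect_true(all(q$hits$motif_id == "planted"))
})

test_that("enrichment of a planted promoter set is maximal", {
  cfg <- sim_config(seed = 15, n_pool_promoters = 50, n_test_promoters = 6,
                    promoter_length = 500, n_motifs = 8,
                    n_planted_motifs = 3, sharing_fraction = 1)
  sim <- simulate_study(cfg)
  e <- promoter_set_enrichment(sim$test_ids, sim$promoters, sim$motifs,
                               n_random = 99, n_inner = 50, seed = 16)
  expect_gt(e$fold, 1)
  expect_equal(e$p_empirical, 1 / 100)
  expect_true(all(sprintf("MOTIF_%02d", 1:3) %in% e$qualifying))
})

test_that("a test set equal to the whole pool gives fold exactly 1", {
  pool <- random_promoters(8, 200, seed = 71)
  lib <- random_motif_library(4, 6:8, seed = 72)
  e <- promoter_set_enrichment(pool$promoter_id, pool, lib,
                               instance_threshold = 3, p_cutoff = 1,
                               n_random = 20, n_inner = 0, seed = 73)
  expect_true(all(e$T_random == e$T_observed))
  expect_equal(e$fold, 1)
  expect_equal(e$p_empirical, 1)
})

test_that("smoothing arithmetic bounds the empirical p at n_random = 1", {
  pool <- random_promoters(10, 150, seed = 81)
  lib <- random_motif_library(3, 6:8, seed = 82)
  e <- promoter_set_enrichment(pool$promoter_id[1:3], pool, lib,
                               instance_threshold = 4, p_cutoff = 1,
                               n_random = 1, n_inner = 0, seed = 83)
  expect_true(e$p_empirical %in% c(0.5, 1))
})

test_that("the conserved variant never exceeds the unfiltered T", {
  cfg <- sim_config(seed = 25, n_pool_promoters = 40, n_test_promoters = 6,
                    promoter_length = 400, n_motifs = 10,
                    n_planted_motifs = 3)
  sim <- simulate_study(cfg)
  e_un <- promoter_set_enrichment(sim$test_ids, sim$promoters, sim$motifs,
                                  n_random = 20, n_inner = 30, seed = 26)
  e_co <- promoter_set_enrichment(sim$test_ids, sim$promoters, sim$motifs,
                                  n_random = 20, n_inner = 30, seed = 26,
                                  variant = "conserved", tracks = sim$tracks)
  expect_lte(e_co$T_observed, e_un$T_observed)
  expect_false(is.na(e_co$conservation_threshold))
})

test_that("estimated fold increases with the planted sharing level", {
  mean_fold <- function(sharing) {
    folds <- vapply(1:10, function(s) {
      cfg <- sim_config(seed = 300 + s, n_pool_promoters = 40,
                        n_test_promoters = 8, promoter_length = 400,
                        n_motifs = 6, n_planted_motifs = 3,
                        sharing_fraction = sharing, sites_per_promoter = 1)
      sim <- simulate_study(cfg)
      e <- promoter_set_enrichment(sim$test_ids, sim$promoters, sim$motifs,
                                   p_cutoff = 1, n_random = 50, n_inner = 0,
                                   seed = 400 + s)
      med <- median(e$T_random)
      e$T_observed / max(med, 0.5)  # guard the motif-poor draws
    }, numeric(1))
    mean(folds)
  }
  f25 <- mean_fold(0.25)
  f50 <- mean_fold(0.5)
  f100 <- mean_fold(1.0)
  expect_lt(f25, f50)
  expect_lt(f50, f100)
})

test_that("identical seeds reproduce the randomization exactly", {
  cfg <- sim_config(seed = 33, n_pool_promoters = 30, n_test_promoters = 5,
                    promoter_length = 300, n_motifs = 6)
  sim <- simulate_study(cfg)
  e1 <- promoter_set_enrichment(sim$test_ids, sim$promoters, sim$motifs,
                                n_random = 40, n_inner = 20, seed = 34)
  e2 <- promoter_set_enrichment(sim$test_ids, sim$promoters, sim$motifs,
                                n_random = 40, n_inner = 20, seed = 34)
  expect_identical(e1$T_random, e2$T_random)
  expect_identical(e1$qualifying, e2$qualifying)
})
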