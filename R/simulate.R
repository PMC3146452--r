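#' Simulation configuration
#'
#' Parameters of the synthetic study generator.  Defaults mirror the scale
#' of a genome-backed miRNA promoter study: a 167-promoter pool, a
#' 12-promoter test set, 2 kb promoters at 41% GC, and a 30-motif library
#' standing in for a few-hundred-motif compendium.  Planted motifs carry
#' high per-column information so consensus-sampled sites score well above
#' the instance threshold; conservation is Beta-distributed per base with
#' an elevated component over planted sites; Ct values follow
#' reference + group shift + donor effect + residual noise.
#'
#' @param seed Master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_pool_promoters,n_test_promoters,promoter_length,gc_content
#'   Promoter pool geometry and composition.
#' @param n_motifs,motif_widths,motif_information_bits Library size, width
#'   range, per-column information range (bits) for non-planted motifs.
#' @param n_planted_motifs,planted_widths,planted_information_bits,sharing_fraction,
#'   sites_per_promoter,proximal_bias Planting scheme: the first
#'   `n_planted_motifs` motifs of the library are written into a
#'   `sharing_fraction` of test promoters, `sites_per_promoter` sites
#'   each, landing in the proximal 500 bp with probability
#'   `proximal_bias`.
#' @param proximal_window Width of the proximal window (bp).
#' @param conservation_background,conservation_planted Beta(a,b) shape
#'   pairs for background and planted-site per-base conservation.
#' @param cell_types Cell-type labels; the first is the monocyte arm, the
#'   rest DC subsets.
#' @param n_donors,donor_sd,residual_sd,base_dct Ct model: per-donor
#'   normal effect, residual noise, baseline dCt of a detected miRNA.
#' @param n_ct_mirnas,n_up_dc,n_up_mono,n_undetected,shift Panel layout
#'   and the dCt group shift (cycles; negative = higher expression) for
#'   designated miRNAs.
#' @param tf_logistic_intercept,tf_logistic_slope Presence-probability
#'   logistic in a motif's true sharing level k.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_pool_promoters = 167, n_test_promoters = 12,
                       promoter_length = 2000, gc_content = 0.41,
                       n_motifs = 30, motif_widths = 7:14,
                       motif_information_bits = c(1.5, 1.9),
                       n_planted_motifs = 5,
                       planted_widths = 10:14,
                       planted_information_bits = c(1.9, 1.95),
                       sharing_fraction = 1.0, sites_per_promoter = 2,
                       proximal_bias = 0.8, proximal_window = 500,
                       conservation_background = c(1, 3),
                       conservation_planted = c(50, 1),
                       cell_types = c("monocyte", "iDC", "mDC", "tDC", "atDC"),
                       n_donors = 3, donor_sd = 0.5, residual_sd = 0.5,
                       base_dct = 8, n_ct_mirnas = 60, n_up_dc = 5,
                       n_up_mono = 5, n_undetected = 5, shift = -6,
                       tf_logistic_intercept = -2, tf_logistic_slope = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_content >= 0, cfg$gc_content <= 1,
            cfg$sharing_fraction >= 0, cfg$sharing_fraction <= 1,
            cfg$proximal_bias >= 0, cfg$proximal_bias <= 1,
            all(cfg$conservation_background > 0),
            all(cfg$conservation_planted > 0),
            cfg$n_planted_motifs <= cfg$n_motifs)
  structure(cfg, class = "sim_config")
}

#' Generate a background promoter pool with a locus table
#'
#' I.i.d. sequences at the configured GC content.  The locus table maps
#' miRNAs to promoters with a few duplicated-locus miRNAs so the promoter
#' count exceeds the miRNA count, as real annotation does.
#'
#' @param config A `sim_config`.
#' @param seed Seed (default `config$seed`).
#' @return List: `promoters` (a `promoter_set`), `locus` (data.frame
#'   mirna_id, promoter_id), `test_ids` (the designated test set).
#' @export
gen_promoter_pool <- function(config, seed = config$seed) {
  n <- config$n_pool_promoters
  L <- config$promoter_length
  probs <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
             G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seqs <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  })
  pid <- sprintf("prom_%03d", seq_len(n))
  n_dup <- min(10L, max(0L, n - 1L))
  n_mirna <- n - n_dup
  mir_of_prom <- c(seq_len(n_mirna), seq_len(n_dup))
  mid <- sprintf("mir_%03d", mir_of_prom)
  promoters <- data.frame(promoter_id = pid, mirna_id = mid, sequence = seqs,
                          strand = "+", stringsAsFactors = FALSE)
  class(promoters) <- c("promoter_set", "data.frame")
  list(promoters = promoters,
       locus = data.frame(mirna_id = mid, promoter_id = pid,
                          stringsAsFactors = FALSE),
       test_ids = pid[seq_len(config$n_test_promoters)])
}

# one motif column with the dominant base at probability c solving
# 2 + c log2 c + (1-c) log2((1-c)/3) = target bits
.column_for_ic <- function(target_bits, dominant) {
  ic_of <- function(cc) {
    rest <- (1 - cc) / 3
    h <- cc * log2(cc) + if (rest > 0) 3 * rest * log2(rest) else 0
    2 + h
  }
  if (target_bits <= 0) {
    cc <- 0.25
  } else if (target_bits >= 2) {
    cc <- 1 - 1e-9
  } else {
    cc <- stats::uniroot(function(x) ic_of(x) - target_bits,
                         c(0.25 + 1e-9, 1 - 1e-9))$root
  }
  col <- rep((1 - cc) / 3, 4)
  col[dominant] <- cc
  col
}

#' Generate a motif library of controlled information content
#'
#' Each column has a random dominant base whose probability is solved so
#' the column's information content hits a target drawn from the
#' configured range; the first `n_planted_motifs` motifs use the
#' (higher) planted range.  Counts are frequencies scaled to 1000
#' observations.
#'
#' @param config A `sim_config`.
#' @param seed Seed.
#' @return A `motif_library`.
#' @export
gen_motif_library <- function(config, seed = config$seed + 1L) {
  with_seed(seed, {
    motifs <- lapply(seq_len(config$n_motifs), function(i) {
      planted <- i <= config$n_planted_motifs
      # planted motifs draw from their own (wider, higher-information)
      # ranges so a planted site carries enough total information to be
      # specific within a 2 kb window
      w <- if (planted) sample(config$planted_widths, 1) else
        sample(config$motif_widths, 1)
      rng <- if (planted) config$planted_information_bits else
        config$motif_information_bits
      freq <- t(vapply(seq_len(w), function(j) {
        .column_for_ic(runif(1, rng[1], rng[2]), sample.int(4, 1))
      }, numeric(4)))
      m <- motif_matrix(sprintf("MOTIF_%02d", i), freq * 1000,
                        tf_name = sprintf("TF%02d", i), pseudocount = 0.01)
      m
    })
    names(motifs) <- vapply(motifs, `[[`, character(1), "motif_id")
    structure(motifs, class = "motif_library")
  })
}

# sample a site sequence from the motif's frequency model
.sample_site <- function(motif) {
  paste(vapply(seq_len(motif$width), function(i) {
    sample(BASES, 1, prob = motif$freq[i, ])
  }, character(1)), collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Plant motif sites into test promoters
#'
#' For each of the first `n_planted_motifs` motifs, writes
#' consensus-sampled sites into `ceiling(sharing_fraction * n_test)` test
#' promoters (`sites_per_promoter` sites each), overwriting background
#' bases so lengths are preserved.  Positions land in the proximal window
#' with probability `proximal_bias`, strand is Bernoulli(1/2), and planted
#' sites never overlap each other within a promoter.
#'
#' @param pool Output of [gen_promoter_pool()] (modified in place and
#'   returned).
#' @param motifs A `motif_library`.
#' @param config A `sim_config`.
#' @param seed Seed.
#' @return List: `promoters` (modified `promoter_set`), `truth`
#'   (data.frame promoter_id, motif_id, start, strand, width).
#' @export
plant_sites <- function(pool, motifs, config, seed = config$seed + 2L) {
  promoters <- pool$promoters
  test_ids <- pool$test_ids
  L <- config$promoter_length
  win <- min(config$proximal_window, L %/% 2)
  truth <- list()
  occupied <- lapply(setNames(test_ids, test_ids), function(x) integer(0))
  with_seed(seed, {
    for (mi in seq_len(config$n_planted_motifs)) {
      motif <- motifs[[mi]]
      w <- motif$width
      n_share <- ceiling(config$sharing_fraction * length(test_ids))
      share_ids <- test_ids[seq_len(n_share)]
      for (pid in share_ids) {
        for (si in seq_len(config$sites_per_promoter)) {
          for (try in 1:200) {
            start <- if (runif(1) < config$proximal_bias) {
              sample((L - win):(L - w), 1)
            } else {
              sample(0:(L - win - 1L), 1)
            }
            span <- start:(start + w - 1L)
            if (!any(span %in% occupied[[pid]])) break
          }
          occupied[[pid]] <- c(occupied[[pid]], span)
          site <- .sample_site(motif)
          strand <- if (runif(1) < 0.5) "+" else "-"
          written <- if (strand == "+") site else .revcomp(site)
          row <- match(pid, promoters$promoter_id)
          substr(promoters$sequence[row], start + 1L, start + w) <- written
          truth[[length(truth) + 1L]] <- data.frame(
            promoter_id = pid, motif_id = motif$motif_id, start = start,
            strand = strand, width = w, stringsAsFactors = FALSE)
        }
      }
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(promoter_id = character(), motif_id = character(),
               start = integer(), strand = character(), width = integer(),
               stringsAsFactors = FALSE)
  pool$promoters <- promoters
  list(promoters = promoters, truth = truth)
}

#' Generate per-base conservation tracks
#'
#' Background bases draw from `Beta(a0, b0)`, bases under planted sites
#' from the elevated `Beta(a1, b1)`.
#'
#' @param promoters A `promoter_set`.
#' @param truth Truth table from [plant_sites()].
#' @param config A `sim_config`.
#' @param seed Seed.
#' @return A `conservation_set`.
#' @export
gen_conservation <- function(promoters, truth, config,
                             seed = config$seed + 3L) {
  a0 <- config$conservation_background[1]; b0 <- config$conservation_background[2]
  a1 <- config$conservation_planted[1]; b1 <- config$conservation_planted[2]
  with_seed(seed, {
    tracks <- lapply(seq_len(nrow(promoters)), function(i) {
      rbeta(nchar(promoters$sequence[i]), a0, b0)
    })
    names(tracks) <- promoters$promoter_id
    for (i in seq_len(nrow(truth))) {
      pid <- truth$promoter_id[i]
      span <- (truth$start[i] + 1L):(truth$start[i] + truth$width[i])
      tracks[[pid]][span] <- rbeta(length(span), a1, b1)
    }
    structure(tracks, class = "conservation_set")
  })
}

#' Generate a synthetic Ct matrix
#'
#' `Ct = reference_ct + base_dct + group_shift + donor_effect + noise`,
#' with a reference row (shift and baseline 0) included.  The first
#' `n_up_dc` panel miRNAs get the configured shift in every DC cell type,
#' the next `n_up_mono` in monocytes, and the last `n_undetected` carry a
#' baseline far above the detection cutoff.
#'
#' @param config A `sim_config`.
#' @param seed Seed.
#' @return List: `ct` (a `ct_matrix`), `truth` (data.frame mirna_id,
#'   class) giving the generating class of each panel miRNA.
#' @export
gen_ct_matrix <- function(config, seed = config$seed + 4L) {
  ctypes <- config$cell_types
  samples <- expand.grid(donor = sprintf("D%d", seq_len(config$n_donors)),
                         cell_type = ctypes, stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  n_m <- config$n_ct_mirnas
  ids <- sprintf("sim-miR-%03d", seq_len(n_m))
  cls <- rep("no_difference", n_m)
  if (config$n_up_dc > 0) cls[seq_len(config$n_up_dc)] <- "up_in_DC"
  if (config$n_up_mono > 0) {
    cls[config$n_up_dc + seq_len(config$n_up_mono)] <- "up_in_monocytes"
  }
  if (config$n_undetected > 0) {
    cls[n_m - config$n_undetected + seq_len(config$n_undetected)] <-
      "not_detected"
  }
  ref_ct <- 18
  with_seed(seed, {
    donor_eff <- setNames(rnorm(config$n_donors, 0, config$donor_sd),
                          sprintf("D%d", seq_len(config$n_donors)))
    vals <- matrix(NA_real_, n_m + 1L, n_s)
    rownames(vals) <- c("hsa-let-7a", ids)
    colnames(vals) <- paste(samples$cell_type, samples$donor, sep = ".")
    vals["hsa-let-7a", ] <- ref_ct + donor_eff[samples$donor]
    for (i in seq_len(n_m)) {
      base <- if (cls[i] == "not_detected") 20 else config$base_dct
      shift <- numeric(n_s)
      if (cls[i] == "up_in_DC") {
        shift[samples$cell_type != ctypes[1]] <- config$shift
      } else if (cls[i] == "up_in_monocytes") {
        shift[samples$cell_type == ctypes[1]] <- config$shift
      }
      vals[ids[i], ] <- ref_ct + base + shift + donor_eff[samples$donor] +
        rnorm(n_s, 0, config$residual_sd)
    }
    list(ct = ct_matrix(vals, samples$cell_type, samples$donor,
                        reference = "hsa-let-7a"),
         truth = data.frame(mirna_id = ids, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a TF presence table
#'
#' Each motif's cognate TF is called present with probability
#' `plogis(intercept + slope * k)` where k is the motif's true sharing
#' level (number of test promoters it was planted into; 0 for non-planted
#' motifs).
#'
#' @param motifs A `motif_library`.
#' @param truth Truth table from [plant_sites()].
#' @param config A `sim_config`.
#' @param seed Seed.
#' @return List: `presence` (a `presence_table`), `map` (motif_id -> tf).
#' @export
gen_presence_table <- function(motifs, truth, config,
                               seed = config$seed + 5L) {
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  tfs <- vapply(motifs, `[[`, character(1), "tf_name")
  k <- vapply(ids, function(m) {
    length(unique(truth$promoter_id[truth$motif_id == m]))
  }, integer(1))
  prob <- plogis(config$tf_logistic_intercept + config$tf_logistic_slope * k)
  with_seed(seed, {
    call <- ifelse(runif(length(ids)) < prob, "present", "absent")
    presence <- data.frame(tf = tfs, call = call, stringsAsFactors = FALSE)
    class(presence) <- c("presence_table", "data.frame")
    list(presence = presence,
         map = data.frame(motif_id = ids, tf = tfs, stringsAsFactors = FALSE))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator with seeds derived from the master seed and
#' optionally writes all inputs as the plain-text formats the readers
#' consume (FASTA, PFM, fixedStep wiggle, TSV).
#'
#' @param config A `sim_config`.
#' @param outdir Optional directory; when given, files
#'   promoters.fa, motifs.pfm, conservation.wig, ct.tsv, presence.tsv,
#'   motif2tf.tsv, locus.tsv, truth.tsv, test_ids.txt are written there.
#' @return List with all in-memory objects: promoters, locus, test_ids,
#'   motifs, truth, tracks, ct, ct_truth, presence, map, config.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  pool <- gen_promoter_pool(config)
  motifs <- gen_motif_library(config)
  planted <- plant_sites(pool, motifs, config)
  pool$promoters <- planted$promoters
  tracks <- gen_conservation(pool$promoters, planted$truth, config)
  ctm <- gen_ct_matrix(config)
  pres <- gen_presence_table(motifs, planted$truth, config)
  out <- list(promoters = pool$promoters, locus = pool$locus,
              test_ids = pool$test_ids, motifs = motifs,
              truth = planted$truth, tracks = tracks, ct = ctm$ct,
              ct_truth = ctm$truth, presence = pres$presence,
              map = pres$map, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_promoter_fasta(out$promoters, file.path(outdir, "promoters.fa"))
    write_motif_library(out$motifs, file.path(outdir, "motifs.pfm"))
    write_conservation_wig(out$tracks, file.path(outdir, "conservation.wig"))
    write_ct_table(out$ct, file.path(outdir, "ct.tsv"))
    write.table(out$presence, file.path(outdir, "presence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$map, file.path(outdir, "motif2tf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$locus, file.path(outdir, "locus.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(out$test_ids, file.path(outdir, "test_ids.txt"))
  }
  out
}
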