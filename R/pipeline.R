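#' Assemble a pipeline run configuration
#'
#' Paths to the six inputs plus every tunable threshold, with the
#' conventional defaults: instance score 6, over-representation p 0.05,
#' detection dCt 12, ANOVA FDR 0.05, post-hoc alpha 0.05, conservation
#' top-percentile 10, proximal window 500 bp, 1000 randomizations.
#'
#' @param promoters,motifs,conservation,ct,presence,motif_tf_map,locus,
#'   test_ids Input file paths (`test_ids`: one promoter id per line
#'   defining the test set; NULL derives it from the expression screen via
#'   the locus table).
#' @param outdir Output directory.
#' @param instance_threshold,p_cutoff,dct_cutoff,fdr_alpha,alpha,
#'   conservation_percentile,proximal_window,n_random,n_inner Thresholds.
#' @param motif_format Motif file dialect.
#' @param seed Master seed.
#' @return A `run_config` list (serializable with yaml/jsonlite).
#' @export
run_config <- function(promoters, motifs, conservation, ct, presence,
                       motif_tf_map, locus, test_ids = NULL,
                       outdir = "mirprom_out",
                       instance_threshold = 6, p_cutoff = 0.05,
                       dct_cutoff = 12, fdr_alpha = 0.05, alpha = 0.05,
                       conservation_percentile = 10, proximal_window = 500,
                       n_random = 1000, n_inner = 100,
                       motif_format = "jaspar_pfm", seed = 17) {
  stopifnot(instance_threshold >= 0, p_cutoff > 0, p_cutoff <= 1,
            fdr_alpha > 0, fdr_alpha <= 1, alpha > 0, alpha <= 1,
            conservation_percentile > 0, conservation_percentile <= 100,
            proximal_window >= 1, n_random >= 1, n_inner >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full promoter-regulatory pipeline
#'
#' Expression screen, motif scan, conservation analysis, shared-motif
#' enrichment (unfiltered and conserved variants) and TF-expression
#' integration, writing tabular outputs plus a JSON manifest with seeds
#' and input digests to `config$outdir`.  Any stage failure aborts with
#' the stage name and removes partial outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_all <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name) {
    path <- file.path(outdir, name)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  inputs <- stage("load_inputs", {
    list(promoters = read_promoter_fasta(config$promoters),
         motifs = read_motif_library(config$motifs, config$motif_format),
         ct = read_ct_table(config$ct),
         presence = read_presence_table(config$presence),
         map = read_motif_tf_map(config$motif_tf_map),
         locus = read_locus_table(config$locus))
  })
  tracks <- stage("load_conservation", {
    read_conservation_wig(config$conservation, inputs$promoters)
  })

  screen <- stage("expression_screen", {
    s <- screen_expression(inputs$ct, dct_cutoff = config$dct_cutoff,
                           fdr_alpha = config$fdr_alpha, alpha = config$alpha)
    write.table(s$table, emit("screen.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    s
  })

  test_ids <- stage("select_test_set", {
    if (!is.null(config$test_ids)) {
      readLines(config$test_ids)
    } else {
      up_dc <- screen$table$mirna_id[screen$table$class == "up_in_DC"]
      unique(inputs$locus$promoter_id[inputs$locus$mirna_id %in% up_dc])
    }
  })
  if (length(test_ids) == 0) {
    unlink(written)
    stop_fmt("pipeline stage 'select_test_set' failed: empty test set")
  }

  enr_un <- stage("enrichment_unfiltered", {
    e <- promoter_set_enrichment(
      test_ids, inputs$promoters, inputs$motifs,
      instance_threshold = config$instance_threshold,
      p_cutoff = config$p_cutoff, n_random = config$n_random,
      n_inner = config$n_inner, variant = "unfiltered",
      seed = config$seed)
    write_hits(e$hits, emit("hits.bed"))
    e
  })
  enr_cons <- stage("enrichment_conserved", {
    promoter_set_enrichment(
      test_ids, inputs$promoters, inputs$motifs,
      instance_threshold = config$instance_threshold,
      p_cutoff = config$p_cutoff, n_random = config$n_random,
      n_inner = config$n_inner, variant = "conserved", tracks = tracks,
      conservation_percentile = config$conservation_percentile,
      seed = config$seed + 1L)
  })
  stage("write_enrichment", {
    as_report <- function(e, seed) {
      list(T_observed = e$T_observed, T_random = e$T_random,
           # an undefined fold (all-zero null) is reported as the flag, not
           # a non-numeric JSON value
           fold = if (is.finite(e$fold)) e$fold else NULL,
           fold_undefined = e$fold_undefined,
           p_empirical = e$p_empirical, n_random = e$n_random, seed = seed,
           conservation_threshold = e$conservation_threshold,
           qualifying = e$qualifying, rule = e$rule)
    }
    jsonlite::write_json(list(
      unfiltered = as_report(enr_un, config$seed),
      conserved = as_report(enr_cons, config$seed + 1L)),
      emit("enrichment.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  overrep <- stage("overrep_table", {
    prof_un <- sharing_profile(enr_un$hits, test_ids, enr_un$qualifying)
    prof_cons <- sharing_profile(enr_cons$hits, test_ids, enr_cons$qualifying)
    tab <- data.frame(
      motif_id = vapply(inputs$motifs, `[[`, character(1), "motif_id"),
      tf_name = vapply(inputs$motifs, `[[`, character(1), "tf_name"),
      stringsAsFactors = FALSE, row.names = NULL)
    tab$n_promoters_unfiltered <-
      prof_un$n_promoters[match(tab$motif_id, prof_un$motif_id)]
    tab$n_promoters_conserved <-
      prof_cons$n_promoters[match(tab$motif_id, prof_cons$motif_id)]
    tab$common_to_all_unfiltered <-
      tab$motif_id %in% common_motifs(prof_un, length(test_ids))
    write.table(tab, emit("overrep.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(table = tab, profile_unfiltered = prof_un,
         profile_conserved = prof_cons)
  })

  cons_res <- stage("conservation_analysis", {
    hits <- add_conservation(enr_un$hits, tracks)
    write_hits(hits, emit("conserved.bed"))
    lens <- promoter_lengths(inputs$promoters)
    nul <- if (nrow(hits) > 0) {
      conservation_null_test(hits, tracks, seed = config$seed + 2L)
    } else list(fold = NA_real_, p = NA_real_)
    corr <- score_conservation_correlation(hits)
    clus <- proximal_cluster_test(hits, config$proximal_window, lens)
    write.table(data.frame(metric = c("random_block_fold", "wilcoxon_p",
                                      "score_conservation_r",
                                      "score_conservation_p",
                                      "proximal_fraction", "proximal_p"),
                           value = c(nul$fold, nul$p, corr$r, corr$p,
                                     clus$proximal_fraction, clus$p)),
                emit("conservation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    dist <- upstream_distribution(hits, promoter_length = lens)
    write.table(dist, emit("positional.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(null = nul, correlation = corr, cluster = clus, distribution = dist,
         hits = hits)
  })

  tfres <- stage("tf_expression", {
    prof <- overrep$profile_conserved
    ef <- expressed_fraction(prof, inputs$map, inputs$presence)
    curve <- sharing_expression_curve(prof, inputs$map, inputs$presence)
    write.table(cbind(curve$table,
                      expressed_fraction = rep(ef$fraction,
                                               nrow(curve$table)),
                      r = rep(curve$r, nrow(curve$table))),
                emit("tfexpr.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(expressed = ef, curve = curve)
  })

  stage("manifest", {
    input_paths <- c(config$promoters, config$motifs, config$conservation,
                     config$ct, config$presence, config$motif_tf_map,
                     config$locus)
    jsonlite::write_json(list(
      package_version = as.character(utils::packageVersion("mirprom")),
      seed = config$seed,
      thresholds = config[c("instance_threshold", "p_cutoff", "dct_cutoff",
                            "fdr_alpha", "alpha", "conservation_percentile",
                            "proximal_window", "n_random", "n_inner")],
      inputs = as.list(tools::md5sum(input_paths)),
      outputs = basename(written)),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(screen = screen, test_ids = test_ids,
                 enrichment_unfiltered = enr_un,
                 enrichment_conserved = enr_cons, overrep = overrep,
                 conservation = cons_res, tf_expression = tfres))
}
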