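#' Read a motif-to-TF mapping table
#'
#' TSV with columns `motif_id`, `tf` (one row per mapped gene symbol;
#' heterodimer motifs may map to several).
#'
#' @param path TSV file.
#' @return Data.frame with columns `motif_id`, `tf`.
#' @export
read_motif_tf_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif_id", "tf") %in% names(df))) {
    stop_fmt("motif-TF map %s needs columns 'motif_id' and 'tf'", path)
  }
  df[, c("motif_id", "tf")]
}

# is a motif "expressed"? any/all of its mapped TFs called present
.motif_expressed <- function(motif_ids, map, presence,
                             marginal_counts_as = "absent",
                             rule = "any") {
  call <- setNames(presence$call, presence$tf)
  if (marginal_counts_as == "present") {
    call[call == "marginal"] <- "present"
  } else {
    call[call == "marginal"] <- "absent"
  }
  vapply(motif_ids, function(m) {
    tfs <- map$tf[map$motif_id == m]
    if (length(tfs) == 0) return(NA)  # unmapped
    pres <- call[tfs] == "present"
    pres[is.na(pres)] <- FALSE
    if (rule == "any") any(pres) else all(pres)
  }, logical(1))
}

#' Fraction of qualifying motifs whose cognate TF is expressed
#'
#' For each motif in the sharing profile, looks up its mapped TF gene
#' symbols in the presence table; a motif counts as expressed when any
#' mapped TF is called present (`rule = "all"` requires all of them).
#' Unmapped motifs are excluded from the denominator and reported.
#'
#' @param profile A `sharing_profile` restricted to qualifying motifs.
#' @param map Motif-to-TF mapping ([read_motif_tf_map()] format).
#' @param presence A `presence_table`.
#' @param marginal_counts_as Treat marginal calls as `"absent"` (default)
#'   or `"present"`.
#' @param rule `"any"` or `"all"` mapped TFs present.
#' @return List: fraction, n_expressed, n_mapped, unmapped (motif ids),
#'   defined (FALSE on an empty profile).
#' @export
expressed_fraction <- function(profile, map, presence,
                               marginal_counts_as = c("absent", "present"),
                               rule = c("any", "all")) {
  marginal_counts_as <- match.arg(marginal_counts_as)
  rule <- match.arg(rule)
  if (nrow(profile) == 0) {
    return(list(fraction = NA_real_, n_expressed = 0L, n_mapped = 0L,
                unmapped = character(), defined = FALSE))
  }
  expr <- .motif_expressed(profile$motif_id, map, presence,
                           marginal_counts_as, rule)
  unmapped <- profile$motif_id[is.na(expr)]
  expr <- expr[!is.na(expr)]
  if (length(expr) == 0) {
    return(list(fraction = NA_real_, n_expressed = 0L, n_mapped = 0L,
                unmapped = unmapped, defined = FALSE))
  }
  list(fraction = mean(expr), n_expressed = sum(expr),
       n_mapped = length(expr), unmapped = unmapped, defined = TRUE)
}

#' Sharing-versus-expression curve
#'
#' Bins qualifying motifs by the number of promoters sharing them
#' (exactly-k by default, cumulative at-least-k optionally) and counts how
#' many motifs in each bin have an expressed cognate TF, then correlates
#' the expressed count with k (Pearson, two-sided).
#'
#' @inheritParams expressed_fraction
#' @param cumulative Use at-least-k binning instead of exactly-k.
#' @return List: `table` (k, n_motifs, n_expressed), r, p, defined.
#' @export
sharing_expression_curve <- function(profile, map, presence,
                                     marginal_counts_as = c("absent", "present"),
                                     rule = c("any", "all"),
                                     cumulative = FALSE) {
  marginal_counts_as <- match.arg(marginal_counts_as)
  rule <- match.arg(rule)
  expr <- .motif_expressed(profile$motif_id, map, presence,
                           marginal_counts_as, rule)
  keep <- !is.na(expr)
  prof <- profile[keep, , drop = FALSE]
  expr <- expr[keep]
  kmax <- if (nrow(prof)) max(prof$n_promoters) else 0L
  ks <- seq_len(max(kmax, 0L))
  tab <- data.frame(k = ks)
  if (cumulative) {
    tab$n_motifs <- vapply(ks, function(k) sum(prof$n_promoters >= k),
                           integer(1))
    tab$n_expressed <- vapply(ks, function(k) sum(expr[prof$n_promoters >= k]),
                              integer(1))
  } else {
    tab$n_motifs <- vapply(ks, function(k) sum(prof$n_promoters == k),
                           integer(1))
    tab$n_expressed <- vapply(ks, function(k) sum(expr[prof$n_promoters == k]),
                              integer(1))
  }
  use <- tab[tab$n_motifs > 0, , drop = FALSE]
  if (nrow(use) < 3 || stats::sd(use$n_expressed) == 0) {
    return(list(table = tab, r = NA_real_, p = NA_real_, defined = FALSE))
  }
  ctest <- cor.test(use$k, use$n_expressed, method = "pearson")
  list(table = tab, r = unname(ctest$estimate), p = ctest$p.value,
       defined = TRUE)
}
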