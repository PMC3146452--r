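#' Delta-Ct normalization
#'
#' `dCt[m, s] = Ct[m, s] - Ct[reference, s]`.  Lower dCt means higher
#' expression.  The reference miRNA's own dCt is 0 in every sample.
#'
#' @param ct A `ct_matrix`.
#' @return Numeric matrix of dCt values with the same dimnames, carrying
#'   the `samples` annotation as an attribute.
#' @export
delta_ct <- function(ct) {
  ref <- ct$values[ct$reference, ]
  if (anyNA(ref)) {
    stop_fmt("missing reference Ct (%s) in sample(s): %s", ct$reference,
             paste(colnames(ct$values)[is.na(ref)], collapse = ", "))
  }
  dct <- sweep(ct$values, 2, ref, "-")
  attr(dct, "samples") <- ct$samples
  attr(dct, "reference") <- ct$reference
  dct
}

#' Detection filter on dCt values
#'
#' A miRNA is called detected when its per-miRNA summary dCt is at or
#' below `cutoff` (boundary inclusive).  The summary is the median across
#' samples by default; `rule = "any"` instead requires a single sample at
#' or below the cutoff.
#'
#' @param dct dCt matrix from [delta_ct()].
#' @param cutoff Detection cutoff in cycles (default 12).
#' @param rule `"median"` or `"any"`.
#' @return Named logical vector, one entry per miRNA.
#' @export
detection_filter <- function(dct, cutoff = 12, rule = c("median", "any")) {
  rule <- match.arg(rule)
  summ <- apply(dct, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(Inf)
    if (rule == "median") median(x) else min(x)
  })
  summ <= cutoff
}

# one-way ANOVA with explicit handling of the degenerate variance cases:
# returns c(F, p); NA when untestable
.anova_one <- function(y, g) {
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(factor(g[ok]))
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) return(c(NA_real_, NA_real_))
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(tab * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  tol <- 1e-12 * max(1, sum((y - grand)^2))
  if (ssb <= tol && ssw <= tol) return(c(0, 1))       # all values identical
  if (ssw <= tol) return(c(Inf, 0))                   # perfect separation
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  c(unname(ft$statistic), unname(ft$p.value))
}

#' Gene-by-gene one-way ANOVA screen
#'
#' Tests every miRNA for a cell-type effect on dCt with a classical
#' one-factor ANOVA, then applies Benjamini-Hochberg FDR adjustment across
#' miRNAs.  Groups with fewer than 2 non-missing values make a miRNA
#' untestable (flagged, never silently dropped).  Degenerate conventions:
#' all values identical gives F = 0, p = 1; zero within-group variance
#' with distinct group means gives F = Inf, p = 0.
#'
#' @param dct dCt matrix from [delta_ct()] (or any matrix with a `samples`
#'   attribute / explicit `cell_type`).
#' @param cell_type Optional explicit group labels (one per column).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param mirnas Optional subset of row names to test.
#' @return Data.frame: mirna_id, F, p, fdr_p, testable, significant
#'   (`fdr_p < fdr_alpha`).
#' @export
anova_screen <- function(dct, cell_type = NULL, fdr_alpha = 0.05,
                         mirnas = NULL) {
  if (is.null(cell_type)) cell_type <- attr(dct, "samples")$cell_type
  if (is.null(cell_type)) stop_fmt("cell_type labels are required")
  if (length(cell_type) != ncol(dct)) {
    stop_fmt("one cell_type label per sample column is required")
  }
  rows <- mirnas %||% rownames(dct)
  res <- t(vapply(rows, function(m) .anova_one(dct[m, ], cell_type),
                  numeric(2)))
  out <- data.frame(mirna_id = rows, F = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  out$testable <- !is.na(out$p)
  out$fdr_p <- NA_real_
  out$fdr_p[out$testable] <- p.adjust(out$p[out$testable], method = "BH")
  out$significant <- !is.na(out$fdr_p) & out$fdr_p < fdr_alpha
  rownames(out) <- NULL
  out
}

# Tukey HSD for one miRNA, with the same degenerate conventions as the
# ANOVA; returns data.frame(pair, diff, p)
.tukey_one <- function(y, g, rank_transform = FALSE) {
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(factor(g[ok]))
  if (rank_transform) y <- rank(y)
  means <- tapply(y, g, mean)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  ssw <- sum((y - means[g])^2)
  tol <- 1e-12 * max(1, sum((y - mean(y))^2))
  if (ssw <= tol) {
    dif <- means[pairs[2, ]] - means[pairs[1, ]]
    p <- ifelse(abs(dif) <= sqrt(tol), 1, 0)
    return(data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                      diff = unname(dif), p = p, stringsAsFactors = FALSE))
  }
  fit <- aov(y ~ g)
  tk <- TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], p = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tukey post-hoc pairwise comparisons
#'
#' Run on the ANOVA-significant miRNAs only.  For every cell-type pair the
#' Tukey HSD adjusted p-value is reported along with the direction on the
#' dCt scale; because lower dCt means higher expression, the "up" member
#' of a significant pair is the one with the lower mean dCt.
#'
#' @param dct dCt matrix.
#' @param mirnas miRNAs to test (normally the ANOVA-significant set).
#' @param cell_type Optional explicit group labels.
#' @param alpha Pairwise significance level (default 0.05).
#' @param rank_transform Rank-transform dCt within each miRNA before the
#'   comparison (a robust variant; off by default).
#' @return Data.frame: mirna_id, group_a, group_b, diff (mean dCt of a
#'   minus b), p, significant, up (the higher-expressed group among
#'   significant pairs, NA otherwise).
#' @export
posthoc_pairs <- function(dct, mirnas, cell_type = NULL, alpha = 0.05,
                          rank_transform = FALSE) {
  if (is.null(cell_type)) cell_type <- attr(dct, "samples")$cell_type
  out <- lapply(mirnas, function(m) {
    tk <- .tukey_one(dct[m, ], cell_type, rank_transform)
    ab <- do.call(rbind, strsplit(tk$pair, "-", fixed = TRUE))
    data.frame(mirna_id = m, group_a = ab[, 1], group_b = ab[, 2],
               diff = tk$diff, p = tk$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(mirna_id = character(), group_a = character(),
                      group_b = character(), diff = numeric(), p = numeric(),
                      significant = logical(), up = character(),
                      stringsAsFactors = FALSE))
  }
  res$significant <- res$p < alpha
  res$up <- ifelse(res$significant,
                   ifelse(res$diff < 0, res$group_a, res$group_b),
                   NA_character_)
  rownames(res) <- NULL
  res
}

#' Classify screened miRNAs into expression classes
#'
#' Partition rule over the two-stage screen (ANOVA over all cell types,
#' then a second ANOVA restricted to the DC subsets):
#' `up_in_monocytes` when every monocyte-vs-DC pair is significant with
#' monocytes higher expressed; `up_in_DC` when every such pair is
#' significant with the DC subset higher; `up_in_DC_subset` when only the
#' DC-restricted ANOVA is significant; `no_difference` otherwise;
#' `not_detected` for miRNAs failing the detection filter (no test
#' statistics populated).
#'
#' @param detected Named logical vector from [detection_filter()].
#' @param screen_all ANOVA results over all cell types ([anova_screen()]).
#' @param posthoc Post-hoc pairs for the significant miRNAs.
#' @param screen_dc ANOVA results restricted to DC subsets.
#' @param monocyte_label Cell-type label identifying monocytes.
#' @return Named character vector of classes, one per miRNA in
#'   `names(detected)`.
#' @export
classify_mirnas <- function(detected, screen_all, posthoc, screen_dc,
                            monocyte_label = "monocyte") {
  cls <- setNames(rep("no_difference", length(detected)), names(detected))
  cls[!detected] <- "not_detected"
  sig_all <- screen_all$mirna_id[screen_all$significant]
  sig_dc <- screen_dc$mirna_id[screen_dc$significant]
  for (m in intersect(sig_all, names(detected)[detected])) {
    ph <- posthoc[posthoc$mirna_id == m &
                    (posthoc$group_a == monocyte_label |
                       posthoc$group_b == monocyte_label), , drop = FALSE]
    if (nrow(ph) > 0 && all(ph$significant)) {
      if (all(ph$up == monocyte_label)) {
        cls[m] <- "up_in_monocytes"
        next
      }
      if (all(ph$up != monocyte_label)) {
        cls[m] <- "up_in_DC"
        next
      }
    }
    if (m %in% sig_dc) cls[m] <- "up_in_DC_subset"
  }
  for (m in intersect(setdiff(sig_dc, sig_all), names(detected)[detected])) {
    cls[m] <- "up_in_DC_subset"
  }
  cls
}

#' Run the full expression screen
#'
#' Delta-Ct normalization, detection filtering, the two-stage ANOVA
#' (all cell types, then DC subsets only), Tukey post-hoc comparison and
#' classification, in one call.
#'
#' @param ct A `ct_matrix`.
#' @param dct_cutoff Detection cutoff (default 12).
#' @param fdr_alpha ANOVA FDR level (default 0.05).
#' @param alpha Post-hoc pairwise level (default 0.05).
#' @param monocyte_label Cell-type label identifying monocytes; all other
#'   cell types are treated as DC subsets.
#' @return A `screen_result` list: `table` (per-miRNA data.frame with
#'   detected, p/fdr_p for both ANOVA passes, class), `posthoc`, `dct`.
#' @export
screen_expression <- function(ct, dct_cutoff = 12, fdr_alpha = 0.05,
                              alpha = 0.05, monocyte_label = "monocyte") {
  dct <- delta_ct(ct)
  dct <- dct[setdiff(rownames(dct), ct$reference), , drop = FALSE]
  attr(dct, "samples") <- ct$samples
  detected <- detection_filter(dct, dct_cutoff)
  dct_det <- dct[names(detected)[detected], , drop = FALSE]
  attr(dct_det, "samples") <- ct$samples
  screen_all <- anova_screen(dct_det, fdr_alpha = fdr_alpha)
  dc_cols <- ct$samples$cell_type != monocyte_label
  dct_dc <- dct_det[, dc_cols, drop = FALSE]
  screen_dc <- anova_screen(dct_dc, cell_type = ct$samples$cell_type[dc_cols],
                            fdr_alpha = fdr_alpha)
  ph <- posthoc_pairs(dct_det, screen_all$mirna_id[screen_all$significant],
                      alpha = alpha)
  cls <- classify_mirnas(detected, screen_all, ph, screen_dc,
                         monocyte_label)
  tab <- data.frame(mirna_id = names(detected), detected = detected,
                    stringsAsFactors = FALSE, row.names = NULL)
  idx_all <- match(tab$mirna_id, screen_all$mirna_id)
  idx_dc <- match(tab$mirna_id, screen_dc$mirna_id)
  tab$p_all <- screen_all$p[idx_all]
  tab$fdr_p_all <- screen_all$fdr_p[idx_all]
  tab$p_dc <- screen_dc$p[idx_dc]
  tab$fdr_p_dc <- screen_dc$fdr_p[idx_dc]
  tab$class <- cls[tab$mirna_id]
  structure(list(table = tab, posthoc = ph, dct = dct,
                 screen_all = screen_all, screen_dc = screen_dc),
            class = "screen_result")
}
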