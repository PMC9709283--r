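#' Paired log2 fold change
#'
#' `log2(mean(b) / mean(a))` over paired subjects, after replacing zeros by
#' an imputed floor (half the smallest positive value across both groups, or
#' a unit offset). Returns `NA` with a flag when either group is entirely
#' zero.
#'
#' @param a,b paired per-subject intensity vectors (group a = reference).
#' @param zero_impute `"halfmin"` or `"unit"`.
#' @return log2 fold change (b vs a); `NA_real_` if a group is all zero.
#' @export
paired_log2fc <- function(a, b, zero_impute = c("halfmin", "unit")) {
  zero_impute <- match.arg(zero_impute)
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (all(a == 0) || all(b == 0)) return(NA_real_)
  pos <- c(a, b)[c(a, b) > 0]
  floor_val <- if (zero_impute == "halfmin") min(pos) / 2 else 1
  a[a == 0] <- floor_val
  b[b == 0] <- floor_val
  log2(mean(b) / mean(a))
}

#' Choose the paired test from a Shapiro-Wilk normality gate
#'
#' Shapiro-Wilk is run on the paired differences; if its p-value is at least
#' `normality_alpha` the differences are treated as normal and the paired
#' t-test is used, otherwise the Wilcoxon signed-rank test. Constant
#' differences are a degenerate case routed to Wilcoxon.
#'
#' @param differences vector of paired differences (b - a), length >= 3.
#' @param normality_alpha level of the normality gate.
#' @return `"paired_t"` or `"wilcoxon"`, with attribute `degenerate` set to
#'   `TRUE` when the differences are constant.
#' @export
choose_test <- function(differences, normality_alpha = 0.05) {
  stopifnot(length(differences) >= 3)
  if (stats::sd(differences) == 0)
    return(structure("wilcoxon", degenerate = TRUE))
  p <- stats::shapiro.test(differences)$p.value
  structure(if (p >= normality_alpha) "paired_t" else "wilcoxon", shapiro_p = p)
}

#' Two-sided paired test p-value
#'
#' Paired Student's t-test or Wilcoxon signed-rank test on the differences.
#' Degenerate cases follow fixed conventions: all-zero differences give
#' p = 1; a constant non-zero difference (zero-variance t) gives p = 0 with
#' a degeneracy flag. The Wilcoxon test is exact for n <= 25 without
#' ties/zeros, otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b paired intensity vectors.
#' @param test `"paired_t"` or `"wilcoxon"`.
#' @return p-value in `[0, 1]` (attribute `degenerate` on the edge cases).
#' @export
paired_test <- function(a, b, test = c("paired_t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  if (all(d == 0)) return(structure(1, degenerate = TRUE))
  if (test == "paired_t") {
    if (stats::sd(d) == 0) return(structure(0, degenerate = TRUE))
    return(stats::t.test(b, a, paired = TRUE)$p.value)
  }
  exact <- length(d) <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
  suppressWarnings(
    stats::wilcox.test(b, a, paired = TRUE, exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone), delegated to
#' [stats::p.adjust()].
#'
#' @param p_values vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  stats::p.adjust(p_values, method = "BH")
}

#' Paired volcano analysis
#'
#' For every feature of a paired comparison: paired log2 fold change,
#' Shapiro-Wilk-guided choice between paired t and Wilcoxon, two-sided
#' p-value, Benjamini-Hochberg adjustment across features, and the joint
#' selection flag `|log2FC| > abs_log2fc_min` (strict) with (adjusted)
#' p `< alpha` (strict). Features with an all-zero group are excluded from
#' testing and never selected.
#'
#' @param paired a `paired_data` object from [subset_comparison()].
#' @param config a [pipeline_config()].
#' @return data.frame of class `volcano_result`: feature_id, mz, rt, log2fc,
#'   fc, test_used, shapiro_p, p_raw, p_adj, excluded, selected.
#' @export
volcano <- function(paired, config = pipeline_config()) {
  stopifnot(inherits(paired, "paired_data"))
  nf <- nrow(paired$a)
  res <- data.frame(feature_id = paired$features$feature_id,
                    mz = paired$features$mz, rt = paired$features$rt,
                    log2fc = NA_real_, fc = NA_real_,
                    test_used = NA_character_, shapiro_p = NA_real_,
                    p_raw = NA_real_, p_adj = NA_real_,
                    excluded = FALSE, selected = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nf)) {
    a <- paired$a[i, ]; b <- paired$b[i, ]
    lfc <- paired_log2fc(a, b, config$zero_impute)
    if (is.na(lfc)) { res$excluded[i] <- TRUE; next }
    res$log2fc[i] <- lfc
    res$fc[i] <- 2^lfc
    tst <- choose_test(b - a, config$shapiro_alpha)
    res$test_used[i] <- as.character(tst)
    res$shapiro_p[i] <- attr(tst, "shapiro_p") %||% NA_real_
    res$p_raw[i] <- as.numeric(paired_test(a, b, as.character(tst)))
  }
  res$p_adj <- bh_adjust(res$p_raw)
  p_crit <- if (config$use_adjusted_p) res$p_adj else res$p_raw
  res$selected <- !res$excluded & !is.na(res$log2fc) & !is.na(p_crit) &
    abs(res$log2fc) > config$abs_log2fc_min & p_crit < config$alpha
  class(res) <- c("volcano_result", "data.frame")
  res
}

#' Volcano-selected feature ids
#'
#' Applies the strict joint thresholds to a volcano result and returns the
#' selected feature ids in deterministic order: decreasing |log2FC|, ties
#' broken by feature_id.
#'
#' @param results a `volcano_result` data.frame.
#' @param abs_log2fc_min,alpha strict thresholds; defaults are the published
#'   values (|log2FC| > 1, adjusted p < 0.05).
#' @param use_adjusted_p compare `alpha` to adjusted (default) or raw p.
#' @return character vector of feature ids.
#' @export
volcano_select <- function(results, abs_log2fc_min = 1, alpha = 0.05,
                           use_adjusted_p = TRUE) {
  p_crit <- if (use_adjusted_p) results$p_adj else results$p_raw
  sel <- !results$excluded & !is.na(results$log2fc) & !is.na(p_crit) &
    abs(results$log2fc) > abs_log2fc_min & p_crit < alpha
  ids <- results$feature_id[sel]
  ord <- order(-abs(results$log2fc[sel]), ids)
  ids[ord]
}
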