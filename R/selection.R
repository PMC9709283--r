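#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` over the predictive
#' plus orthogonal components, with per-component normalized weights and
#' `SSY_a` the y-variance explained by component a. Because every weight
#' vector has unit norm, `sum_j VIP_j^2 = p` (the feature count) whatever
#' the SSY distribution. The total-VIP convention (orthogonal components
#' included) is the default; `predictive_only = TRUE` restricts to the
#' predictive component (the identity still holds).
#'
#' @param model a fitted [fit_oplsda()] model.
#' @param predictive_only use only the predictive component.
#' @return named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model, predictive_only = FALSE) {
  stopifnot(inherits(model, "oplsda"))
  W <- cbind(model$w, if (!predictive_only && model$n_ortho > 0) model$W_o)
  ssy <- model$ssy[seq_len(ncol(W))]
  if (sum(ssy) <= 0 || !is.finite(sum(ssy)))
    stop("degenerate model: no explained y-variance, VIP undefined")
  p_feat <- nrow(W)
  w2 <- sweep(W^2, 2, colSums(W^2), "/")   # guard rounding of unit norms
  stats::setNames(sqrt(p_feat * drop(w2 %*% ssy) / sum(ssy)), model$features)
}

#' Jack-knife confidence intervals for VIP scores
#'
#' Martens' jack-knife over the cross-validation sub-models:
#' `SE_j^2 = ((G - 1)/G) * sum_g (VIP_jg - VIP_j)^2` around the full-model
#' VIP, with a `t_{1 - alpha/2, G-1}` interval. Features absent from a
#' sub-model (zero training variance) contribute VIP 0 for that fold; a
#' sub-model whose VIP computation fails is excluded with a warning and G
#' reduced.
#'
#' @param cv a `cv_q2` object from [cross_validated_q2()] (its sub-models
#'   are reused).
#' @param full_vip named full-model VIP vector from [vip_scores()].
#' @param confidence interval coverage (default 0.95).
#' @param predictive_only passed to [vip_scores()] for the sub-models.
#' @return data.frame: feature_id, vip, ci_low, ci_high.
#' @export
jackknife_ci <- function(cv, full_vip, confidence = 0.95,
                         predictive_only = FALSE) {
  stopifnot(inherits(cv, "cv_q2"), length(cv$submodels) >= 3)
  features <- names(full_vip)
  rows <- lapply(cv$submodels, function(s) {
    v <- tryCatch(vip_scores(s$model, predictive_only), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    out <- stats::setNames(numeric(length(features)), features)
    out[intersect(names(v), features)] <- v[intersect(names(v), features)]
    out
  })
  failed <- vapply(rows, is.null, logical(1))
  if (any(failed))
    warning(sprintf("%d sub-model(s) excluded from the jack-knife", sum(failed)))
  V <- do.call(rbind, rows[!failed])
  G <- nrow(V)
  if (G < 3) stop("fewer than 3 usable sub-models for the jack-knife")
  se <- sqrt(((G - 1) / G) * colSums(sweep(V, 2, full_vip)^2))
  tcrit <- stats::qt(1 - (1 - confidence) / 2, df = G - 1)
  data.frame(feature_id = features, vip = unname(full_vip),
             ci_low = unname(full_vip - tcrit * se),
             ci_high = unname(full_vip + tcrit * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Discriminant-variable selection cascade
#'
#' Ranks all modeled features by VIP (descending, ties broken by
#' feature_id), takes the first `top_n`, and within those keeps the
#' features with `VIP > vip_min`, a jack-knife confidence interval that
#' does not include zero (strictly positive lower bound or strictly
#' negative upper bound; a zero-width interval at 0 includes zero), and a
#' two-sided fold change `max(FC, 1/FC) > fc_min`. Because the top-`top_n`
#' cut precedes the filters, at most `top_n` variables can ever be
#' selected.
#'
#' @param vip_table data.frame with columns feature_id, vip, ci_low,
#'   ci_high, fc (raw-scale b-vs-a fold change).
#' @param top_n,vip_min,fc_min cascade thresholds (defaults 30, 1, 1.2).
#' @return data.frame of selected variables with their `rank` (VIP rank
#'   among all modeled features), ordered by rank.
#' @export
select_discriminant <- function(vip_table, top_n = 30, vip_min = 1,
                                fc_min = 1.2) {
  need <- c("feature_id", "vip", "ci_low", "ci_high", "fc")
  stopifnot(all(need %in% names(vip_table)))
  ord <- order(-vip_table$vip, vip_table$feature_id)
  ranked <- vip_table[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  top <- ranked[seq_len(min(top_n, nrow(ranked))), , drop = FALSE]
  two_sided_fc <- pmax(top$fc, 1 / top$fc)
  keep <- top$vip > vip_min &
    (top$ci_low > 0 | top$ci_high < 0) &
    !is.na(two_sided_fc) & two_sided_fc > fc_min
  out <- top[keep, , drop = FALSE]
  out$two_sided_fc <- two_sided_fc[keep]
  rownames(out) <- NULL
  out
}

#' Manual peak-verification checklist
#'
#' Selected features are meant to be verified by eye against extracted ion
#' chromatograms of QC injections (peak shape, retention time); this writes
#' the review material: one row per selected feature with its m/z, RT and
#' QC-pool intensities in injection order. A report artifact, not an
#' automated classifier.
#'
#' @param selected data.frame with feature_id (e.g., from
#'   [select_discriminant()]).
#' @param table the `feature_table` holding the QC intensities.
#' @param path optional TSV output path.
#' @return data.frame checklist (invisibly written to `path` if given):
#'   rank, feature_id, mz, rt, n_qc, qc_intensities (semicolon-joined, in
#'   injection order).
#' @export
verify_peak <- function(selected, table, path = NULL) {
  validate_feature_table(table)
  qc <- which(table$injections$sample_type == "qc")
  qc <- qc[order(table$injections$injection_order[qc])]
  idx <- match(selected$feature_id, table$features$feature_id)
  if (anyNA(idx))
    stop("selected feature(s) absent from table: ",
         paste(selected$feature_id[is.na(idx)], collapse = ", "))
  checklist <- data.frame(
    rank = if (!is.null(selected$rank)) selected$rank else seq_along(idx),
    feature_id = selected$feature_id,
    mz = table$features$mz[idx], rt = table$features$rt[idx],
    n_qc = rep(length(qc), length(idx)),
    qc_intensities = vapply(idx, function(i)
      paste(signif(table$intensities[i, qc], 6), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path))
    utils::write.table(checklist, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  checklist
}
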