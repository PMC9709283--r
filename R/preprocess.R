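#' Coefficient of variation, in percent
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation. Undefined (returned as `NA`) when the mean is not positive.
#'
#' @param values numeric vector, length >= 2.
#' @return percentage, or `NA_real_` when the mean is <= 0.
#' @export
cv_percent <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Median fold-change normalization
#'
#' Removes per-injection dilution differences: the reference profile is the
#' feature-wise median over all study injections; each non-blank injection
#' is divided by the median, over features positive in both the injection
#' and the reference, of intensity/reference. Blank injections pass through
#' unscaled (they carry no sample material).
#'
#' @param table a `feature_table`.
#' @return normalized `feature_table` with per-injection factors recorded in
#'   the `medfc_factors` attribute and in the provenance log.
#' @export
medfc_normalize <- function(table) {
  validate_feature_table(table)
  if (nrow(table$injections) < 2) stop("need at least 2 injections")
  study <- table$injections$sample_type == "study"
  if (!any(study)) stop("no study injections to build the reference profile")
  ref <- apply(table$intensities[, study, drop = FALSE], 1, stats::median)
  factors <- rep(1, ncol(table$intensities))
  names(factors) <- table$injections$injection_id
  for (j in seq_len(ncol(table$intensities))) {
    if (table$injections$sample_type[j] == "blank") next
    v <- table$intensities[, j]
    shared <- ref > 0 & v > 0
    if (!any(shared))
      stop("injection '", table$injections$injection_id[j],
           "' shares no positive features with the reference profile")
    factors[j] <- stats::median(v[shared] / ref[shared])
    table$intensities[, j] <- v / factors[j]
  }
  attr(table, "medfc_factors") <- factors
  log_stage(table, sprintf("medFC normalization: factors in [%.3g, %.3g]",
                           min(factors), max(factors)))
}

#' QC-anchored LOESS drift correction
#'
#' Per feature, fits a local-linear LOESS curve of QC-pool intensity against
#' injection order, interpolates the fitted curve linearly between QC orders
#' (clamped outside their range), and rescales every injection by
#' `median(QC intensity) / fitted(order)`. Features whose QC intensities are
#' all zero pass through unchanged and are logged.
#'
#' @param table a `feature_table` with at least 4 QC injections.
#' @param span LOESS span (fraction of QC points in each local fit).
#' @return corrected `feature_table`.
#' @export
loess_qc_correct <- function(table, span = 0.75) {
  validate_feature_table(table)
  qc <- table$injections$sample_type == "qc"
  if (sum(qc) < 4)
    stop("need >= 4 QC injections for LOESS drift correction; ",
         "with fewer, skip this stage explicitly")
  qc_order <- table$injections$injection_order[qc]
  all_order <- table$injections$injection_order
  skipped <- character(0)
  for (i in seq_len(nrow(table$intensities))) {
    v <- table$intensities[i, qc]
    if (all(v == 0)) {
      skipped <- c(skipped, table$features$feature_id[i])
      next
    }
    fit <- suppressWarnings(
      stats::loess(v ~ qc_order, span = span, degree = 1,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")))
    fitted_qc <- stats::fitted(fit)
    curve <- stats::approx(qc_order, fitted_qc, xout = all_order, rule = 2)$y
    ref <- stats::median(v)
    # a drift curve crossing zero would flip signs; clamp to a small
    # positive floor instead (logged implicitly through provenance counts)
    curve <- pmax(curve, 1e-6 * ref)
    table$intensities[i, ] <- table$intensities[i, ] * ref / curve
  }
  msg <- sprintf("LOESS QC drift correction (span %.2f, %d QCs)", span, sum(qc))
  if (length(skipped))
    msg <- paste0(msg, sprintf("; %d feature(s) with all-zero QC passed through",
                               length(skipped)))
  out <- log_stage(table, msg)
  attr(out, "loess_skipped") <- skipped
  out
}

#' Quality-assurance filter
#'
#' Retains a feature iff its QC coefficient of variation is strictly below
#' `cv_max_pct` and its percentage of zero intensities among study
#' injections does not exceed `zero_max_pct`. A feature whose QC CV is
#' undefined (QC mean zero) fails the CV criterion. The report lists every
#' feature with its statistics and removal reason.
#'
#' @param table a `feature_table` containing QC injections.
#' @param cv_max_pct CV threshold (%), exclusive.
#' @param zero_max_pct zero-percentage threshold (%), inclusive.
#' @return list with `table` (filtered `feature_table`) and `report`
#'   (data.frame: feature_id, qc_cv_pct, zero_pct, retained, reason).
#' @export
qa_filter <- function(table, cv_max_pct = 30, zero_max_pct = 60) {
  validate_feature_table(table)
  qc <- table$injections$sample_type == "qc"
  study <- table$injections$sample_type == "study"
  if (sum(qc) < 2) stop("need >= 2 QC injections to compute QC CV")
  if (!any(study)) stop("no study injections")
  qc_cv <- apply(table$intensities[, qc, drop = FALSE], 1, cv_percent)
  zero_pct <- 100 * rowMeans(table$intensities[, study, drop = FALSE] == 0)
  cv_ok <- !is.na(qc_cv) & qc_cv < cv_max_pct
  zero_ok <- zero_pct <= zero_max_pct
  retained <- cv_ok & zero_ok
  reason <- ifelse(retained, "pass", ifelse(!cv_ok, "cv_fail", "zero_fail"))
  report <- data.frame(feature_id = table$features$feature_id,
                       qc_cv_pct = qc_cv, zero_pct = zero_pct,
                       retained = retained, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  out <- table
  out$features <- table$features[retained, , drop = FALSE]
  out$intensities <- table$intensities[retained, , drop = FALSE]
  out <- log_stage(out, sprintf(
    "QA filter (CV < %g%%, zeros <= %g%%): %d of %d features retained (%d cv_fail, %d zero_fail)",
    cv_max_pct, zero_max_pct, sum(retained), length(retained),
    sum(reason == "cv_fail"), sum(reason == "zero_fail")))
  list(table = out, report = report)
}
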