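#' Run the full differential-analysis pipeline for one comparison
#'
#' Stage order: medFC normalization, QC-LOESS drift correction, QA
#' filtering, paired volcano pre-selection, then PCA and OPLS-DA with the
#' full validation battery (cross-validated Q2, CV-ANOVA, permutation test)
#' fitted on the volcano-selected features only, the
#' VIP / jack-knife / fold-change selection cascade, and annotation of the
#' selected variables against a compound library. With fewer than 2
#' volcano-selected features the multivariate stage is skipped with an
#' explicit status and any selected feature is still annotated.
#'
#' Every stage appends its input/output counts to the audit log; the result
#' is deterministic given the inputs and `config$seed`.
#'
#' @param table a `feature_table` (raw intensities).
#' @param spec a [comparison_spec()] (or the name of a
#'   [comparison_presets()] entry).
#' @param config a [pipeline_config()].
#' @param library optional compound library data.frame for annotation.
#' @param skip_loess skip the drift-correction stage explicitly (e.g., too
#'   few QCs).
#' @return list of class `metabopair_result`: normalized table, QA report,
#'   volcano table, PCA / OPLS-DA models, validation report, VIP table,
#'   selected variables, annotations, audit log and status.
#' @export
run_pipeline <- function(table, spec, config = pipeline_config(),
                         library = NULL, skip_loess = FALSE) {
  if (is.character(spec)) {
    presets <- comparison_presets()
    if (!spec %in% names(presets))
      stop("unknown comparison preset: ", spec)
    spec <- presets[[spec]]
  }
  audit <- list()
  note <- function(stage, ...) {
    audit[[length(audit) + 1]] <<- list(stage = stage, message = sprintf(...))
  }
  validate_feature_table(table)
  note("input", "%d features, %d injections", nrow(table$features),
       nrow(table$injections))

  table <- medfc_normalize(table)
  note("medfc", "per-injection factors in [%.3g, %.3g]",
       min(attr(table, "medfc_factors")), max(attr(table, "medfc_factors")))
  n_qc <- sum(table$injections$sample_type == "qc")
  if (!skip_loess && n_qc >= 4) {
    table <- loess_qc_correct(table, span = config$loess_span)
    note("loess", "drift corrected against %d QCs (span %.2f)", n_qc,
         config$loess_span)
  } else {
    note("loess", "skipped (%s)",
         if (skip_loess) "explicitly disabled" else sprintf("only %d QCs", n_qc))
  }
  qa <- qa_filter(table, config$cv_max_pct, config$zero_max_pct)
  note("qa_filter", "%d of %d features retained (%d cv_fail, %d zero_fail)",
       sum(qa$report$retained), nrow(qa$report),
       sum(qa$report$reason == "cv_fail"), sum(qa$report$reason == "zero_fail"))
  table <- qa$table

  paired <- subset_comparison(table, spec)
  note("pairing", "'%s': %d complete pairs%s", spec$name, length(paired$subjects),
       if (length(paired$dropped))
         sprintf(" (dropped: %s)", paste(paired$dropped, collapse = ", ")) else "")

  volc <- volcano(paired, config)
  sel_ids <- volcano_select(volc, config$abs_log2fc_min, config$alpha,
                            config$use_adjusted_p)
  note("volcano", "%d of %d features selected", length(sel_ids), nrow(volc))

  result <- list(comparison = spec$name, config = config, table = table,
                 qa_report = qa$report, paired = paired, volcano = volc,
                 volcano_selected = sel_ids, pca = NULL, opls = NULL,
                 validation = NULL, vip_table = NULL, selected = NULL,
                 annotation = NULL, status = "ok", audit = NULL)

  if (length(sel_ids) < 2) {
    result$status <- "multivariate_skipped"
    note("multivariate", "skipped: only %d volcano-selected feature(s)",
         length(sel_ids))
    if (length(sel_ids) == 1) {
      # the lone variable still flows to annotation, mirroring the
      # one-variable dialysate contrast
      i <- match(sel_ids, volc$feature_id)
      result$selected <- data.frame(
        feature_id = sel_ids, vip = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, fc = volc$fc[i], rank = 1L,
        two_sided_fc = pmax(volc$fc[i], 1 / volc$fc[i]),
        stringsAsFactors = FALSE)
    }
  } else {
    idx <- match(sel_ids, paired$features$feature_id)
    # rows: group-a samples then group-b samples; columns: selected features
    X <- rbind(t(paired$a[idx, , drop = FALSE]), t(paired$b[idx, , drop = FALSE]))
    colnames(X) <- sel_ids
    rownames(X) <- c(paste0(paired$subjects, "_a"), paste0(paired$subjects, "_b"))
    y <- factor(rep(c("a", "b"), each = length(paired$subjects)),
                levels = c("a", "b"))

    sm <- scale_matrix(X, config$scaling)
    result$pca <- fit_pca(sm, n_components = min(2, ncol(sm$X)))
    n_ortho <- suppressWarnings(
      choose_n_ortho(X, y, config$max_ortho, config$cv_folds, config$seed,
                     config$scaling))
    note("opls", "forward-selected %d orthogonal component(s); CV Q2 path: %s",
         as.integer(n_ortho),
         paste(sprintf("%.3f", attr(n_ortho, "q2_path")), collapse = ", "))
    opls <- fit_oplsda(sm, y, n_ortho = as.integer(n_ortho))
    cv <- suppressWarnings(
      cross_validated_q2(X, y, as.integer(n_ortho), config$cv_folds,
                         config$seed, config$scaling))
    anova <- cv_anova(cv$press, cv$ss_tot, nrow(X), 1 + opls$n_ortho)
    perm <- if (config$run_permutation)
      permutation_test(X, y, config$n_permutations, config$seed,
                       as.integer(n_ortho), config$cv_folds, config$scaling)
    else NULL
    validation <- list(
      r2y = opls$r2y, q2 = cv$q2, q2_threshold_passed = cv$q2 > 0.5,
      cv_anova = anova, permutation = perm,
      overall_valid = cv$q2 > 0.5 && anova$p < 0.05 &&
        (is.null(perm) || (perm$p_r2 < 0.05 && perm$p_q2 < 0.05)))
    note("validation", "R2Y %.3f, Q2 %.3f, CV-ANOVA p %.3g%s", opls$r2y,
         cv$q2, anova$p,
         if (!is.null(perm)) sprintf(", permutation p(R2) %.3g p(Q2) %.3g",
                                     perm$p_r2, perm$p_q2) else "")

    vip <- vip_scores(opls)
    vt <- jackknife_ci(cv, vip)
    vt$fc <- volc$fc[match(vt$feature_id, volc$feature_id)]
    selected <- select_discriminant(vt, config$top_n, config$vip_min,
                                    config$fc_min)
    note("selection", "%d variable(s) pass the VIP/CI/FC cascade",
         nrow(selected))
    result$opls <- opls
    result$cv <- cv
    result$validation <- validation
    result$vip_table <- vt
    result$selected <- selected
  }

  if (!is.null(library) && !is.null(result$selected) && nrow(result$selected)) {
    feats <- table$features[match(result$selected$feature_id,
                                  table$features$feature_id), , drop = FALSE]
    result$annotation <- annotate_features(feats, library, config$adducts,
                                           config$ppm_tol)
    note("annotation", "%d hit row(s) for %d selected variable(s)",
         nrow(result$annotation), nrow(result$selected))
  }

  result$audit <- do.call(rbind, lapply(audit, function(e)
    data.frame(stage = e$stage, message = e$message, stringsAsFactors = FALSE)))
  class(result) <- "metabopair_result"
  result
}

#' @export
print.metabopair_result <- function(x, ...) {
  cat(sprintf("<metabopair_result> comparison '%s' [%s]\n", x$comparison,
              x$status))
  cat(sprintf("  volcano: %d selected of %d features\n",
              length(x$volcano_selected), nrow(x$volcano)))
  if (!is.null(x$validation))
    cat(sprintf("  OPLS-DA: R2Y %.3f, Q2 %.3f, CV-ANOVA p %.3g, valid: %s\n",
                x$validation$r2y, x$validation$q2, x$validation$cv_anova$p,
                x$validation$overall_valid))
  if (!is.null(x$selected))
    cat(sprintf("  selection cascade: %d variable(s)\n", nrow(x$selected)))
  if (!is.null(x$annotation))
    cat(sprintf("  annotation: %d row(s)\n", nrow(x$annotation)))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Per-stage delimited tables (QA report, volcano table, VIP table,
#' selected variables, annotation), a JSON model/validation summary, the
#' audit log (TSV and JSON lines) and the peak-verification checklist.
#'
#' @param result a `metabopair_result`.
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "metabopair_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$qa_report, "qa_report.tsv")
  wr(result$volcano, "volcano.tsv")
  if (!is.null(result$vip_table)) wr(result$vip_table, "vip.tsv")
  if (!is.null(result$selected)) wr(result$selected, "selected_variables.tsv")
  if (!is.null(result$annotation)) wr(result$annotation, "annotation.tsv")
  wr(result$audit, "audit_log.tsv")
  summary <- list(
    comparison = result$comparison, status = result$status,
    n_features = nrow(result$volcano),
    n_volcano_selected = length(result$volcano_selected),
    n_selected = if (!is.null(result$selected)) nrow(result$selected) else 0L)
  if (!is.null(result$validation)) {
    v <- result$validation
    summary$validation <- list(
      r2y = v$r2y, q2 = v$q2, q2_threshold_passed = v$q2_threshold_passed,
      cv_anova_p = v$cv_anova$p,
      permutation_p_r2 = if (!is.null(v$permutation)) v$permutation$p_r2,
      permutation_p_q2 = if (!is.null(v$permutation)) v$permutation$p_q2,
      overall_valid = v$overall_valid)
  }
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, sp)
  if (!is.null(result$selected) && nrow(result$selected) > 0) {
    cp <- file.path(dir, "peak_checklist.tsv")
    verify_peak(result$selected, result$table, cp)
    paths <- c(paths, cp)
  }
  invisible(paths)
}
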