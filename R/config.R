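#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis cascade. The defaults are
#' the study's published settings: QC CV < 30%, zero fraction <= 60%,
#' |log2FC| > 1 with adjusted p < 0.05 at the volcano stage, 7-fold cross
#' validation, a 1,000-iteration permutation test, and a selection cascade of
#' the top 30 VIP-ranked variables with VIP > 1, a jack-knife CI excluding
#' zero, and two-sided fold change > 1.2; annotation within +/- 10 ppm for
#' the M+H, M+Na and M+H-H2O adducts.
#'
#' @param cv_max_pct QA: retain features with QC CV strictly below this (%).
#' @param zero_max_pct QA: retain features whose zero percentage among study
#'   injections does not exceed this (%).
#' @param abs_log2fc_min volcano: require |log2FC| strictly above this.
#' @param alpha volcano significance level (applied to BH-adjusted p when
#'   `use_adjusted_p`).
#' @param use_adjusted_p compare `alpha` against BH-adjusted p (default) or
#'   raw p.
#' @param shapiro_alpha level of the Shapiro-Wilk normality gate choosing
#'   paired t vs Wilcoxon.
#' @param zero_impute `"halfmin"` (half the smallest positive value of the
#'   feature) or `"unit"` (offset of 1) before fold-change ratios.
#' @param loess_span span of the per-feature QC LOESS drift curve.
#' @param cv_folds folds of the stratified cross-validation behind Q2.
#' @param n_permutations iterations of the permutation test.
#' @param run_permutation whether `run_pipeline()` runs the permutation test.
#' @param max_ortho largest number of orthogonal OPLS components tried by
#'   forward selection.
#' @param scaling `"uv"`, `"pareto"` or `"center_only"` column scaling for
#'   the multivariate stage.
#' @param top_n,vip_min,fc_min discriminant-variable cascade: the first
#'   `top_n` VIP-ranked variables with VIP > `vip_min` and two-sided fold
#'   change > `fc_min`.
#' @param ppm_tol annotation mass tolerance (ppm).
#' @param adducts adduct names understood by [adduct_shifts()].
#' @param seed integer seed driving fold assignment and permutations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cv_max_pct = 30, zero_max_pct = 60,
                            abs_log2fc_min = 1, alpha = 0.05,
                            use_adjusted_p = TRUE, shapiro_alpha = 0.05,
                            zero_impute = c("halfmin", "unit"),
                            loess_span = 0.75, cv_folds = 7,
                            n_permutations = 1000, run_permutation = TRUE,
                            max_ortho = 3,
                            scaling = c("uv", "pareto", "center_only"),
                            top_n = 30, vip_min = 1, fc_min = 1.2,
                            ppm_tol = 10,
                            adducts = c("M+H", "M+Na", "M+H-H2O"),
                            seed = 1L) {
  zero_impute <- match.arg(zero_impute)
  scaling <- match.arg(scaling)
  cfg <- list(cv_max_pct = cv_max_pct, zero_max_pct = zero_max_pct,
              abs_log2fc_min = abs_log2fc_min, alpha = alpha,
              use_adjusted_p = isTRUE(use_adjusted_p),
              shapiro_alpha = shapiro_alpha, zero_impute = zero_impute,
              loess_span = loess_span, cv_folds = as.integer(cv_folds),
              n_permutations = as.integer(n_permutations),
              run_permutation = isTRUE(run_permutation),
              max_ortho = as.integer(max_ortho), scaling = scaling,
              top_n = as.integer(top_n), vip_min = vip_min, fc_min = fc_min,
              ppm_tol = ppm_tol, adducts = adducts, seed = as.integer(seed))
  num <- c("cv_max_pct", "zero_max_pct", "abs_log2fc_min", "alpha",
           "shapiro_alpha", "loess_span", "cv_folds", "n_permutations",
           "top_n", "vip_min", "fc_min", "ppm_tol")
  for (nm in num)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be finite and positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are an error; absent keys keep their defaults.
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
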