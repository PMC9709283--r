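#' Specification of a synthetic crossover study
#'
#' Describes the generative model used by [simulate_study()]: a two-arm
#' crossover with paired timepoints, log-normal feature intensities with
#' between-subject and residual log-scale variation, a designated subset of
#' features whose post-dialysis level is shifted by a known multiplicative
#' fold change, smooth multiplicative injection-order drift, interleaved QC
#' pool injections, and zero-censoring of study intensities.
#'
#' Defaults mirror the emulated study design: 21 subjects, two arms, paired
#' pre/post sampling, 500 features, 5 leading QCs and a QC every 6 study
#' injections. Effect sizes default to a clearance-type fold change of 0.46
#' (post/pre), the magnitude reported for creatinine removal; variance
#' parameters are field conventions discussed in the package vignette.
#'
#' @param n_subjects number of subjects (default 21).
#' @param arms crossover arms (default `c("AD","CD")`).
#' @param timepoints sampled timepoints, subset of pre/mid/post/rebound.
#' @param n_features number of molecular features (default 500).
#' @param n_affected number of features given a true post/pre effect.
#' @param fc_affected multiplicative post/pre fold change of affected
#'   features (> 0; scalar or length `n_affected`).
#' @param baseline_log_mean,baseline_log_sd natural-log intensity location
#'   and spread across features.
#' @param subject_sd between-subject multiplicative spread (log scale), per
#'   feature and subject, shared across that subject's injections.
#' @param noise_sd residual log-scale noise per cell.
#' @param drift_amplitude peak-to-trough multiplicative drift over the
#'   injection sequence (0 = no drift).
#' @param qc_every interleave period: one QC pool after every `qc_every`
#'   study injections.
#' @param n_lead_qc QC injections at the start of the sequence (default 5).
#' @param n_trail_qc QC injections closing the sequence.
#' @param n_blank blank injections at the end of the sequence.
#' @param zero_rate probability a study intensity is censored to 0.
#' @param seed integer seed; the whole table is reproducible from it.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 21, arms = c("AD", "CD"),
                            timepoints = c("pre", "post"),
                            n_features = 500, n_affected = 30,
                            fc_affected = 0.46,
                            baseline_log_mean = 7, baseline_log_sd = 1.2,
                            subject_sd = 0.3, noise_sd = 0.15,
                            drift_amplitude = 0.3,
                            qc_every = 6, n_lead_qc = 5, n_trail_qc = 1,
                            n_blank = 1, zero_rate = 0.05, seed = 1L) {
  stopifnot(n_affected <= n_features, all(fc_affected > 0),
            zero_rate >= 0, zero_rate < 1, drift_amplitude >= 0,
            all(timepoints %in% c("pre", "mid", "post", "rebound")),
            "pre" %in% timepoints)
  structure(list(n_subjects = n_subjects, arms = arms, timepoints = timepoints,
                 n_features = n_features, n_affected = n_affected,
                 fc_affected = fc_affected,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, qc_every = qc_every,
                 n_lead_qc = n_lead_qc, n_trail_qc = n_trail_qc,
                 n_blank = n_blank, zero_rate = zero_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# smooth drift shape on [0,1]: gentle trend plus one slow oscillation
drift_shape <- function(u) 0.6 * u + 0.2 * (1 - cos(2 * pi * u))

#' Multiplicative injection-order drift factor
#'
#' A smooth positive function of injection order (low-order sinusoid plus a
#' linear trend) rescaled so that the ratio of its maximum to its minimum
#' over the sequence equals `1 + amplitude`. With `amplitude = 0` the factor
#' is identically 1.
#'
#' @param order injection order(s), 1-based.
#' @param n_total total number of injections in the sequence.
#' @param amplitude peak-to-trough drift amplitude (>= 0).
#' @return numeric vector of positive factors.
#' @export
drift_profile <- function(order, n_total, amplitude) {
  stopifnot(all(order >= 1), all(order <= n_total), amplitude >= 0)
  if (amplitude == 0) return(rep(1, length(order)))
  grid <- drift_shape(seq(0, 1, length.out = 2001))
  u <- if (n_total == 1) rep(0, length(order)) else (order - 1) / (n_total - 1)
  s <- drift_shape(u)
  1 + amplitude * (s - min(grid)) / (max(grid) - min(grid))
}

#' Simulate a crossover feature table with known ground truth
#'
#' Study intensity of feature f in injection i is
#' `exp(baseline_f + subject_{f,s} + effect_f * [timepoint == post] + eps) *
#' drift(order_i)`, followed by zero-censoring; QC pool intensity is
#' `exp(baseline_f + eps_qc) * drift(order_i)` (no censoring: the pool is
#' the same well-characterized material injected repeatedly). Blanks are
#' zero. Study injections are run in randomized order with `n_lead_qc`
#' leading QCs, one QC after every `qc_every` study injections, trailing
#' QCs and final blanks.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `table` (a [feature_table()]) and `truth`
#'   (affected features with true fold changes, drift factors per injection,
#'   per-subject random effects, and the spec).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  nf <- spec$n_features
  feats <- data.frame(
    feature_id = sprintf("F%04d", seq_len(nf)),
    mz = round(sort(stats::runif(nf, 100, 1700)), 5),
    rt = round(stats::runif(nf, 0.4, 14), 4),
    stringsAsFactors = FALSE)
  baseline <- stats::rnorm(nf, spec$baseline_log_mean, spec$baseline_log_sd)
  affected_idx <- sort(sample.int(nf, spec$n_affected))
  fc <- rep_len(spec$fc_affected, spec$n_affected)
  effect <- numeric(nf)
  effect[affected_idx] <- log(fc)

  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  study <- expand.grid(subject_id = subjects, arm = spec$arms,
                       timepoint = spec$timepoints,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  study <- study[sample.int(nrow(study)), , drop = FALSE]  # randomized run order
  n_study <- nrow(study)

  # build the injection sequence: lead QCs, study blocks with interleaved
  # QCs, trailing QCs, closing blanks
  seq_type <- c(rep("qc", spec$n_lead_qc))
  study_pos <- integer(0)
  for (i in seq_len(n_study)) {
    seq_type <- c(seq_type, "study")
    study_pos <- c(study_pos, length(seq_type))
    if (i %% spec$qc_every == 0 && i < n_study) seq_type <- c(seq_type, "qc")
  }
  seq_type <- c(seq_type, rep("qc", spec$n_trail_qc), rep("blank", spec$n_blank))
  n_total <- length(seq_type)
  drift <- drift_profile(seq_len(n_total), n_total, spec$drift_amplitude)

  inj <- data.frame(
    injection_id = sprintf("I%03d", seq_len(n_total)),
    subject_id = NA_character_, timepoint = NA_character_,
    arm = NA_character_, sample_type = seq_type,
    injection_order = seq_len(n_total), stringsAsFactors = FALSE)
  inj$subject_id[study_pos] <- study$subject_id
  inj$timepoint[study_pos] <- study$timepoint
  inj$arm[study_pos] <- study$arm

  subj_eff <- matrix(stats::rnorm(nf * spec$n_subjects, 0, spec$subject_sd),
                     nrow = nf, dimnames = list(feats$feature_id, subjects))

  mat <- matrix(0, nrow = nf, ncol = n_total,
                dimnames = list(feats$feature_id, inj$injection_id))
  for (j in seq_len(n_total)) {
    if (seq_type[j] == "blank") next
    eps <- stats::rnorm(nf, 0, spec$noise_sd)
    if (seq_type[j] == "qc") {
      mat[, j] <- exp(baseline + eps) * drift[j]
    } else {
      s <- inj$subject_id[j]
      post <- as.numeric(inj$timepoint[j] == "post")
      mat[, j] <- exp(baseline + subj_eff[, s] + effect * post + eps) * drift[j]
    }
  }
  if (spec$zero_rate > 0) {
    cens <- matrix(stats::runif(nf * length(study_pos)) < spec$zero_rate,
                   nrow = nf)
    mat[, study_pos][cens] <- 0
  }

  table <- feature_table(feats, inj, mat,
                         provenance = sprintf("simulated study (seed %d): %d features, %d study injections",
                                              spec$seed, nf, n_study))
  truth <- list(
    affected = data.frame(feature_id = feats$feature_id[affected_idx],
                          fc = fc, stringsAsFactors = FALSE),
    drift = data.frame(injection_id = inj$injection_id,
                       injection_order = inj$injection_order,
                       factor = drift, stringsAsFactors = FALSE),
    subject_effects = subj_eff,
    baseline = baseline,
    spec = spec)
  list(table = table, truth = truth)
}

#' Bundled reference annotation fixture
#'
#' Returns the packaged mini feature list (reported accurate masses with
#' their adduct and formula assignments from a plasma hemodialysis
#' metabolomics dataset, including unassigned level-4 masses) together with
#' the matching compound mini-library, both shipped as plain-text files
#' under `inst/extdata/`.
#'
#' @return list with data.frames `features` (observed_mz, rt, adduct,
#'   formula, name) and `library` (name, formula, class, evidence flags).
#' @export
make_annotation_fixture <- function() {
  fpath <- system.file("extdata", "reference_features.tsv",
                       package = "metabopair", mustWork = TRUE)
  lpath <- system.file("extdata", "compound_library.tsv",
                       package = "metabopair", mustWork = TRUE)
  features <- utils::read.table(fpath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, quote = "")
  library <- read_compound_library(lpath)
  list(features = features, library = library)
}
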