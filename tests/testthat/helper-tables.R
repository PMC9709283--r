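# shared fixture builders (all generated in code)

# minimal deterministic table: nf features, a study block per subject x
# timepoint (single arm), lead + trailing QCs, one blank
tiny_table <- function(nf = 3, n_subjects = 2, timepoints = c("pre", "post"),
                       values = NULL) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  study <- expand.grid(subject_id = subjects, timepoint = timepoints,
                       stringsAsFactors = FALSE)
  n_study <- nrow(study)
  n_qc <- 3
  n <- n_study + n_qc + 1
  inj <- data.frame(
    injection_id = sprintf("I%02d", seq_len(n)),
    subject_id = c(rep(NA, 2), study$subject_id, rep(NA, n - n_study - 2)),
    timepoint = c(rep(NA, 2), study$timepoint, rep(NA, n - n_study - 2)),
    arm = c(rep(NA, 2), rep("AD", n_study), rep(NA, n - n_study - 2)),
    sample_type = c("qc", "qc", rep("study", n_study), "qc", "blank"),
    injection_order = seq_len(n), stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = sprintf("F%02d", seq_len(nf)),
                      mz = 100 + seq_len(nf), rt = seq_len(nf) / 10,
                      stringsAsFactors = FALSE)
  if (is.null(values)) {
    set.seed(99)
    values <- matrix(stats::runif(nf * n, 50, 150), nf, n)
    values[, inj$sample_type == "blank"] <- 0
  }
  feature_table(feats, inj, values)
}

# a QA-oriented table with explicit QC triples and study vectors per feature
qa_table <- function(qc_values, study_values) {
  nf <- nrow(qc_values)
  n_study <- ncol(study_values)
  n_qc <- ncol(qc_values)
  inj <- data.frame(
    injection_id = sprintf("I%02d", seq_len(n_qc + n_study)),
    subject_id = c(rep(NA, n_qc), sprintf("S%02d", seq_len(n_study))),
    timepoint = c(rep(NA, n_qc), rep("pre", n_study)),
    arm = c(rep(NA, n_qc), rep("AD", n_study)),
    sample_type = c(rep("qc", n_qc), rep("study", n_study)),
    injection_order = seq_len(n_qc + n_study), stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = sprintf("F%02d", seq_len(nf)),
                      mz = 100 + seq_len(nf), rt = rep(1, nf),
                      stringsAsFactors = FALSE)
  feature_table(feats, inj, cbind(qc_values, study_values))
}

# two-class Gaussian matrix with a mean shift in a leading block of features
separated_classes <- function(n_per_class = 20, n_features = 200,
                              frac_informative = 0.2, delta = 2, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  k <- round(frac_informative * n_features)
  X[seq_len(n_per_class) + n_per_class, seq_len(k)] <-
    X[seq_len(n_per_class) + n_per_class, seq_len(k)] + delta
  colnames(X) <- sprintf("V%03d", seq_len(n_features))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per_class)),
       informative = colnames(X)[seq_len(k)])
}

# brute-force Benjamini-Hochberg step-up used as the independent oracle
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)  # rank of p[i]
    adj[i] <- min(1, min(p[ord][k:m] * m / (k:m)))
  }
  adj
}
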