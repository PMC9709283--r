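test_that("cv_percent matches closed forms and is scale invariant", {
  expect_equal(cv_percent(c(1, 1, 1)), 0)
  expect_equal(cv_percent(c(90, 100, 110)), 10)
  v <- c(3, 7, 11, 5)
  expect_equal(cv_percent(v * 17), cv_percent(v))
  expect_true(is.na(cv_percent(c(0, 0))))
})

test_that("medFC recovers exact per-injection scale factors", {
  base <- matrix(c(10, 20, 30, 40,
                   5, 10, 15, 20,
                   2, 4, 6, 8), nrow = 3, byrow = TRUE)
  # 5 identical study profiles + one exactly doubled
  vals <- cbind(base[, 1], base[, 1], base[, 1], base[, 1], base[, 1],
                2 * base[, 1], base[, 1], base[, 1])
  inj <- data.frame(injection_id = sprintf("I%d", 1:8),
                    subject_id = c(sprintf("S%d", 1:6), NA, NA),
                    timepoint = c(rep("pre", 6), NA, NA),
                    arm = c(rep("AD", 6), NA, NA),
                    sample_type = c(rep("study", 6), "qc", "qc"),
                    injection_order = 1:8, stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = c("F1", "F2", "F3"),
                      mz = c(101, 102, 103), rt = c(1, 2, 3))
  tab <- feature_table(feats, inj, vals)
  out <- medfc_normalize(tab)
  f <- attr(out, "medfc_factors")
  expect_equal(unname(f[6]), 2)
  expect_equal(out$intensities[, 6], out$intensities[, 1])
  # identical injections: all factors 1, table unchanged
  same <- tab; same$intensities <- cbind(base[, 1], base[, 1], base[, 1],
                                         base[, 1], base[, 1], base[, 1],
                                         base[, 1], base[, 1])
  colnames(same$intensities) <- same$injections$injection_id
  rownames(same$intensities) <- same$features$feature_id
  out2 <- medfc_normalize(same)
  expect_equal(unname(attr(out2, "medfc_factors")), rep(1, 8))
  expect_equal(out2$intensities, same$intensities)
})

test_that("medFC undoes simulated dilution and is idempotent", {
  # low biological spread so the median-of-ratios factor is a sharp oracle
  sim <- simulate_study(simulation_spec(n_subjects = 8, arms = "AD",
                                        n_features = 200, n_affected = 0,
                                        noise_sd = 0.01, subject_sd = 0.02,
                                        zero_rate = 0,
                                        drift_amplitude = 0, seed = 31))
  tab <- sim$table
  study_idx <- which(tab$injections$sample_type == "study")[1:3]
  dil <- c(0.5, 1, 2)
  for (k in 1:3) tab$intensities[, study_idx[k]] <-
    tab$intensities[, study_idx[k]] * dil[k]
  out <- medfc_normalize(tab)
  f <- attr(out, "medfc_factors")
  # recovered factors proportional to the injected dilutions
  rel <- f[study_idx] / f[study_idx[2]]
  expect_equal(unname(rel), dil, tolerance = 0.01)
  # idempotence: a second pass finds (almost) nothing left to scale; the
  # reference profile is re-estimated, so equality is statistical, not exact
  f2 <- attr(medfc_normalize(out), "medfc_factors")
  expect_equal(unname(f2), rep(1, length(f2)), tolerance = 0.01)
})

test_that("LOESS correction is a no-op without drift and shrinks QC CV under drift", {
  flat <- simulate_study(simulation_spec(n_subjects = 8, arms = "AD",
                                         n_features = 100, n_affected = 0,
                                         noise_sd = 1e-9, zero_rate = 0,
                                         drift_amplitude = 0, seed = 41))
  out <- loess_qc_correct(flat$table, span = 0.75)
  expect_equal(out$intensities, flat$table$intensities, tolerance = 1e-6)

  drift <- simulate_study(simulation_spec(n_subjects = 10, arms = c("AD", "CD"),
                                          n_features = 150, n_affected = 0,
                                          noise_sd = 0.05, zero_rate = 0,
                                          drift_amplitude = 1, seed = 42))
  qc <- drift$table$injections$sample_type == "qc"
  cv_before <- apply(drift$table$intensities[, qc, drop = FALSE], 1, cv_percent)
  corr <- loess_qc_correct(drift$table, span = 0.75)
  cv_after <- apply(corr$intensities[, qc, drop = FALSE], 1, cv_percent)
  expect_gte(mean(cv_after < cv_before), 0.95)
})

test_that("LOESS refuses to run on too few QCs", {
  tab <- tiny_table()
  keep <- tab$injections$sample_type != "qc"
  keep[which(tab$injections$sample_type == "qc")[1:2]] <- TRUE
  tab$injections <- tab$injections[keep, , drop = FALSE]
  tab$intensities <- tab$intensities[, keep, drop = FALSE]
  expect_error(loess_qc_correct(tab), "skip")
})

test_that("QA filter applies the exact boundary semantics", {
  # rows: CV 10% retained / constant QC retained / CV exactly 30% removed /
  # 70% zeros removed / exactly 60% zeros retained
  qc <- rbind(c(90, 100, 110),
              c(100, 100, 100),
              c(70, 100, 130),
              c(100, 101, 102),
              c(100, 101, 102))
  study <- rbind(rep(10, 10),
                 rep(10, 10),
                 rep(10, 10),
                 c(rep(0, 7), rep(10, 3)),
                 c(rep(0, 6), rep(10, 4)))
  tab <- qa_table(qc, study)
  res <- qa_filter(tab, cv_max_pct = 30, zero_max_pct = 60)
  expect_equal(res$report$retained, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$report$reason, c("pass", "pass", "cv_fail", "zero_fail", "pass"))
  expect_equal(res$report$qc_cv_pct[1:3], c(10, 0, 30))
  expect_equal(res$report$zero_pct[4:5], c(70, 60))
  # conservation: retained + removed = input
  expect_equal(sum(res$report$retained) + sum(!res$report$retained),
               nrow(tab$features))
  expect_equal(nrow(res$table$features), 3)
})

test_that("lowering the CV threshold never rescues a CV-removed feature", {
  set.seed(7)
  qc <- matrix(stats::runif(40 * 5, 50, 150), 40, 5)
  study <- matrix(stats::runif(40 * 6, 50, 150), 40, 6)
  tab <- qa_table(qc, study)
  loose <- qa_filter(tab, cv_max_pct = 30, zero_max_pct = 60)$report
  tight <- qa_filter(tab, cv_max_pct = 20, zero_max_pct = 60)$report
  expect_true(all(!loose$retained | loose$reason != "cv_fail" |
                    !tight$retained))
  # tight retains a subset of loose
  expect_true(all(!tight$retained | loose$retained))
})
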