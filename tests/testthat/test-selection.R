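fake_oplsda <- function(w, ssy = c(predictive = 1)) {
  structure(list(w = w, W_o = matrix(0, length(w), 0), n_ortho = 0,
                 ssy = ssy, features = names(w)), class = "oplsda")
}

fake_cv <- function(vip_matrix) {
  # wrap per-fold VIP vectors as sub-models understood by vip_scores()
  subs <- lapply(seq_len(nrow(vip_matrix)), function(g) {
    v <- vip_matrix[g, ]
    # invert VIP -> weights for a single-component model: vip = sqrt(p)*|w|
    w <- v / sqrt(sum(v^2))
    list(model = fake_oplsda(stats::setNames(w, colnames(vip_matrix))))
  })
  structure(list(submodels = subs), class = "cv_q2")
}

test_that("VIP is 1 for equally weighted features and sums to the feature count", {
  y <- factor(rep(c("a", "b"), each = 6))
  y_num <- as.numeric(y == "b") * 2 - 1
  X <- matrix(rep(y_num, 5), ncol = 5) + matrix(stats::rnorm(60, 0, 1e-9), 12, 5)
  colnames(X) <- sprintf("V%d", 1:5)
  fit <- fit_oplsda(scale_matrix(X, "uv"), y, 0)
  expect_equal(unname(vip_scores(fit)), rep(1, 5), tolerance = 1e-6)

  set.seed(20)
  for (k in 0:2) {
    X <- matrix(stats::rnorm(14 * 9), 14, 9)
    yy <- factor(rep(c("a", "b"), each = 7))
    fit <- fit_oplsda(scale_matrix(X, "uv"), yy, k)
    v <- vip_scores(fit)
    expect_equal(sum(v^2), 9, tolerance = 1e-6)
  }
})

test_that("a feature with zero weight gets VIP zero", {
  y <- factor(rep(c("a", "b"), each = 4))
  y_num <- as.numeric(y == "b") * 2 - 1
  orth <- c(1, -1, 1, -1, 1, -1, 1, -1)  # exactly orthogonal to y coding
  X <- cbind(sig = y_num + c(0.01, -0.02, 0.015, 0, 0.01, 0.02, -0.01, 0),
             dead = orth)
  fit <- fit_oplsda(scale_matrix(X, "center_only"), y, 0)
  v <- vip_scores(fit)
  expect_lt(v[["dead"]], 0.05)
})

test_that("jack-knife intervals collapse for identical sub-models and widen with jitter", {
  p <- 4
  v3 <- c(1.2, 1.1, 0.9)
  # squared VIPs must sum to p for the weight inversion to be exact
  vip_full <- stats::setNames(c(v3, sqrt(p - sum(v3^2))), sprintf("V%d", 1:p))
  base <- matrix(rep(vip_full, each = 5), nrow = 5)
  colnames(base) <- names(vip_full)
  ci0 <- jackknife_ci(fake_cv(base), vip_full)
  expect_equal(ci0$ci_low, ci0$ci_high, tolerance = 1e-9)
  expect_equal(ci0$vip, unname(vip_full))

  set.seed(30)
  jit_small <- base * matrix(exp(stats::rnorm(20, 0, 0.01)), 5)
  jit_big <- base * matrix(exp(stats::rnorm(20, 0, 0.2)), 5)
  w_small <- with(jackknife_ci(fake_cv(jit_small), vip_full), ci_high - ci_low)
  w_big <- with(jackknife_ci(fake_cv(jit_big), vip_full), ci_high - ci_low)
  expect_true(all(w_big > w_small))

  # a feature with VIP 0 in every sub-model: CI [0,0], so it includes zero
  v0 <- c(0, sqrt(2), 1, 1)
  zero_full <- stats::setNames(v0, colnames(base))
  z <- matrix(rep(v0, each = 5), 5, p, dimnames = list(NULL, colnames(base)))
  ciz <- jackknife_ci(fake_cv(z), zero_full)
  expect_equal(ciz$ci_low[1], 0, tolerance = 1e-9)
  expect_equal(ciz$ci_high[1], 0, tolerance = 1e-9)
})

test_that("the selection cascade applies VIP, CI and fold-change rules in order", {
  vt <- data.frame(
    feature_id = c("low_vip", "ci_zero", "weak_fc", "good_up", "good_down"),
    vip = c(0.9, 1.8, 1.5, 1.6, 1.3),
    ci_low = c(0.5, -0.1, 1.0, 1.2, 0.9),
    ci_high = c(1.2, 2.0, 2.0, 2.0, 1.7),
    fc = c(3, 3, 1.1, 2.5, 0.3), stringsAsFactors = FALSE)
  sel <- select_discriminant(vt, top_n = 30, vip_min = 1, fc_min = 1.2)
  expect_setequal(sel$feature_id, c("good_up", "good_down"))
  # two-sided fold change: 0.3 passes because 1/0.3 > 1.2
  expect_equal(sel$two_sided_fc[sel$feature_id == "good_down"], 1 / 0.3)
})

test_that("at most top_n variables are selected and ordering is canonical", {
  set.seed(31)
  n <- 40
  vt <- data.frame(feature_id = sprintf("F%02d", 1:n),
                   vip = stats::runif(n, 1.2, 3),
                   ci_low = rep(0.5, n), ci_high = rep(3.5, n),
                   fc = rep(2, n), stringsAsFactors = FALSE)
  sel <- select_discriminant(vt, top_n = 30, vip_min = 1, fc_min = 1.2)
  expect_equal(nrow(sel), 30)
  expect_equal(sel$rank, 1:30)
  expect_true(all(diff(sel$vip) <= 0))
  # invariance to input row order
  perm <- vt[sample(n), ]
  sel2 <- select_discriminant(perm, top_n = 30, vip_min = 1, fc_min = 1.2)
  expect_equal(sel2$feature_id, sel$feature_id)
})

test_that("raising the fold-change threshold never adds selections", {
  set.seed(32)
  vt <- data.frame(feature_id = sprintf("F%02d", 1:25),
                   vip = stats::runif(25, 0.5, 2.5),
                   ci_low = stats::runif(25, -0.5, 1),
                   ci_high = stats::runif(25, 1, 3),
                   fc = stats::runif(25, 0.1, 4), stringsAsFactors = FALSE)
  s1 <- select_discriminant(vt, fc_min = 1.2)$feature_id
  s2 <- select_discriminant(vt, fc_min = 2)$feature_id
  expect_true(all(s2 %in% s1))
})

test_that("the peak-verification checklist carries QC traces in injection order", {
  tab <- tiny_table(nf = 6)
  sel <- data.frame(feature_id = tab$features$feature_id[1:5], rank = 1:5,
                    stringsAsFactors = FALSE)
  chk <- verify_peak(sel, tab)
  expect_equal(nrow(chk), 5)
  qc_idx <- which(tab$injections$sample_type == "qc")
  expected <- paste(signif(tab$intensities[1, qc_idx], 6), collapse = ";")
  expect_equal(chk$qc_intensities[1], expected)
  empty <- verify_peak(sel[0, , drop = FALSE], tab)
  expect_equal(nrow(empty), 0)
})
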