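test_that("scaling modes behave as documented and invert exactly", {
  set.seed(2)
  X <- matrix(stats::rnorm(60, 5, 3), 10, 6)
  X <- cbind(X, rep(1, 10))  # zero-variance column
  colnames(X) <- sprintf("V%d", 1:7)
  sm <- scale_matrix(X, "uv")
  expect_equal(sm$dropped, "V7")
  expect_equal(unname(apply(sm$X, 2, stats::sd)), rep(1, 6))
  co <- scale_matrix(X[, 1:6], "center_only")
  expect_equal(unname(colMeans(co$X)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(co$X, 2, stats::sd)),
               unname(apply(X[, 1:6], 2, stats::sd)))
  expect_equal(unscale_matrix(sm), X[, 1:6], ignore_attr = TRUE)
})

test_that("PCA matches a direct eigendecomposition and reconstructs the data", {
  set.seed(3)
  X <- scale(matrix(stats::rnorm(20), 5, 4), scale = FALSE)
  pca <- fit_pca(scale_matrix(X, "center_only"), n_components = 4)
  ev <- eigen(stats::cov(X))$values
  expect_equal(unname(pca$r2x), ev[1:4] / sum(ev), tolerance = 1e-10)
  expect_equal(pca$scores %*% t(pca$loadings), X, ignore_attr = TRUE,
               tolerance = 1e-10)
  # collinear samples: one component explains everything
  line <- outer(1:6, c(1, 2, 3))
  p1 <- fit_pca(scale_matrix(line, "center_only"), 2)
  expect_equal(unname(p1$r2x[1]), 1, tolerance = 1e-12)
})

test_that("with no orthogonal component OPLS-DA reduces to PLS1 component 1", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(4)
  for (i in 1:3) {
    X <- matrix(stats::rnorm(80), 10, 8)
    y <- factor(rep(c("a", "b"), each = 5))
    sm <- scale_matrix(X, "uv")
    fit <- fit_oplsda(sm, y, n_ortho = 0)
    ref <- mixOmics::pls(sm$X, as.numeric(y == "b") - 0.5, ncomp = 1,
                         scale = FALSE, mode = "regression")
    w_ref <- ref$loadings$X[, 1]
    align <- sign(sum(w_ref * fit$w))
    expect_equal(unname(fit$w), unname(align * w_ref), tolerance = 1e-8)
    expect_gt(abs(stats::cor(fit$t_p, ref$variates$X[, 1])), 1 - 1e-8)
  }
})

test_that("predictive and orthogonal scores are orthogonal", {
  set.seed(6)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(150), 15, 10)
    y <- factor(rep(c("a", "b"), c(7, 8)))
    fit <- fit_oplsda(scale_matrix(X, "uv"), y, n_ortho = 2)
    for (a in seq_len(fit$n_ortho)) {
      t_o <- fit$T_o[, a]
      expect_lt(abs(sum(fit$t_p * t_o)) /
                  (sqrt(sum(fit$t_p^2)) * sqrt(sum(t_o^2))), 1e-8)
    }
  }
})

test_that("strong class separation yields high R2Y; no signal yields none", {
  sep <- separated_classes(delta = 5, seed = 9)
  fit <- fit_oplsda(scale_matrix(sep$X, "uv"), sep$y, n_ortho = 1)
  expect_gt(fit$r2y, 0.9)
  expect_true(fit$r2y <= 1 && fit$r2y >= 0)

  # X constructed orthogonal to y: no explained variance
  set.seed(10)
  y <- factor(rep(c("a", "b"), each = 10))
  y_num <- as.numeric(y == "b") - 0.5
  X <- matrix(stats::rnorm(20 * 8), 20, 8)
  X <- X - outer(y_num, drop(crossprod(X, y_num)) / sum(y_num^2))
  X <- X + matrix(stats::rnorm(20 * 8, 0, 1e-3), 20, 8)
  fit0 <- fit_oplsda(scale_matrix(X, "center_only"), y, n_ortho = 0)
  expect_lt(fit0$r2y, 0.05)
})

test_that("Q2 reaches 1 for perfectly predictive data and stays near 0 under permutation", {
  set.seed(11)
  y <- factor(rep(c("a", "b"), each = 10))
  y_num <- as.numeric(y == "b") * 2 - 1
  X <- cbind(y_num, y_num, y_num) + matrix(stats::rnorm(60, 0, 1e-3), 20, 3)
  cv <- cross_validated_q2(X, y, n_ortho = 0, folds = 7, seed = 1)
  expect_gt(cv$q2, 0.99)

  Xn <- matrix(stats::rnorm(20 * 10), 20, 10)
  q2s <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    yp <- sample(y)
    suppressWarnings(cross_validated_q2(Xn, yp, 0, 7, seed = s))$q2
  }, numeric(1))
  expect_lte(mean(q2s), 0.05)
})

test_that("Q2 is invariant to relabeling the classes", {
  sep <- separated_classes(n_per_class = 10, n_features = 30, seed = 12)
  y2 <- factor(ifelse(sep$y == "a", "z", "w"), levels = c("w", "z"))
  q_a <- cross_validated_q2(sep$X, sep$y, 1, 5, seed = 3)$q2
  q_b <- cross_validated_q2(sep$X, y2, 1, 5, seed = 3)$q2
  expect_equal(q_a, q_b, tolerance = 1e-10)
})

test_that("CV-ANOVA limits and conservative null behaviour", {
  # no predictive ability: PRESS = SS_tot
  res <- cv_anova(press = 10, ss_tot = 10, n_samples = 20, n_components = 1)
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  # perfect prediction limit
  res2 <- cv_anova(press = 1e-9, ss_tot = 10, n_samples = 20, n_components = 1)
  expect_lt(res2$p, 1e-10)
  expect_error(cv_anova(1, 10, n_samples = 3, n_components = 2), "d2")

  # size under the null: the F-approximation never exceeds nominal by much
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    X <- matrix(stats::rnorm(20 * 5), 20, 5)
    y <- factor(rep(c("a", "b"), each = 10))
    yp <- sample(y)
    cv <- suppressWarnings(cross_validated_q2(X, yp, 0, 5, seed = s))
    cv_anova(cv$press, cv$ss_tot, 20, 1)$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.12)
})

test_that("permutation p-values follow the add-one formula and bounds", {
  sep <- separated_classes(n_per_class = 8, n_features = 40, delta = 4, seed = 14)
  perm <- permutation_test(sep$X, sep$y, n_iter = 19, seed = 2, n_ortho = 0,
                           folds = 4)
  # observed diagnostics dominate every permutation of a strong signal
  expect_equal(perm$p_q2, 1 / 20)
  expect_equal(perm$p_r2, 1 / 20)
  expect_gte(min(perm$p_r2, perm$p_q2), 1 / (perm$n_iter + 1))
  expect_length(perm$perm_q2, 19)
  # observed values equal direct fits (the identity permutation)
  direct <- fit_oplsda(scale_matrix(sep$X, "uv"), sep$y, 0)$r2y
  expect_equal(perm$obs_r2, direct, tolerance = 1e-12)
})

test_that("forward selection of orthogonal components is reproducible and bounded", {
  sep <- separated_classes(n_per_class = 10, n_features = 50, seed = 15)
  a1 <- choose_n_ortho(sep$X, sep$y, max_ortho = 2, folds = 5, seed = 8)
  a2 <- choose_n_ortho(sep$X, sep$y, max_ortho = 2, folds = 5, seed = 8)
  expect_identical(as.integer(a1), as.integer(a2))
  expect_true(as.integer(a1) %in% 0:2)
  expect_length(attr(a1, "q2_path"), 3)
})
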