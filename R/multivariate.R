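#' Center and scale a samples-by-features matrix
#'
#' Column-centers the matrix and scales by the sample SD (`"uv"`, the
#' chemometrics default), by the square root of the SD (`"pareto"`), or not
#' at all (`"center_only"`). Zero-variance columns are removed and recorded.
#' Centers and scale factors are retained for the inverse transform and for
#' projecting new samples.
#'
#' @param X numeric matrix, samples x features (>= 2 samples).
#' @param scaling one of `"uv"`, `"pareto"`, `"center_only"`.
#' @return list of class `scaled_matrix`: `X` (scaled), `center`, `scale`,
#'   `scaling`, `kept`, `dropped`.
#' @export
scale_matrix <- function(X, scaling = c("uv", "pareto", "center_only")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all columns have zero variance")
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  center <- colMeans(X)
  scl <- switch(scaling,
                uv = sds[keep],
                pareto = sqrt(sds[keep]),
                center_only = rep(1, sum(keep)))
  names(scl) <- colnames(X)
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  structure(list(X = Xs, center = center, scale = scl, scaling = scaling,
                 kept = colnames(X), dropped = dropped),
            class = "scaled_matrix")
}

#' Invert the centering/scaling of a scaled matrix
#'
#' @param sm a `scaled_matrix`.
#' @param X optional matrix on the scaled scale (defaults to `sm$X`).
#' @return matrix on the original scale (dropped columns are not restored).
#' @export
unscale_matrix <- function(sm, X = sm$X) {
  stopifnot(inherits(sm, "scaled_matrix"))
  sweep(sweep(X, 2, sm$scale, "*"), 2, sm$center, "+")
}

#' Project new samples with a fitted scaling
#'
#' @param sm a `scaled_matrix`.
#' @param newX raw matrix with (at least) the columns retained by `sm`.
#' @return scaled matrix restricted to the retained columns.
#' @export
apply_scaling <- function(sm, newX) {
  stopifnot(inherits(sm, "scaled_matrix"))
  newX <- as.matrix(newX)[, sm$kept, drop = FALSE]
  sweep(sweep(newX, 2, sm$center), 2, sm$scale, "/")
}

as_model_matrix <- function(X) {
  if (inherits(X, "scaled_matrix")) X$X else as.matrix(X)
}

#' Principal component analysis by singular value decomposition
#'
#' Successive variance-maximizing components; scores `T = U D`, orthonormal
#' loadings `P = V`, explained variance per component
#' `R2X_a = d_a^2 / sum(X^2)`. Deterministic sign convention: the
#' largest-magnitude loading element of each component is positive.
#'
#' @param X a `scaled_matrix` (or an already-centered matrix).
#' @param n_components number of components (<= min(samples - 1, features)).
#' @return list of class `pca_model`: `scores`, `loadings`, `r2x`.
#' @export
fit_pca <- function(X, n_components = 2) {
  M <- as_model_matrix(X)
  n_components <- min(n_components, nrow(M) - 1, ncol(M))
  stopifnot(n_components >= 1)
  sv <- svd(M, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  flip <- vapply(seq_len(n_components), function(a) {
    j <- which.max(abs(sv$v[, a]))
    sign(sv$v[j, a])
  }, numeric(1))
  loadings <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(sv$u, 2, d * flip, "*")
  rownames(loadings) <- colnames(M)
  rownames(scores) <- rownames(M)
  colnames(loadings) <- colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  structure(list(scores = scores, loadings = loadings,
                 r2x = d^2 / sum(M^2)), class = "pca_model")
}

code_classes <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly 2 classes required")
  if (any(table(y) < 2)) stop("each class needs >= 2 samples")
  ifelse(y == levels(y)[2], 1, -1)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projection to latent structures discriminant analysis for a
#' binary response, by the NIPALS-type O-PLS algorithm: the predictive
#' weight is `w = X'y / ||X'y||`; each orthogonal component removes from X
#' the y-orthogonal part of the X-loading (`w_o = p - (w'p) w`, normalized;
#' `t_o = X w_o`; deflation `X <- X - t_o p_o'`); the single predictive
#' component is then computed on the deflated matrix. The class response is
#' coded as a centered +/- 1 dummy.
#'
#' @param X a `scaled_matrix` or an already centered/scaled samples x
#'   features matrix.
#' @param y two-level class labels (factor or character), >= 2 per class.
#' @param n_ortho number of orthogonal components (reduced with a warning if
#'   the matrix rank is exhausted).
#' @return list of class `oplsda`: predictive weight `w`, loading `p_p`,
#'   score `t_p`, y-loading `q`, orthogonal `W_o`, `P_o`, `T_o`, `n_ortho`,
#'   `r2y`, per-component explained y-variance `ssy`, class levels and
#'   response coding.
#' @export
fit_oplsda <- function(X, y, n_ortho = 0) {
  M <- as_model_matrix(X)
  y_num <- code_classes(y)
  stopifnot(length(y_num) == nrow(M))
  y_c <- y_num - mean(y_num)
  p_feat <- ncol(M)
  Xd <- M
  w <- drop(crossprod(Xd, y_c))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) stop("y is orthogonal to every column of X")
  w <- w / nw
  W_o <- P_o <- matrix(0, p_feat, 0)
  T_o <- matrix(0, nrow(M), 0)
  ssy_o <- numeric(0)
  k <- 0
  while (k < n_ortho) {
    t_pred <- drop(Xd %*% w)
    p_load <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
    w_o <- p_load - drop(crossprod(w, p_load)) * w
    nrm <- sqrt(sum(w_o^2))
    if (!is.finite(nrm) || nrm < 1e-10 * sqrt(sum(p_load^2)) || nrm < 1e-12) {
      warning(sprintf("rank exhausted: using %d orthogonal component(s) instead of %d",
                      k, n_ortho))
      break
    }
    w_o <- w_o / nrm
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    q_o <- sum(y_c * t_o) / sum(t_o^2)
    ssy_o <- c(ssy_o, q_o^2 * sum(t_o^2))
    k <- k + 1
  }
  t_p <- drop(Xd %*% w)
  p_p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  q <- sum(y_c * t_p) / sum(t_p^2)
  fitted <- t_p * q
  ss_tot <- sum(y_c^2)
  r2y <- 1 - sum((y_c - fitted)^2) / ss_tot
  structure(list(w = stats::setNames(w, colnames(M)), p_p = p_p, t_p = t_p,
                 q = q, W_o = W_o, P_o = P_o, T_o = T_o, n_ortho = k,
                 r2y = r2y, ssy = c(predictive = q^2 * sum(t_p^2),
                                    if (k > 0) stats::setNames(ssy_o, sprintf("ortho%d", seq_len(k)))),
                 levels = levels(as.factor(y)), y_center = mean(y_num),
                 features = colnames(M)),
            class = "oplsda")
}

#' Predict from an OPLS-DA model
#'
#' New samples are deflated by the orthogonal components and projected on
#' the predictive weight; predictions are on the +/- 1 coding scale.
#'
#' @param object fitted `oplsda`.
#' @param newdata matrix on the same (scaled) scale as the training matrix,
#'   with the model's feature columns.
#' @param ... unused.
#' @return list with `score` (predictive score), `y_hat` (numeric, +/- 1
#'   scale) and `class` (predicted label).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  M <- as.matrix(newdata)[, object$features, drop = FALSE]
  k <- object$n_ortho
  if (k > 0) {
    for (a in seq_len(k)) {
      t_o <- drop(M %*% object$W_o[, a])
      M <- M - tcrossprod(t_o, object$P_o[, a])
    }
  }
  score <- drop(M %*% object$w)
  y_hat <- score * object$q + object$y_center
  list(score = score, y_hat = y_hat,
       class = ifelse(y_hat > 0, object$levels[2], object$levels[1]))
}

make_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  smallest <- min(table(y))
  if (folds > smallest) {
    warning(sprintf("reducing folds from %d to %d so every training set keeps both classes",
                    folds, smallest))
    folds <- smallest
  }
  set.seed(seed)
  assign <- integer(length(y))
  # iterate classes in first-occurrence order so the assignment (and hence
  # Q2) is invariant to relabeling the two classes
  for (lv in unique(as.character(y))) {
    idx <- sample(which(y == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  structure(assign, folds = folds)
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Stratified, seeded k-fold cross-validation. Each training fold is
#' centered/scaled afresh and a sub-model fitted; `PRESS` accumulates the
#' squared out-of-fold prediction errors of the coded response and
#' `Q2 = 1 - PRESS / SS_tot`. Sub-models are retained for jack-knifing.
#'
#' @param X raw samples x features matrix (scaling happens within folds).
#' @param y two-level class labels.
#' @param n_ortho orthogonal components per sub-model.
#' @param folds number of folds (default 7, reduced with a warning if a
#'   class is smaller).
#' @param seed integer seed for the fold assignment.
#' @param scaling scaling mode, as in [scale_matrix()].
#' @return list of class `cv_q2`: `q2`, `press`, `ss_tot`, `fold`,
#'   `submodels` (per fold: model + scaling), `predictions`.
#' @export
cross_validated_q2 <- function(X, y, n_ortho = 0, folds = 7, seed = 1,
                               scaling = "uv") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y_num <- code_classes(y)
  fold <- make_folds(y, folds, seed)
  nfold <- attr(fold, "folds")
  preds <- numeric(length(y_num))
  submodels <- vector("list", nfold)
  for (g in seq_len(nfold)) {
    tr <- fold != g; te <- !tr
    sm <- scale_matrix(X[tr, , drop = FALSE], scaling)
    fit <- fit_oplsda(sm$X, factor(y, levels = levels(as.factor(y)))[tr],
                      n_ortho = n_ortho)
    Xte <- apply_scaling(sm, X[te, , drop = FALSE])
    preds[te] <- predict(fit, Xte)$y_hat
    submodels[[g]] <- list(model = fit, scaling = sm)
  }
  press <- sum((y_num - preds)^2)
  ss_tot <- sum((y_num - mean(y_num))^2)
  structure(list(q2 = 1 - press / ss_tot, press = press, ss_tot = ss_tot,
                 fold = as.integer(fold), submodels = submodels,
                 predictions = preds, n_ortho = n_ortho, seed = seed),
            class = "cv_q2")
}

#' Forward selection of the number of orthogonal components
#'
#' Tries 0 to `max_ortho` orthogonal components and returns the smallest
#' count whose cross-validated Q2 is within `1e-6` of the best.
#'
#' @inheritParams cross_validated_q2
#' @param max_ortho largest count tried.
#' @return integer, with attribute `q2_path` (Q2 per candidate).
#' @export
choose_n_ortho <- function(X, y, max_ortho = 3, folds = 7, seed = 1,
                           scaling = "uv") {
  q2s <- vapply(0:max_ortho, function(a)
    suppressWarnings(cross_validated_q2(X, y, a, folds, seed, scaling)$q2),
    numeric(1))
  best <- which(q2s >= max(q2s) - 1e-6)[1] - 1L
  structure(best, q2_path = stats::setNames(q2s, 0:max_ortho))
}

#' CV-ANOVA significance of cross-validated predictions
#'
#' F-test comparing the cross-validated predictive residuals (PRESS) with
#' the total response variation, after Eriksson, Trygg & Wold (2008),
#' "CV-ANOVA for significance testing of PLS and OPLS(R) models", J.
#' Chemometrics 22:594-600: `F = ((SS_tot - PRESS)/d1) / (PRESS/d2)` with
#' `d1` = number of model components (predictive + orthogonal) + 1 and
#' `d2 = N - d1 - 1`; the p-value is the upper tail of `F(d1, d2)`. A
#' model with no predictive ability (PRESS >= SS_tot) gives F = 0, p = 1.
#'
#' @param press cross-validated PRESS (from [cross_validated_q2()]).
#' @param ss_tot total sum of squares of the coded response.
#' @param n_samples number of samples N.
#' @param n_components model components (1 predictive + orthogonal count).
#' @return list: `f`, `d1`, `d2`, `p`.
#' @export
cv_anova <- function(press, ss_tot, n_samples, n_components) {
  d1 <- n_components + 1
  d2 <- n_samples - d1 - 1
  if (d2 <= 0) stop("too few samples for CV-ANOVA (d2 <= 0)")
  f <- max(0, ((ss_tot - press) / d1) / (press / d2))
  list(f = f, d1 = d1, d2 = d2,
       p = stats::pf(f, d1, d2, lower.tail = FALSE))
}

#' Permutation test of OPLS-DA diagnostics
#'
#' Permutes the class labels `n_iter` times, refits the model and its
#' cross-validated Q2, and compares the permuted R2Y / Q2 null samples with
#' the observed values; `p = (1 + #\{perm >= observed\}) / (1 + n_iter)`.
#'
#' @inheritParams cross_validated_q2
#' @param n_iter number of permutations (the published default is 1,000).
#' @return list: `n_iter`, `obs_r2`, `obs_q2`, `perm_r2`, `perm_q2`,
#'   `p_r2`, `p_q2`.
#' @export
permutation_test <- function(X, y, n_iter = 1000, seed = 1, n_ortho = 0,
                             folds = 7, scaling = "uv") {
  stopifnot(n_iter >= 1)
  X <- as.matrix(X)
  obs_r2 <- fit_oplsda(scale_matrix(X, scaling), y, n_ortho)$r2y
  obs_q2 <- suppressWarnings(
    cross_validated_q2(X, y, n_ortho, folds, seed, scaling))$q2
  perm_r2 <- perm_q2 <- numeric(n_iter)
  y <- as.factor(y)
  for (i in seq_len(n_iter)) {
    set.seed(seed + i)
    yp <- y[sample.int(length(y))]
    perm_r2[i] <- fit_oplsda(scale_matrix(X, scaling), yp, n_ortho)$r2y
    perm_q2[i] <- suppressWarnings(
      cross_validated_q2(X, yp, n_ortho, folds, seed + i, scaling))$q2
  }
  list(n_iter = n_iter, obs_r2 = obs_r2, obs_q2 = obs_q2,
       perm_r2 = perm_r2, perm_q2 = perm_q2,
       p_r2 = (1 + sum(perm_r2 >= obs_r2)) / (1 + n_iter),
       p_q2 = (1 + sum(perm_q2 >= obs_q2)) / (1 + n_iter))
}
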