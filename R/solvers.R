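#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the elementary update of coordinate
#' descent for L1-penalized least squares.
#'
#' @param z Numeric vector.
#' @param t Non-negative threshold.
#' @return Numeric vector.
#' @export
#' @examples
#' soft_threshold(3, 1)    # 2
#' soft_threshold(-2.5, 1.5)  # -1
soft_threshold <- function(z, t) {
  stopifnot(all(t >= 0))
  sign(z) * pmax(abs(z) - t, 0)
}

#' Penalty specification for the elastic-net family
#'
#' `alpha` follows the mixing convention `alpha = lambda2 / (lambda1 +
#' lambda2)`: **`alpha` is the ridge share**, so `alpha = 1` is pure
#' ridge and `alpha = 0` is pure lasso.  This is the REVERSE of glmnet's
#' `alpha` (its lasso share); use [to_glmnet_penalty()] when comparing.
#' The internal objective is
#' `F(beta) = (1/2n)||y - X beta||^2 + lambda (1-alpha) sum w_j |beta_j|
#'  + lambda alpha sum beta_j^2`,
#' which maps to raw penalties `lambda1 = 2 n lambda (1-alpha)` (L1) and
#' `lambda2 = 2 n lambda alpha` (L2) on the unscaled residual sum of
#' squares.
#'
#' @param lambda Overall penalty strength (>= 0).
#' @param alpha Ridge share in `[0, 1]`.
#' @param gamma Adaptive-weight exponent (> 0), NA when not adaptive.
#' @param weights Per-coefficient adaptive weights in `(0, Inf]`;
#'   default all 1.  `Inf` pins a coefficient at zero.
#' @param n Optional sample size, used to record `lambda1`/`lambda2`.
#' @return List of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda, alpha = 0, gamma = NA_real_,
                         weights = NULL, n = NULL) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  if (!is.null(weights) && any(weights <= 0))
    stop("adaptive weights must be positive (Inf allowed)")
  out <- list(lambda = lambda, alpha = alpha, gamma = gamma,
              weights = weights)
  if (!is.null(n)) {
    out$lambda1 <- 2 * n * lambda * (1 - alpha)
    out$lambda2 <- 2 * n * lambda * alpha
  }
  structure(out, class = "penalty_spec")
}

#' Convert a (lambda, alpha) pair to glmnet's convention
#'
#' glmnet minimizes `(1/2n)||y - X b||^2 + lg * ((1-ag)/2 ||b||_2^2 +
#' ag ||b||_1)` where `ag` is the LASSO share.  Our `(lambda, alpha)`
#' with `alpha` the RIDGE share maps to `lg = lambda (1 + alpha)`,
#' `ag = (1 - alpha) / (1 + alpha)`.
#'
#' @param lambda,alpha Penalty in this package's convention.
#' @return List with `lambda` and `alpha` in glmnet's convention.
#' @export
to_glmnet_penalty <- function(lambda, alpha) {
  list(lambda = lambda * (1 + alpha), alpha = (1 - alpha) / (1 + alpha))
}

#' Pathwise lambda grid
#'
#' Log-spaced decreasing grid from `lambda_max` down to
#' `lambda_max * min_ratio`.  `lambda_max` is the smallest penalty at
#' which the solution is entirely zero for a pure-L1 fit:
#' `max_j |x_j' y| / (n * max(1 - alpha, 0.001) * w_j)` (the `0.001`
#' floor keeps the grid finite as `alpha -> 1`, where no finite penalty
#' zeroes a ridge fit).
#'
#' @param Xc Column-centered marker matrix.
#' @param yc Mean-centered phenotype vector.
#' @param n_lambda Grid length (default 100).
#' @param min_ratio Ratio of smallest to largest lambda (default 1e-4).
#' @param alpha Ridge share.
#' @param weights Optional adaptive weights (Inf entries are excluded).
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(Xc, yc, n_lambda = 100L, min_ratio = 1e-4,
                        alpha = 0, weights = NULL) {
  stopifnot(min_ratio > 0, min_ratio < 1, n_lambda >= 1)
  if (all(yc == 0)) stop("phenotype vector is identically zero")
  n <- nrow(Xc)
  score <- abs(drop(crossprod(Xc, yc))) / n
  if (!is.null(weights)) {
    score <- score / weights
    score[!is.finite(weights)] <- 0
  }
  lmax <- max(score) / max(1 - alpha, 0.001)
  if (lmax <= 0) stop("all marker scores are zero")
  if (n_lambda == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit the weighted elastic net by cyclical coordinate descent
#'
#' Minimizes `F(beta) = (1/2n)||yc - Xc beta||^2 +
#' lambda (1-alpha) sum_j w_j |beta_j| + lambda alpha sum_j beta_j^2`
#' by cyclical coordinate descent: `beta_j <- S((1/n) x_j' r +
#' (x_j'x_j/n) beta_j, lambda (1-alpha) w_j) / (x_j'x_j/n + 2 lambda
#' alpha)`, sweeping until the largest coordinate change falls below
#' `tol`.  `alpha = 1` is ridge, `alpha = 0` the (weighted) lasso.
#' With `rescale = TRUE` the reported coefficients are the naive
#' solution multiplied by `1 + lambda2/n = 1 + 2 lambda alpha`, the
#' elastic-net de-biasing factor (used when reporting ENET/ADAENET
#' estimates); the naive coefficients are always retained.
#'
#' @param Xc Column-centered matrix (n x p).
#' @param yc Mean-centered response.
#' @param lambda,alpha Penalty (this package's convention; see
#'   [penalty_spec()]).
#' @param weights Adaptive weights, default all 1; `Inf` pins a
#'   coordinate at zero.
#' @param beta_init Warm start (default zero).
#' @param tol Convergence tolerance on the max absolute coordinate
#'   change (default 1e-7).
#' @param max_iter Maximum number of full sweeps (default 1e5).
#' @param rescale Apply the `1 + 2 lambda alpha` elastic-net rescale to
#'   the reported coefficients.
#' @param model_tag Label stored on the fit.
#' @return Object of class `gs_fit`: `beta` (reported), `beta_naive`,
#'   `mu` (0 here; set by [fit_model()]), `penalty`, convergence
#'   diagnostics, `nonzero_count`.
#' @export
fit_enet_cd <- function(Xc, yc, lambda, alpha = 0, weights = NULL,
                        beta_init = NULL, tol = 1e-7, max_iter = 100000L,
                        rescale = FALSE, model_tag = "enet_cd") {
  Xc <- as.matrix(Xc)
  p <- ncol(Xc)
  if (is.null(weights)) weights <- rep(1, p)
  if (is.null(beta_init)) beta_init <- rep(0, p)
  if (any(!is.finite(Xc)) || any(!is.finite(yc)))
    stop("non-finite values in Xc or yc")
  if (any(weights <= 0)) stop("weights must be positive (Inf allowed)")
  res <- cd_enet(Xc, yc, lambda, alpha, as.numeric(weights),
                 as.numeric(beta_init), tol, as.integer(max_iter))
  beta <- res$beta
  names(beta) <- colnames(Xc)
  reported <- if (rescale) beta * (1 + 2 * lambda * alpha) else beta
  structure(list(
    beta = reported, beta_naive = beta, mu = 0,
    column_means = rep(0, p), y_mean = 0,
    penalty = penalty_spec(lambda, alpha, weights = weights,
                           n = nrow(Xc)),
    model_tag = model_tag, n_iter = res$n_iter,
    max_coord_change = res$max_coord_change,
    converged = res$converged, nonzero_count = res$nonzero_count,
    rescaled = rescale
  ), class = "gs_fit")
}

#' Elastic-net objective value (internal scaling)
#'
#' The function minimized by [fit_enet_cd()]; exported for diagnostics
#' and oracle tests.
#'
#' @inheritParams fit_enet_cd
#' @param beta Coefficient vector (naive scale).
#' @return Scalar objective value.
#' @export
enet_objective <- function(beta, Xc, yc, lambda, alpha = 0, weights = NULL) {
  n <- nrow(Xc)
  if (is.null(weights)) weights <- rep(1, length(beta))
  w <- ifelse(beta == 0 & !is.finite(weights), 0, weights * abs(beta))
  r <- yc - drop(Xc %*% beta)
  sum(r^2) / (2 * n) + lambda * (1 - alpha) * sum(w) +
    lambda * alpha * sum(beta^2)
}

#' Karush-Kuhn-Tucker residual of a fit
#'
#' For the objective of [fit_enet_cd()] the stationarity conditions are
#' `(1/n) x_j' r - 2 lambda alpha beta_j = lambda (1-alpha) w_j
#' sign(beta_j)` for active coordinates and `|(1/n) x_j' r| <=
#' lambda (1-alpha) w_j` for zero ones.  Returns the largest violation;
#' a correct solution has violation ~ solver tolerance.
#'
#' @param fit A `gs_fit` (naive coefficients are checked).
#' @param Xc,yc The centered data the fit was computed on.
#' @return Maximum KKT violation (scalar).
#' @export
kkt_violation <- function(fit, Xc, yc) {
  beta <- fit$beta_naive
  lam <- fit$penalty$lambda
  alpha <- fit$penalty$alpha
  w <- fit$penalty$weights
  if (is.null(w)) w <- rep(1, length(beta))
  n <- nrow(Xc)
  r <- yc - drop(Xc %*% beta)
  g <- drop(crossprod(Xc, r)) / n - 2 * lam * alpha * beta
  t <- lam * (1 - alpha) * w
  zero <- beta == 0
  v_zero <- if (any(zero)) {
    tz <- t[zero]
    viol <- pmax(abs(g[zero]) - tz, 0)
    viol[!is.finite(tz)] <- 0   # pinned coordinates are always feasible
    max(viol)
  } else 0
  v_act <- if (any(!zero)) max(abs(g[!zero] - t[!zero] * sign(beta[!zero])))
           else 0
  max(v_zero, v_act)
}

#' Fit a whole regularization path with warm starts
#'
#' Solutions are computed largest-lambda first, each warm-started from
#' the previous one.
#'
#' @inheritParams fit_enet_cd
#' @param grid Strictly decreasing lambda grid (see [lambda_grid()]).
#' @return Object of class `lambda_path`: `lambdas`, `beta` (grid x p
#'   matrix of naive coefficients), `n_iter`, `nonzero_count`.
#' @export
fit_path <- function(Xc, yc, grid, alpha = 0, weights = NULL,
                     tol = 1e-7, max_iter = 100000L) {
  if (length(grid) > 1L && any(diff(grid) >= 0))
    stop("lambda grid must be strictly decreasing")
  p <- ncol(Xc)
  B <- matrix(0, length(grid), p)
  iters <- integer(length(grid))
  nz <- integer(length(grid))
  b <- rep(0, p)
  for (k in seq_along(grid)) {
    fit <- tryCatch(
      fit_enet_cd(Xc, yc, grid[k], alpha, weights, beta_init = b,
                  tol = tol, max_iter = max_iter),
      error = function(e) stop("path failed at lambda = ", grid[k], ": ",
                               conditionMessage(e)))
    b <- fit$beta_naive
    B[k, ] <- b
    iters[k] <- fit$n_iter
    nz[k] <- fit$nonzero_count
  }
  colnames(B) <- colnames(Xc)
  structure(list(lambdas = grid, beta = B, n_iter = iters,
                 nonzero_count = nz, alpha = alpha, weights = weights),
            class = "lambda_path")
}

# Exact ridge solutions for a whole lambda grid via the n x n dual form:
# beta(lambda) = X'(XX' + 2 n lambda I)^{-1} y, computed from one
# eigendecomposition of XX'.  Used as a fast exact route for pure-ridge
# (alpha = 1) path evaluations in cross-validation; identical (to
# numerical precision) to the coordinate-descent solution of the same
# objective.
ridge_path_dual <- function(Xc, yc, grid) {
  n <- nrow(Xc)
  ed <- eigen(tcrossprod(Xc), symmetric = TRUE)
  d <- pmax(ed$values, 0)
  Uy <- drop(crossprod(ed$vectors, yc))
  B <- matrix(0, length(grid), ncol(Xc))
  for (k in seq_along(grid)) {
    a <- ed$vectors %*% (Uy / (d + 2 * n * grid[k]))
    B[k, ] <- drop(crossprod(Xc, a))
  }
  colnames(B) <- colnames(Xc)
  B
}

#' Adaptive weights from an initial estimator
#'
#' `w_j = |beta_ini_j|^(-gamma)`; an exactly-zero initial coefficient
#' yields `w_j = Inf`, which downstream solvers treat as "pinned at
#' zero".
#'
#' @param beta_ini Initial coefficient vector (e.g. a CV-tuned ridge or
#'   elastic-net fit).
#' @param gamma Positive exponent.
#' @return Weight vector in `(0, Inf]`.
#' @export
adaptive_weights <- function(beta_ini, gamma) {
  stopifnot(gamma > 0)
  w <- abs(beta_ini)^(-gamma)
  w[beta_ini == 0] <- Inf
  w
}

#' Adaptive lasso at fixed penalty
#'
#' The weighted-L1 fit with weights `|beta_ini|^(-gamma)` from an
#' initial consistent estimator (a CV-tuned ridge fit by default
#' upstream, since p >> n rules out least squares).  Two equivalent
#' implementations are provided: `"weighted"` solves the weighted
#' soft-threshold updates directly; `"rescale"` divides each column by
#' its weight, solves a plain lasso, and scales the coefficients back.
#'
#' @inheritParams fit_enet_cd
#' @param gamma Positive adaptive exponent.
#' @param initial A `gs_fit` (or numeric vector) providing the initial
#'   coefficients.
#' @param method `"weighted"` (default) or `"rescale"`.
#' @return A `gs_fit` with `model_tag = "alasso"`.
#' @export
fit_adaptive_lasso <- function(Xc, yc, lambda, gamma, initial,
                               method = c("weighted", "rescale"),
                               tol = 1e-7, max_iter = 100000L) {
  method <- match.arg(method)
  b0 <- if (inherits(initial, "gs_fit")) initial$beta else initial
  if (all(b0 == 0))
    stop("initial estimator is identically zero; no finite adaptive weights")
  w <- adaptive_weights(b0, gamma)
  if (method == "weighted") {
    fit <- fit_enet_cd(Xc, yc, lambda, alpha = 0, weights = w,
                       tol = tol, max_iter = max_iter, model_tag = "alasso")
  } else {
    act <- is.finite(w)
    Xs <- sweep(Xc[, act, drop = FALSE], 2, w[act], "/")
    f0 <- fit_enet_cd(Xs, yc, lambda, alpha = 0, tol = tol,
                      max_iter = max_iter, model_tag = "alasso")
    beta <- numeric(ncol(Xc))
    beta[act] <- f0$beta_naive / w[act]
    names(beta) <- colnames(Xc)
    fit <- f0
    fit$beta <- fit$beta_naive <- beta
    fit$column_means <- rep(0, ncol(Xc))
    fit$nonzero_count <- sum(beta != 0)
    fit$penalty <- penalty_spec(lambda, 0, gamma, w, n = nrow(Xc))
  }
  fit$penalty$gamma <- gamma
  fit
}

#' Adaptive elastic net at fixed penalties
#'
#' Two-stage estimator: (1) an elastic-net fit supplies initial
#' coefficients; (2) adaptive weights `|beta_enet_j|^(-gamma)` reweight
#' the L1 part of a second elastic-net solve at `(lambda, alpha)`;
#' (3) the reported coefficients carry the `1 + 2 lambda alpha` rescale.
#' Zero-variance columns should be filtered upstream
#' ([filter_zero_variance()]).
#'
#' @inheritParams fit_enet_cd
#' @param gamma Positive adaptive exponent.
#' @param stage1 A `gs_fit` from the stage-1 elastic net (or a numeric
#'   coefficient vector).
#' @return A `gs_fit` with `model_tag = "adaenet"`.
#' @export
fit_adaptive_enet <- function(Xc, yc, lambda, alpha, gamma, stage1,
                              tol = 1e-7, max_iter = 100000L) {
  b0 <- if (inherits(stage1, "gs_fit")) stage1$beta else stage1
  if (all(b0 == 0))
    stop("stage-1 elastic net is identically zero; no finite adaptive weights")
  w <- adaptive_weights(b0, gamma)
  fit <- fit_enet_cd(Xc, yc, lambda, alpha, weights = w, tol = tol,
                     max_iter = max_iter, rescale = TRUE,
                     model_tag = "adaenet")
  fit$penalty$gamma <- gamma
  fit
}

#' Predict GEBVs from a fitted model
#'
#' For centered fits: `GEBV_i = y_mean + sum_j (x_ij - column_mean_j)
#' beta_j`.  RR-BLUP fits (uncentered) use the explicit intercept on the
#' raw coding.
#'
#' @param object A `gs_fit`.
#' @param newdata Genotype matrix with the training marker columns.
#' @param ... Unused.
#' @return Named numeric vector of GEBVs.
#' @export
predict.gs_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$beta))
    stop("marker mismatch: fit has ", length(object$beta),
         " markers, newdata has ", ncol(X))
  if (!is.null(colnames(X)) && !is.null(names(object$beta)) &&
      !identical(colnames(X), names(object$beta)))
    stop("marker ids of newdata do not match the training markers")
  cm <- object$column_means
  if (is.null(cm)) cm <- rep(0, ncol(X))
  out <- object$y_mean + object$mu +
    drop(sweep(X, 2, cm) %*% object$beta)
  names(out) <- rownames(X)
  out
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("<gs_fit> model:", x$model_tag,
      " lambda:", signif(x$penalty$lambda, 4),
      " alpha:", x$penalty$alpha,
      if (!is.na(x$penalty$gamma)) paste(" gamma:", x$penalty$gamma) else "",
      "\n  nonzero:", x$nonzero_count, "/", length(x$beta),
      " sweeps:", x$n_iter, "\n")
  invisible(x)
}
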