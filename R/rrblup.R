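#' Ridge regression BLUP: REML estimation of the ridge penalty
#'
#' Fits the mixed model `y = 1 mu + X beta + e` with random marker
#' effects `beta ~ N(0, I sigma_beta^2)` and residuals
#' `e ~ N(0, I sigma_e^2)`; the ridge penalty is the variance ratio
#' `lambda = sigma_e^2 / sigma_beta^2` estimated by REML.  Markers are
#' NOT mean-centered for this model.
#'
#' The restricted likelihood is profiled to a one-dimensional function
#' of the ratio through the eigendecomposition of the intercept-projected
#' `X X'` (n x n dual form, chosen because p >> n): with
#' `Q` an orthonormal basis of the complement of the intercept,
#' `Q' X X' Q = U diag(theta) U'` and `eta = U' Q' y`, the profiled
#' restricted log-likelihood at ratio `lambda` is
#' `-0.5 * (sum log(theta_i + lambda) + (n-1) log(sum eta_i^2 /
#' (theta_i + lambda)))` up to a constant.  The ratio is found by a
#' bounded derivative-free search on `log(lambda) in [-10, 10]` to
#' tolerance 1e-8; hitting a bound sets `boundary = TRUE`.  Effects are
#' recovered in dual form, `beta = X'(X X' + lambda I)^{-1}(y - 1 mu)`,
#' with `mu` the generalized-least-squares intercept.
#'
#' @param X Genotype matrix on the raw {-1,0,1} coding (uncentered).
#' @param y Phenotype vector.
#' @param log_ratio_bounds Search interval for `log(lambda)` (default
#'   `c(-10, 10)`).
#' @param tol Search tolerance (default 1e-8).
#' @return List with `varcomp` (class `variance_components`:
#'   `sigma_beta2`, `sigma_e2`, `lambda_ratio`, `boundary`) and `fit`
#'   (a `gs_fit` with `model_tag = "rrblup"`, explicit intercept `mu`).
#' @export
reml_fit <- function(X, y, log_ratio_bounds = c(-10, 10), tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need n >= 3 for REML")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L)))
    stop("X is all-constant")

  K <- tcrossprod(X)                       # n x n
  Q <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1L, drop = FALSE]
  Kt <- crossprod(Q, K %*% Q)
  ed <- eigen(Kt, symmetric = TRUE)
  theta <- pmax(ed$values, 1e-10)          # eigenvalue floor
  eta <- drop(crossprod(ed$vectors, crossprod(Q, y)))
  m <- n - 1L

  negll <- function(loglam) {
    lam <- exp(loglam)
    dl <- theta + lam
    0.5 * (sum(log(dl)) + m * log(sum(eta^2 / dl)))
  }
  opt <- optimize(negll, log_ratio_bounds, tol = tol)
  loglam <- opt$minimum
  boundary <- min(abs(loglam - log_ratio_bounds)) < 1e-3
  if (boundary)
    warning("REML ratio search converged at a bound (log-ratio = ",
            signif(loglam, 4), ")")
  lam <- exp(loglam)
  sigma_beta2 <- sum(eta^2 / (theta + lam)) / m
  sigma_e2 <- lam * sigma_beta2

  C <- K + diag(lam, n)
  Ci1 <- solve(C, rep(1, n))
  Ciy <- solve(C, y)
  mu <- sum(Ciy) / sum(Ci1)
  beta <- drop(crossprod(X, solve(C, y - mu)))
  names(beta) <- colnames(X)

  varcomp <- structure(list(sigma_beta2 = sigma_beta2, sigma_e2 = sigma_e2,
                            lambda_ratio = lam, boundary = boundary,
                            log_ratio = loglam),
                       class = "variance_components")
  fit <- structure(list(
    beta = beta, beta_naive = beta, mu = mu,
    column_means = rep(0, ncol(X)), y_mean = 0,
    penalty = penalty_spec(lam, alpha = 1),
    model_tag = "rrblup", n_iter = NA_integer_,
    max_coord_change = NA_real_, converged = !boundary,
    nonzero_count = sum(beta != 0), rescaled = FALSE,
    varcomp = varcomp
  ), class = "gs_fit")
  list(varcomp = varcomp, fit = fit)
}

#' Predict GEBVs from an RR-BLUP fit
#'
#' `GEBV = mu + X_new beta` on the raw {-1,0,1} coding.
#'
#' @param fit A `gs_fit` from [reml_fit()] (or the list it returns).
#' @param X_new Genotype matrix with the training marker columns.
#' @return Named numeric vector of GEBVs.
#' @export
predict_rrblup <- function(fit, X_new) {
  if (!inherits(fit, "gs_fit") && !is.null(fit$fit)) fit <- fit$fit
  predict(fit, X_new)
}
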