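#' Family-stratified k-fold cross-validation scheme
#'
#' Within each full-sib family the phenotyped members are randomly
#' permuted and dealt round-robin into `k` folds (the fold receiving the
#' remainder is itself randomized), so per-family fold loads differ by
#' at most one.  With 200 families of 10 phenotyped members and `k = 5`
#' every fold holds exactly 400 individuals, two per family.
#'
#' @param pedigree Pedigree data.frame with columns `id`, `family_id`,
#'   `phenotyped` (as in a `population`).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the deals.
#' @return Object of class `cv_scheme`: `fold` (named integer vector,
#'   ids -> fold), `k`, `seed`.
#' @export
make_family_folds <- function(pedigree, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  ped <- pedigree[pedigree$phenotyped, , drop = FALSE]
  if (nrow(ped) == 0) stop("no phenotyped individuals in pedigree")
  set.seed(seed)
  fold <- integer(nrow(ped))
  names(fold) <- ped$id
  for (fam in split(seq_len(nrow(ped)), ped$family_id)) {
    m <- length(fam)
    deal <- rep(sample.int(k), length.out = m)
    fold[fam[sample.int(m)]] <- deal
  }
  structure(list(fold = fold, k = as.integer(k), seed = seed),
            class = "cv_scheme")
}

#' Cross-validated error of a fitter at fixed hyperparameters
#'
#' For each fold the model is refit on the remaining folds (the fitter
#' re-centers within its own training split), the held-out fold is
#' predicted, and validation MSE and Pearson r against the held-out
#' phenotypes are recorded.  Constant predictions make r undefined; such
#' folds report r = 0 and are flagged.
#'
#' @param X Genotype matrix with row ids covering the scheme's ids.
#' @param y Named phenotype vector covering the scheme's ids.
#' @param scheme A `cv_scheme`.
#' @param fitter Function `(X_train, y_train) -> gs_fit`.
#' @return List: `mean_mse`, `fold_mse`, `fold_r`, `fold_n`,
#'   `r_undefined` (logical per fold).
#' @export
cv_error <- function(X, y, scheme, fitter) {
  ids <- names(scheme$fold)
  stopifnot(all(ids %in% rownames(X)), all(ids %in% names(y)))
  k <- scheme$k
  fold_mse <- fold_r <- numeric(k)
  fold_n <- integer(k)
  undef <- logical(k)
  for (f in seq_len(k)) {
    val_ids <- ids[scheme$fold == f]
    tr_ids <- ids[scheme$fold != f]
    fit <- tryCatch(fitter(X[tr_ids, , drop = FALSE], y[tr_ids]),
                    error = function(e) stop("fold ", f, ": ",
                                             conditionMessage(e)))
    pred <- predict(fit, X[val_ids, , drop = FALSE])
    obs <- y[val_ids]
    fold_mse[f] <- mean((pred - obs)^2)
    if (length(pred) < 2 || sd(pred) == 0 || sd(obs) == 0) {
      fold_r[f] <- 0
      undef[f] <- TRUE
    } else {
      fold_r[f] <- stats::cor(pred, obs)
    }
    fold_n[f] <- length(val_ids)
  }
  list(mean_mse = mean(fold_mse), fold_mse = fold_mse, fold_r = fold_r,
       fold_n = fold_n, r_undefined = undef)
}

#' Select lambda by cross-validation along a warm-started path
#'
#' For each fold the whole path is fit on the training split (re-centered
#' within the split) and the held-out fold is predicted at every grid
#' point; the lambda minimizing the mean validation MSE is returned,
#' ties breaking toward the larger lambda (more shrinkage).
#'
#' @inheritParams cv_error
#' @param alpha Ridge share of the penalty.
#' @param weights Optional adaptive weights (used for the grid and, when
#'   `fold_weights` is NULL, for every fold).
#' @param fold_weights Optional list of k weight vectors, one per fold,
#'   each computed from that fold's own training data (leakage-free
#'   adaptive tuning; see [select_gamma()]).
#' @param grid Optional decreasing lambda grid; default from
#'   [lambda_grid()] on the full centered data.
#' @param n_lambda,min_ratio Grid controls when `grid` is NULL.
#' @param tol,max_iter Solver controls.
#' @return List: `lambda`, `cv_mse` (per grid point), `grid`,
#'   `fold_mse` (k x grid matrix).
#' @export
select_lambda <- function(X, y, scheme, alpha = 0, weights = NULL,
                          fold_weights = NULL,
                          grid = NULL, n_lambda = 100L, min_ratio = 1e-4,
                          tol = 1e-7, max_iter = 100000L) {
  ids <- names(scheme$fold)
  X <- X[ids, , drop = FALSE]
  y <- y[ids]
  if (is.null(grid)) {
    cx <- center_columns(X)
    cy <- center_phenotype(y)
    grid <- lambda_grid(cx$values, cy$values, n_lambda, min_ratio,
                        alpha, weights)
  }
  if (length(grid) == 0) stop("empty lambda grid")
  k <- scheme$k
  if (!is.null(fold_weights)) stopifnot(length(fold_weights) == k)
  M <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- scheme$fold != f
    cx <- center_columns(X[tr, , drop = FALSE])
    cy <- center_phenotype(y[tr])
    wf <- if (is.null(fold_weights)) weights else fold_weights[[f]]
    B <- if (alpha == 1 && is.null(wf)) {
      ridge_path_dual(cx$values, cy$values, grid)  # exact, O(n^3) once
    } else {
      fit_path(cx$values, cy$values, grid, alpha, wf,
               tol = tol, max_iter = max_iter)$beta
    }
    Xv <- sweep(X[!tr, , drop = FALSE], 2, cx$column_means)
    pred <- cy$mean + Xv %*% t(B)   # n_val x grid
    M[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cv_mse <- colMeans(M)
  best <- which.min(cv_mse)  # first index = largest lambda on ties
  list(lambda = grid[best], cv_mse = cv_mse, grid = grid, fold_mse = M,
       index = best)
}

#' Select the elastic-net mixing parameter by nested cross-validation
#'
#' For each candidate `alpha`, `lambda` is first resolved by an inner
#' family-stratified CV ([select_lambda()]); the `(alpha,
#' lambda(alpha))` pair is then scored by an outer family-stratified CV,
#' and the `alpha` minimizing the outer mean MSE wins, ties breaking
#' toward the larger (more ridge-like) `alpha`.
#'
#' @inheritParams cv_error
#' @param pedigree Pedigree used to build the inner fold scheme.
#' @param alpha_grid Candidate ridge shares in `[0, 1]`; default
#'   `seq(0, 1, 0.1)`.
#' @param scheme Outer `cv_scheme`.
#' @param seed Seed for the inner fold deals.
#' @param n_lambda,min_ratio,tol,max_iter Passed to [select_lambda()].
#' @return List: `alpha`, `lambda`, `table` (per-alpha outer MSE and
#'   chosen lambda), `inner_scheme`.
#' @export
select_alpha <- function(X, y, pedigree, scheme,
                         alpha_grid = seq(0, 1, 0.1), seed = 1L,
                         n_lambda = 100L, min_ratio = 1e-4,
                         tol = 1e-7, max_iter = 100000L) {
  if (length(alpha_grid) == 0) stop("empty alpha grid")
  stopifnot(all(alpha_grid >= 0), all(alpha_grid <= 1))
  inner <- make_family_folds(pedigree, scheme$k, child_seed(seed, "inner"))
  ids <- names(scheme$fold)
  Xs <- X[ids, , drop = FALSE]
  ys <- y[ids]
  lam <- mse <- numeric(length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    a <- alpha_grid[i]
    sl <- select_lambda(X, y, inner, alpha = a, n_lambda = n_lambda,
                        min_ratio = min_ratio, tol = tol,
                        max_iter = max_iter)
    lam[i] <- sl$lambda
    # outer CV at (a, lambda(a)); the path down to lambda(a) is refit on
    # each outer training split with warm starts (equivalent to, and much
    # cheaper than, a cold fit at lambda(a) alone)
    g2 <- sl$grid[seq_len(sl$index)]
    fm <- numeric(scheme$k)
    for (f in seq_len(scheme$k)) {
      tr <- scheme$fold != f
      cx <- center_columns(Xs[tr, , drop = FALSE])
      cy <- center_phenotype(ys[tr])
      b <- if (a == 1) {
        drop(ridge_path_dual(cx$values, cy$values, sl$lambda))
      } else {
        p2 <- fit_path(cx$values, cy$values, g2, alpha = a,
                       tol = tol, max_iter = max_iter)
        p2$beta[length(g2), ]
      }
      b <- b * (1 + 2 * sl$lambda * a)   # elastic-net rescale
      pred <- cy$mean +
        drop(sweep(Xs[!tr, , drop = FALSE], 2, cx$column_means) %*% b)
      fm[f] <- mean((pred - ys[!tr])^2)
    }
    mse[i] <- mean(fm)
  }
  # ties break toward larger alpha
  best <- order(mse, -alpha_grid)[1L]
  list(alpha = alpha_grid[best], lambda = lam[best],
       table = data.frame(alpha = alpha_grid, lambda = lam,
                          outer_mse = mse),
       inner_scheme = inner)
}

#' Select the adaptive exponent gamma (and its partner lambda)
#'
#' Two-dimensional grid search for the adaptive lasso / adaptive elastic
#' net: for each `gamma` in the grid (default `{0.5, 1, 2}`), adaptive
#' weights are built from the initial estimator and `lambda` is resolved
#' by family-stratified CV with those weights; the pair with the
#' smallest CV MSE wins, ties breaking toward the smaller `gamma`.
#'
#' When `initial_fn` is supplied, the initial estimator is refit on each
#' tuning fold's own training split and that fold's weights are derived
#' from it, so the lambda search never sees weights informed by its
#' validation data.  (Weights built once from a full-data initial fit
#' leak the validation individuals' noise into the penalty and
#' systematically over-select.)  The per-fold initial coefficients are
#' computed once and shared across the gamma grid.
#'
#' @inheritParams cv_error
#' @param gamma_grid Candidate exponents, default `c(0.5, 1, 2)`.
#' @param initial A `gs_fit` (or coefficient vector) supplying the
#'   full-data initial coefficients (CV-tuned ridge for the adaptive
#'   lasso; stage-1 elastic net for the adaptive elastic net), used for
#'   the lambda grid and as the fallback fold weights.
#' @param alpha Ridge share of the weighted solve: 0 for the adaptive
#'   lasso; the stage-1 alpha for the adaptive elastic net.
#' @param initial_fn Optional function `(Xc_train, yc_train) ->
#'   coefficient vector` refitting the initial estimator on centered
#'   fold-training data.
#' @param n_lambda,min_ratio,tol,max_iter Passed to [select_lambda()].
#' @return List: `gamma`, `lambda`, `table` (per-gamma CV MSE and
#'   lambda).
#' @export
select_gamma <- function(X, y, scheme, initial,
                         gamma_grid = c(0.5, 1, 2), alpha = 0,
                         initial_fn = NULL,
                         n_lambda = 100L, min_ratio = 1e-4,
                         tol = 1e-7, max_iter = 100000L) {
  if (length(gamma_grid) == 0) stop("empty gamma grid")
  b0 <- if (inherits(initial, "gs_fit")) initial$beta else initial
  if (all(b0 == 0)) stop("initial estimator is identically zero")
  fold_betas <- NULL
  if (!is.null(initial_fn)) {
    ids <- names(scheme$fold)
    fold_betas <- lapply(seq_len(scheme$k), function(f) {
      tr <- ids[scheme$fold != f]
      cx <- center_columns(X[tr, , drop = FALSE])
      cy <- center_phenotype(y[tr])
      initial_fn(cx$values, cy$values)
    })
  }
  lam <- mse <- numeric(length(gamma_grid))
  for (i in seq_along(gamma_grid)) {
    w <- adaptive_weights(b0, gamma_grid[i])
    fw <- if (is.null(fold_betas)) NULL else
      lapply(fold_betas, adaptive_weights, gamma = gamma_grid[i])
    sl <- select_lambda(X, y, scheme, alpha = alpha, weights = w,
                        fold_weights = fw,
                        n_lambda = n_lambda, min_ratio = min_ratio,
                        tol = tol, max_iter = max_iter)
    lam[i] <- sl$lambda
    mse[i] <- min(sl$cv_mse)
  }
  best <- order(mse, gamma_grid)[1L]  # ties -> smaller gamma
  list(gamma = gamma_grid[best], lambda = lam[best],
       table = data.frame(gamma = gamma_grid, lambda = lam, cv_mse = mse))
}
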