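test_that("soft threshold matches its closed form", {
  expect_equal(soft_threshold(0.5, 1.0), 0)
  expect_equal(soft_threshold(3.0, 1.0), 2.0)
  expect_equal(soft_threshold(-2.5, 1.5), -1.0)
  expect_equal(soft_threshold(c(-3, 0, 3), 1), c(-2, 0, 2))
})

test_that("lambda grid is log-spaced and lambda_max zeroes the lasso", {
  fx <- make_regression(40, 10, 3, seed = 2)
  g <- lambda_grid(fx$Xc, fx$yc, n_lambda = 20, min_ratio = 1e-3, alpha = 0)
  expect_length(g, 20)
  expect_true(all(diff(g) < 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 19))
  # KKT at zero: the fit at lambda_max is the zero vector
  f <- fit_enet_cd(fx$Xc, fx$yc, g[1], alpha = 0)
  expect_equal(unname(f$beta), rep(0, 10))
  expect_equal(lambda_grid(fx$Xc, fx$yc, n_lambda = 1, alpha = 0), g[1])
  expect_error(lambda_grid(fx$Xc, rep(0, 40)), "zero")
})

test_that("coordinate descent at alpha = 1 matches the dense ridge solve", {
  fx <- make_regression(50, 20, 4, seed = 3)
  for (lam in c(0.01, 0.3, 5)) {
    f <- fit_enet_cd(fx$Xc, fx$yc, lam, alpha = 1, tol = 1e-10)
    bref <- ridge_closed_form(fx$Xc, fx$yc, lam)
    expect_lt(max(abs(f$beta - bref)), 1e-8)
  }
})

test_that("coordinate descent matches the sign-enumeration oracle at p = 3", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3); X <- scale(X, scale = FALSE)
  y <- drop(X %*% c(1.5, -0.8, 0)) + rnorm(20, 0, 0.5); y <- y - mean(y)
  cases <- list(
    list(lambda = 0.1, alpha = 0, w = NULL),
    list(lambda = 0.05, alpha = 0.4, w = NULL),
    list(lambda = 0.08, alpha = 0, w = c(0.5, 2, 1)),
    list(lambda = 0.05, alpha = 0.3, w = c(1, 4, Inf))
  )
  for (cs in cases) {
    f <- fit_enet_cd(X, y, cs$lambda, cs$alpha, weights = cs$w, tol = 1e-10)
    o <- enet_exhaustive(X, y, cs$lambda, cs$alpha, cs$w)
    expect_lt(max(abs(f$beta_naive - o$beta)), 1e-6)
    expect_lt(kkt_violation(f, X, y), 1e-8)
  }
})

test_that("solver agrees with glmnet under the convention map", {
  skip_if_not_installed("glmnet")
  fx <- make_regression(80, 40, 5, seed = 5)
  # glmnet rescales y to unit variance internally (even with
  # standardize = FALSE), which shifts its L1:L2 balance; feeding it
  # unit-variance y makes the documented objective exact
  ys <- fx$yc / sqrt(mean(fx$yc^2))
  for (alpha in c(0, 0.3, 0.7)) {
    lam <- lambda_grid(fx$Xc, ys, 30, 1e-2, alpha)[15]
    f <- fit_enet_cd(fx$Xc, ys, lam, alpha, tol = 1e-12)
    gp <- to_glmnet_penalty(lam, alpha)
    g <- glmnet::glmnet(fx$Xc, ys, alpha = gp$alpha, lambda = gp$lambda,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14, maxit = 1e8)
    expect_lt(max(abs(f$beta_naive - as.numeric(g$beta))), 1e-5)
  }
})

test_that("solution is invariant to column order", {
  fx <- make_regression(40, 15, 4, seed = 6)
  perm <- sample(15)
  f1 <- fit_enet_cd(fx$Xc, fx$yc, 0.05, alpha = 0.2, tol = 1e-10)
  f2 <- fit_enet_cd(fx$Xc[, perm], fx$yc, 0.05, alpha = 0.2, tol = 1e-10)
  expect_lt(max(abs(f1$beta_naive[perm] - f2$beta_naive)), 1e-7)
})

test_that("the path warm starts match cold starts and saturates at n", {
  fx <- make_regression(30, 60, 5, seed = 7)  # p > n
  g <- lambda_grid(fx$Xc, fx$yc, 25, 1e-2, alpha = 0)
  pth <- fit_path(fx$Xc, fx$yc, g, alpha = 0, tol = 1e-9)
  # first path point at lambda_max is the zero vector
  expect_equal(unname(pth$beta[1, ]), rep(0, 60))
  # lasso never selects more than n markers before saturating
  expect_true(all(pth$nonzero_count <= 30))
  expect_gte(pth$nonzero_count[25], pth$nonzero_count[1])
  # cold-start refits agree with the warm-started path
  for (k in c(5, 15, 25)) {
    cold <- fit_enet_cd(fx$Xc, fx$yc, g[k], alpha = 0, tol = 1e-9)
    expect_lt(max(abs(cold$beta_naive - pth$beta[k, ])), 1e-6)
  }
  expect_error(fit_path(fx$Xc, fx$yc, rev(g), alpha = 0), "decreasing")
})

test_that("adaptive weights follow |beta|^-gamma with the Inf convention", {
  expect_equal(adaptive_weights(c(1, 0.5, 0), 2), c(1, 4, Inf))
  expect_equal(adaptive_weights(c(1, -1), 0.5), c(1, 1))
  expect_error(adaptive_weights(c(1, 2), 0), "gamma")
  # Inf-weight coordinates are pinned at zero downstream
  fx <- make_regression(30, 5, 2, seed = 8)
  f <- fit_enet_cd(fx$Xc, fx$yc, 0.01, alpha = 0,
                   weights = c(Inf, 1, 1, 1, Inf))
  expect_equal(unname(f$beta[c(1, 5)]), c(0, 0))
})

test_that("adaptive lasso reduces to plain lasso at unit weights and both
           implementations agree", {
  fx <- make_regression(50, 30, 5, seed = 9)
  plain <- fit_enet_cd(fx$Xc, fx$yc, 0.08, alpha = 0, tol = 1e-10)
  unit_ini <- rep(1, 30)
  ada <- fit_adaptive_lasso(fx$Xc, fx$yc, 0.08, gamma = 1, unit_ini,
                            tol = 1e-10)
  expect_lt(max(abs(ada$beta - plain$beta)), 1e-9)

  ini <- fit_enet_cd(fx$Xc, fx$yc, 0.5, alpha = 1, tol = 1e-10)
  a1 <- fit_adaptive_lasso(fx$Xc, fx$yc, 0.05, gamma = 1, ini,
                           method = "weighted", tol = 1e-11)
  a2 <- fit_adaptive_lasso(fx$Xc, fx$yc, 0.05, gamma = 1, ini,
                           method = "rescale", tol = 1e-11)
  expect_lt(max(abs(a1$beta - a2$beta)), 1e-8)

  expect_error(fit_adaptive_lasso(fx$Xc, fx$yc, 0.05, 1, rep(0, 30)),
               "identically zero")
})

test_that("adaptive lasso matches the exhaustive oracle at p = 3", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3); X <- scale(X, scale = FALSE)
  y <- drop(X %*% c(2, 0.3, 0)) + rnorm(20, 0.3); y <- y - mean(y)
  ini <- ridge_closed_form(X, y, 0.1)
  f <- fit_adaptive_lasso(X, y, 0.06, gamma = 1, ini, tol = 1e-10)
  o <- enet_exhaustive(X, y, 0.06, alpha = 0, adaptive_weights(ini, 1))
  expect_lt(max(abs(f$beta_naive - o$beta)), 1e-6)
})

test_that("adaptive elastic net: weight-neutral case, constant-weight algebra
           and the exhaustive oracle", {
  fx <- make_regression(40, 12, 3, seed = 11)
  enet <- fit_enet_cd(fx$Xc, fx$yc, 0.05, alpha = 0.3, rescale = TRUE,
                      tol = 1e-10)
  # forced unit weights reproduce the rescaled elastic net exactly
  ada <- fit_adaptive_enet(fx$Xc, fx$yc, 0.05, 0.3, gamma = 1,
                           stage1 = rep(1, 12), tol = 1e-10)
  expect_lt(max(abs(ada$beta - enet$beta)), 1e-9)

  # constant stage-1 coefficients c act as a pure L1 rescale c^-gamma
  cc <- 0.5; gam <- 2
  adac <- fit_adaptive_enet(fx$Xc, fx$yc, 0.05, 0.3, gamma = gam,
                            stage1 = rep(cc, 12), tol = 1e-11)
  # equivalent unweighted problem: l1' = 0.05*(1-0.3)*cc^-gam, l2' = 0.05*0.3
  l1p <- 0.05 * 0.7 * cc^(-gam); l2p <- 0.05 * 0.3
  lam2 <- l1p + l2p; alpha2 <- l2p / lam2
  ref <- fit_enet_cd(fx$Xc, fx$yc, lam2, alpha2, tol = 1e-11)
  expect_lt(max(abs(adac$beta_naive - ref$beta_naive)), 1e-8)

  # exhaustive oracle on the weighted objective at p = 3
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3); X <- scale(X, scale = FALSE)
  y <- drop(X %*% c(1, -2, 0.2)) + rnorm(20, 0, 0.4); y <- y - mean(y)
  s1 <- fit_enet_cd(X, y, 0.03, alpha = 0.3, rescale = TRUE, tol = 1e-10)
  f <- fit_adaptive_enet(X, y, 0.04, 0.3, gamma = 1, s1, tol = 1e-10)
  o <- enet_exhaustive(X, y, 0.04, 0.3, adaptive_weights(s1$beta, 1))
  expect_lt(max(abs(f$beta_naive - o$beta)), 1e-6)
  # reported coefficients carry the 1 + 2*lambda*alpha rescale
  expect_equal(f$beta, f$beta_naive * (1 + 2 * 0.04 * 0.3))
})

test_that("prediction re-applies stored centering", {
  fx <- make_regression(25, 4, 2, seed = 13)
  fit <- fit_model(fx$X, fx$y, "lasso", lambda = 0.05)
  # in-sample predictions equal fitted values by construction
  pred <- predict(fit, fx$X)
  manual <- mean(fx$y) +
    drop(sweep(fx$X, 2, fit$column_means) %*% fit$beta)
  expect_equal(unname(pred), manual, ignore_attr = TRUE)

  # zero-coefficient fit predicts the training mean
  fit0 <- fit_model(fx$X, fx$y, "lasso",
                    lambda = 10 * lambda_grid(fx$Xc, fx$yc, 1, alpha = 0))
  expect_equal(unname(predict(fit0, fx$X)), rep(mean(fx$y), 25))

  # pencil-and-paper case: 2 markers, 3 training individuals
  Xh <- matrix(c(1, 0, -1, 0, 1, -1), 3, 2,
               dimnames = list(NULL, c("a", "b")))
  fith <- structure(list(beta = c(a = 2, b = -1), beta_naive = c(2, -1),
                         mu = 0, column_means = c(0, 0), y_mean = 3,
                         penalty = penalty_spec(0.1), model_tag = "hand",
                         nonzero_count = 2), class = "gs_fit")
  expect_equal(unname(predict(fith, Xh)), c(3 + 2, 3 - 1, 3 - 2 + 1))
  expect_error(predict(fith, Xh[, 1, drop = FALSE]), "marker mismatch")
})
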