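#' Fit one of the six genomic-prediction models
#'
#' A single front door over the solver family, handling the
#' centering conventions: markers and phenotypes are mean-centered for
#' all models EXCEPT RR-BLUP, which works on the raw coding with an
#' explicit REML-estimated intercept; stored means are re-applied at
#' prediction time.
#'
#' Models and their hyperparameters:
#' * `"rr"` — ridge regression; `lambda`.
#' * `"rrblup"` — ridge with `lambda` estimated by REML ([reml_fit()]);
#'   no tuning parameters.
#' * `"lasso"` — L1; `lambda`.
#' * `"alasso"` — adaptive lasso; `lambda`, `gamma`, plus
#'   `initial_lambda` for the internal ridge fit that supplies the
#'   initial consistent estimator (refit on the same training data).
#' * `"enet"` — elastic net; `lambda`, `alpha` (ridge share; see
#'   [penalty_spec()]); coefficients carry the `1 + 2 lambda alpha`
#'   rescale.
#' * `"adaenet"` — adaptive elastic net; `lambda`, `alpha`, `gamma`,
#'   plus `stage1_lambda`/`stage1_alpha` for the internal stage-1
#'   elastic net (refit on the same training data).
#'
#' @param X Genotype matrix ({-1,0,1}), rows = individuals.
#' @param y Phenotype vector aligned with the rows of `X`.
#' @param model One of `"rr"`, `"rrblup"`, `"lasso"`, `"alasso"`,
#'   `"enet"`, `"adaenet"`.
#' @param lambda,alpha,gamma Penalty parameters (model-dependent).
#' @param initial_lambda Ridge penalty for the adaptive lasso's initial
#'   estimator.
#' @param stage1_lambda,stage1_alpha Stage-1 elastic-net penalty for the
#'   adaptive elastic net.
#' @param tol,max_iter Coordinate-descent controls.
#' @return A `gs_fit`; use [predict.gs_fit()] for GEBVs.
#' @export
fit_model <- function(X, y,
                      model = c("rr", "rrblup", "lasso", "alasso",
                                "enet", "adaenet"),
                      lambda = NULL, alpha = NULL, gamma = NULL,
                      initial_lambda = NULL,
                      stage1_lambda = NULL, stage1_alpha = NULL,
                      tol = 1e-7, max_iter = 100000L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (model == "rrblup") return(reml_fit(X, y)$fit)
  stopifnot(!is.null(lambda))
  cx <- center_columns(X)
  cy <- center_phenotype(y)
  fit <- switch(model,
    rr = fit_enet_cd(cx$values, cy$values, lambda, alpha = 1,
                     tol = tol, max_iter = max_iter, model_tag = "rr"),
    lasso = fit_enet_cd(cx$values, cy$values, lambda, alpha = 0,
                        tol = tol, max_iter = max_iter,
                        model_tag = "lasso"),
    enet = {
      stopifnot(!is.null(alpha))
      fit_enet_cd(cx$values, cy$values, lambda, alpha, rescale = TRUE,
                  tol = tol, max_iter = max_iter, model_tag = "enet")
    },
    alasso = {
      stopifnot(!is.null(gamma), !is.null(initial_lambda))
      ini <- fit_enet_cd(cx$values, cy$values, initial_lambda, alpha = 1,
                         tol = tol, max_iter = max_iter,
                         model_tag = "rr_initial")
      fit_adaptive_lasso(cx$values, cy$values, lambda, gamma, ini,
                         tol = tol, max_iter = max_iter)
    },
    adaenet = {
      stopifnot(!is.null(alpha), !is.null(gamma),
                !is.null(stage1_lambda), !is.null(stage1_alpha))
      s1 <- fit_enet_cd(cx$values, cy$values, stage1_lambda, stage1_alpha,
                        rescale = TRUE, tol = tol, max_iter = max_iter,
                        model_tag = "enet_stage1")
      fit_adaptive_enet(cx$values, cy$values, lambda, alpha, gamma, s1,
                        tol = tol, max_iter = max_iter)
    })
  fit$column_means <- cx$column_means
  fit$y_mean <- cy$mean
  fit$model_tag <- model
  fit
}
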