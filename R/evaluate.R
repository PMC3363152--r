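#' Pearson correlation with a constant-vector guard
#'
#' Standard product-moment correlation; if either vector is constant the
#' correlation is undefined and 0 is returned with a warning (callers
#' treat this as "no predictive signal").
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 observations")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("correlation undefined for a constant vector; returning 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Root mean squared error
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  sqrt(mean((pred - truth)^2))
}

#' Comparative accuracy report
#'
#' One row per model with the seven accuracy columns: mean/min/max of
#' the per-fold Pearson r between predicted GEBVs and held-out
#' phenotypes (five-fold family-stratified CV), Pearson r of the
#' predictions for the unphenotyped candidates against their true
#' genomic values (TGV) and true breeding values (TBV), and the RMSE
#' against both (trait scale, uncentered predictions).
#'
#' @param predictions Named list (by model tag) of GEBV vectors for the
#'   prediction candidates.
#' @param tgv,tbv Named truth vectors covering the prediction
#'   candidates.
#' @param cv_tables Named list (by model tag) of [cv_error()] results.
#' @return data.frame of class `accuracy_report` with columns `model`,
#'   `cv_mean_r`, `cv_min_r`, `cv_max_r`, `r_tgv`, `r_tbv`, `rmse_tgv`,
#'   `rmse_tbv`.
#' @export
evaluate_models <- function(predictions, tgv, tbv, cv_tables) {
  tags <- union(names(predictions), names(cv_tables))
  rows <- lapply(tags, function(tag) {
    pred <- predictions[[tag]]
    cvt <- cv_tables[[tag]]
    if (is.null(pred) || is.null(cvt)) {
      message("model '", tag, "' is incomplete; reporting NA row")
      return(data.frame(model = tag, cv_mean_r = NA_real_,
                        cv_min_r = NA_real_, cv_max_r = NA_real_,
                        r_tgv = NA_real_, r_tbv = NA_real_,
                        rmse_tgv = NA_real_, rmse_tbv = NA_real_))
    }
    ids <- names(pred)
    data.frame(
      model = tag,
      cv_mean_r = mean(cvt$fold_r),
      cv_min_r = min(cvt$fold_r),
      cv_max_r = max(cvt$fold_r),
      r_tgv = pearson(pred, tgv[ids]),
      r_tbv = pearson(pred, tbv[ids]),
      rmse_tgv = rmse(pred, tgv[ids]),
      rmse_tbv = rmse(pred, tbv[ids])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) sprintf("%.4f", v))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Default benchmark configuration
#'
#' Nested list of the generator, fitting and CV settings, with the
#' study-design defaults (five 1-Morgan chromosomes of 1998 SNPs at
#' 0.05 cM; 20 sires x 10 dams x 15 progeny with 10 phenotyped per
#' family; 30 QTL, 30% carrying dominance, h2 = 0.5).  Override any
#' subset via `...` using the same nesting, e.g.
#' `benchmark_config(genome = list(n_chrom = 1), pedigree =
#' list(n_sires = 6))`.
#'
#' @param ... Named nested overrides.
#' @return Nested configuration list.
#' @export
benchmark_config <- function(...) {
  cfg <- list(
    genome = list(n_chrom = 5L, length_morgan = 1, n_markers = 1998L,
                  spacing_cm = 0.05),
    founders = list(n_founders = 400L, ld_scale_cm = 1.0, maf_min = 0.05),
    pedigree = list(n_sires = 20L, dams_per_sire = 10L,
                    progeny_per_mating = 15L, phenotyped_per_family = 10L),
    trait = list(n_qtl = 30L, additive_sd = 1, dominance_prob = 0.3,
                 dominance_sd = 0.5, h2 = 0.5, trait_mean = 0),
    fitting = list(n_lambda = 100L, min_ratio = 1e-4, tol = 1e-7,
                   cv_tol = 1e-5,
                   max_iter = 100000L, alpha_grid = seq(0, 1, 0.1),
                   gamma_grid = c(0.5, 1, 2),
                   models = c("rr", "rrblup", "lasso", "alasso", "enet",
                              "adaenet")),
    cv = list(k = 5L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
  }
  cfg
}

#' Run the full comparative benchmark
#'
#' End to end: simulate a population, encode the candidates' marker
#' matrix, drop zero-variance markers (computed on the training split),
#' tune every requested model by family-stratified CV, refit each on the
#' full training set at its chosen hyperparameters, predict the
#' unphenotyped candidates, and assemble the seven-column accuracy
#' report.  Each stage consumes a named child seed of `seed`; rerunning
#' with the same `(config, seed)` is bit-identical.
#'
#' @param config Configuration from [benchmark_config()].
#' @param seed Global integer seed.
#' @param out_dir Optional directory; when given, the simulated tables,
#'   per-model fits, CV tables, the report and a JSON run manifest are
#'   persisted there.
#' @return List: `report` (an `accuracy_report`), `fits`, `tuning`
#'   (chosen hyperparameters per model), `cv_tables`, `predictions`,
#'   `population`, `kept_markers`.
#' @export
run_benchmark <- function(config = benchmark_config(), seed = 1L,
                          out_dir = NULL) {
  t0 <- Sys.time()
  pop <- do.call(simulate_population,
                 c(config$genome, config$founders, config$pedigree,
                   config$trait, list(seed = seed)))

  ped <- pop$pedigree
  prog <- ped[ped$role == "progeny", , drop = FALSE]
  train_ids <- prog$id[prog$phenotyped]
  pred_ids <- prog$id[!prog$phenotyped]
  Xprog <- genotypes(pop, "progeny")
  y <- pop$phenotype

  fz <- filter_zero_variance(Xprog[train_ids, , drop = FALSE])
  Xtr <- fz$X
  Xpr <- Xprog[pred_ids, fz$kept_indices, drop = FALSE]

  ft <- config$fitting
  scheme <- make_family_folds(ped, config$cv$k, child_seed(seed, "folds"))
  models <- ft$models
  tuning <- list()
  log <- list()

  need_ridge <- any(c("rr", "alasso") %in% models)
  if (need_ridge) {
    sl <- select_lambda(Xtr, y, scheme, alpha = 1, n_lambda = ft$n_lambda,
                        min_ratio = ft$min_ratio, tol = ft$cv_tol,
                        max_iter = ft$max_iter)
    tuning$rr <- list(lambda = sl$lambda)
  }
  if ("lasso" %in% models) {
    sl <- select_lambda(Xtr, y, scheme, alpha = 0, n_lambda = ft$n_lambda,
                        min_ratio = ft$min_ratio, tol = ft$cv_tol,
                        max_iter = ft$max_iter)
    tuning$lasso <- list(lambda = sl$lambda)
  }
  need_enet <- any(c("enet", "adaenet") %in% models)
  if (need_enet) {
    sa <- select_alpha(Xtr, y, ped, scheme, alpha_grid = ft$alpha_grid,
                       seed = seed, n_lambda = ft$n_lambda,
                       min_ratio = ft$min_ratio, tol = ft$cv_tol,
                       max_iter = ft$max_iter)
    tuning$enet <- list(lambda = sa$lambda, alpha = sa$alpha)
    log$alpha_table <- sa$table
  }
  if ("alasso" %in% models) {
    ini <- fit_model(Xtr, y, "rr", lambda = tuning$rr$lambda,
                     tol = ft$tol, max_iter = ft$max_iter)
    sg <- select_gamma(Xtr, y, scheme, ini, gamma_grid = ft$gamma_grid,
                       alpha = 0,
                       initial_fn = function(Xc, yc)
                         drop(ridge_path_dual(Xc, yc, tuning$rr$lambda)),
                       n_lambda = ft$n_lambda,
                       min_ratio = ft$min_ratio, tol = ft$cv_tol,
                       max_iter = ft$max_iter)
    tuning$alasso <- list(lambda = sg$lambda, gamma = sg$gamma,
                          initial_lambda = tuning$rr$lambda)
    log$alasso_gamma_table <- sg$table
  }
  if ("adaenet" %in% models) {
    s1 <- fit_model(Xtr, y, "enet", lambda = tuning$enet$lambda,
                    alpha = tuning$enet$alpha, tol = ft$tol,
                    max_iter = ft$max_iter)
    sg <- select_gamma(Xtr, y, scheme, s1, gamma_grid = ft$gamma_grid,
                       alpha = tuning$enet$alpha,
                       initial_fn = function(Xc, yc)
                         fit_enet_cd(Xc, yc, tuning$enet$lambda,
                                     tuning$enet$alpha, rescale = TRUE,
                                     tol = ft$cv_tol,
                                     max_iter = ft$max_iter)$beta,
                       n_lambda = ft$n_lambda,
                       min_ratio = ft$min_ratio, tol = ft$cv_tol,
                       max_iter = ft$max_iter)
    tuning$adaenet <- list(lambda = sg$lambda, alpha = tuning$enet$alpha,
                           gamma = sg$gamma,
                           stage1_lambda = tuning$enet$lambda,
                           stage1_alpha = tuning$enet$alpha)
    log$adaenet_gamma_table <- sg$table
  }

  fitter_for <- function(tag) {
    hyper <- tuning[[tag]]
    function(Xs, ys) do.call(fit_model,
      c(list(X = Xs, y = ys, model = tag, tol = ft$tol,
             max_iter = ft$max_iter), hyper))
  }

  fits <- cv_tables <- predictions <- list()
  for (tag in models) {
    fit <- fitter_for(tag)(Xtr, y[train_ids])
    fits[[tag]] <- fit
    cv_tables[[tag]] <- cv_error(Xprog[, fz$kept_indices, drop = FALSE],
                                 y, scheme, fitter_for(tag))
    predictions[[tag]] <- predict(fit, Xpr)
  }

  report <- evaluate_models(predictions, pop$tgv, pop$tbv, cv_tables)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tables(pop, file.path(out_dir, "data"))
    data.table::fwrite(as.data.frame(report),
                       file.path(out_dir, "report.tsv"), sep = "\t")
    for (tag in names(fits)) {
      f <- fits[[tag]]
      hdr <- c(sprintf("# model\t%s", tag),
               sprintf("# mu\t%.10g", f$mu + f$y_mean),
               sprintf("# lambda\t%.10g", f$penalty$lambda),
               sprintf("# alpha\t%.10g", f$penalty$alpha),
               sprintf("# gamma\t%s", f$penalty$gamma),
               sprintf("# seed\t%d", seed))
      if (tag == "rrblup")
        hdr <- c(hdr, sprintf("# sigma_beta2\t%.10g", f$varcomp$sigma_beta2),
                 sprintf("# sigma_e2\t%.10g", f$varcomp$sigma_e2))
      path <- file.path(out_dir, sprintf("fit_%s.tsv", tag))
      writeLines(hdr, path)
      data.table::fwrite(data.table::data.table(
        marker_id = names(f$beta), beta = f$beta), path, sep = "\t",
        append = TRUE, col.names = TRUE)
      cvt <- cv_tables[[tag]]
      data.table::fwrite(data.table::data.table(
        fold = seq_along(cvt$fold_mse), n_val = cvt$fold_n,
        mse = cvt$fold_mse, pearson_r = cvt$fold_r),
        file.path(out_dir, sprintf("cv_%s.tsv", tag)), sep = "\t")
    }
    manifest <- list(seed = seed, config = config,
                     tuning = tuning, elapsed_sec = elapsed,
                     n_train = length(train_ids), n_predict = length(pred_ids),
                     n_markers_kept = ncol(Xtr),
                     nonzero = lapply(fits, `[[`, "nonzero_count"),
                     r_version = as.character(getRversion()))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(out_dir, "manifest.json"))
  }

  list(report = report, fits = fits, tuning = tuning,
       cv_tables = cv_tables, predictions = predictions,
       population = pop, kept_markers = fz$kept_indices,
       elapsed_sec = elapsed, log = log)
}
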