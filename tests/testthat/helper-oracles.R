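# Independent oracles and small fixture builders shared across tests.

# Exhaustive minimizer of the weighted elastic-net objective
#   (1/2n)||y - X b||^2 + lambda (1-alpha) sum w|b| + lambda alpha sum b^2
# by enumerating all 3^p sign patterns and solving each constrained
# quadratic.  Only feasible for tiny p; completely independent of the
# coordinate-descent code path.
enet_exhaustive <- function(X, y, lambda, alpha = 0, weights = NULL) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(p <= 6)
  if (is.null(weights)) weights <- rep(1, p)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  best <- NULL; best_obj <- Inf
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    if (any(s != 0 & !is.finite(weights))) next  # pinned coords stay zero
    beta <- numeric(p)
    A <- which(s != 0)
    if (length(A)) {
      XA <- X[, A, drop = FALSE]
      M <- crossprod(XA) / n + diag(2 * lambda * alpha, length(A))
      rhs <- drop(crossprod(XA, y)) / n -
        lambda * (1 - alpha) * weights[A] * s[A]
      bA <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(bA)) next
      if (any(sign(bA) != s[A])) next
      beta[A] <- bA
    }
    obj <- gsreg::enet_objective(beta, X, y, lambda, alpha, weights)
    if (obj < best_obj) { best_obj <- obj; best <- beta }
  }
  list(beta = best, objective = best_obj)
}

# Dense closed-form ridge minimizer of the same objective at alpha = 1:
# beta = (X'X/n + 2 lambda I)^{-1} X'y / n.
ridge_closed_form <- function(X, y, lambda) {
  p <- ncol(X)
  drop(solve(crossprod(X) / n_or(X) + diag(2 * lambda, p),
             crossprod(X, y) / n_or(X)))
}
n_or <- function(X) nrow(X)

# Random centered regression fixture with k causal effects.
make_regression <- function(n, p, k, beta_size = 1, noise_sd = 1,
                            seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.4) - 1, n, p)
  colnames(X) <- paste0("m", seq_len(p))
  causal <- sample.int(p, k)
  b <- numeric(p)
  b[causal] <- beta_size * sample(c(-1, 1), k, replace = TRUE)
  y <- drop(X %*% b) + rnorm(n, 0, noise_sd)
  Xc <- scale(X, scale = FALSE)
  attr(Xc, "scaled:center") <- NULL
  list(X = X, Xc = Xc, y = y, yc = y - mean(y), beta = b, causal = causal)
}

# Synthetic pedigree table (families of equal size, all phenotyped) for
# fold-construction tests that do not need genotypes.
make_flat_pedigree <- function(n_family, family_size) {
  n <- n_family * family_size
  data.frame(
    id = sprintf("I%04d", seq_len(n)),
    sire = NA_character_, dam = NA_character_,
    family_id = rep(sprintf("F%03d", seq_len(n_family)), each = family_size),
    phenotyped = TRUE,
    role = "progeny",
    stringsAsFactors = FALSE
  )
}

# Small complete population for end-to-end tests (fast).
make_tiny_population <- function(seed = 7, n_markers = 120L, n_sires = 4L,
                                 h2 = 0.5, dominance_prob = 0.3) {
  simulate_population(
    n_chrom = 2L, length_morgan = 1, n_markers = n_markers,
    spacing_cm = 0.5, n_founders = 60L, ld_scale_cm = 1, maf_min = 0.05,
    n_sires = n_sires, dams_per_sire = 3L, progeny_per_mating = 15L,
    phenotyped_per_family = 10L, n_qtl = 12L, additive_sd = 1,
    dominance_prob = dominance_prob, dominance_sd = 0.5, h2 = h2,
    trait_mean = 0, seed = seed)
}
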