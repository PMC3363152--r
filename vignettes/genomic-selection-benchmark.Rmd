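---
title: "Comparing regularized regression models for genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing regularized regression models for genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genomic selection predicts an individual's genetic merit — its genomic
estimated breeding value (GEBV) — from dense genome-wide SNP markers.
With thousands of markers and only hundreds to a few thousand phenotyped
individuals, ordinary least squares is unusable (p >> n) and some form
of shrinkage is mandatory.  `gsreg` implements and compares six
penalized estimators of the marker-effect model

    y = mu * 1_n + X beta + e,    e ~ N(0, I sigma_e^2)

where `X` is the n x p matrix of marker covariates coded 1 (A1A1),
-1 (A2A2) and 0 (heterozygote), and `beta` holds the additive marker
effects.  The six estimators are:

* **Ridge regression (rr)** — L2 penalty `lambda * ||beta||_2^2`; keeps
  every marker, shrinking correlated markers toward each other.
* **Ridge regression BLUP (rrblup)** — the same estimator, but the
  penalty is not tuned by cross-validation: treating `beta` as random
  effects with variance `sigma_beta^2 I`, REML estimates both variance
  components and fixes `lambda = sigma_e^2 / sigma_beta^2`.
* **Lasso** — L1 penalty `lambda * ||beta||_1`; performs automatic
  variable selection but cannot select more than n markers and lacks
  the oracle property.
* **Adaptive lasso (alasso)** — weighted L1 penalty with data-driven
  weights `w_j = |beta_ini_j|^(-gamma)` from an initial consistent
  estimator (here a CV-tuned ridge fit, since p >> n rules out OLS);
  restores the oracle property.
* **Elastic net (enet)** — mixture `lambda2 ||beta||_2^2 +
  lambda1 ||beta||_1`; robust to the strong inter-marker correlation
  (LD) that destabilizes the lasso, and able to select groups of
  correlated markers.
* **Adaptive elastic net (adaenet)** — two stages: an elastic-net fit
  supplies `|beta_enet_j|^(-gamma)` weights for the L1 part of a second
  elastic-net solve, combining the oracle property with the grouping
  stability of the elastic net.

Accuracy is summarized in a seven-column table per model: mean/min/max
of the per-fold Pearson correlation between predicted GEBVs and held-out
phenotypes under five-fold family-stratified CV, plus correlation and
RMSE of the unphenotyped candidates' GEBVs against the simulated true
genomic values (TGV) and true breeding values (TBV).

# Penalty conventions (read this before comparing with other software)

The mixing parameter follows the convention `alpha = lambda2 /
(lambda1 + lambda2)`: **`alpha` is the ridge share**, so `alpha = 1` is
pure ridge and `alpha = 0` is pure lasso — the reverse of glmnet.
`to_glmnet_penalty()` converts.  Internally every L1/L2 fit minimizes

    F(beta) = (1/2n) ||y_c - X_c beta||^2
            + lambda (1 - alpha) sum_j w_j |beta_j|
            + lambda alpha sum_j beta_j^2

on column-centered `X_c` and mean-centered `y_c` (centering is the whole
intercept treatment for every model except RR-BLUP, which REML-fits an
explicit intercept on the raw coding).  This maps to raw penalties on
the unscaled residual sum of squares as `lambda1 = 2 n lambda (1 -
alpha)` and `lambda2 = 2 n lambda alpha`, so penalties are comparable
across sample sizes.  The elastic-net family is defined with a leading
de-biasing factor which we read as `(1 + lambda2 / n)`; under the
internal mapping that is `1 + 2 lambda alpha`, applied as a final
rescale of the reported ENET/ADAENET coefficients (`beta_naive` retains
the unrescaled solution; the alternative reading `1 + lambda2` would be
enormous at these n and is not implemented).

# The solver

All L1/L2 fits use cyclical coordinate descent with the update

    beta_j <- S(rho_j, lambda (1-alpha) w_j) / (x_j'x_j / n + 2 lambda alpha)

where `S` is the soft-threshold operator and `rho_j` the partial
residual correlation.  Design choices:

* **Convergence** is declared only when a full sweep over *all*
  coordinates moves none by more than `tol` (default `1e-7`); between
  full sweeps the solver cycles the ever-active (nonzero) set, which
  changes nothing about the exit condition or the solution but avoids
  quadratic slowdown near the saturated end of a p > n lasso path.
  Every returned fit satisfies the KKT conditions of `F` within solver
  tolerance (`kkt_violation()` is exported and tested).
* **Paths** are computed largest-lambda first on a log-spaced grid from
  `lambda_max` (the smallest penalty with an all-zero solution; the
  `max(1 - alpha, 0.001)` floor keeps it finite as alpha -> 1) with
  warm starts.  Grid defaults are `n_lambda = 100`, `min_ratio = 1e-4`;
  the benchmark configurations use `min_ratio = 0.01`, the common
  practice when p > n, where tiny penalties only explore the degenerate
  saturated region.
* **Infinite adaptive weights** (from exactly-zero initial
  coefficients) pin their coordinates at zero, implementing the
  convention that a variable discarded by the initial estimator stays
  discarded.
* **Pure ridge path evaluations** inside cross-validation use the exact
  n x n dual solution `X'(XX' + 2 n lambda I)^{-1} y` from a single
  eigendecomposition; the coordinate-descent and closed-form routes are
  verified against each other in the test suite.
* No strong-rule screening or covariance updates are used; correctness
  and auditability take precedence at these problem sizes.

# RR-BLUP by REML

The restricted likelihood of the ratio `lambda = sigma_e^2 /
sigma_beta^2` is profiled through the eigendecomposition of the
intercept-projected `XX'` (the n x n dual form, since p ~ 10^4 >> n),
and maximized by a bounded golden-section/parabolic search on
`log(lambda) in [-10, 10]` to tolerance 1e-8 — wide enough to cover
heritabilities from ~0 to ~1 at these scales; convergence onto a bound
raises a warning and sets a `boundary` flag (this legitimately happens
for noise-free traits, where `sigma_e^2 -> 0`).  Eigenvalues are
floored at 1e-10 against rank degeneracy.  Marker effects are recovered
in dual form and the intercept by generalized least squares; the test
suite checks the primal/dual identity and the equivalence with the
coordinate-descent ridge at `lambda_cd = lambda / (2n)`.

# Hyperparameter search

Folds are family-stratified: within every full-sib family the
phenotyped members are permuted and dealt round-robin into k = 5 folds,
so each fold holds (up to remainder) the same number of members of
every family.  Full sibs are far more alike than unrelated candidates;
stratification keeps each family represented in training while the
held-out sibs remain genuine validation cases.  The same construction
(with a child seed) builds the inner folds — the design is silent on
inner stratification in general, and we prefer consistent
family-leakage control at both levels.

* `lambda` is selected along the warm-started path by inner five-fold
  CV MSE; ties break toward the larger lambda (more shrinkage, in the
  one-standard-error spirit without implementing the 1-SE rule).
* `alpha` (elastic net) is selected by an outer five-fold CV over the
  grid `{0, 0.1, ..., 1}`, with `lambda` re-resolved by inner CV at
  every `alpha`; ties break toward the larger (more ridge-like) alpha.
  The outer score refits the path down to the chosen lambda on each
  outer training split — identical to a cold fit at that lambda, but
  warm-started.
* `gamma` (adaptive models) is grid-searched over `{0.5, 1, 2}`
  jointly with `lambda` (two-dimensional search); ties break toward
  the smaller gamma.  For the adaptive elastic net the stage-1
  elastic-net `(alpha, lambda)` come from the elastic-net tuning, and
  the second-stage search holds `alpha` fixed at the stage-1 value, so
  `lambda2` scales with the searched `lambda` rather than adding a
  third free axis; a full `(lambda1, lambda2, gamma)` search is
  explicitly out of scope.
* Selection always minimizes validation MSE; per-fold Pearson r is
  reported but never used for selection.
* During path CV the solver runs at a relaxed `cv_tol` (default
  `1e-5`; the desk-scale configurations use `1e-4`), since MSE curves
  are flat on the scale of coordinate changes far below the noise
  level; all reported fits are refit at the full `tol = 1e-7`.
* Adaptive weights are refit *inside every tuning fold*: the initial
  estimator (ridge for the adaptive lasso, the stage-1 elastic net for
  the adaptive elastic net) is recomputed on each fold's training split
  and that fold's weights derived from it.  Building weights once from
  a full-data initial fit leaks the validation individuals' noise into
  the penalty — noise markers that drew spuriously large initial
  coefficients become cheap exactly where they will be validated — and
  measurably over-selects (in our support-recovery experiments it more
  than tripled the adaptive lasso's false positives, erasing its
  advantage over the plain lasso).  The final accuracy report likewise
  refits the initial estimator inside every CV training split.

# The population simulator

The generator reproduces the statistical structure of the emulated
dataset rather than its (undisclosed) realization:

* **Genome**: five 1-Morgan chromosomes, 1998 SNPs each at 0.05 cM
  (positions `i * 0.05`, i = 1..1998, matching the printed
  per-chromosome count of 1998 rather than 2000), 9990 loci in total.
* **Founders**: the original data's 1000-generation drift history is
  replaced by a one-knob Markov model: allele frequencies are uniform
  on `[maf_min, 1 - maf_min]` and a latent state is copied from locus
  to locus with probability `exp(-d_cM / ld_scale_cm)`.  The default
  `ld_scale_cm = 1.0` gives LD that decays on the centimorgan scale, as
  in livestock-like populations.  This reproduces distance-decaying
  pairwise LD but not long-range haplotype blocks or allele-frequency
  spectra shaped by selection.
* **Pedigree**: 20 sires x 10 dams x 15 progeny (3000 candidates); 10
  progeny per full-sib family phenotyped (2000) and 5 genotype-only
  (1000).  Meiosis is Haldane: Poisson crossover counts with uniform
  positions and no interference.
* **Trait**: the emulated dataset's architecture was never published,
  so the defaults are explicit stand-ins: 30 QTL placed *at marker
  loci* (so the signal is capturable by the fitted markers), additive
  effects N(0, 1), a 30% chance of a dominance deviation N(0, 0.5^2),
  heritability 0.5.  A sparse architecture is deliberate: it is the
  regime in which selection-capable penalties are expected to shine,
  which is the comparison of interest.
* **Truth surfaces**: `TGV_i = sum_j a_j x_ij + d_j 1(x_ij = 0)` is the
  expected phenotype given the individual's own genotype;
  `TBV_i = sum_j (x_ij + 1 - 2 p_j) alpha_j` with substitution effects
  `alpha_j = a_j + d_j (q_j - p_j)` is the classical breeding value
  (twice the expected progeny-mean deviation under random mating — the
  factor 2 is verified against a progeny-simulation oracle in the
  tests).  With no dominance, TGV and TBV are perfectly correlated.
* **Phenotypes**: `y = trait_mean + TGV + e` with `sigma_e^2` set from
  the realized TGV variance among phenotyped candidates, so `h2` is
  broad-sense with respect to the modeled genetic value.
* **Reproducibility**: a single global seed spawns deterministic named
  child seeds per stage (`child_seed()`), so any stage can be rerun in
  isolation and full runs are bit-identical.

Zero-variance markers (monomorphic in the training candidates) are
removed before fitting — they carry no information and would produce
infinite adaptive weights.

# What the desk-scale results do and do not show

The tests and the acceptance script run a scaled design — one 1-Morgan
chromosome of 1000 markers and 60 families (600 training, 300
prediction candidates), chosen so the complete six-model comparison
with nested tuning replicates five times within minutes — plus
dedicated smaller fixtures per solver (oracle checks at p = 3, REML
recovery at n = 300 / p = 1000, support recovery at n = 400 / p = 500).
On this scale the qualitative findings are stable across seeds:
selection-capable models beat the ridge-type models in CV accuracy on
sparse architectures, and RMSE against TBV clearly exceeds RMSE against
TGV (TBV lives on the full breeding-value scale).  One relation
deserves a caveat: because the substitution effects `alpha_j = a_j +
d_j (q_j - p_j)` make TBV exactly the best *linear* gene-content
approximation of TGV, additive marker models trained on own-phenotypes
track TBV essentially as well as TGV under this generator — the
correlation gap `r_tgv - r_tbv` has median near zero at the default
mild-dominance architecture, rather than the clear TGV advantage seen
on richer (undisclosed) trait architectures.  Numeric accuracy values
depend on the trait architecture and are expected to differ from any
particular dataset's table; they are not reproduction targets.

Known limitations: no epistasis, imprinting or sex chromosomes; no
missing genotypes (readers reject rather than impute); founder LD is a
first-order Markov surrogate; the lasso-family solvers are dense
in-memory implementations sized for p up to ~10^4.
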