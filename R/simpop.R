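#' Build a genome map with evenly spaced markers
#'
#' Lays `n_markers` markers on each of `n_chrom` chromosomes at positions
#' `i * spacing_cm` (i = 1..n_markers), so the default
#' `build_map(5, 1, 1998, 0.05)` reproduces the study design of five
#' 1-Morgan chromosomes carrying 1998 SNPs each at 0.05 cM spacing
#' (9990 loci in total).
#'
#' @param n_chrom Number of chromosomes.
#' @param length_morgan Length of each chromosome in Morgan.
#' @param n_markers Markers per chromosome.
#' @param spacing_cm Marker spacing in centiMorgan.
#' @return An object of class `genome_map`: a list with `chromosomes`
#'   (data.frame of `chrom`, `length_morgan`), `markers` (data.frame of
#'   `marker_id`, `chrom`, `pos_cm`), and `chrom_index` (list of marker
#'   row indices per chromosome).
#' @export
#' @examples
#' m <- build_map(5, 1, 1998, 0.05)
#' nrow(m$markers)  # 9990
build_map <- function(n_chrom = 5L, length_morgan = 1, n_markers = 1998L,
                      spacing_cm = 0.05) {
  stopifnot(n_chrom >= 1, length_morgan > 0, n_markers >= 1, spacing_cm > 0)
  if (n_markers * spacing_cm > 100 * length_morgan + 1e-9)
    stop("markers would exceed chromosome length: ", n_markers, " x ",
         spacing_cm, " cM > ", 100 * length_morgan, " cM")
  pos <- seq_len(n_markers) * spacing_cm
  chrom <- rep(seq_len(n_chrom), each = n_markers)
  markers <- data.frame(
    marker_id = sprintf("M%d_%d", chrom, rep(seq_len(n_markers), n_chrom)),
    chrom = chrom,
    pos_cm = rep(pos, n_chrom),
    stringsAsFactors = FALSE
  )
  structure(list(
    chromosomes = data.frame(chrom = seq_len(n_chrom),
                             length_morgan = length_morgan),
    markers = markers,
    chrom_index = split(seq_len(nrow(markers)), chrom)
  ), class = "genome_map")
}

#' Simulate a founder haplotype pool with distance-decaying LD
#'
#' Stands in for a long drift history: per-locus allele frequencies are
#' drawn uniformly on `[maf_min, 1 - maf_min]`, and haplotypes are
#' generated by a first-order Markov chain along each chromosome.  A
#' latent uniform state is carried from locus j to j+1 with probability
#' `rho = exp(-delta_cM / ld_scale_cm)` and refreshed otherwise; the
#' allele at locus j is 1 (A1) when the latent state falls below the
#' locus frequency.  This yields linkage disequilibrium that decays with
#' map distance, with `ld_scale_cm` the decay length; `ld_scale_cm = 0`
#' gives independent loci.  Chromosomes are independent.
#'
#' @param map A `genome_map`.
#' @param n_founders Number of diploid founders (pool holds `2 * n_founders`
#'   haplotypes).
#' @param ld_scale_cm LD decay scale in cM (default 1.0).
#' @param maf_min Lower bound for founder minor-allele frequency.
#' @param seed Integer seed.
#' @return A list of class `founder_pool`: `haplotypes` (2F x p binary
#'   matrix, 1 = A1), `freqs` (target allele-frequency draws), `map`.
#' @export
simulate_founders <- function(map, n_founders, ld_scale_cm = 1.0,
                              maf_min = 0.05, seed = 1L) {
  stopifnot(inherits(map, "genome_map"))
  if (n_founders <= 0) stop("n_founders must be positive")
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must lie in (0, 0.5)")
  if (ld_scale_cm < 0) stop("ld_scale_cm must be >= 0")
  set.seed(seed)
  p <- nrow(map$markers)
  nh <- 2L * as.integer(n_founders)
  freqs <- runif(p, maf_min, 1 - maf_min)
  H <- matrix(0L, nh, p)
  for (idx in map$chrom_index) {
    pos <- map$markers$pos_cm[idx]
    m <- length(idx)
    u <- matrix(0, nh, m)
    u[, 1L] <- runif(nh)
    if (m > 1L) {
      d <- diff(pos)
      rho <- if (ld_scale_cm > 0) exp(-d / ld_scale_cm) else rep(0, m - 1L)
      for (j in 2L:m) {
        keep <- runif(nh) < rho[j - 1L]
        fresh <- runif(nh)
        u[, j] <- ifelse(keep, u[, j - 1L], fresh)
      }
    }
    H[, idx] <- ifelse(u < matrix(freqs[idx], nh, m, byrow = TRUE), 1L, 0L)
  }
  rownames(H) <- sprintf("F%d_h%d", rep(seq_len(n_founders), each = 2L),
                         rep(1:2, n_founders))
  structure(list(haplotypes = H, freqs = freqs, map = map),
            class = "founder_pool")
}

#' Single meiosis: recombine a parent's haplotype pair into one gamete
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' chromosome length in Morgan, crossover positions are uniform on the
#' map, and there is no interference (Haldane model).  The gamete starts
#' on either parental haplotype with probability 1/2 and switches source
#' at every crossover.
#'
#' @param h1,h2 The parent's two haplotypes (integer vectors over all
#'   markers of `map`).
#' @param map A `genome_map`.
#' @param seed Optional integer seed; by default the ambient RNG stream
#'   (seeded by the calling stage) is consumed.
#' @return An integer gamete haplotype of the same length.
#' @export
meiosis <- function(h1, h2, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(map$markers)
  stopifnot(length(h1) == p, length(h2) == p)
  g <- integer(p)
  for (k in seq_along(map$chrom_index)) {
    idx <- map$chrom_index[[k]]
    L <- map$chromosomes$length_morgan[k]
    nxo <- rpois(1L, L)
    start <- sample.int(2L, 1L)
    if (nxo == 0L) {
      g[idx] <- if (start == 1L) h1[idx] else h2[idx]
    } else {
      xo <- sort(runif(nxo, 0, 100 * L))
      # source haplotype flips at each crossover position
      src <- (start - 1L + findInterval(map$markers$pos_cm[idx], xo)) %% 2L
      g[idx] <- ifelse(src == 0L, h1[idx], h2[idx])
    }
  }
  g
}

#' Gene-drop a sire x dam pedigree from a founder pool
#'
#' Draws `n_sires` sires and `n_sires * dams_per_sire` dams without
#' replacement from the founder pool (an individual never appears in both
#' roles), mates each sire to its dams, and produces
#' `progeny_per_mating` progeny per mating through two [meiosis()] calls.
#' Exactly `phenotyped_per_family` randomly chosen progeny per full-sib
#' family are flagged phenotyped.  The default configuration
#' (20 sires x 10 dams x 15 progeny, 10 phenotyped) reproduces the study
#' pedigree: 3000 progeny, 2000 phenotyped, 1000 unphenotyped.
#'
#' @param map A `genome_map`.
#' @param founders A `founder_pool`.
#' @param n_sires,dams_per_sire,progeny_per_mating Pedigree dimensions.
#' @param phenotyped_per_family Progeny per family flagged phenotyped.
#' @param seed Integer seed.
#' @return A `population` object (without trait values): list with `map`,
#'   `pedigree` (data.frame `id`, `sire`, `dam`, `family_id`, `phenotyped`,
#'   `role`), haplotype matrices `hap1`/`hap2` (rows = individuals), and
#'   the founder `freqs`.
#' @export
simulate_pedigree <- function(map, founders, n_sires = 20L,
                              dams_per_sire = 10L, progeny_per_mating = 15L,
                              phenotyped_per_family = 10L, seed = 1L) {
  stopifnot(inherits(founders, "founder_pool"))
  if (phenotyped_per_family > progeny_per_mating)
    stop("phenotyped_per_family exceeds progeny_per_mating")
  n_founders <- nrow(founders$haplotypes) / 2L
  n_parents <- n_sires + n_sires * dams_per_sire
  if (n_parents > n_founders)
    stop("founder pool too small: need ", n_parents, " distinct parents, have ",
         n_founders)
  set.seed(seed)
  picks <- sample.int(n_founders, n_parents)
  sire_f <- picks[seq_len(n_sires)]
  dam_f <- picks[(n_sires + 1L):n_parents]
  if (anyDuplicated(c(sire_f, dam_f)))
    stop("a founder was drawn for both sire and dam roles")

  sire_ids <- sprintf("S%02d", seq_len(n_sires))
  dam_ids <- sprintf("D%03d", seq_len(n_sires * dams_per_sire))
  p <- nrow(map$markers)
  n_prog <- n_sires * dams_per_sire * progeny_per_mating
  n_all <- n_parents + n_prog

  hap1 <- matrix(0L, n_all, p)
  hap2 <- matrix(0L, n_all, p)
  H <- founders$haplotypes
  hap1[seq_len(n_sires), ] <- H[2L * sire_f - 1L, , drop = FALSE]
  hap2[seq_len(n_sires), ] <- H[2L * sire_f, , drop = FALSE]
  di <- (n_sires + 1L):n_parents
  hap1[di, ] <- H[2L * dam_f - 1L, , drop = FALSE]
  hap2[di, ] <- H[2L * dam_f, , drop = FALSE]

  ped <- data.frame(
    id = c(sire_ids, dam_ids, character(n_prog)),
    sire = NA_character_, dam = NA_character_,
    family_id = NA_character_,
    phenotyped = FALSE,
    role = c(rep("sire", n_sires), rep("dam", length(dam_ids)),
             rep("progeny", n_prog)),
    stringsAsFactors = FALSE
  )

  row <- n_parents
  fam <- 0L
  for (s in seq_len(n_sires)) {
    for (d in seq_len(dams_per_sire)) {
      fam <- fam + 1L
      dam_row <- n_sires + (s - 1L) * dams_per_sire + d
      fam_rows <- row + seq_len(progeny_per_mating)
      pheno <- sample.int(progeny_per_mating, phenotyped_per_family)
      for (k in seq_len(progeny_per_mating)) {
        row <- row + 1L
        hap1[row, ] <- meiosis(hap1[s, ], hap2[s, ], map)
        hap2[row, ] <- meiosis(hap1[dam_row, ], hap2[dam_row, ], map)
        ped$id[row] <- sprintf("P%04d", row - n_parents)
        ped$sire[row] <- sire_ids[s]
        ped$dam[row] <- dam_ids[dam_row - n_sires]
        ped$family_id[row] <- sprintf("FAM%03d", fam)
      }
      ped$phenotyped[fam_rows[pheno]] <- TRUE
    }
  }
  rownames(hap1) <- rownames(hap2) <- ped$id
  structure(list(map = map, pedigree = ped, hap1 = hap1, hap2 = hap2,
                 founder_freqs = founders$freqs, seed = seed),
            class = "population")
}

#' Assign a quantitative-trait architecture on marker loci
#'
#' QTL positions are drawn uniformly without replacement among the marker
#' loci (markers double as causal loci; their identity is never revealed
#' to the fitting code).  Additive effects are Normal(0, `additive_sd`^2);
#' each locus carries a dominance deviation with probability
#' `dominance_prob`, drawn Normal(0, `dominance_sd`^2), else zero.
#'
#' @param map A `genome_map`.
#' @param n_qtl Number of QTL.
#' @param additive_sd SD of additive effects (trait units).
#' @param dominance_prob Probability that a QTL has a dominance deviation.
#' @param dominance_sd SD of dominance deviations (trait units).
#' @param founder_freqs Per-locus founder allele frequencies (A1).
#' @param seed Integer seed.
#' @return A `qtl_model`: data.frame with `marker_index`, `marker_id`,
#'   `a`, `d`, `p` (founder frequency of A1).
#' @export
assign_qtl <- function(map, n_qtl = 30L, additive_sd = 1,
                       dominance_prob = 0.3, dominance_sd = 0.5,
                       founder_freqs = NULL, seed = 1L) {
  p <- nrow(map$markers)
  if (n_qtl > p) stop("n_qtl exceeds number of marker loci")
  set.seed(seed)
  loci <- if (n_qtl > 0) sort(sample.int(p, n_qtl)) else integer(0)
  a <- rnorm(n_qtl, 0, additive_sd)
  has_d <- runif(n_qtl) < dominance_prob
  d <- ifelse(has_d, rnorm(n_qtl, 0, dominance_sd), 0)
  pf <- if (is.null(founder_freqs)) rep(NA_real_, n_qtl) else founder_freqs[loci]
  structure(data.frame(marker_index = loci,
                       marker_id = map$markers$marker_id[loci],
                       a = a, d = d, p = pf,
                       stringsAsFactors = FALSE),
            class = c("qtl_model", "data.frame"))
}

#' Extract the {-1, 0, 1} genotype matrix of a population
#'
#' Coding is 1 for A1A1, -1 for A2A2 and 0 for the heterozygote
#' (haplotype sum minus one).
#'
#' @param pop A `population`.
#' @param role Which individuals: `"progeny"` (the prediction candidates,
#'   default), `"all"`, or any subset of roles.
#' @return Integer matrix, rows named by individual id, columns by
#'   marker id.
#' @export
genotypes <- function(pop, role = "progeny") {
  keep <- if (identical(role, "all")) rep(TRUE, nrow(pop$pedigree))
          else pop$pedigree$role %in% role
  X <- pop$hap1[keep, , drop = FALSE] + pop$hap2[keep, , drop = FALSE] - 1L
  colnames(X) <- pop$map$markers$marker_id
  X
}

#' True genomic values of all individuals
#'
#' `TGV_i = sum_j a_j x_ij + d_j 1(x_ij = 0)` over the QTL, with genotypes
#' coded 1/-1/0 for A1A1 / A2A2 / heterozygote: each individual's expected
#' phenotype given its own genotype.
#'
#' @param pop A `population`.
#' @param qtl A `qtl_model`.
#' @return Named numeric vector over all individuals in `pop`.
#' @export
compute_tgv <- function(pop, qtl) {
  X <- genotypes(pop, "all")
  if (nrow(qtl) == 0) {
    tgv <- rep(0, nrow(X))
    names(tgv) <- rownames(X)
    return(tgv)
  }
  Xq <- X[, qtl$marker_index, drop = FALSE]
  tgv <- drop(Xq %*% qtl$a) + drop((Xq == 0L) %*% qtl$d)
  names(tgv) <- rownames(X)
  tgv
}

#' True breeding values of all individuals
#'
#' Classical breeding values from average allele-substitution effects:
#' `alpha_j = a_j + d_j (q_j - p_j)` with `q_j = 1 - p_j`, and
#' `TBV_i = sum_j (x_ij + 1 - 2 p_j) alpha_j` (`x + 1` counts A1 alleles).
#' Under random mating the expected progeny-mean deviation from the
#' population mean is TBV/2 (a parent transmits half its alleles).
#' Frequencies default to the empirical A1 frequency among the progeny
#' candidates.
#'
#' @param pop A `population`.
#' @param qtl A `qtl_model`.
#' @param freqs Optional per-QTL allele frequencies (A1), same order as
#'   `qtl`; default: empirical progeny frequencies.
#' @return Named numeric vector over all individuals in `pop`.
#' @export
compute_tbv <- function(pop, qtl, freqs = NULL) {
  X <- genotypes(pop, "all")
  if (nrow(qtl) == 0) {
    tbv <- rep(0, nrow(X))
    names(tbv) <- rownames(X)
    return(tbv)
  }
  Xq <- X[, qtl$marker_index, drop = FALSE]
  if (is.null(freqs)) {
    cand <- pop$pedigree$role == "progeny"
    Xc <- X[cand, qtl$marker_index, drop = FALSE]
    freqs <- colMeans(Xc + 1L) / 2
  }
  stopifnot(length(freqs) == nrow(qtl))
  alpha <- qtl$a + qtl$d * (1 - 2 * freqs)
  tbv <- drop(sweep(Xq + 1, 2, 2 * freqs) %*% alpha)
  names(tbv) <- rownames(X)
  tbv
}

#' Simulate phenotypes at a target heritability
#'
#' Residual variance is set from the TGV variance among phenotyped
#' candidates so that `h2 = var(TGV) / (var(TGV) + sigma_e^2)`, i.e.
#' heritability is broad-sense with respect to the modeled genetic value.
#' `y_i = trait_mean + TGV_i + e_i`, `e_i ~ N(0, sigma_e^2)`, generated
#' only for phenotyped individuals.
#'
#' @param pop A `population` with `tgv` already attached.
#' @param h2 Heritability in `(0, 1]`.
#' @param trait_mean Trait mean (default 0).
#' @param seed Integer seed.
#' @return Named numeric vector of phenotypes for phenotyped individuals.
#' @export
simulate_phenotypes <- function(pop, h2 = 0.5, trait_mean = 0, seed = 1L) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  stopifnot(!is.null(pop$tgv))
  ph <- pop$pedigree$phenotyped
  tgv_ph <- pop$tgv[ph]
  vg <- var(tgv_ph)
  if (h2 < 1 && (is.na(vg) || vg <= 0))
    stop("TGV variance is zero among phenotyped candidates; cannot set h2 < 1")
  sigma_e2 <- if (h2 == 1) 0 else vg * (1 - h2) / h2
  set.seed(seed)
  e <- rnorm(length(tgv_ph), 0, sqrt(sigma_e2))
  y <- trait_mean + tgv_ph + e
  names(y) <- pop$pedigree$id[ph]
  y
}

#' Simulate a complete population with trait values
#'
#' Runs the full generator: map, LD-bearing founders, gene dropping
#' through the sire x dam pedigree, QTL assignment, TGV/TBV, and
#' phenotypes.  Every stage consumes a named child seed of `seed`
#' (see [child_seed()]), so stages are reproducible in isolation.
#' Defaults emulate the study design at full scale; pass smaller
#' dimensions for desk-scale work.
#'
#' @param n_chrom,length_morgan,n_markers,spacing_cm Map parameters
#'   (see [build_map()]).
#' @param n_founders,ld_scale_cm,maf_min Founder-pool parameters.
#' @param n_sires,dams_per_sire,progeny_per_mating,phenotyped_per_family
#'   Pedigree parameters.
#' @param n_qtl,additive_sd,dominance_prob,dominance_sd Trait architecture.
#' @param h2,trait_mean Phenotype parameters.
#' @param seed Global integer seed.
#' @return A `population` with `qtl`, `tgv`, `tbv` and `phenotype`
#'   attached.
#' @export
simulate_population <- function(n_chrom = 5L, length_morgan = 1,
                                n_markers = 1998L, spacing_cm = 0.05,
                                n_founders = 400L, ld_scale_cm = 1.0,
                                maf_min = 0.05,
                                n_sires = 20L, dams_per_sire = 10L,
                                progeny_per_mating = 15L,
                                phenotyped_per_family = 10L,
                                n_qtl = 30L, additive_sd = 1,
                                dominance_prob = 0.3, dominance_sd = 0.5,
                                h2 = 0.5, trait_mean = 0, seed = 1L) {
  map <- build_map(n_chrom, length_morgan, n_markers, spacing_cm)
  founders <- simulate_founders(map, n_founders, ld_scale_cm, maf_min,
                                seed = child_seed(seed, "founders"))
  pop <- simulate_pedigree(map, founders, n_sires, dams_per_sire,
                           progeny_per_mating, phenotyped_per_family,
                           seed = child_seed(seed, "pedigree"))
  pop$qtl <- assign_qtl(map, n_qtl, additive_sd, dominance_prob,
                        dominance_sd, founder_freqs = founders$freqs,
                        seed = child_seed(seed, "qtl"))
  pop$tgv <- compute_tgv(pop, pop$qtl)
  pop$tbv <- compute_tbv(pop, pop$qtl)
  pop$phenotype <- simulate_phenotypes(pop, h2, trait_mean,
                                       seed = child_seed(seed, "phenotype"))
  pop$seed <- seed
  pop
}
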