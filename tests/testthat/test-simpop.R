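test_that("genome map lays out evenly spaced markers and rejects overflow", {
  m <- build_map(5, 1, 1998, 0.05)
  expect_equal(nrow(m$markers), 9990)
  expect_equal(length(m$chrom_index), 5)
  expect_equal(max(m$markers$pos_cm), 99.90)
  # positions strictly increasing within each chromosome
  for (idx in m$chrom_index)
    expect_true(all(diff(m$markers$pos_cm[idx]) > 0))
  expect_true(anyDuplicated(m$markers$marker_id) == 0)

  one <- build_map(1, 1, 1, 0.05)
  expect_equal(one$markers$pos_cm, 0.05)

  expect_error(build_map(1, 1, 3000, 0.05), "exceed")
})

test_that("founder LD decays with map distance and hits both limits", {
  map <- build_map(1, 1, 200, 0.05)   # 10 cM span
  r2 <- function(H, j, k) cor(H[, j], H[, k])^2

  # independence limit: ld_scale 0
  f0 <- simulate_founders(map, 500, ld_scale_cm = 0, seed = 1)
  r2s <- sapply(seq(1, 199, by = 10), function(j) r2(f0$haplotypes, j, j + 1))
  expect_lt(mean(r2s), 0.02)

  # copy limit: enormous scale shares one latent state along the
  # chromosome, so adjacent loci become strongly (comonotonically)
  # correlated -- far above the independence baseline
  fb <- simulate_founders(map, 300, ld_scale_cm = 1e6, seed = 2)
  r2b <- sapply(seq(1, 199, by = 10), function(j) r2(fb$haplotypes, j, j + 1))
  expect_gt(mean(r2b), 10 * mean(r2s))
  expect_gt(mean(r2b), 0.2)

  # decay: r2 at 0.05 cM gap exceeds r2 at 5 cM gap
  f1 <- simulate_founders(map, 2000, ld_scale_cm = 1.0, seed = 3)
  close_pairs <- sapply(seq(1, 180, by = 6),
                        function(j) r2(f1$haplotypes, j, j + 1))   # 0.05 cM
  far_pairs <- sapply(seq(1, 100, by = 6),
                      function(j) r2(f1$haplotypes, j, j + 100))  # 5 cM
  expect_gt(mean(close_pairs), mean(far_pairs))
})

test_that("meiosis follows the Haldane model", {
  map <- build_map(1, 1, 50, 2)   # markers at 2..100 cM, span 0.98 Morgan
  h1 <- rep(0L, 50); h2 <- rep(1L, 50)

  # crossover count: with opposite-allele parents, haplotype switches
  # along the gamete count the crossovers inside the marker span
  set.seed(42)
  n_m <- 4000
  switches <- replicate(n_m, {
    g <- meiosis(h1, h2, map)
    sum(diff(g) != 0)
  })
  expect_equal(mean(switches), 0.98, tolerance = 0.08)

  # recombinant fraction at 10 cM: Haldane r = (1 - exp(-0.2))/2 = 0.0906
  map2 <- build_map(1, 1, 2, 10)  # loci at 10 and 20 cM
  set.seed(7)
  rec <- replicate(10000, {
    g <- meiosis(c(0L, 0L), c(1L, 1L), map2)
    g[1] != g[2]
  })
  expect_equal(mean(rec), (1 - exp(-0.2)) / 2, tolerance = 0.12)

  # zero-crossover meioses reproduce a parental haplotype exactly
  set.seed(9)
  hA <- rbinom(50, 1, 0.5); hB <- rbinom(50, 1, 0.5)
  found_exact <- FALSE
  for (i in 1:50) {
    g <- meiosis(hA, hB, map)
    if (identical(g, as.integer(hA)) || identical(g, as.integer(hB))) {
      found_exact <- TRUE; break
    }
  }
  expect_true(found_exact)  # P(zero crossovers) = e^-1, 50 tries
})

test_that("gene dropping respects the pedigree and transmits parental alleles", {
  map <- build_map(2, 1, 40, 1)
  f <- simulate_founders(map, 50, 1, seed = 5)
  pop <- simulate_pedigree(map, f, n_sires = 3, dams_per_sire = 2,
                           progeny_per_mating = 4, phenotyped_per_family = 2,
                           seed = 6)
  ped <- pop$pedigree
  expect_equal(sum(ped$role == "progeny"), 24)
  expect_equal(sum(ped$phenotyped), 12)
  # one sire-dam pair per family, 2 phenotyped per family
  fams <- split(ped[ped$role == "progeny", ], ped$family_id[ped$role == "progeny"])
  for (fm in fams) {
    expect_equal(length(unique(fm$sire)), 1)
    expect_equal(length(unique(fm$dam)), 1)
    expect_equal(sum(fm$phenotyped), 2)
  }
  # every progeny allele is a mosaic of its named parents' haplotypes
  rows <- which(ped$role == "progeny")
  for (r in rows[1:8]) {
    si <- match(ped$sire[r], ped$id); di <- match(ped$dam[r], ped$id)
    expect_true(all(pop$hap1[r, ] == pop$hap1[si, ] |
                    pop$hap1[r, ] == pop$hap2[si, ]))
    expect_true(all(pop$hap2[r, ] == pop$hap1[di, ] |
                    pop$hap2[r, ] == pop$hap2[di, ]))
  }
  # parent roles never overlap
  expect_error(simulate_pedigree(map, f, n_sires = 30, dams_per_sire = 2,
                                 progeny_per_mating = 2,
                                 phenotyped_per_family = 1, seed = 1),
               "founder pool too small")
})

test_that("QTL assignment matches its declared distributions", {
  map <- build_map(1, 1, 50, 1)
  expect_error(assign_qtl(map, 51), "exceeds")

  q0 <- assign_qtl(map, 10, dominance_prob = 0, seed = 3)
  expect_true(all(q0$d == 0))

  # moment check on many draws
  qb <- assign_qtl(build_map(1, 1, 1998, 0.05), 1500, additive_sd = 0.7,
                   dominance_prob = 1, dominance_sd = 0.3, seed = 4)
  expect_equal(sd(qb$a), 0.7, tolerance = 0.05)
  expect_equal(sd(qb$d), 0.3, tolerance = 0.05)
})

test_that("TGV and TBV follow their genetic definitions", {
  # single-locus population with genotypes 1, 0, -1 built by hand
  map <- build_map(1, 1, 1, 0.05)
  pop <- structure(list(
    map = map,
    pedigree = data.frame(id = c("a", "b", "c"), sire = NA, dam = NA,
                          family_id = "f", phenotyped = TRUE,
                          role = "progeny", stringsAsFactors = FALSE),
    hap1 = matrix(c(1L, 1L, 0L), 3, 1), hap2 = matrix(c(1L, 0L, 0L), 3, 1)
  ), class = "population")
  qtl <- structure(data.frame(marker_index = 1L, marker_id = "M1_1",
                              a = 2, d = 0.5, p = 0.3),
                   class = c("qtl_model", "data.frame"))
  tgv <- compute_tgv(pop, qtl)
  expect_equal(unname(tgv), c(2, 0.5, -2))

  # TBV against a progeny-simulation oracle: expected progeny-mean
  # deviation from the population mean equals TBV/2 under random mating
  p_f <- 0.3; a <- 1; d <- 0.4
  qtl2 <- structure(data.frame(marker_index = 1L, marker_id = "M1_1",
                               a = a, d = d, p = p_f),
                    class = c("qtl_model", "data.frame"))
  tbv <- compute_tbv(pop, qtl2, freqs = p_f)
  set.seed(11)
  nprog <- 2e5
  gval <- function(cnt) ifelse(cnt == 2, a, ifelse(cnt == 1, d, -a))
  prog_mean <- sapply(c(2, 1, 0), function(cnt) {
    from_parent <- rbinom(nprog, 1, cnt / 2)
    from_mate <- rbinom(nprog, 1, p_f)
    mean(gval(from_parent + from_mate))
  })
  # population mean of progeny under HWE at freq p_f
  hw <- c(p_f^2, 2 * p_f * (1 - p_f), (1 - p_f)^2)
  pop_mean <- sum(hw * gval(c(2, 1, 0)))
  expect_equal(unname(tbv), 2 * (prog_mean - pop_mean), tolerance = 0.02)

  # additive limit: TGV and TBV perfectly correlated
  popn <- make_tiny_population(seed = 21, dominance_prob = 0)
  expect_equal(cor(popn$tgv, popn$tbv), 1, tolerance = 1e-12)

  # p = 0.5 makes the substitution effect equal a even with dominance
  tbv_half <- compute_tbv(pop, qtl2, freqs = 0.5)
  expect_equal(unname(diff(tbv_half)), c(-a, -a))
})

test_that("phenotypes hit the requested heritability", {
  pop <- make_tiny_population(seed = 31)
  # h2 = 1: phenotype equals TGV exactly
  y1 <- simulate_phenotypes(pop, h2 = 1, trait_mean = 5, seed = 1)
  expect_equal(unname(y1), unname(pop$tgv[names(y1)]) + 5)

  # realized variance ratio near target on a larger population
  big <- simulate_population(n_chrom = 1, n_markers = 60, spacing_cm = 1,
                             n_founders = 250, n_sires = 20,
                             dams_per_sire = 5, progeny_per_mating = 10,
                             phenotyped_per_family = 10, n_qtl = 15,
                             h2 = 0.5, seed = 41)
  ph <- names(big$phenotype)
  e <- big$phenotype - big$tgv[ph]
  ratio <- var(big$tgv[ph]) / (var(big$tgv[ph]) + var(e))
  expect_equal(ratio, 0.5, tolerance = 0.06)
  # regression slope of y on TGV near 1
  slope <- coef(lm(big$phenotype ~ big$tgv[ph]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)

  expect_error(simulate_phenotypes(pop, h2 = 0), "h2")
  expect_error(simulate_phenotypes(pop, h2 = 1.2), "h2")
})

test_that("simulation is bit-reproducible given (config, seed)", {
  a <- make_tiny_population(seed = 55)
  b <- make_tiny_population(seed = 55)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$qtl, b$qtl)
  c <- make_tiny_population(seed = 56)
  expect_false(identical(a$phenotype, c$phenotype))
})
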