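test_that("simConfig enforces its invariants", {
  expect_error(simConfig(n_generations = 0), "n_generations")
  expect_error(simConfig(markers_per_chromosome = 1), "markers_per_chromosome")
  expect_error(simConfig(missing_rate = 1), "missing_rate")
  expect_error(simConfig(variance_components = c(sigma2_A = -1, sigma2_PE = 0,
                                                 sigma2_SH = 0, sigma2_E = 1)),
               "variances")
})

test_that("simulated pedigrees order parents first and are reproducible", {
  cfg <- tiny_config()
  ped <- simulatePedigree(cfg, seed = 5)
  tab <- pedigreeTable(ped)
  pos <- setNames(seq_len(nrow(tab)), tab$id)
  for (i in seq_len(nrow(tab))) {
    for (p in c(tab$sire[i], tab$dam[i]))
      if (p != "0") expect_lt(pos[[p]], i)
  }
  founders <- tab$sire == "0" & tab$dam == "0"
  expect_identical(sum(founders), cfg$n_founders)
  expect_true(all(tab$generation[founders] == 0L))
  ped2 <- simulatePedigree(cfg, seed = 5)
  expect_identical(pedigreeTable(ped2), tab)
  ## founders-only pedigree is non-inbred
  expect_true(all(inbreeding(Pedigree(1:5, rep(0, 5), rep(0, 5))) == 0))
})

test_that("founder panels have high within-block LD and low between-block LD", {
  cfg <- tiny_config(seed = 21)
  panel <- simulateFounderHaplotypes(cfg)
  g <- gametes(panel)
  map <- markerMap(panel)
  poly <- apply(g, 2, function(x) mean(x) > 0 && mean(x) < 1)
  within <- c(); between <- c()
  for (j in 2:nrow(map)) {
    i <- j - 1
    if (!poly[i] || !poly[j] || map$chrom[i] != map$chrom[j]) next
    r2 <- oracle_r2(g, i, j)
    if (map$block[i] == map$block[j]) within <- c(within, r2)
    else between <- c(between, r2)
  }
  ## counting-oracle check over many pairs plus lots of random distant pairs
  set.seed(1)
  for (rep in 1:1000) {
    ij <- sample(which(poly), 2)
    r2a <- oracle_r2(g, ij[1], ij[2])
    if (map$chrom[ij[1]] == map$chrom[ij[2]])
      expect_equal(pairwiseR2(panel, ij[1], ij[2]), r2a, tolerance = 1e-12)
    if (map$chrom[ij[1]] != map$chrom[ij[2]] ||
        map$block[ij[1]] != map$block[ij[2]])
      between <- c(between, r2a)
  }
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.5)
  expect_lt(mean(between), 0.2)
})

test_that("degenerate ancestral pools behave as expected", {
  cfg <- tiny_config(n_ancestral_alleles = 1)
  panel <- simulateFounderHaplotypes(cfg, seed = 3)
  d <- dosages(panel)
  ## one ancestral allele per block: every marker monomorphic
  expect_true(all(apply(d, 2, function(x) length(unique(x)) == 1)))
  ## two complementary ancestral alleles: within-block r2 is exactly 1
  cfg2 <- tiny_config(n_ancestral_alleles = 2, block_split_prob = 1)
  panel2 <- simulateFounderHaplotypes(cfg2, seed = 4)
  g <- gametes(panel2)
  map <- markerMap(panel2)
  poly <- apply(g, 2, function(x) mean(x) > 0 && mean(x) < 1)
  blocks <- split(seq_len(nrow(map)), map$block)
  checked <- 0
  for (b in blocks) {
    b <- b[poly[b]]
    if (length(b) < 2) next
    for (k in 2:length(b)) {
      expect_equal(pairwiseR2(panel2, b[1], b[k]), 1, tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("gene drop transmits intact gametes without recombination", {
  cfg <- tiny_config(seed = 31)
  ped <- simulatePedigree(cfg)
  founders <- simulateFounderHaplotypes(cfg)
  panel <- geneDrop(ped, founders, recomb_rate_per_bp = 0, seed = 9)
  g <- gametes(panel)
  tab <- pedigreeTable(validatePedigree(ped))
  pos <- setNames(seq_len(nrow(tab)), tab$id)
  map <- markerMap(panel)
  non_founders <- which(tab$sire != "0")
  ## chromosomes assort independently, but within a chromosome the
  ## transmitted gamete is one intact parental haplotype
  for (i in sample(non_founders, 10)) {
    si <- pos[[tab$sire[i]]]
    for (ch in unique(map$chrom)) {
      j <- map$chrom == ch
      paternal <- g[2 * i - 1, j]
      expect_true(identical(paternal, g[2 * si - 1, j]) ||
                  identical(paternal, g[2 * si, j]))
    }
  }
})

test_that("gene drop is Mendelian-consistent and preserves allele frequencies", {
  ## drift check uses one generation of random mating so the binomial
  ## sampling bound applies without strong family correlation
  cfg <- simConfig(n_founders = 300, n_generations = 1, sire_ratio = 1,
                   n_chromosomes = 2, markers_per_chromosome = 60,
                   n_qtl = 8, seed = 41)
  ped <- validatePedigree(simulatePedigree(cfg))
  founders <- simulateFounderHaplotypes(cfg)
  tab <- pedigreeTable(ped)
  outside <- 0L; total <- 0L
  for (rep in 1:3) {
    panel <- geneDrop(ped, founders, seed = rep)
    d <- dosages(panel)
    ## zero opposing homozygotes between offspring and each parent
    for (i in which(tab$sire != "0")) {
      for (p in c(tab$sire[i], tab$dam[i])) {
        pi <- match(p, tab$id)
        expect_identical(sum(d[i, ] == 0L & d[pi, ] == 2L) +
                         sum(d[i, ] == 2L & d[pi, ] == 0L), 0L)
      }
    }
    ## drift of descendant allele frequency stays within 3 binomial SDs
    desc <- tab$generation == max(tab$generation)
    p0 <- colMeans(dosages(founders)) / 2
    p1 <- colMeans(d[desc, , drop = FALSE]) / 2
    sdv <- sqrt(pmax(p0 * (1 - p0), 1e-12) / (2 * sum(desc)))
    poly <- p0 > 0 & p0 < 1
    outside <- outside + sum(abs(p1 - p0)[poly] > 3 * sdv[poly])
    total <- total + sum(poly)
  }
  expect_gte(1 - outside / total, 0.99)
})

test_that("QTL effects are additive and recover the target genetic variance", {
  cfg <- tiny_config(seed = 51)
  ped <- simulatePedigree(cfg)
  founders <- simulateFounderHaplotypes(cfg)
  panel <- geneDrop(ped, founders, seed = 2)
  ## zero effect size gives zero breeding values
  cfg0 <- tiny_config(seed = 51, qtl_effect_sd = 0)
  tv0 <- assignQtlEffects(panel, cfg0, seed = 1)
  expect_true(all(tv0$tbv == 0))
  ## single-QTL additivity: tbv is dosage times effect
  tv <- assignQtlEffects(panel, cfg, seed = 3)
  d <- dosages(panel)[, tv$qtl_idx, drop = FALSE]
  expect_equal(unname(tv$tbv), unname(drop(d %*% tv$qtl_effects)),
               tolerance = 1e-12)
  ## HWE additive variance: empirical var(tbv) close to 2 sum p q beta^2
  ratio <- replicate(10, {
    tvr <- assignQtlEffects(panel, cfg, seed = sample.int(1e6, 1))
    dr <- dosages(panel)[, tvr$qtl_idx, drop = FALSE]
    p <- colMeans(dr) / 2
    var(tvr$tbv) / (2 * sum(p * (1 - p) * tvr$qtl_effects^2))
  })
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("age classes reproduce the lactation-specific cutoffs", {
  expect_identical(ageToClass(1, 23.0), 1L)
  expect_identical(ageToClass(1, 23.4), 1L)
  expect_identical(ageToClass(1, 23.5), 2L)
  expect_identical(ageToClass(1, 25.6), 3L)
  expect_identical(ageToClass(2, 35.9), 4L)
  expect_identical(ageToClass(2, 36.5), 5L)
  expect_identical(ageToClass(2, 39.6), 6L)
  expect_identical(ageToClass(3, 48.0), 7L)
  expect_identical(ageToClass(3, 50.0), 8L)
  expect_identical(ageToClass(3, 60.0), 9L)
  expect_identical(ageToClass(c(1, 2, 3), c(24, 37, 54)), c(2L, 5L, 9L))
  expect_error(ageToClass(4, 30), "lactation")
  expect_error(ageToClass(1, -1), "positive")
})

test_that("somatic cell score anchors at 12.5 and doubles per point to 9", {
  expect_identical(sccToScs(12.5), 0L)
  expect_identical(sccToScs(6400), 9L)
  expect_identical(sccToScs(50), 2L)
  expect_identical(sccToScs(100000), 9L)  # clamped above
  expect_identical(sccToScs(1), 0L)       # clamped below
  expect_identical(sccToScs(12.5 * 2^(0:9)), 0:9)
  expect_error(sccToScs(0), "positive")
})

test_that("phenotypes follow the record model and its noiseless limit", {
  cfg <- tiny_config(seed = 61,
                     variance_components = c(sigma2_A = 0.3, sigma2_PE = 0,
                                             sigma2_SH = 0, sigma2_E = 0),
                     hys_effect_sd = 0, age_effect_sd = 0, mu = 10)
  ped <- simulatePedigree(cfg)
  founders <- simulateFounderHaplotypes(cfg)
  panel <- geneDrop(ped, founders, seed = 1)
  tv <- assignQtlEffects(panel, cfg, seed = 2)
  ph <- simulatePhenotypes(ped, tv, cfg, seed = 3)
  expect_equal(ph$y, 10 + unname(tv$tbv[ph$animal]), tolerance = 1e-12)
  expect_identical(ph$age_class, ageToClass(ph$lactation, ph$age_months))
  ## repeated records per cow share the permanent-environment deviation:
  ## with only PE variance on, within-cow record differences are zero
  cfg2 <- tiny_config(seed = 61,
                      variance_components = c(sigma2_A = 0.3, sigma2_PE = 0.4,
                                              sigma2_SH = 0, sigma2_E = 0),
                      hys_effect_sd = 0, age_effect_sd = 0)
  ph2 <- simulatePhenotypes(ped, tv, cfg2, seed = 4)
  spread <- tapply(ph2$y, ph2$animal, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("phenotype variance components are recoverable by moments", {
  vc <- c(sigma2_A = 0.5, sigma2_PE = 0.3, sigma2_SH = 0, sigma2_E = 0.7)
  ests <- sapply(1:4, function(s) {
    cfg <- simConfig(n_founders = 600, n_generations = 1, n_chromosomes = 1,
                     markers_per_chromosome = 40, n_qtl = 10,
                     variance_components = vc, hys_effect_sd = 0,
                     age_effect_sd = 0, seed = s)
    ped <- simulatePedigree(cfg)
    founders <- simulateFounderHaplotypes(cfg)
    panel <- geneDrop(ped, founders, seed = s)
    tv <- assignQtlEffects(panel, cfg, seed = s + 100)
    ph <- simulatePhenotypes(ped, tv, cfg, seed = s + 200)
    s2e <- mean(tapply(ph$y, ph$animal, var))
    means <- tapply(ph$y, ph$animal, mean)
    nrec <- mean(table(ph$animal))
    s2a <- var(tv$tbv[names(means)])
    s2pe <- var(means) - s2e / nrec - s2a
    c(A = s2a, PE = s2pe, E = s2e)
  })
  est <- rowMeans(ests)
  expect_lt(abs(est[["A"]] / vc[["sigma2_A"]] - 1), 0.15)
  expect_lt(abs(est[["PE"]] / vc[["sigma2_PE"]] - 1), 0.15)
  expect_lt(abs(est[["E"]] / vc[["sigma2_E"]] - 1), 0.15)
})

test_that("missingness injection is uniform, seeded, and leaves the panel intact", {
  cfg <- tiny_config()
  panel <- simulateFounderHaplotypes(cfg, seed = 2)
  g0 <- injectMissingness(panel, 0, seed = 1)
  expect_identical(g0@dosages, unname(dosages(panel)))
  gm <- injectMissingness(panel, 0.5, seed = 7)
  n <- length(gm@dosages)
  frac <- mean(gm@dosages == 5L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  expect_identical(injectMissingness(panel, 0.5, seed = 7)@dosages, gm@dosages)
  expect_error(injectMissingness(panel, 1), "rate")
})

test_that("dataset simulation is deterministic in the master seed", {
  cfg <- tiny_config(seed = 77, missing_rate = 0.02)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$genotypes@dosages, d2$genotypes@dosages)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth, d2$truth)
})

test_that("config YAML round-trips", {
  cfg <- tiny_config(seed = 5, missing_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".yml")
  writeSimConfig(cfg, path)
  cfg2 <- readSimConfig(path)
  expect_equal(cfg2, cfg)
})
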