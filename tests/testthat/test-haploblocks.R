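## Panels with exactly known haplotype composition for LD arithmetic
panel_from_gametes <- function(g, bp = NULL) {
  m <- ncol(g)
  if (is.null(bp)) bp <- seq_len(m) * 1e4
  HaplotypePanel(g, as.character(seq_len(nrow(g) / 2)),
                 data.frame(chrom = 1L, id = paste0("m", seq_len(m)), bp = bp))
}

test_that("pairwise r-squared matches haplotype-frequency arithmetic", {
  ## identical columns
  g <- cbind(rep(c(1L, 0L), 10), rep(c(1L, 0L), 10))
  expect_equal(pairwiseR2(panel_from_gametes(g), 1, 2), 1)
  ## two-haplotype system AB/ab at 50/50
  g <- rbind(matrix(1L, 10, 2), matrix(0L, 10, 2))
  expect_equal(pairwiseR2(panel_from_gametes(g), 1, 2), 1)
  ## all four haplotypes at 25 percent: independence
  g <- cbind(rep(c(1L, 1L, 0L, 0L), 5), rep(c(1L, 0L, 1L, 0L), 5))
  expect_equal(pairwiseR2(panel_from_gametes(g), 1, 2), 0)
  ## random 200-chromosome panel vs the counting oracle
  set.seed(42)
  for (rep in 1:20) {
    g <- matrix(rbinom(400, 1, runif(1, 0.2, 0.8)), 200, 2)
    if (any(colMeans(g) %in% c(0, 1))) next
    p <- panel_from_gametes(g)
    expect_equal(pairwiseR2(p, 1, 2), oracle_r2(g, 1, 2), tolerance = 1e-12)
  }
  expect_error(pairwiseR2(panel_from_gametes(cbind(rep(1L, 20), rep(c(0L, 1L), 10))), 1, 2),
               "monomorphic")
})

test_that("block detection honours the all-pairs rule and the span cap", {
  ## three markers in complete LD, 10 kb apart: one block of three
  g3 <- rbind(matrix(1L, 12, 3), matrix(0L, 8, 3))
  b <- detectBlocks(panel_from_gametes(g3))
  expect_identical(nrow(b), 1L)
  expect_identical(b$n_snps, 3L)
  ## r2(1,2) and r2(2,3) high but r2(1,3) low: all-pairs keeps only {1,2}
  h <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 0), c(0, 0, 1), c(0, 0, 0),
             c(0, 0, 0), c(1, 1, 1), c(0, 0, 1), c(1, 1, 0), c(0, 0, 0))
  g <- matrix(0L, 40, 3)
  set.seed(7)
  pick <- sample(nrow(h), 40, replace = TRUE)
  g[] <- as.integer(h[pick, ])
  p <- panel_from_gametes(g)
  r12 <- pairwiseR2(p, 1, 2); r13 <- pairwiseR2(p, 1, 3)
  expect_gte(r12, 0.8)
  expect_lt(r13, 0.8)
  b <- detectBlocks(p)
  expect_identical(b$n_snps, 2L)
  expect_identical(b$members[[1]], c(1L, 2L))
  ## adjacent-pair mode accepts the full chain when adjacent r2 passes
  if (pairwiseR2(p, 2, 3) >= 0.8)
    expect_identical(detectBlocks(p, pair_mode = "adjacent")$n_snps, 3L)
  ## span cap: complete LD but 300 kb apart is no block
  b <- detectBlocks(panel_from_gametes(g3, bp = c(1, 3e5, 6e5)))
  expect_identical(nrow(b), 0L)
})

test_that("block detection equals the exhaustive oracle on random panels", {
  set.seed(2024)
  for (rep in 1:200) {
    panel <- random_panel(n = 25, m = 20, pool = sample(2:5, 1))
    got <- detectBlocks(panel)
    want <- oracle_blocks(panel)
    expect_identical(nrow(got), length(want))
    if (length(want))
      expect_identical(unname(unclass(got$members)), unname(want))
  }
})

test_that("block detection is invariant to animal ordering", {
  panel <- random_panel(n = 40, m = 20, seed = 5, pool = 3)
  ord <- sample(animalIds(panel))
  shuffled <- subsetGenotypes(panel, animals = ord)
  b1 <- detectBlocks(panel)
  b2 <- detectBlocks(shuffled)
  expect_identical(b1$members, b2$members)
})

test_that("haplotype alleles partition the chromosomes of a block", {
  ## 2-SNP block with chromosomes AB, AB, ab, ab
  g <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  panel <- panel_from_gametes(g)
  al <- enumerateHaplotypeAlleles(panel, c(1L, 2L))
  expect_identical(al$allele_string, c("11", "22"))
  expect_equal(al$frequency, c(0.5, 0.5))
  ## monomorphic block: a single allele at frequency 1
  gm <- matrix(1L, 8, 2)
  expect_equal(enumerateHaplotypeAlleles(panel_from_gametes(gm), 1:2)$frequency, 1)
  ## frequencies always sum to one
  p <- random_panel(n = 30, m = 6, seed = 9, pool = 4)
  expect_equal(sum(enumerateHaplotypeAlleles(p, 1:6)$frequency), 1)
})

test_that("pseudo-SNP dosages count copies of each haplotype allele", {
  ## animal 1 = AB/AB, animal 2 = AB/ab, animal 3 = ab/ab
  g <- rbind(c(1L, 1L), c(1L, 1L),
             c(1L, 1L), c(0L, 0L),
             c(0L, 0L), c(0L, 0L))
  panel <- panel_from_gametes(g)
  blocks <- detectBlocks(panel)
  ps <- encodePseudoSnps(panel, blocks, freq_min = 0)
  d <- dosages(ps)
  pr <- provenance(ps)
  ab <- which(pr$allele_string == "22")
  expect_identical(unname(d[, ab]), c(2L, 1L, 0L))
  expect_identical(unname(d[, pr$allele_string == "11"]), c(0L, 1L, 2L))
  ## conservation: per-animal per-block sums equal 2 with no filtering
  expect_true(all(rowSums(d) == 2L))
})

test_that("rare haplotype alleles are dropped by the one-percent rule", {
  set.seed(31)
  ## 200 chromosomes: allele 'ab' at frequency 0.5 percent
  g <- rbind(matrix(1L, 199, 2), c(0L, 0L))
  panel <- HaplotypePanel(g[sample(200), ], as.character(1:100),
                          data.frame(chrom = 1L, id = c("m1", "m2"), bp = c(1e4, 2e4)))
  al <- enumerateHaplotypeAlleles(panel, 1:2)
  expect_equal(min(al$frequency), 0.005)
  blocks <- data.frame(chrom = 1L, first = 1L, last = 2L, start_bp = 1e4,
                       end_bp = 2e4, span_bp = 1e4, n_snps = 2L)
  blocks$members <- I(list(1:2))
  ps <- encodePseudoSnps(panel, blocks, freq_min = 0.01)
  expect_identical(ncol(dosages(ps)), 1L)
  expect_true(all(rowSums(dosages(ps)) <= 2L))
  ## a retained pseudo-SNP treated as a biallelic locus reproduces the
  ## haplotype-allele frequency
  expect_equal(unname(alleleFrequency(dosages(ps)[, 1])[["p"]]),
               provenance(ps)$frequency[1])
})

test_that("pseudo-SNP conservation holds on simulated panels", {
  cfg <- tiny_config(seed = 71)
  ds <- simulateDataset(cfg)
  blocks <- detectBlocks(ds$genotyped_panel)
  expect_gt(nrow(blocks), 3)
  ps0 <- encodePseudoSnps(ds$genotyped_panel, blocks, freq_min = 0)
  pr <- provenance(ps0)
  d <- dosages(ps0)
  for (b in unique(pr$block)) {
    sums <- rowSums(d[, pr$block == b, drop = FALSE])
    expect_true(all(sums == 2L))
  }
  ps1 <- encodePseudoSnps(ds$genotyped_panel, blocks, freq_min = 0.01)
  pr1 <- provenance(ps1)
  d1 <- dosages(ps1)
  for (b in unique(pr1$block))
    expect_true(all(rowSums(d1[, pr1$block == b, drop = FALSE]) <= 2L))
})

test_that("the SNP-HAP subset is the ordered union of block members", {
  some <- detectBlocks(random_panel(10, 6, seed = 1, pool = 2))
  expect_identical(selectHapSnps(some[0, ]), integer(0))
  blocks <- data.frame(n_snps = c(2L, 3L))
  blocks$members <- I(list(c(4L, 5L), c(9L, 10L, 11L)))
  expect_identical(selectHapSnps(blocks), c(4L, 5L, 9L, 10L, 11L))
  ## union over simulated blocks, sorted and unique
  cfg <- tiny_config(seed = 81)
  panel <- simulateFounderHaplotypes(cfg)
  b <- detectBlocks(panel)
  idx <- selectHapSnps(b)
  expect_identical(idx, sort(unique(idx)))
  expect_identical(length(idx), sum(b$n_snps))
})

test_that("block summaries agree with an independent recount", {
  blocks <- data.frame(chrom = c(1, 1), n_snps = c(2L, 4L),
                       span_bp = c(1000, 3000))
  blocks$members <- I(list(1:2, 4:7))
  s <- blockSummary(blocks)$overall
  expect_equal(s$snps_mean, 3)
  expect_identical(s$snps_min, 2L)
  expect_identical(s$snps_max, 4L)
  expect_identical(blockSummary(blocks[0, ])$overall$n_blocks, 0L)
  cfg <- tiny_config(seed = 91)
  panel <- simulateFounderHaplotypes(cfg)
  b <- detectBlocks(panel)
  s <- blockSummary(b)
  expect_identical(s$overall$n_blocks, nrow(b))
  expect_equal(s$overall$snps_mean, mean(lengths(b$members)))
  expect_identical(sum(s$per_chromosome$n_blocks), nrow(b))
})

test_that("blocks export as BED-like text with allele frequencies", {
  cfg <- tiny_config(seed = 15)
  panel <- simulateFounderHaplotypes(cfg)
  b <- detectBlocks(panel)
  path <- withr::local_tempfile()
  writeBlocksBed(panel, b, path)
  lines <- readLines(path)
  expect_identical(length(lines), nrow(b))
  first <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.numeric(first[2]), b$start_bp[1])
  expect_equal(as.integer(first[4]), b$n_snps[1])
})
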