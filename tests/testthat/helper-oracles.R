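## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths.

## r-squared by direct 2x2 haplotype counting on a gamete matrix
oracle_r2 <- function(g, i, j) {
  a <- g[, i]; b <- g[, j]
  n <- length(a)
  nAB <- sum(a == 1 & b == 1)
  pA <- sum(a) / n; pB <- sum(b) / n
  D <- nAB / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## exhaustive left-to-right partition into maximal contiguous runs whose
## pairs all satisfy r2 >= r2_min within the span cap; every candidate run
## is verified by checking all pairs from scratch
oracle_blocks <- function(panel, r2_min = 0.80, min_snps = 2, max_span_kb = 200) {
  g <- gametes(panel)
  map <- markerMap(panel)
  poly <- apply(g, 2, function(x) {
    p <- mean(x); p > 0 && p < 1
  })
  run_ok <- function(idx) {
    if (map$bp[idx[length(idx)]] - map$bp[idx[1]] > max_span_kb * 1000) return(FALSE)
    if (length(unique(map$chrom[idx])) > 1) return(FALSE)
    if (!all(poly[idx])) return(FALSE)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      if (oracle_r2(g, idx[a], idx[b]) < r2_min) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    s <- 1
    while (s <= length(idx)) {
      best <- 0
      for (e in s:length(idx)) {
        if (run_ok(idx[s:e])) best <- e else break
      }
      if (best >= s && (best - s + 1) >= min_snps)
        out[[length(out) + 1]] <- idx[s:best]
      s <- if (best >= s) best + 1 else s + 1
    }
  }
  out
}

## random pedigree with valid parent ordering (returns a Pedigree, shuffled)
random_pedigree <- function(n, p_founder = 0.3) {
  id <- as.character(seq_len(n))
  sire <- dam <- rep("0", n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  for (i in 3:n) {
    if (runif(1) < p_founder) next
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    if (!length(males) || !length(females)) next
    sire[i] <- id[sample(males, 1)]
    dam[i] <- id[sample(females, 1)]
  }
  ord <- sample.int(n)
  Pedigree(id[ord], sire[ord], dam[ord], sex = sex[ord])
}

## tiny random phased panel: m markers on one chromosome, n animals,
## drawn from a pool of founder haplotypes to create LD runs
random_panel <- function(n = 30, m = 20, seed = NULL, pool = 6,
                         bp_step = 2e4) {
  if (!is.null(seed)) set.seed(seed)
  hapstrings <- matrix(rbinom(pool * m, 1, 0.5), pool, m)
  pick <- sample.int(pool, 2 * n, replace = TRUE)
  al <- hapstrings[pick, , drop = FALSE]
  map <- data.frame(chrom = 1L, id = paste0("m", seq_len(m)),
                    bp = cumsum(sample(round(bp_step * c(0.5, 1, 4)), m, replace = TRUE)))
  HaplotypePanel(al, as.character(seq_len(n)), map)
}

## small config used by several module tests
tiny_config <- function(seed = 11, ...) {
  simConfig(n_founders = 40, n_generations = 2, n_chromosomes = 2,
            markers_per_chromosome = 60, n_qtl = 8, seed = seed, ...)
}
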