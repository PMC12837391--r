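## Synthetic population generator: multi-generation pedigree, founder
## haplotypes with block-wise high LD, gene dropping with recombination,
## additive QTL, and repeated lactation records with herd-year-season,
## age-class, permanent-environment and sire-herd effects.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-population generator. Defaults are
#' the desk-scale study conditions used throughout the test-suite: a
#' five-cohort pedigree, three chromosomes whose markers come in ancestral
#' LD blocks averaging ~3.5 SNPs (block spans of a few tens of kb separated
#' by wide gaps), an additive trait with repeatability-model variance
#' structure and heritability 0.30.
#'
#' @param n_founders founders in generation 0.
#' @param n_generations generations bred after the founders.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome (>= 2).
#' @param chromosome_length_bp approximate physical length; between-block
#'   gaps are scaled so the chromosome ends near this length.
#' @param mean_block_snps mean SNPs per ancestral LD block (>= 1).
#' @param n_ancestral_alleles distinct founder haplotype alleles per block.
#' @param block_split_prob probability that a block marker follows the
#'   block's primary bipartition of the ancestral pool; markers following
#'   the primary split are in complete LD with one another.
#' @param recomb_rate_per_bp recombination rate (Morgans per bp).
#' @param n_qtl number of additive QTL sampled among markers.
#' @param qtl_effect_sd per-allele effect SD in trait units, or NULL
#'   (default) to rescale a standard-normal draw so the Hardy-Weinberg
#'   additive variance of the QTL equals \code{sigma2_A}.
#' @param qtl_in_blocks place QTL only on markers inside multi-SNP blocks.
#' @param variance_components named numeric: sigma2_A, sigma2_PE, sigma2_SH,
#'   sigma2_E (trait units squared, all >= 0).
#' @param mu overall trait mean.
#' @param hys_effect_sd,age_effect_sd SDs of the simulated fixed
#'   herd-year-season and age-class effects.
#' @param n_herds,n_years herd and birth-year structure of the records.
#' @param lactations_per_cow records per cow (1 to 3).
#' @param missing_rate fraction of dosage entries masked as missing.
#' @param sire_ratio fraction of available males used as sires each
#'   generation.
#' @param genotyped_generations how many of the youngest generations are
#'   genotyped.
#' @param seed master seed; all RNG streams derive from it.
#' @return A list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(n_founders = 20, n_generations = 2,
#'                  markers_per_chromosome = 30, n_chromosomes = 1)
#' @export
simConfig <- function(n_founders = 100, n_generations = 4,
                      n_chromosomes = 3, markers_per_chromosome = 200,
                      chromosome_length_bp = 2.5e7,
                      mean_block_snps = 3.5, n_ancestral_alleles = 4,
                      block_split_prob = 0.85,
                      recomb_rate_per_bp = 1e-8,
                      n_qtl = 20, qtl_effect_sd = NULL, qtl_in_blocks = TRUE,
                      variance_components = c(sigma2_A = 0.30, sigma2_PE = 0.15,
                                              sigma2_SH = 0.05, sigma2_E = 0.50),
                      mu = 0, hys_effect_sd = 0.5, age_effect_sd = 0.2,
                      n_herds = 8, n_years = 6, lactations_per_cow = 3,
                      missing_rate = 0, sire_ratio = 0.25,
                      genotyped_generations = 2, seed = 1L) {
  vc <- variance_components
  req <- c("sigma2_A", "sigma2_PE", "sigma2_SH", "sigma2_E")
  if (!all(req %in% names(vc))) stop("variance_components must name ", paste(req, collapse = ", "))
  if (any(vc < 0)) stop("all variances must be >= 0")
  if (markers_per_chromosome < 2) stop("markers_per_chromosome must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (mean_block_snps < 1) stop("mean_block_snps must be >= 1")
  if (n_ancestral_alleles < 1) stop("n_ancestral_alleles must be >= 1")
  if (lactations_per_cow < 1 || lactations_per_cow > 3)
    stop("lactations_per_cow must be 1..3")
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              chromosome_length_bp = chromosome_length_bp,
              mean_block_snps = mean_block_snps,
              n_ancestral_alleles = as.integer(n_ancestral_alleles),
              block_split_prob = block_split_prob,
              recomb_rate_per_bp = recomb_rate_per_bp,
              n_qtl = as.integer(n_qtl), qtl_effect_sd = qtl_effect_sd,
              qtl_in_blocks = isTRUE(qtl_in_blocks),
              variance_components = vc[req], mu = mu,
              hys_effect_sd = hys_effect_sd, age_effect_sd = age_effect_sd,
              n_herds = as.integer(n_herds), n_years = as.integer(n_years),
              lactations_per_cow = as.integer(lactations_per_cow),
              missing_rate = missing_rate, sire_ratio = sire_ratio,
              genotyped_generations = as.integer(genotyped_generations),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Read / write a simulation configuration as YAML
#' @param path file path.
#' @param config a \code{SimConfig}.
#' @return \code{readSimConfig} returns a validated \code{SimConfig}.
#' @export
readSimConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$variance_components))
    raw$variance_components <- unlist(raw$variance_components)
  do.call(simConfig, raw)
}

#' @rdname readSimConfig
#' @export
writeSimConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$variance_components <- as.list(cfg$variance_components)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## Derive deterministic child seeds from a master seed.
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0, unknown parents) are split evenly between sexes;
#' each later generation has \code{n_founders} offspring whose dams are
#' drawn from the previous generation's females and whose sires are drawn
#' from a restricted pool (fraction \code{sire_ratio}) of earlier males,
#' emulating the narrow sire usage of dairy populations.
#'
#' @param config a \code{SimConfig}.
#' @param seed optional seed (defaults to the config master seed stream).
#' @return A \linkS4class{Pedigree}, parents always preceding offspring.
#' @export
simulatePedigree <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- .childSeeds(config$seed, 8)[1]
  .withSeed(seed, {
    nf <- config$n_founders
    id <- as.character(seq_len(nf))
    sire <- dam <- rep("0", nf)
    sex <- rep(c("M", "F"), length.out = nf)
    gen <- rep(0L, nf)
    nxt <- nf + 1L
    for (g in seq_len(config$n_generations)) {
      males <- id[sex == "M" & gen < g]
      females <- id[sex == "F" & gen == g - 1L]
      if (!length(females)) females <- id[sex == "F"]
      nsire <- max(1L, round(length(males) * config$sire_ratio))
      pool <- sample(males, nsire)
      n_off <- config$n_founders
      off_id <- as.character(seq(nxt, nxt + n_off - 1L))
      nxt <- nxt + n_off
      off_sire <- sample(pool, n_off, replace = TRUE)
      off_dam <- sample(females, n_off, replace = TRUE)
      id <- c(id, off_id); sire <- c(sire, off_sire); dam <- c(dam, off_dam)
      sex <- c(sex, sample(c("M", "F"), n_off, replace = TRUE))
      gen <- c(gen, rep(g, n_off))
    }
    Pedigree(id, sire, dam, sex = sex, generation = gen)
  })
}

## Block partition of a chromosome: sizes 1 + Poisson(mean-1), then physical
## positions with tight within-block spacing and wide between-block gaps
## scaled to hit chromosome_length_bp.
.chromLayout <- function(config) {
  m <- config$markers_per_chromosome
  sizes <- integer(0)
  while (sum(sizes) < m)
    sizes <- c(sizes, 1L + rpois(m, max(config$mean_block_snps - 1, 0)))
  nb <- which(cumsum(sizes) >= m)[1]
  sizes <- sizes[seq_len(nb)]
  sizes[nb] <- sizes[nb] - (sum(sizes) - m)
  sizes <- sizes[sizes > 0L]
  nb <- length(sizes)
  within <- runif(m, 5e3, 25e3)
  gap_target <- max(5e4, (config$chromosome_length_bp - sum(within)) / nb)
  between <- runif(nb, 0.5 * gap_target, 1.5 * gap_target)
  pos <- numeric(m); block <- integer(m)
  cur <- 0; k <- 0L
  for (b in seq_len(nb)) {
    cur <- cur + between[b]
    for (s in seq_len(sizes[b])) {
      k <- k + 1L
      if (s > 1L) cur <- cur + within[k]
      pos[k] <- cur
      block[k] <- b
    }
  }
  list(bp = round(pos), block = block, sizes = sizes)
}

#' Simulate founder haplotypes with block-wise high LD
#'
#' Founder chromosomes are mosaics drawn from a small pool of distinct
#' ancestral haplotype alleles per block (sampled independently across
#' blocks), so within-block SNP pairs are in high LD while between-block
#' pairs are essentially independent. Each block has a primary bipartition
#' of its ancestral pool; markers following it (probability
#' \code{block_split_prob}) are in complete mutual LD, the rest follow an
#' alternative split, diluting r-squared below 1 for some pairs.
#'
#' @inheritParams simulatePedigree
#' @return A \linkS4class{HaplotypePanel} for the founders, whose map
#'   carries the true generator block id in column \code{block}.
#' @export
simulateFounderHaplotypes <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- .childSeeds(config$seed, 8)[2]
  .withSeed(seed, {
    nf <- config$n_founders
    K <- config$n_ancestral_alleles
    ngam <- 2L * nf
    maps <- vector("list", config$n_chromosomes)
    cols <- vector("list", config$n_chromosomes)
    for (ch in seq_len(config$n_chromosomes)) {
      lay <- .chromLayout(config)
      m <- length(lay$bp)
      al <- matrix(0L, ngam, m)
      for (b in unique(lay$block)) {
        idx <- which(lay$block == b)
        ## ancestral pool patterns: one 0/1 value per (pool allele, marker)
        primary <- rep(FALSE, K)
        primary[sample(K, max(1L, floor(K / 2)))] <- TRUE
        pat <- matrix(0L, K, length(idx))
        for (j in seq_along(idx)) {
          if (K == 1L) { pat[, j] <- rbinom(1, 1, 0.5); next }
          if (runif(1) < config$block_split_prob) split <- primary
          else {
            split <- rep(FALSE, K)
            split[sample(K, sample(K - 1L, 1L))] <- TRUE
          }
          pat[, j] <- as.integer(split)
        }
        w <- rexp(K); w <- w / sum(w)
        pick <- sample.int(K, ngam, replace = TRUE, prob = w)
        al[, idx] <- pat[pick, , drop = FALSE]
      }
      maps[[ch]] <- data.frame(chrom = ch,
                               id = sprintf("snp%d_%d", ch, seq_len(m)),
                               bp = lay$bp, block = lay$block + 1000L * ch,
                               stringsAsFactors = FALSE)
      cols[[ch]] <- al
    }
    HaplotypePanel(do.call(cbind, cols), as.character(seq_len(nf)),
                   do.call(rbind, maps))
  })
}

## One meiosis: recombine the two gamete rows of a parent.
.meiosis <- function(h1, h2, map, rate) {
  out <- integer(length(h1))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]
    len_m <- (max(bp) - min(bp)) * rate
    ncx <- if (len_m > 0) rpois(1, len_m) else 0L
    src <- rep(rbinom(1, 1, 0.5), length(idx))
    if (ncx > 0) {
      cx <- sort(runif(ncx, min(bp), max(bp)))
      nflips <- findInterval(bp, cx)
      src <- (src + nflips) %% 2L
    }
    out[idx] <- ifelse(src == 0L, h1[idx], h2[idx])
  }
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Every non-founder inherits one recombined gamete from each parent:
#' crossover counts are Poisson in the chromosome map length (Haldane, no
#' interference) with positions uniform in bp. Mendelian consistency holds
#' by construction.
#'
#' @param pedigree a \linkS4class{Pedigree} (any order; sorted internally).
#' @param founder_panel \linkS4class{HaplotypePanel} covering all founders.
#' @param recomb_rate_per_bp Morgans per bp (0 transmits intact gametes).
#' @param seed RNG seed.
#' @return A \linkS4class{HaplotypePanel} over all pedigree animals.
#' @export
geneDrop <- function(pedigree, founder_panel, recomb_rate_per_bp = 1e-8,
                     seed = NULL) {
  ped <- validatePedigree(pedigree)
  .withSeed(seed, {
    ids <- ped@id
    map <- founder_panel@map
    m <- nrow(map)
    al <- matrix(0L, 2L * length(ids), m)
    row_of <- function(i) c(2L * i - 1L, 2L * i)
    pos <- setNames(seq_along(ids), ids)
    fpos <- setNames(seq_along(founder_panel@animalIds), founder_panel@animalIds)
    for (i in seq_along(ids)) {
      s <- ped@sire[i]; d <- ped@dam[i]
      if (s == "0" && d == "0") {
        fi <- fpos[[ids[i]]]
        if (is.null(fi) || is.na(fi)) stop("missing founder genotype for ", ids[i])
        al[row_of(i), ] <- founder_panel@alleles[c(2L * fi - 1L, 2L * fi), ]
      } else if (s != "0" && d != "0") {
        ps <- row_of(pos[[s]]); pd <- row_of(pos[[d]])
        al[2L * i - 1L, ] <- .meiosis(al[ps[1], ], al[ps[2], ], map, recomb_rate_per_bp)
        al[2L * i, ] <- .meiosis(al[pd[1], ], al[pd[2], ], map, recomb_rate_per_bp)
      } else stop("animal ", ids[i], " has exactly one known parent; gene drop ",
                  "requires both parents or none")
    }
    HaplotypePanel(al, ids, map)
  })
}

#' Sample additive QTL and compute true breeding values
#'
#' QTL are sampled among the panel's markers (restricted to multi-SNP
#' ancestral blocks when \code{qtl_in_blocks}); per-allele substitution
#' effects are i.i.d. normal. With \code{qtl_effect_sd = NULL} the draw is
#' rescaled by one common factor so the Hardy-Weinberg additive variance
#' 2*sum(p*q*beta^2) (panel allele frequencies) equals \code{sigma2_A},
#' anchoring the trait's variance components to the simulated genome.
#'
#' @param panel gene-dropped \linkS4class{HaplotypePanel}.
#' @inheritParams simulatePedigree
#' @return list of class \code{TrueValues}: \code{tbv} (named per animal),
#'   \code{qtl_idx}, \code{qtl_effects}.
#' @export
assignQtlEffects <- function(panel, config, seed = NULL) {
  if (is.null(seed)) seed <- .childSeeds(config$seed, 8)[3]
  .withSeed(seed, {
    map <- panel@map
    if (config$n_qtl > nrow(map)) stop("n_qtl exceeds marker count")
    cand <- seq_len(nrow(map))
    if (config$qtl_in_blocks && !is.null(map$block)) {
      multi <- names(which(table(map$block) >= 2))
      inblk <- which(as.character(map$block) %in% multi)
      if (length(inblk) >= config$n_qtl) cand <- inblk
    }
    qtl <- sort(sample(cand, config$n_qtl))
    dos <- dosages(panel)[, qtl, drop = FALSE]
    p <- colMeans(dos) / 2
    if (is.null(config$qtl_effect_sd)) {
      beta <- rnorm(config$n_qtl)
      hw <- 2 * sum(p * (1 - p) * beta^2)
      if (hw > 0) beta <- beta * sqrt(config$variance_components[["sigma2_A"]] / hw)
    } else beta <- rnorm(config$n_qtl, 0, config$qtl_effect_sd)
    tbv <- drop(dos %*% beta)
    names(tbv) <- panel@animalIds
    structure(list(tbv = tbv, qtl_idx = qtl, qtl_effects = beta),
              class = "TrueValues")
  })
}

#' Lactation-specific calving-age class (1..9)
#'
#' Classifies calving age in months into nine classes, three per lactation,
#' using the dairy-recording cutoffs: lactation 1 splits at 23.4 and 25.5
#' months (classes 1-3), lactation 2 at 35.9 and 39.5 (classes 4-6),
#' lactation 3 at 48.7 and 53.3 (classes 7-9).
#'
#' @param lactation integer vector in 1..3.
#' @param age_months positive numeric vector.
#' @param cutoffs list of two upper bounds per lactation.
#' @return integer class 1..9, vectorized.
#' @examples
#' ageToClass(1, 23.0)  # 1
#' ageToClass(2, 36.5)  # 5
#' @export
ageToClass <- function(lactation, age_months,
                       cutoffs = list(c(23.4, 25.5), c(35.9, 39.5), c(48.7, 53.3))) {
  n <- max(length(lactation), length(age_months))
  lactation <- rep_len(as.integer(lactation), n)
  age_months <- rep_len(age_months, n)
  if (any(!lactation %in% 1:3)) stop("lactation must be 1, 2 or 3")
  if (any(age_months <= 0)) stop("age_months must be positive")
  out <- integer(n)
  for (l in 1:3) {
    i <- lactation == l
    cut <- cutoffs[[l]]
    out[i] <- (l - 1L) * 3L + ifelse(age_months[i] <= cut[1], 1L,
                                     ifelse(age_months[i] <= cut[2], 2L, 3L))
  }
  out
}

#' Somatic cell count to somatic cell score
#'
#' Log2 linear score: 0 anchors at 12.5 (thousand cells/mL) and each point
#' doubles the count up to 9 = 6400. Rounding is half-up to the nearest
#' integer before clamping to 0..9.
#'
#' @param scc_thousands_per_ml positive numeric, in 1000 cells/mL.
#' @return integer score 0..9.
#' @examples
#' sccToScs(c(12.5, 50, 6400))  # 0 2 9
#' @export
sccToScs <- function(scc_thousands_per_ml) {
  if (any(scc_thousands_per_ml <= 0)) stop("somatic cell count must be positive")
  score <- floor(log2(scc_thousands_per_ml / 12.5) + 0.5)
  as.integer(pmin(pmax(score, 0), 9))
}

#' Simulate repeated lactation records under the evaluation model
#'
#' Generates records for every female: lactations 1..\code{lactations_per_cow},
#' herd-year-season contemporary groups (two six-month seasons), age class
#' via \code{\link{ageToClass}}, a permanent-environment deviation constant
#' across a cow's records, a sire-herd interaction deviation constant within
#' each sire-by-herd pair, the animal's true breeding value, and i.i.d.
#' residuals: y = mu + HYS + AGE + PE + SH + TBV + e.
#'
#' @param pedigree \linkS4class{Pedigree}.
#' @param true_values \code{TrueValues} with tbv for every animal.
#' @inheritParams simulatePedigree
#' @return data.frame: animal, herd, year, season, lactation, age_months,
#'   age_class, hys, y.
#' @export
simulatePhenotypes <- function(pedigree, true_values, config, seed = NULL) {
  if (is.null(seed)) seed <- .childSeeds(config$seed, 8)[4]
  .withSeed(seed, {
    tab <- pedigreeTable(pedigree)
    cows <- tab[tab$sex %in% "F", , drop = FALSE]
    if (!nrow(cows)) stop("no females to phenotype")
    if (!all(cows$id %in% names(true_values$tbv)))
      stop("every phenotyped cow needs a true breeding value")
    vc <- config$variance_components
    nlact <- config$lactations_per_cow
    herd <- sample.int(config$n_herds, nrow(cows), replace = TRUE)
    gen <- ifelse(is.na(cows$generation), 0L, cows$generation)
    byear <- 2000L + (gen %% config$n_years)
    age1 <- rnorm(nrow(cows), 24.5, 1.3)
    pe <- rnorm(nrow(cows), 0, sqrt(vc[["sigma2_PE"]]))
    rec <- vector("list", nlact)
    for (l in seq_len(nlact)) {
      age <- age1 + (l - 1L) * 12.8 + if (l > 1) rnorm(nrow(cows), 0, 0.8) else 0
      rec[[l]] <- data.frame(animal = cows$id, sire = cows$sire, herd = herd,
                             year = byear + 1L + l, season = sample(1:2, nrow(cows), replace = TRUE),
                             lactation = l, age_months = round(age, 1), pe = pe,
                             stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rec)
    rec$age_class <- ageToClass(rec$lactation, rec$age_months)
    rec$hys <- sprintf("h%d.y%d.s%d", rec$herd, rec$year, rec$season)
    hys_lev <- sort(unique(rec$hys))
    hys_eff <- setNames(rnorm(length(hys_lev), 0, config$hys_effect_sd), hys_lev)
    age_eff <- rnorm(9, 0, config$age_effect_sd)
    sh <- sprintf("%s.h%d", rec$sire, rec$herd)
    sh_lev <- sort(unique(sh))
    sh_eff <- setNames(rnorm(length(sh_lev), 0, sqrt(vc[["sigma2_SH"]])), sh_lev)
    e <- rnorm(nrow(rec), 0, sqrt(vc[["sigma2_E"]]))
    rec$y <- config$mu + hys_eff[rec$hys] + age_eff[rec$age_class] + rec$pe +
      sh_eff[sh] + true_values$tbv[rec$animal] + e
    rec$pe <- NULL
    ord <- order(as.numeric(rec$animal), rec$lactation)
    rec <- rec[ord, , drop = FALSE]
    rownames(rec) <- NULL
    rec
  })
}

#' Mask dosage entries as missing, uniformly at random
#'
#' @param x \linkS4class{HaplotypePanel} or \linkS4class{GenotypeMatrix};
#'   the phased panel itself is never modified.
#' @param rate missing fraction in [0, 1).
#' @param seed RNG seed.
#' @return A \linkS4class{GenotypeMatrix} with code 5 at masked entries.
#' @export
injectMissingness <- function(x, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  d <- if (is(x, "HaplotypePanel")) dosages(x) else x@dosages
  .withSeed(seed, {
    if (rate > 0) {
      mask <- runif(length(d)) < rate
      d[mask] <- 5L
    }
    GenotypeMatrix(d, animalIds(x), markerMap(x))
  })
}

#' Simulate a complete dataset for the three-analysis comparison
#'
#' Runs the full generator under one master seed: pedigree, founder
#' haplotypes, gene drop, QTL effects, phenotypes, and the genotyped
#' subset (the youngest \code{genotyped_generations} generations) with
#' missingness injected into its dosage matrix.
#'
#' @param config a \code{SimConfig}.
#' @return list of class \code{HapblupDataset}: config, pedigree, panel,
#'   truth, phenotypes, genotyped_ids, genotypes (GenotypeMatrix).
#' @export
simulateDataset <- function(config) {
  seeds <- .childSeeds(config$seed, 8)
  ped <- simulatePedigree(config, seeds[1])
  founders <- simulateFounderHaplotypes(config, seeds[2])
  panel <- geneDrop(ped, founders, config$recomb_rate_per_bp, seeds[5])
  truth <- assignQtlEffects(panel, config, seeds[3])
  pheno <- simulatePhenotypes(ped, truth, config, seeds[4])
  gen <- ped@generation
  gmin <- max(gen, na.rm = TRUE) - config$genotyped_generations + 1L
  geno_ids <- ped@id[!is.na(gen) & gen >= gmin]
  gpanel <- subsetGenotypes(panel, animals = geno_ids)
  geno <- injectMissingness(gpanel, config$missing_rate, seeds[6])
  structure(list(config = config, pedigree = ped, panel = panel,
                 truth = truth, phenotypes = pheno,
                 genotyped_ids = geno_ids, genotyped_panel = gpanel,
                 genotypes = geno),
            class = "HapblupDataset")
}
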