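## Orchestration of the three analyses — SNP_ALL, HAP_PSEUDOSNP, SNP_HAP —
## over one dataset, and the comparative report (explained variance, sum of
## squared effects, reliability ANOVA, significant-region overlap).

#' Run one genomic analysis end to end
#'
#' Builds the marker set for the requested label (all QC-passed SNPs;
#' haplotype-block alleles recoded as pseudo-SNPs then QC'd; or only the
#' SNPs forming blocks, QC'd), then the relationship structures (A,
#' A-inverse, VanRaden G blended and tuned against A22, single-step
#' H-inverse), fits the evaluation model and back-solves marker effects.
#' All labels consume identical phenotypes, pedigree and variance
#' components — only the marker matrix differs.
#'
#' @param dataset a \code{HapblupDataset} from \code{\link{simulateDataset}}
#'   (or an equivalent list with pedigree, phenotypes, genotyped_panel,
#'   genotypes, config).
#' @param label one of \code{"SNP_ALL"}, \code{"HAP_PSEUDOSNP"},
#'   \code{"SNP_HAP"}.
#' @param r2_min,min_snps,max_span_kb block-detection parameters.
#' @param freq_min pseudo-SNP haplotype-frequency threshold.
#' @param maf_min,call_rate_min,hwe_p_min,conflict_max QC thresholds.
#' @param blend_alpha,tune,tau,omega single-step conditioning parameters.
#' @param alpha GWAS significance level.
#' @param blocks optional precomputed \code{\link{detectBlocks}} output.
#' @param A optional precomputed numerator relationship matrix.
#' @param Ainv optional precomputed pedigree inverse.
#' @return list of class \code{AnalysisResult}: label, marker_count,
#'   genotyped ids kept, fit (\code{ssFit}), gwas (\code{ssGwas}),
#'   reliability vector of genotyped animals, significant regions
#'   (chrom/start/end), qc report, blocks.
#' @export
runAnalysis <- function(dataset, label = c("SNP_ALL", "HAP_PSEUDOSNP", "SNP_HAP"),
                        r2_min = 0.80, min_snps = 2, max_span_kb = 200,
                        freq_min = 0.01, maf_min = 0.05, call_rate_min = 0.95,
                        hwe_p_min = 0.15, conflict_max = 0.01,
                        blend_alpha = 0.95, tune = TRUE, tau = 1, omega = 1,
                        alpha = 0.01, blocks = NULL, A = NULL, Ainv = NULL) {
  label <- match.arg(label)
  ped <- validatePedigree(dataset$pedigree)
  vc <- dataset$config$variance_components
  needBlocks <- label %in% c("HAP_PSEUDOSNP", "SNP_HAP")
  if (needBlocks && is.null(blocks))
    blocks <- detectBlocks(dataset$genotyped_panel, r2_min = r2_min,
                           min_snps = min_snps, max_span_kb = max_span_kb)
  geno <- switch(label,
    SNP_ALL = dataset$genotypes,
    HAP_PSEUDOSNP = {
      if (!nrow(blocks)) stop("no haplotype blocks detected: empty marker set")
      encodePseudoSnps(dataset$genotyped_panel, blocks, freq_min = freq_min)
    },
    SNP_HAP = {
      idx <- selectHapSnps(blocks)
      if (!length(idx)) stop("no haplotype blocks detected: empty marker set")
      subsetGenotypes(dataset$genotypes, markers = idx)
    })
  qc <- qcGenotypes(geno, ped, call_rate_min = call_rate_min,
                    conflict_max = conflict_max, maf_min = maf_min,
                    hwe_p_min = hwe_p_min)
  geno <- qc$geno
  if (nMarkers(geno) < 2) stop("marker set empty after QC")
  gids <- animalIds(geno)
  if (is.null(A)) A <- buildA(ped)
  if (is.null(Ainv)) Ainv <- buildAinv(ped)
  A22 <- A[gids, gids]
  d <- dosages(geno)
  G <- buildG(d)
  Gb <- blendTuneG(G, A22, alpha = blend_alpha, tune = tune)
  Ginv <- chol2inv(chol(Gb))
  dimnames(Ginv) <- dimnames(Gb)
  A22inv <- chol2inv(chol(A22))
  dimnames(A22inv) <- dimnames(A22)
  Hinv <- buildHinv(Ainv, Ginv, A22inv, tau = tau, omega = omega)
  fit <- fitSSModel(dataset$phenotypes, ped, Hinv, vc, genotyped_ids = gids)
  gw <- runGwas(fit, geno, Ginv, alpha = alpha)
  sig <- significantMarkers(gw$table, gw$threshold)
  regions <- if (is(geno, "PseudoSNPSet")) {
    pr <- provenance(geno)
    pr <- pr[match(sig$id, markerMap(geno)$id), , drop = FALSE]
    data.frame(chrom = pr$chrom, start_bp = pr$start_bp, end_bp = pr$end_bp,
               id = sig$id, stringsAsFactors = FALSE)
  } else data.frame(chrom = sig$chrom, start_bp = sig$bp, end_bp = sig$bp,
                    id = sig$id, stringsAsFactors = FALSE)
  rel <- fit$solutions$reliability[match(gids, fit$solutions$id)]
  structure(list(label = label, marker_count = nMarkers(geno),
                 genotyped_ids = gids, fit = fit, gwas = gw,
                 reliability = setNames(rel, gids),
                 significant_regions = regions, qc_report = qc$report,
                 blocks = if (needBlocks) blocks),
            class = "AnalysisResult")
}

#' @export
print.AnalysisResult <- function(x, ...) {
  cat(sprintf("%s: %d markers, %d genotyped, mean reliability %.3f, EXGV %.4g\n",
              x$label, x$marker_count, length(x$genotyped_ids),
              mean(x$reliability), x$gwas$exgv_total))
  invisible(x)
}

## number of regions in a overlapping any region of b (same chromosome,
## closed intervals)
.overlapCount <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0L)
  sum(vapply(seq_len(nrow(a)), function(i) {
    j <- b$chrom == a$chrom[i] & b$start_bp <= a$end_bp[i] &
         b$end_bp >= a$start_bp[i]
    any(j)
  }, logical(1)))
}

#' Comparative report over analysis results
#'
#' Assembles the explained-genetic-variance and sum-of-squared-effects
#' tables, the reliability means with one-way ANOVA and grouping letters,
#' and the pairwise overlap of significant genomic regions (pseudo-SNPs
#' are mapped to their block span so overlap with individual SNPs is well
#' defined).
#'
#' @param results list of \code{AnalysisResult} objects (>= 1).
#' @return list of class \code{ComparisonReport}: \code{exgv},
#'   \code{sum_sq_effects}, \code{reliability} (means table with letters,
#'   NULL ANOVA when only one result), \code{anova}, \code{overlap} matrix.
#' @export
compareAnalyses <- function(results) {
  if (!length(results)) stop("no results to compare")
  labs <- vapply(results, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("analysis labels must be unique")
  names(results) <- labs
  exgv_tab <- data.frame(
    analysis = labs,
    marker_count = vapply(results, `[[`, 0L, "marker_count"),
    exgv = vapply(results, function(r) r$gwas$exgv_total, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  ss_tab <- data.frame(
    analysis = labs,
    sum_sq_effects = vapply(results, function(r) r$gwas$sum_sq_effects, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  an <- NULL
  rel_tab <- data.frame(
    analysis = labs,
    n = vapply(results, function(r) length(r$reliability), 0L),
    mean = vapply(results, function(r) mean(r$reliability), 0),
    se = vapply(results, function(r)
      sd(r$reliability) / sqrt(length(r$reliability)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(results) >= 2) {
    an <- anovaReliabilities(lapply(results, `[[`, "reliability"))
    rel_tab$letters <- an$table$letters[match(labs, an$table$group)]
  }
  ov <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in labs) for (j in labs)
    ov[i, j] <- .overlapCount(results[[i]]$significant_regions,
                              results[[j]]$significant_regions)
  structure(list(exgv = exgv_tab, sum_sq_effects = ss_tab,
                 reliability = rel_tab, anova = an, overlap = ov),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Explained genetic variance:\n"); print(x$exgv)
  cat("Reliability of GBVs:\n"); print(x$reliability)
  if (!is.null(x$anova))
    cat(sprintf("ANOVA: F = %.3f, p = %.3g\n", x$anova$F, x$anova$p_value))
  invisible(x)
}

#' Run the full three-way comparison on one dataset
#'
#' Convenience wrapper: shared block detection and pedigree matrices, the
#' three analyses, and the comparative report.
#'
#' @param dataset a \code{HapblupDataset}.
#' @param labels which analyses to run.
#' @param ... parameters forwarded to \code{\link{runAnalysis}}.
#' @return list: \code{results} (per label), \code{report}
#'   (\code{ComparisonReport}).
#' @export
runComparison <- function(dataset,
                          labels = c("SNP_ALL", "HAP_PSEUDOSNP", "SNP_HAP"),
                          ...) {
  ped <- validatePedigree(dataset$pedigree)
  A <- buildA(ped)
  Ainv <- buildAinv(ped)
  dots <- list(...)
  blocks <- do.call(detectBlocks, c(list(dataset$genotyped_panel),
    dots[intersect(names(dots), c("r2_min", "min_snps", "max_span_kb"))]))
  results <- lapply(labels, function(l)
    do.call(runAnalysis, c(list(dataset, l, blocks = blocks, A = A,
                                Ainv = Ainv), dots)))
  list(results = results, report = compareAnalyses(results))
}
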