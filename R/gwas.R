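## ssGWAS: back-solving marker effects from genomic breeding values,
## standard errors by exact error propagation of the MME prediction-error
## covariance, normal-score p-values, Bonferroni thresholds, and explained
## genetic variance.

## Centered marker matrix Z = dosages - 2p (missing imputed at 2p) and the
## scalar k = 1 / (2 sum p q).
.centeredZ <- function(dosages, freqs = NULL) {
  fr <- .colFreqs(dosages)
  p <- if (is.null(freqs)) fr$p else freqs
  d <- dosages
  miss <- d == 5L
  if (any(miss)) {
    imp <- matrix(rep(2 * p, each = nrow(d)), nrow(d))
    d <- ifelse(miss, imp, d)
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("sum of p*q is zero")
  list(Z = sweep(d, 2, 2 * p), p = p, k = 1 / denom)
}

#' Back-solve marker effects from genomic breeding values
#'
#' a-hat = k D Z' G^-1 u-hat, with Z the allele-frequency-centered marker
#' matrix, k = 1 / (2 sum p q), and D a diagonal marker-weight matrix
#' (identity by default).
#'
#' @param u_genotyped GBVs of the genotyped animals, ordered as the rows
#'   of \code{dosages}.
#' @param dosages genotype matrix (0/1/2, 5 missing) of those animals.
#' @param Ginv inverse of the genomic relationship matrix built from the
#'   same marker set and frequencies.
#' @param freqs optional A-allele frequencies (observed ones by default).
#' @param D optional diagonal weights (vector of length m).
#' @return numeric vector of per-marker allele-substitution effects.
#' @export
backsolveEffects <- function(u_genotyped, dosages, Ginv, freqs = NULL, D = NULL) {
  if (length(u_genotyped) != nrow(dosages))
    stop("GBV vector and dosage rows differ in length")
  cz <- .centeredZ(dosages, freqs)
  if (is.null(D)) D <- rep(1, ncol(dosages))
  if (length(D) != ncol(dosages)) stop("weight vector length mismatch")
  a <- cz$k * D * drop(crossprod(cz$Z, Ginv %*% u_genotyped))
  names(a) <- colnames(dosages)
  a
}

#' VanRaden marker weights from a previous pass of effects
#'
#' d_i proportional to a_i^2 * 2 p_i q_i, normalized so the trace equals
#' the marker count. Iterating re-estimates effects under the new weights.
#'
#' @param a marker effects from a previous back-solve.
#' @param freqs A-allele frequencies.
#' @return numeric weight vector with sum equal to \code{length(a)}.
#' @export
vanradenWeights <- function(a, freqs) {
  w <- a^2 * 2 * freqs * (1 - freqs)
  if (all(w == 0)) stop("all effects zero: weights undefined")
  w * length(w) / sum(w)
}

#' Standard deviations of back-solved marker effects
#'
#' Exact linear propagation: with B = k D Z' G^-1, Var(a-hat) =
#' B PEC(u-hat) B', where PEC is the prediction-error covariance of the
#' genotyped animals' GBVs from the MME inverse. Only the diagonal is
#' formed.
#'
#' @inheritParams backsolveEffects
#' @param PEC prediction-error covariance matrix of the genotyped GBVs.
#' @return numeric vector of sd(a-hat).
#' @export
effectSd <- function(dosages, Ginv, PEC, freqs = NULL, D = NULL) {
  cz <- .centeredZ(dosages, freqs)
  if (is.null(D)) D <- rep(1, ncol(dosages))
  B <- cz$k * D * as.matrix(crossprod(cz$Z, Ginv))  # m x n
  v <- rowSums((B %*% PEC) * B)
  if (any(v < -1e-8)) stop("negative effect variance: non-PSD PEC upstream")
  sqrt(pmax(v, 0))
}

#' Two-sided normal p-values for marker effects
#'
#' p_i = 2 (1 - Phi(|a_i| / sd_i)). Markers with zero (or missing) sd are
#' flagged NA and excluded from testing.
#'
#' @param a,sd effect and standard-deviation vectors.
#' @return list: \code{p_value}, \code{minus_log10_p} (NA where untestable).
#' @export
pvalues <- function(a, sd) {
  if (length(a) != length(sd)) stop("length mismatch")
  z <- ifelse(sd > 0, abs(a) / sd, NA_real_)
  p <- 2 * pnorm(z, lower.tail = FALSE)
  list(p_value = p, minus_log10_p = -log10(p))
}

#' Genome-wide Bonferroni threshold on the -log10 p scale
#'
#' @param m number of tested markers.
#' @param alpha family-wise significance level (default 0.01).
#' @return -log10(alpha / m); markers are significant when their
#'   -log10 p exceeds it.
#' @examples
#' bonferroniThreshold(1)       # 2
#' bonferroniThreshold(35552)   # 6.55...
#' @export
bonferroniThreshold <- function(m, alpha = 0.01) {
  if (any(m < 1)) stop("m must be >= 1")
  -log10(alpha / m)
}

#' Explained genetic variance per marker and in total
#'
#' EXGVu_i = 2 p_i q_i a_i^2 under Hardy-Weinberg equilibrium, summed over
#' markers for the total; the sum of squared effects is also reported.
#'
#' @param freqs A-allele frequencies.
#' @param a marker effects.
#' @return list: \code{per_marker}, \code{total}, \code{sum_sq_effects}.
#' @export
exgv <- function(freqs, a) {
  if (length(freqs) != length(a)) stop("length mismatch")
  per <- 2 * freqs * (1 - freqs) * a^2
  list(per_marker = per, total = sum(per), sum_sq_effects = sum(a^2))
}

#' Assemble the per-marker effect table of one ssGWAS run
#'
#' Runs back-solving, standard errors, p-values and explained variance for
#' one marker set against a fitted model, optionally with VanRaden
#' iterative weighting.
#'
#' @param fit an \code{ssFit} with \code{PEC_g} for the genotyped animals.
#' @param geno \linkS4class{GenotypeMatrix} (or \linkS4class{PseudoSNPSet})
#'   of the genotyped animals, same id order as \code{fit$genotyped_ids}.
#' @param Ginv inverse genomic relationship matrix used in the model.
#' @param weight_mode \code{"identity"} (single pass, default) or
#'   \code{"vanraden_iterative"}.
#' @param n_weight_iters weight iterations when iterative.
#' @param alpha significance level for the Bonferroni threshold.
#' @return list of class \code{ssGwas}: \code{table} (data.frame: id,
#'   chrom, bp, p, q, effect, sd, p_value, minus_log10_p, exgv_u),
#'   \code{exgv_total}, \code{sum_sq_effects}, \code{threshold},
#'   \code{weights}.
#' @export
runGwas <- function(fit, geno, Ginv,
                    weight_mode = c("identity", "vanraden_iterative"),
                    n_weight_iters = 1, alpha = 0.01) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(fit$PEC_g)) stop("fit lacks the genotyped-animal PEC; refit ",
                               "with genotyped_ids set")
  ids <- fit$genotyped_ids
  d <- dosages(geno)
  if (!identical(rownames(d), ids)) d <- d[ids, , drop = FALSE]
  u <- fit$solutions$gbv[match(ids, fit$solutions$id)]
  p <- .colFreqs(d)$p
  D <- rep(1, ncol(d))
  a <- backsolveEffects(u, d, Ginv, freqs = p, D = D)
  if (weight_mode == "vanraden_iterative") {
    for (it in seq_len(n_weight_iters)) {
      D <- vanradenWeights(a, p)
      a <- backsolveEffects(u, d, Ginv, freqs = p, D = D)
    }
  }
  sdv <- effectSd(d, Ginv, fit$PEC_g, freqs = p, D = D)
  pv <- pvalues(a, sdv)
  ex <- exgv(p, a)
  map <- markerMap(geno)
  tab <- data.frame(id = map$id, chrom = map$chrom, bp = map$bp,
                    p = p, q = 1 - p, effect = as.numeric(a), sd = sdv,
                    p_value = pv$p_value, minus_log10_p = pv$minus_log10_p,
                    exgv_u = ex$per_marker, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab, exgv_total = ex$total,
                 sum_sq_effects = ex$sum_sq_effects,
                 threshold = bonferroniThreshold(ncol(d), alpha),
                 weights = D, alpha = alpha),
            class = "ssGwas")
}

#' @export
print.ssGwas <- function(x, ...) {
  cat(sprintf("ssGWAS: %d markers, EXGV %.4g, threshold -log10 p > %.3f (%d significant)\n",
              nrow(x$table), x$exgv_total, x$threshold,
              nrow(significantMarkers(x$table, x$threshold))))
  invisible(x)
}

#' Markers exceeding the genome-wide threshold
#'
#' Strict inequality on the -log10 p scale; untestable markers (NA) never
#' qualify.
#'
#' @param table marker-effect table (from \code{\link{runGwas}}).
#' @param threshold -log10 p threshold.
#' @return the significant subset of \code{table}.
#' @export
significantMarkers <- function(table, threshold) {
  table[!is.na(table$minus_log10_p) & table$minus_log10_p > threshold, ,
        drop = FALSE]
}

#' Plot-ready Manhattan records
#'
#' @param table marker-effect table.
#' @param threshold -log10 p threshold.
#' @param path optional CSV output path.
#' @return data.frame: chrom, bp, minus_log10_p, significant, threshold.
#' @export
manhattanTable <- function(table, threshold, path = NULL) {
  out <- data.frame(chrom = table$chrom, bp = table$bp,
                    minus_log10_p = table$minus_log10_p,
                    significant = !is.na(table$minus_log10_p) &
                      table$minus_log10_p > threshold,
                    threshold = threshold)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
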