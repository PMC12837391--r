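## Henderson mixed-model equations for the repeatability animal model
## y = mu + HYS + AGE + PE + SH + animal + e, solved against A-inverse or
## the single-step H-inverse, with exact PEV and reliability.

#' Build design matrices for the evaluation model
#'
#' Fixed effects (overall mean plus drop-first-level dummies for each
#' factor in \code{fixed}) and incidence matrices for the animal,
#' permanent-environment and sire-herd random terms. Repeated records of a
#' cow share their animal and PE columns; every incidence row sums to 1.
#'
#' @param records data.frame with columns \code{animal}, \code{y} and the
#'   factors used (\code{hys}, \code{age_class}, and \code{sire},
#'   \code{herd} for the sire-herd term).
#' @param animal_ids full pedigree id vector ordering the animal columns.
#' @param fixed character vector of fixed-factor column names.
#' @param intercept include the overall mean column (default TRUE).
#' @return list: \code{X} dense fixed matrix, sparse \code{Z_ani},
#'   \code{Z_pe}, \code{Z_sh}, level name vectors, and \code{y}.
#' @export
buildDesign <- function(records, animal_ids,
                        fixed = c("hys", "age_class"), intercept = TRUE) {
  if (!all(records$animal %in% animal_ids))
    stop("record references an animal absent from the pedigree")
  n <- nrow(records)
  X <- if (intercept) matrix(1, n, 1, dimnames = list(NULL, "mu"))
       else matrix(0, n, 0)
  for (f in fixed) {
    if (!f %in% names(records)) stop("unknown fixed factor: ", f)
    lev <- sort(unique(as.character(records[[f]])))
    if (length(lev) < 2) next  # constant factor absorbed by the mean
    D <- outer(as.character(records[[f]]), lev[-1], `==`) * 1
    colnames(D) <- paste0(f, ".", lev[-1])
    X <- cbind(X, D)
  }
  ## drop aliased columns (confounded levels) so the fixed block is estimable
  if (ncol(X) > 1) {
    q <- qr(X)
    if (q$rank < ncol(X)) {
      keep <- sort(q$pivot[seq_len(q$rank)])
      message("dropping ", ncol(X) - q$rank,
              " confounded fixed-effect column(s): ",
              paste(colnames(X)[-keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
    }
  }
  inc <- function(fac, levels) {
    Matrix::sparseMatrix(i = seq_len(n), j = match(fac, levels),
                         x = 1, dims = c(n, length(levels)),
                         dimnames = list(NULL, levels))
  }
  Z_ani <- inc(records$animal, animal_ids)
  pe_lev <- sort(unique(records$animal))
  Z_pe <- inc(records$animal, pe_lev)
  Z_sh <- NULL
  sh_lev <- character(0)
  if (all(c("sire", "herd") %in% names(records))) {
    sh <- paste(records$sire, records$herd, sep = ".")
    sh_lev <- sort(unique(sh))
    Z_sh <- inc(sh, sh_lev)
  }
  list(X = X, Z_ani = Z_ani, Z_pe = Z_pe, Z_sh = Z_sh,
       animal_ids = animal_ids, pe_levels = pe_lev, sh_levels = sh_lev,
       y = records$y)
}

#' Assemble Henderson's mixed-model equations
#'
#' Coefficient matrix for effect order (fixed, PE, SH, animal):
#' C = W'W with lambda = sigma2_E / sigma2 added to each random block —
#' identity for PE and SH, \code{Kinv} (A-inverse or H-inverse) scaled by
#' lambda_ani for the animal block.
#'
#' @param design output of \code{\link{buildDesign}} (Z_pe / Z_sh may be
#'   NULL to exclude the term).
#' @param Kinv relationship inverse over \code{design$animal_ids}.
#' @param vc named variances: sigma2_A, sigma2_PE, sigma2_SH, sigma2_E.
#' @return list: dense symmetric \code{C}, \code{rhs}, and \code{blocks} —
#'   column index ranges per effect.
#' @export
assembleMME <- function(design, Kinv, vc) {
  lam <- function(s2) vc[["sigma2_E"]] / s2
  Ws <- list(Matrix::Matrix(design$X, sparse = TRUE))
  blocks <- list(fixed = seq_len(ncol(design$X)))
  off <- ncol(design$X)
  if (!is.null(design$Z_pe) && vc[["sigma2_PE"]] > 0) {
    Ws <- c(Ws, design$Z_pe)
    blocks$pe <- off + seq_len(ncol(design$Z_pe)); off <- off + ncol(design$Z_pe)
  }
  if (!is.null(design$Z_sh) && vc[["sigma2_SH"]] > 0) {
    Ws <- c(Ws, design$Z_sh)
    blocks$sh <- off + seq_len(ncol(design$Z_sh)); off <- off + ncol(design$Z_sh)
  }
  Ws <- c(Ws, design$Z_ani)
  blocks$ani <- off + seq_len(ncol(design$Z_ani))
  W <- do.call(cbind, Ws)
  C <- as.matrix(Matrix::crossprod(W))
  rhs <- as.numeric(Matrix::crossprod(W, design$y))
  if (!is.null(blocks$pe)) {
    i <- blocks$pe
    C[cbind(i, i)] <- C[cbind(i, i)] + lam(vc[["sigma2_PE"]])
  }
  if (!is.null(blocks$sh)) {
    i <- blocks$sh
    C[cbind(i, i)] <- C[cbind(i, i)] + lam(vc[["sigma2_SH"]])
  }
  i <- blocks$ani
  C[i, i] <- C[i, i] + as.matrix(Kinv) * lam(vc[["sigma2_A"]])
  list(C = C, rhs = rhs, blocks = blocks)
}

#' Solve the mixed-model equations by dense factorization
#'
#' @param C,rhs from \code{\link{assembleMME}}.
#' @return list: \code{sol}, \code{residual_inf} (max abs of C sol - rhs),
#'   \code{rcond} reciprocal condition estimate.
#' @export
solveMME <- function(C, rhs) {
  sol <- tryCatch(solve(C, rhs),
                  error = function(e) stop("MME numerically singular ",
                                           "(confounded fixed levels?): ",
                                           conditionMessage(e)))
  list(sol = as.numeric(sol),
       residual_inf = max(abs(C %*% sol - rhs)),
       rcond = rcond(C))
}

#' Prediction error variance and reliability per animal
#'
#' PEV_i is the animal-block diagonal of the inverse coefficient matrix
#' times sigma2_E; reliability_i = 1 - PEV_i / (sigma2_A (1 + F_i)),
#' clamped into [0, 1] with the clamp count reported.
#'
#' @param C coefficient matrix.
#' @param ani_idx animal-block column indices in C.
#' @param vc named variance components.
#' @param F inbreeding coefficients aligned with the animal block.
#' @param pec_idx optional indices (within the animal block) for which the
#'   full prediction-error covariance is returned (needed by the ssGWAS
#'   standard errors).
#' @return list: \code{pev}, \code{reliability}, \code{n_clamped},
#'   optional \code{PEC}.
#' @export
pevReliability <- function(C, ani_idx, vc, F, pec_idx = NULL) {
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) solve(C))
  s2e <- vc[["sigma2_E"]]
  pev <- diag(Cinv)[ani_idx] * s2e
  rel <- 1 - pev / (vc[["sigma2_A"]] * (1 + F))
  n_clamped <- sum(rel < 0 | rel > 1)
  rel <- pmin(pmax(rel, 0), 1)
  out <- list(pev = pev, reliability = rel, n_clamped = n_clamped)
  if (!is.null(pec_idx))
    out$PEC <- Cinv[ani_idx[pec_idx], ani_idx[pec_idx], drop = FALSE] * s2e
  out
}

#' Fit the single-step evaluation model
#'
#' End-to-end convenience: design, MME assembly against \code{Kinv},
#' direct solve, PEV and Eq.-6 reliabilities, and (when
#' \code{genotyped_ids} is given) the prediction-error covariance of the
#' genotyped animals' breeding values for downstream marker back-solving.
#'
#' @param records phenotype data.frame (see \code{\link{buildDesign}}).
#' @param pedigree a \linkS4class{Pedigree}.
#' @param Kinv relationship inverse (A-inverse or H-inverse) whose dimnames
#'   are the canonical pedigree ids.
#' @param vc named variance components.
#' @param genotyped_ids optional character ids.
#' @param fixed,intercept passed to \code{\link{buildDesign}}.
#' @return list of class \code{ssFit}: \code{solutions} data.frame (id,
#'   gbv, pev, reliability, F), \code{fixed_effects}, \code{pe}, \code{sh},
#'   \code{PEC_g}, \code{vc}, diagnostics.
#' @export
fitSSModel <- function(records, pedigree, Kinv, vc, genotyped_ids = NULL,
                       fixed = c("hys", "age_class"), intercept = TRUE) {
  ped <- validatePedigree(pedigree)
  ids <- ped@id
  if (!identical(rownames(Kinv), ids))
    Kinv <- Kinv[ids, ids]
  des <- buildDesign(records, ids, fixed = fixed, intercept = intercept)
  mme <- assembleMME(des, Kinv, vc)
  solved <- solveMME(mme$C, mme$rhs)
  Fv <- inbreeding(ped)
  pec_idx <- if (!is.null(genotyped_ids)) match(genotyped_ids, ids) else NULL
  pr <- pevReliability(mme$C, mme$blocks$ani, vc, Fv, pec_idx)
  sol <- solved$sol
  u <- sol[mme$blocks$ani]
  names(u) <- ids
  res <- list(
    solutions = data.frame(id = ids, gbv = u, pev = pr$pev,
                           reliability = pr$reliability, F = Fv,
                           stringsAsFactors = FALSE, row.names = NULL),
    fixed_effects = setNames(sol[mme$blocks$fixed], colnames(des$X)),
    pe = if (!is.null(mme$blocks$pe)) setNames(sol[mme$blocks$pe], des$pe_levels),
    sh = if (!is.null(mme$blocks$sh)) setNames(sol[mme$blocks$sh], des$sh_levels),
    PEC_g = pr$PEC, genotyped_ids = genotyped_ids, vc = vc,
    n_clamped = pr$n_clamped, residual_inf = solved$residual_inf,
    rcond = solved$rcond)
  class(res) <- "ssFit"
  res
}

#' @export
print.ssFit <- function(x, ...) {
  cat(sprintf("ssGBLUP fit: %d animals, mean reliability %.3f (%d clamped)\n",
              nrow(x$solutions), mean(x$solutions$reliability), x$n_clamped))
  invisible(x)
}

#' Write breeding-value solutions as CSV
#' @param fit an \code{ssFit}.
#' @param path file path.
#' @export
writeSolutionsCsv <- function(fit, path) {
  write.csv(fit$solutions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-way fixed-effects ANOVA across analyses
#'
#' F statistic from the between/within sums-of-squares decomposition, with
#' a means table (mean, SE) and Tukey-HSD grouping letters, formatted like
#' a reliability-comparison table.
#'
#' @param groups named list of numeric vectors (one per analysis), each of
#'   length >= 2.
#' @param alpha significance level for the grouping letters.
#' @return list: \code{F}, \code{p_value}, \code{df}, \code{table}
#'   (group, n, mean, se, letters).
#' @export
anovaReliabilities <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least two values")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  ni <- lengths(groups)
  N <- sum(ni)
  mi <- vapply(groups, mean, 0)
  gm <- sum(unlist(groups)) / N
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  Fstat <- if (ssb == 0) 0 else if (msw == 0) Inf else (ssb / df1) / msw
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
  ## Tukey HSD pairwise p-values and letter display
  sig <- matrix(FALSE, k, k)
  if (msw > 0) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j]))
      q <- abs(mi[i] - mi[j]) / se
      sig[i, j] <- sig[j, i] <- ptukey(q, k, df2, lower.tail = FALSE) < alpha
    }
  }
  ord <- order(-mi)
  letters_out <- rep("", k)
  li <- 0L
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && !any(sig[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1L
    li <- li + 1L
    idx <- ord[i:j]
    letters_out[idx] <- paste0(letters_out[idx], letters[li])
    i <- if (j == k) k + 1L else {
      nx <- i + 1L
      while (nx <= j && any(sig[ord[nx], ord[(nx + 1):min(j + 1, k)]])) nx <- nx + 1L
      max(nx, i + 1L)
    }
  }
  list(F = Fstat, p_value = pval, df = c(df1, df2),
       table = data.frame(group = names(groups), n = ni, mean = mi,
                          se = vapply(groups, function(g) sd(g) / sqrt(length(g)), 0),
                          letters = letters_out, row.names = NULL,
                          stringsAsFactors = FALSE))
}
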