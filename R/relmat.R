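## Pedigree and genomic relationship structures: A (tabular method),
## inbreeding (Meuwissen-Luo), sparse A-inverse (Henderson rules with
## inbreeding), VanRaden G, blending/tuning against A22, and the
## single-step H-inverse.

#' Validate and canonically order a pedigree
#'
#' Topologically sorts the pedigree so parents always precede offspring,
#' breaking ties by numeric-aware animal id; the result is invariant to the
#' input row order. Cycles and self-parenting are rejected; parents absent
#' from the id list are treated as unknown founders of the animals citing
#' them only if explicitly coded \code{"0"} — otherwise an error.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @return The reordered \linkS4class{Pedigree}.
#' @export
validatePedigree <- function(pedigree) {
  id <- pedigree@id
  n <- length(id)
  sire <- match(pedigree@sire, id)
  dam <- match(pedigree@dam, id)
  if (any(is.na(sire) & pedigree@sire != "0") ||
      any(is.na(dam) & pedigree@dam != "0"))
    stop("parent id not present in pedigree (use '0' for unknown)")
  ## Kahn topological sort over parent -> child edges
  indeg <- (!is.na(sire)) + (!is.na(dam))
  depth <- rep(0L, n)
  queue <- which(indeg == 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(sire[i])) children[[sire[i]]] <- c(children[[sire[i]]], i)
    if (!is.na(dam[i])) children[[dam[i]]] <- c(children[[dam[i]]], i)
  }
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (w in children[[v]]) {
      depth[w] <- max(depth[w], depth[v] + 1L)
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < n) stop("pedigree contains a cycle")
  num <- suppressWarnings(as.numeric(id))
  ord <- if (!anyNA(num)) order(depth, num) else order(depth, id)
  new("Pedigree", id = id[ord], sire = pedigree@sire[ord],
      dam = pedigree@dam[ord], sex = pedigree@sex[ord],
      generation = pedigree@generation[ord])
}

.parentIdx <- function(ped) {
  list(s = match(ped@sire, ped@id, nomatch = 0L),
       d = match(ped@dam, ped@id, nomatch = 0L))
}

#' Numerator relationship matrix by the tabular method
#'
#' A_jj = 1 + A_sire,dam / 2 and A_ij = (A_i,sire + A_i,dam) / 2, with
#' unknown-parent terms zero.
#'
#' @param pedigree a \linkS4class{Pedigree} (sorted internally).
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
buildA <- function(pedigree) {
  ped <- validatePedigree(pedigree)
  n <- length(ped@id)
  pa <- .parentIdx(ped)
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (j in seq_len(n)) {
    s <- pa$s[j]; d <- pa$d[j]
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (j > 1L) {
      i <- seq_len(j - 1L)
      v <- numeric(j - 1L)
      if (s > 0L) v <- v + 0.5 * A[i, s]
      if (d > 0L) v <- v + 0.5 * A[i, d]
      A[i, j] <- v
      A[j, i] <- v
    }
  }
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Equals \code{diag(buildA(pedigree)) - 1} but is computed by tracing each
#' animal's ancestor contributions (L and within-family variance D), which
#' scales to long pedigrees without the full matrix.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @return named numeric vector of F in [0, 1), founders 0, ordered as the
#'   canonical pedigree.
#' @export
inbreeding <- function(pedigree) {
  ped <- validatePedigree(pedigree)
  n <- length(ped@id)
  pa <- .parentIdx(ped)
  Fv <- numeric(n)
  Dv <- function(j) {
    fs <- if (pa$s[j] > 0L) Fv[pa$s[j]] else -1
    fd <- if (pa$d[j] > 0L) Fv[pa$d[j]] else -1
    0.5 - 0.25 * (fs + fd)
  }
  L <- numeric(n)
  for (i in seq_len(n)) {
    if (pa$s[i] == 0L || pa$d[i] == 0L) { Fv[i] <- 0; next }
    anc <- i
    L[i] <- 1
    fi <- -1
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      if (pa$s[j] > 0L) {
        if (!(pa$s[j] %in% anc)) anc <- c(anc, pa$s[j])
        L[pa$s[j]] <- L[pa$s[j]] + 0.5 * L[j]
      }
      if (pa$d[j] > 0L) {
        if (!(pa$d[j] %in% anc)) anc <- c(anc, pa$d[j])
        L[pa$d[j]] <- L[pa$d[j]] + 0.5 * L[j]
      }
      fi <- fi + L[j]^2 * Dv(j)
      L[j] <- 0
    }
    Fv[i] <- fi
  }
  names(Fv) <- ped@id
  Fv
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding-adjusted Mendelian-sampling variances:
#' alpha = 1/d with d = 0.5 - 0.25 (F_s + F_d) for two known parents,
#' 0.75 - 0.25 F_p for one, and 1 for none.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param F optional inbreeding vector in canonical pedigree order
#'   (computed by \code{\link{inbreeding}} when NULL).
#' @return sparse symmetric \code{\link[Matrix]{Matrix}} with id dimnames.
#' @export
buildAinv <- function(pedigree, F = NULL) {
  ped <- validatePedigree(pedigree)
  if (is.null(F)) F <- inbreeding(ped)
  n <- length(ped@id)
  pa <- .parentIdx(ped)
  s <- pa$s; d <- pa$d
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  dmv <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
         ifelse(s > 0L, 0.75 - 0.25 * Fs,
         ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  a <- 1 / dmv
  i0 <- seq_len(n)
  ii <- i0; jj <- i0; xx <- a
  for (p in list(s, d)) {
    k <- which(p > 0L)
    ii <- c(ii, i0[k], p[k], p[k])
    jj <- c(jj, p[k], i0[k], p[k])
    xx <- c(xx, -a[k] / 2, -a[k] / 2, a[k] / 4)
  }
  k <- which(s > 0L & d > 0L)
  ii <- c(ii, s[k], d[k]); jj <- c(jj, d[k], s[k])
  xx <- c(xx, a[k] / 4, a[k] / 4)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped@id, ped@id))
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' Missing dosages (code 5) are imputed to twice the allele frequency;
#' columns are centered at 2p and G = M M' / (2 sum p q). Allele
#' frequencies default to the observed frequencies of the genotyped set.
#'
#' @param dosages integer matrix (animals x markers, rownames = ids),
#'   values 0/1/2 with 5 missing.
#' @param freqs optional per-marker A-allele frequencies.
#' @return dense symmetric matrix with id dimnames, and the scaling
#'   denominator attached as attribute \code{"k_denom"} (2 sum p q).
#' @export
buildG <- function(dosages, freqs = NULL) {
  if (ncol(dosages) < 2) stop("need at least 2 markers after QC")
  d <- dosages
  fr <- .colFreqs(d)
  p <- if (is.null(freqs)) fr$p else freqs
  miss <- d == 5L
  if (any(miss)) {
    imp <- matrix(rep(2 * p, each = nrow(d)), nrow(d))
    d <- ifelse(miss, imp, d)
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("sum of p*q is zero: all markers monomorphic")
  M <- sweep(d, 2, 2 * p)
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  attr(G, "k_denom") <- denom
  G
}

#' Blend and tune G against the pedigree relationships of genotyped animals
#'
#' Optional tuning rescales G as a + bG so its mean diagonal and mean
#' off-diagonal match A22, then blends G* = alpha G + (1 - alpha) A22.
#' Fails if the blend is not invertible (alpha too high).
#'
#' @param G,A22 conformable matrices in the same id order.
#' @param alpha blending weight on G (default 0.95).
#' @param tune logical, mean-matching rescale before blending.
#' @return blended matrix.
#' @export
blendTuneG <- function(G, A22, alpha = 0.95, tune = TRUE) {
  if (!all(dim(G) == dim(A22))) stop("G and A22 are not conformable")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 id order differs")
  att <- attr(G, "k_denom")
  if (tune && nrow(G) > 1) {
    off <- row(G) != col(G)
    md_g <- mean(diag(G)); mo_g <- mean(G[off])
    md_a <- mean(diag(A22)); mo_a <- mean(A22[off])
    if (abs(md_g - mo_g) > 1e-12) {
      b <- (md_a - mo_a) / (md_g - mo_g)
      a <- md_a - b * md_g
      G <- a + b * G
    }
  }
  Gb <- alpha * G + (1 - alpha) * A22
  if (alpha < 1) {
    ch <- tryCatch(chol(Gb), error = function(e) NULL)
    if (is.null(ch))
      stop("blended G is not invertible; lower alpha or check inputs")
  }
  attr(Gb, "k_denom") <- att
  Gb
}

#' Single-step H-inverse
#'
#' H^-1 = A^-1 + [[0, 0], [0, tau G^-1 - omega A22^-1]] on the genotyped
#' block, in the id order of \code{Ainv}.
#'
#' @param Ainv sparse pedigree inverse with id dimnames (all animals).
#' @param Ginv inverse of the (blended) genomic matrix, id dimnames.
#' @param A22inv inverse of the pedigree relationships among genotyped
#'   animals, same id order as \code{Ginv}.
#' @param tau,omega scaling of the genomic and pedigree corrections.
#' @return symmetric \code{\link[Matrix]{Matrix}}.
#' @export
buildHinv <- function(Ainv, Ginv, A22inv, tau = 1, omega = 1) {
  ids <- rownames(Ainv)
  H <- as(Ainv, "CsparseMatrix")
  if (is.null(dim(Ginv)) || ncol(Ginv) == 0) return(H)
  gids <- rownames(Ginv)
  if (is.null(gids) || !all(gids %in% ids))
    stop("genotyped ids must be a subset of pedigree ids")
  if (!identical(gids, rownames(A22inv)))
    stop("Ginv and A22inv id order differs")
  idx <- match(gids, ids)
  H[idx, idx] <- H[idx, idx] + tau * Ginv - omega * A22inv
  H
}
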