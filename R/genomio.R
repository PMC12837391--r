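## On-disk formats (PLINK PED/MAP text, dosage-matrix dialect, CSV) and
## genotype quality control.

#' Write / read a phased panel as PLINK PED/MAP text
#'
#' PED columns are family id, animal id, sire, dam, sex, phenotype, then one
#' allele pair per marker ("A"/"B", stored phased: first allele of each pair
#' is gamete 1). MAP columns are chromosome, marker id, genetic position
#' (written 0) and bp. Round-trip write-then-read is the identity.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param ped_path,map_path file paths.
#' @return \code{readPedMap} returns a \linkS4class{HaplotypePanel}.
#' @export
writePedMap <- function(panel, ped_path, map_path) {
  map <- panel@map
  write.table(data.frame(map$chrom, map$id, 0, map$bp),
              map_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- length(panel@animalIds)
  g1 <- panel@alleles[seq(1, 2 * n, 2), , drop = FALSE]
  g2 <- panel@alleles[seq(2, 2 * n, 2), , drop = FALSE]
  m <- ncol(g1)
  geno <- matrix("", n, 2 * m)
  geno[, seq(1, 2 * m, 2)] <- ifelse(g1 == 1L, "A", "B")
  geno[, seq(2, 2 * m, 2)] <- ifelse(g2 == 1L, "A", "B")
  lines <- paste("FAM", panel@animalIds, "0 0 0 -9",
                 apply(geno, 1, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(ped_path)
}

#' @rdname writePedMap
#' @export
readPedMap <- function(ped_path, map_path) {
  map <- read.table(map_path, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "bp"))
  map$cm <- NULL
  lines <- readLines(ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  ids <- character(length(toks))
  al <- matrix(0L, 2L * length(toks), m)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != 6 + 2 * m)
      stop("PED row ", i, ": expected ", 6 + 2 * m, " fields, got ", length(tk))
    ids[i] <- tk[2]
    alleles <- tk[-(1:6)]
    bad <- setdiff(unique(alleles), c("A", "B"))
    if (length(bad)) stop("PED row ", i, ": non-biallelic code ", bad[1])
    a <- as.integer(alleles == "A")
    al[2L * i - 1L, ] <- a[seq(1, 2 * m, 2)]
    al[2L * i, ] <- a[seq(2, 2 * m, 2)]
  }
  if (anyDuplicated(ids)) stop("duplicate animal id in PED file")
  HaplotypePanel(al, ids, map)
}

#' Write / read the dosage-matrix text dialect
#'
#' One row per animal: the id, a single space, then a contiguous digit
#' string of per-marker dosages (0/1/2, with 5 = missing). A companion MAP
#' file (chrom, id, 0, bp) carries the marker coordinates.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path,map_path file paths.
#' @return \code{readDosageMatrix} returns a \linkS4class{GenotypeMatrix}.
#' @export
writeDosageMatrix <- function(geno, path, map_path = NULL) {
  d <- geno@dosages
  lines <- paste(geno@animalIds,
                 apply(d, 1, function(r) paste(r, collapse = "")))
  writeLines(lines, path)
  if (!is.null(map_path)) {
    map <- geno@map
    write.table(data.frame(map$chrom, map$id, 0, map$bp),
                map_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeDosageMatrix
#' @export
readDosageMatrix <- function(path, map_path) {
  map <- read.table(map_path, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "bp"))
  map$cm <- NULL
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(parts, `[`, "", 1)
  rows <- lapply(parts, function(p) {
    digs <- as.integer(strsplit(p[2], "")[[1]])
    digs[digs %in% c(3L, 4L)] <- 5L  # partial calls collapse to missing
    digs
  })
  if (length(unique(lengths(rows))) != 1L || lengths(rows)[1] != nrow(map))
    stop("ragged dosage rows or marker count mismatch with map")
  GenotypeMatrix(do.call(rbind, rows), ids, map)
}

#' Write a pedigree / phenotype table as CSV
#' @param pedigree a \linkS4class{Pedigree}.
#' @param phenotypes data.frame from \code{\link{simulatePhenotypes}}.
#' @param path file path.
#' @export
writePedigreeCsv <- function(pedigree, path) {
  tab <- pedigreeTable(pedigree)[, c("id", "sire", "dam")]
  names(tab)[1] <- "animal"
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePedigreeCsv
#' @export
writePhenotypesCsv <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a QC report (removed animals and markers) as CSV
#' @param report the \code{report} element of \code{\link{qcGenotypes}}.
#' @param path file path.
#' @export
writeQcReportCsv <- function(report, path) {
  an <- report$animals_removed
  mk <- report$markers_removed
  out <- rbind(
    if (nrow(an)) data.frame(type = "animal", id = an$id, reason = an$reason),
    if (nrow(mk)) data.frame(type = "marker", id = mk$id, reason = mk$reason))
  if (is.null(out))
    out <- data.frame(type = character(0), id = character(0),
                      reason = character(0))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Allele frequency of the A allele from a dosage column
#'
#' p = sum(dosage) / (2 * non-missing count); entries coded 5 are missing.
#'
#' @param dosage_column integer vector in \{0, 1, 2, 5\}.
#' @return named numeric: \code{p}, \code{maf}, \code{n} (non-missing count).
#' @examples
#' alleleFrequency(c(0, 1, 2, 2))["p"]  # 0.625
#' @export
alleleFrequency <- function(dosage_column) {
  ok <- dosage_column != 5L
  n <- sum(ok)
  if (n == 0) stop("all genotypes missing for this marker")
  p <- sum(dosage_column[ok]) / (2 * n)
  c(p = p, maf = min(p, 1 - p), n = n)
}

## Column-wise allele frequencies of a dosage matrix (missing-aware).
.colFreqs <- function(d) {
  miss <- d == 5L
  dd <- d; dd[miss] <- 0L
  n <- nrow(d) - colSums(miss)
  p <- ifelse(n > 0, colSums(dd) / (2 * n), NA_real_)
  list(p = p, n = n, call_rate = n / nrow(d))
}

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Goodness of fit of observed genotype counts (BB, AB, AA) against the
#' p^2 / 2pq / q^2 expectation with p estimated from allele counts.
#' Monomorphic markers are flagged and not tested.
#'
#' @param n_BB,n_AB,n_AA genotype counts.
#' @return list: \code{chi2}, \code{p_value}, \code{monomorphic}.
#' @examples
#' hweTest(25, 50, 25)$chi2  # 0
#' @export
hweTest <- function(n_BB, n_AB, n_AA) {
  n <- n_BB + n_AB + n_AA
  if (n <= 0) stop("no genotypes to test")
  p <- (2 * n_AA + n_AB) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi2 = NA_real_, p_value = NA_real_, monomorphic = TRUE))
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- c(n_BB, n_AB, n_AA)
  chi2 <- sum((obs - expd)^2 / expd)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Opposing-homozygote conflict rate between two genotype vectors
#'
#' Fraction of markers, non-missing in both, where one genotype is 0 and
#' the other 2 — impossible under parent-progeny transmission.
#'
#' @param child_dosages,parent_dosages integer vectors over the same markers.
#' @return fraction in [0, 1].
#' @export
parentProgenyConflictRate <- function(child_dosages, parent_dosages) {
  if (length(child_dosages) != length(parent_dosages))
    stop("marker sets differ in length")
  ok <- child_dosages != 5L & parent_dosages != 5L
  if (!any(ok)) stop("no overlapping non-missing markers")
  conf <- (child_dosages == 0L & parent_dosages == 2L) |
          (child_dosages == 2L & parent_dosages == 0L)
  sum(conf & ok) / sum(ok)
}

#' Animal-level genotype quality control
#'
#' Removes animals whose genotype call rate falls below
#' \code{call_rate_min}, or whose opposing-homozygote conflict rate with
#' any genotyped parent reaches \code{conflict_max}. Call rates use the
#' full (pre-marker-QC) marker set.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param pedigree optional \linkS4class{Pedigree} for the conflict rule.
#' @param call_rate_min,conflict_max thresholds in (0, 1].
#' @return list: \code{kept} ids, \code{report} data.frame (id, reason).
#' @export
qcAnimals <- function(geno, pedigree = NULL, call_rate_min = 0.95,
                      conflict_max = 0.01) {
  d <- geno@dosages
  ids <- geno@animalIds
  cr <- rowSums(d != 5L) / ncol(d)
  removed <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  low <- cr < call_rate_min
  if (any(low))
    removed <- rbind(removed, data.frame(id = ids[low], reason = "low_call_rate"))
  if (!is.null(pedigree)) {
    tab <- pedigreeTable(pedigree)
    tab <- tab[match(ids, tab$id), , drop = FALSE]
    for (i in seq_along(ids)) {
      if (low[i] || is.na(tab$id[i])) next
      for (par in c(tab$sire[i], tab$dam[i])) {
        pi <- match(par, ids)
        if (par == "0" || is.na(pi)) next
        rate <- tryCatch(parentProgenyConflictRate(d[i, ], d[pi, ]),
                         error = function(e) NA_real_)
        if (!is.na(rate) && rate >= conflict_max) {
          removed <- rbind(removed, data.frame(id = ids[i], reason = "parent_conflict"))
          break
        }
      }
    }
  }
  list(kept = setdiff(ids, removed$id), report = removed)
}

#' Marker-level genotype quality control
#'
#' Removes markers that are monomorphic, have minor allele frequency below
#' \code{maf_min}, call rate below \code{call_rate_min}, or fail the
#' Hardy-Weinberg screen. The HWE screen defaults to the literal rule
#' (drop when the chi-square p-value < \code{hwe_p_min}); mode
#' \code{"het_dev"} instead drops when |observed - expected| heterozygote
#' frequency exceeds \code{hwe_p_min}, the convention of common QC tools.
#' Surviving marker order is preserved.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param maf_min,call_rate_min,hwe_p_min thresholds.
#' @param hwe_mode \code{"pvalue"} (default) or \code{"het_dev"}.
#' @return list: \code{kept} integer marker indices, \code{report}
#'   data.frame (id, reason).
#' @export
qcMarkers <- function(geno, maf_min = 0.05, call_rate_min = 0.95,
                      hwe_p_min = 0.15, hwe_mode = c("pvalue", "het_dev")) {
  hwe_mode <- match.arg(hwe_mode)
  d <- geno@dosages
  fr <- .colFreqs(d)
  reason <- rep(NA_character_, ncol(d))
  mono <- !is.na(fr$p) & (fr$p == 0 | fr$p == 1)
  reason[fr$call_rate < call_rate_min] <- "low_call_rate"
  maf <- pmin(fr$p, 1 - fr$p)
  reason[is.na(reason) & mono] <- "monomorphic"
  reason[is.na(reason) & !mono & maf < maf_min] <- "low_maf"
  for (j in which(is.na(reason) & !mono)) {
    col <- d[, j]; col <- col[col != 5L]
    ht <- hweTest(sum(col == 0L), sum(col == 1L), sum(col == 2L))
    bad <- if (hwe_mode == "pvalue") !is.na(ht$p_value) && ht$p_value < hwe_p_min
           else {
             p <- (2 * sum(col == 2L) + sum(col == 1L)) / (2 * length(col))
             abs(mean(col == 1L) - 2 * p * (1 - p)) > hwe_p_min
           }
    if (bad) reason[j] <- "hwe"
  }
  kept <- which(is.na(reason))
  list(kept = kept,
       report = data.frame(id = geno@map$id[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE))
}

#' Full genotype quality control (animals, then markers)
#'
#' Applies \code{\link{qcAnimals}} on the full marker set, then
#' \code{\link{qcMarkers}} on the surviving animals — the sequential flow
#' of standard genomic-evaluation preprocessing. The order can be reversed
#' via \code{order}, which may change the result.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param pedigree optional \linkS4class{Pedigree}.
#' @param order \code{"animals_first"} (default) or \code{"markers_first"}.
#' @param ... thresholds passed to \code{\link{qcAnimals}} /
#'   \code{\link{qcMarkers}} (\code{call_rate_min}, \code{conflict_max},
#'   \code{maf_min}, \code{hwe_p_min}, \code{hwe_mode}).
#' @param call_rate_min,conflict_max,maf_min,hwe_p_min,hwe_mode see the
#'   underlying QC functions.
#' @return list: \code{geno} (filtered \linkS4class{GenotypeMatrix}),
#'   \code{report} with \code{animals_removed}, \code{markers_removed} and
#'   the thresholds used.
#' @export
qcGenotypes <- function(geno, pedigree = NULL,
                        order = c("animals_first", "markers_first"),
                        call_rate_min = 0.95, conflict_max = 0.01,
                        maf_min = 0.05, hwe_p_min = 0.15,
                        hwe_mode = "pvalue") {
  order <- match.arg(order)
  doAnimals <- function(g) qcAnimals(g, pedigree, call_rate_min, conflict_max)
  doMarkers <- function(g) qcMarkers(g, maf_min, call_rate_min, hwe_p_min, hwe_mode)
  if (order == "animals_first") {
    qa <- doAnimals(geno)
    g2 <- subsetGenotypes(geno, animals = qa$kept)
    qm <- doMarkers(g2)
    g3 <- subsetGenotypes(g2, markers = qm$kept)
  } else {
    qm <- doMarkers(geno)
    g2 <- subsetGenotypes(geno, markers = qm$kept)
    qa <- doAnimals(g2)
    g3 <- subsetGenotypes(g2, animals = qa$kept)
  }
  list(geno = g3,
       report = list(animals_removed = qa$report, markers_removed = qm$report,
                     thresholds = list(call_rate_min = call_rate_min,
                                       conflict_max = conflict_max,
                                       maf_min = maf_min, hwe_p_min = hwe_p_min,
                                       hwe_mode = hwe_mode, order = order)))
}
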