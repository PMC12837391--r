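## LD computation on phased chromosomes, high-LD block detection,
## haplotype-allele enumeration, pseudo-SNP encoding, and the SNP-HAP
## marker subset.

## r-squared between two 0/1 gamete columns; NA when either is monomorphic.
.r2cols <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(NA_real_)
  D <- mean(a == 1L & b == 1L) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' Haplotype frequencies are counted directly on the phased chromosomes:
#' D = p_AB - p_A p_B and r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B)).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param marker_i,marker_j marker column indices (or marker ids).
#' @return r-squared in [0, 1].
#' @export
pairwiseR2 <- function(panel, marker_i, marker_j) {
  g <- panel@alleles
  ix <- if (is.character(marker_i)) match(marker_i, panel@map$id) else marker_i
  jx <- if (is.character(marker_j)) match(marker_j, panel@map$id) else marker_j
  r2 <- .r2cols(g[, ix], g[, jx])
  if (is.na(r2)) stop("r-squared undefined: monomorphic marker")
  r2
}

#' Detect high-LD haplotype blocks
#'
#' Greedy left-to-right scan per chromosome: the current block is extended
#' marker by marker while every pairwise r-squared among its members stays
#' at or above \code{r2_min} (\code{pair_mode = "adjacent"} checks only the
#' adjacent pair) and the physical span stays within \code{max_span_kb}.
#' On the first failing marker the block is emitted (if it has at least
#' \code{min_snps} members) and the scan restarts at that marker, so blocks
#' form a disjoint partition into maximal runs favouring the
#' earlier-started block. Monomorphic markers never join or start a block.
#'
#' @param panel a \linkS4class{HaplotypePanel} (map sorted by position).
#' @param r2_min minimum r-squared (default 0.80).
#' @param min_snps minimum markers per block (default 2).
#' @param max_span_kb maximum block span in kb (default 200).
#' @param pair_mode \code{"all"} pairs (default) or \code{"adjacent"} only.
#' @return data.frame with one row per block: chrom, first, last (global
#'   0-based inclusive marker indices are 1-based here), start_bp, end_bp,
#'   span_bp, n_snps, and a list column \code{members} of marker indices.
#' @export
detectBlocks <- function(panel, r2_min = 0.80, min_snps = 2,
                         max_span_kb = 200, pair_mode = c("all", "adjacent")) {
  pair_mode <- match.arg(pair_mode)
  map <- panel@map
  g <- panel@alleles
  p <- colMeans(g)
  poly <- p > 0 & p < 1
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (any(diff(map$bp[idx]) <= 0)) stop("marker map not sorted by position")
    s <- 1L
    n <- length(idx)
    while (s <= n) {
      if (!poly[idx[s]]) { s <- s + 1L; next }
      run <- s
      j <- s + 1L
      while (j <= n) {
        gj <- idx[j]
        if (!poly[gj]) break
        if ((map$bp[gj] - map$bp[idx[s]]) > max_span_kb * 1000) break
        cmp <- if (pair_mode == "adjacent") run[length(run)] else run
        ok <- all(vapply(cmp, function(k) {
          r2 <- .r2cols(g[, idx[k]], g[, gj])
          !is.na(r2) && r2 >= r2_min
        }, logical(1)))
        if (!ok) break
        run <- c(run, j)
        j <- j + 1L
      }
      if (length(run) >= min_snps) {
        mem <- idx[run]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, first = mem[1], last = mem[length(mem)],
          start_bp = map$bp[mem[1]], end_bp = map$bp[mem[length(mem)]],
          span_bp = map$bp[mem[length(mem)]] - map$bp[mem[1]],
          n_snps = length(mem))
        out[[length(out)]]$members <- I(list(mem))
      }
      s <- j  # restart at the first failing marker
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), first = integer(0), last = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      span_bp = numeric(0), n_snps = integer(0),
                      members = I(list())))
  do.call(rbind, out)
}

## Allele strings of a block over the gametes: "2" = A allele, "1" = B.
.blockStrings <- function(panel, members) {
  sub <- panel@alleles[, members, drop = FALSE]
  chars <- ifelse(sub == 1L, "2", "1")
  apply(chars, 1, paste, collapse = "")
}

#' Enumerate the haplotype alleles of a block
#'
#' Distinct phased allele strings over the block's markers ("2" = A allele,
#' "1" = B allele per SNP) with their population frequencies over all
#' chromosomes, ordered by descending frequency then lexicographically.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param block one row of \code{\link{detectBlocks}} output, or an integer
#'   vector of member marker indices.
#' @return data.frame: allele_string, count, frequency (summing to 1).
#' @export
enumerateHaplotypeAlleles <- function(panel, block) {
  members <- if (is.data.frame(block)) block$members[[1]] else block
  strs <- .blockStrings(panel, members)
  tab <- table(strs)
  df <- data.frame(allele_string = names(tab), count = as.integer(tab),
                   frequency = as.numeric(tab) / length(strs),
                   stringsAsFactors = FALSE)
  df[order(-df$frequency, df$allele_string), , drop = FALSE]
}

#' Recode haplotype-block alleles as pseudo-SNP dosages
#'
#' Every retained haplotype allele (population frequency above
#' \code{freq_min}) of every block becomes one biallelic pseudo-marker —
#' carrier allele versus all others — whose dosage is the number of copies
#' (0/1/2) the animal carries. Pseudo-marker map positions are the block
#' midpoint in bp (offset by one per extra allele of the same block).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param blocks output of \code{\link{detectBlocks}}.
#' @param freq_min frequency threshold; alleles at or below it are dropped
#'   (default 0.01, the "present in more than 1 percent" rule).
#' @return A \linkS4class{PseudoSNPSet}.
#' @export
encodePseudoSnps <- function(panel, blocks, freq_min = 0.01) {
  n <- length(panel@animalIds)
  cols <- list(); prov <- list(); mapped <- list()
  for (b in seq_len(nrow(blocks))) {
    members <- blocks$members[[b]]
    strs <- .blockStrings(panel, members)
    g1 <- strs[seq(1, 2 * n, 2)]
    g2 <- strs[seq(2, 2 * n, 2)]
    alleles <- enumerateHaplotypeAlleles(panel, members)
    alleles <- alleles[alleles$frequency > freq_min, , drop = FALSE]
    if (!nrow(alleles)) next
    mid <- floor((blocks$start_bp[b] + blocks$end_bp[b]) / 2)
    for (k in seq_len(nrow(alleles))) {
      a <- alleles$allele_string[k]
      cols[[length(cols) + 1L]] <- as.integer(g1 == a) + as.integer(g2 == a)
      prov[[length(prov) + 1L]] <- data.frame(
        block = b, chrom = blocks$chrom[b], start_bp = blocks$start_bp[b],
        end_bp = blocks$end_bp[b], allele_string = a,
        frequency = alleles$frequency[k], stringsAsFactors = FALSE)
      mapped[[length(mapped) + 1L]] <- data.frame(
        chrom = blocks$chrom[b],
        id = sprintf("hap%s_%d_%d", blocks$chrom[b], blocks$start_bp[b], k),
        bp = mid + (k - 1L), stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) stop("no pseudo-SNP columns after frequency filtering")
  map <- do.call(rbind, mapped)
  ## guarantee strictly increasing positions within chromosome
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    for (k in seq_along(i)[-1])
      if (map$bp[i[k]] <= map$bp[i[k - 1]])
        map$bp[i[k]] <- map$bp[i[k - 1]] + 1L
  }
  new("PseudoSNPSet", dosages = do.call(cbind, cols),
      animalIds = panel@animalIds, map = map, provenance = do.call(rbind, prov))
}

#' Markers forming haplotype blocks (the SNP-HAP subset)
#'
#' @param blocks output of \code{\link{detectBlocks}}.
#' @return sorted unique integer marker indices, original order preserved.
#' @export
selectHapSnps <- function(blocks) {
  if (!nrow(blocks)) return(integer(0))
  sort(unique(unlist(blocks$members)))
}

#' Summary statistics of detected blocks
#'
#' @param blocks output of \code{\link{detectBlocks}}.
#' @return list with \code{overall} (n_blocks, SNPs-per-block mean/sd/
#'   min/max, span mean/min/max in kb) and \code{per_chromosome} counts.
#' @export
blockSummary <- function(blocks) {
  if (!nrow(blocks))
    return(list(overall = data.frame(n_blocks = 0L),
                per_chromosome = data.frame(chrom = character(0), n_blocks = integer(0))))
  list(overall = data.frame(
         n_blocks = nrow(blocks),
         snps_mean = mean(blocks$n_snps), snps_sd = sd(blocks$n_snps),
         snps_min = min(blocks$n_snps), snps_max = max(blocks$n_snps),
         span_kb_mean = mean(blocks$span_bp) / 1000,
         span_kb_min = min(blocks$span_bp) / 1000,
         span_kb_max = max(blocks$span_bp) / 1000),
       per_chromosome = aggregate(list(n_blocks = blocks$n_snps),
                                  by = list(chrom = blocks$chrom), FUN = length))
}

#' Write blocks as BED-like text
#'
#' Columns: chrom, start_bp, end_bp, n_snps, then semicolon-joined
#' allele_string:frequency pairs.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param blocks output of \code{\link{detectBlocks}}.
#' @param path file path.
#' @export
writeBlocksBed <- function(panel, blocks, path) {
  lines <- vapply(seq_len(nrow(blocks)), function(b) {
    al <- enumerateHaplotypeAlleles(panel, blocks$members[[b]])
    paste(blocks$chrom[b], blocks$start_bp[b], blocks$end_bp[b],
          blocks$n_snps[b],
          paste(sprintf("%s:%.4f", al$allele_string, al$frequency),
                collapse = ";"),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
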