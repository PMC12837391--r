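#' @import methods
#' @importFrom stats rnorm rpois runif rbinom rexp pchisq pnorm pf ptukey sd var cor aggregate setNames
#' @importFrom utils read.table write.table write.csv
NULL

## Internal allele coding on phased panels: integer 0/1, where 1 is the "A"
## allele (the allele whose copies a dosage counts, so dosage = 0/1/2 of A).
## Gametes are stored as rows 2i-1 and 2i for animal i.

.validMarkerMap <- function(map) {
  req <- c("chrom", "id", "bp")
  if (!is.data.frame(map) || !all(req %in% names(map)))
    return("marker map must be a data.frame with columns chrom, id, bp")
  if (anyDuplicated(map$id))
    return("marker ids must be unique")
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (any(diff(bp) <= 0))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  TRUE
}

#' Pedigree of animals with optional sex and generation annotation
#'
#' Stores animal, sire and dam identifiers as parallel character vectors,
#' with \code{"0"} coding an unknown parent. Ordering is not part of the
#' class contract; \code{\link{validatePedigree}} produces the canonical
#' parents-first ordering required by the relationship-matrix builders.
#'
#' @slot id character, unique animal identifiers.
#' @slot sire,dam character, parent identifiers (\code{"0"} = unknown).
#' @slot sex character, \code{"M"}/\code{"F"}/\code{NA}.
#' @slot generation integer, generation number (founders = 0) or NA.
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character",
                 sex = "character", generation = "integer"),
  validity = function(object) {
    n <- length(object@id)
    if (length(object@sire) != n || length(object@dam) != n)
      return("id, sire and dam must have equal length")
    if (length(object@sex) != n || length(object@generation) != n)
      return("sex and generation must have the same length as id")
    if (anyDuplicated(object@id)) return("animal ids must be unique")
    if (any(object@id == "0")) return("'0' is reserved for unknown parents")
    if (any(object@sire == object@id) || any(object@dam == object@id))
      return("an animal cannot be its own parent")
    TRUE
  })

#' Construct a Pedigree
#'
#' @param id,sire,dam animal and parent identifiers (coerced to character;
#'   0/NA parents become \code{"0"}).
#' @param sex optional "M"/"F" per animal.
#' @param generation optional integer generation (founders 0).
#' @return A \linkS4class{Pedigree}.
#' @examples
#' Pedigree(id = c("A", "B", "X"), sire = c(0, 0, "A"), dam = c(0, 0, "B"))
#' @export
Pedigree <- function(id, sire, dam, sex = NULL, generation = NULL) {
  canon <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "0"
    x
  }
  id <- as.character(id)
  n <- length(id)
  if (is.null(sex)) sex <- rep(NA_character_, n)
  if (is.null(generation)) generation <- rep(NA_integer_, n)
  new("Pedigree", id = id, sire = canon(sire), dam = canon(dam),
      sex = as.character(sex), generation = as.integer(generation))
}

#' Phased biallelic haplotype panel
#'
#' Holds one row per gamete (two consecutive rows per animal) over the
#' markers of a \code{map}. Allele 1 is the A allele; dosages are counts
#' of A over the two gametes. The map may carry extra columns; the
#' simulator records the true ancestral block id in column \code{block}.
#'
#' @slot alleles integer matrix, \code{2 * nAnimals} rows by markers, 0/1.
#' @slot animalIds character identifiers, one per animal.
#' @slot map data.frame with columns chrom, id, bp (positions strictly
#'   increasing within chromosome).
#' @export
setClass("HaplotypePanel",
  representation(alleles = "matrix", animalIds = "character", map = "data.frame"),
  validity = function(object) {
    ok <- .validMarkerMap(object@map)
    if (!isTRUE(ok)) return(ok)
    if (nrow(object@alleles) != 2L * length(object@animalIds))
      return("alleles must have two rows (gametes) per animal")
    if (ncol(object@alleles) != nrow(object@map))
      return("allele columns must match the marker map")
    if (length(object@alleles) && !all(object@alleles %in% c(0L, 1L)))
      return("phased alleles must be coded 0/1")
    if (anyDuplicated(object@animalIds)) return("animal ids must be unique")
    TRUE
  })

#' @rdname HaplotypePanel-class
#' @param alleles,animalIds,map see slots.
#' @export
HaplotypePanel <- function(alleles, animalIds, map) {
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  new("HaplotypePanel", alleles = alleles, animalIds = as.character(animalIds),
      map = map)
}

#' Unphased dosage matrix with missing code 5
#'
#' Animals by markers, entries in \{0, 1, 2\} counting copies of the A
#' allele, and 5 for a missing genotype (the matrix-dialect convention:
#' codes 3/4/5 of the raw data all collapse to missing on read).
#'
#' @slot dosages integer matrix, animals by markers, values 0/1/2/5.
#' @slot animalIds character, one per row.
#' @slot map data.frame (chrom, id, bp).
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", animalIds = "character", map = "data.frame"),
  validity = function(object) {
    ok <- .validMarkerMap(object@map)
    if (!isTRUE(ok)) return(ok)
    if (nrow(object@dosages) != length(object@animalIds))
      return("one dosage row per animal required")
    if (ncol(object@dosages) != nrow(object@map))
      return("dosage columns must match the marker map")
    if (length(object@dosages) && !all(object@dosages %in% c(0L, 1L, 2L, 5L)))
      return("dosages must be coded 0/1/2 with 5 = missing")
    if (anyDuplicated(object@animalIds)) return("animal ids must be unique")
    TRUE
  })

#' @rdname GenotypeMatrix-class
#' @param dosages,animalIds,map see slots.
#' @export
GenotypeMatrix <- function(dosages, animalIds, map) {
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- NULL
  new("GenotypeMatrix", dosages = dosages, animalIds = as.character(animalIds),
      map = map)
}

#' Pseudo-SNP dosage set derived from haplotype-block alleles
#'
#' A \linkS4class{GenotypeMatrix} whose columns are retained haplotype
#' alleles of LD blocks, recoded as biallelic carrier-versus-rest markers
#' (dosage = copies of the specific allele string carried). Provenance
#' links every column back to its block and allele string.
#'
#' @slot provenance data.frame with one row per column: block index,
#'   chromosome, block start/end bp, allele string, population frequency.
#' @export
setClass("PseudoSNPSet", contains = "GenotypeMatrix",
  representation(provenance = "data.frame"),
  validity = function(object) {
    if (nrow(object@provenance) != ncol(object@dosages))
      return("one provenance row per pseudo-SNP column required")
    TRUE
  })

## ---- Generics & accessors ----

#' Number of animals in a container
#' @param x a Pedigree, HaplotypePanel or GenotypeMatrix.
#' @return integer count.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' Number of markers in a container
#' @param x a HaplotypePanel or GenotypeMatrix.
#' @return integer count.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' Animal identifiers
#' @param x a Pedigree, HaplotypePanel or GenotypeMatrix.
#' @return character vector.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' Marker map (chrom, id, bp) of a container
#' @param x a HaplotypePanel or GenotypeMatrix.
#' @return data.frame.
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' Dosage matrix (copies of the A allele; 5 = missing)
#' @param x a HaplotypePanel (phased, never missing) or GenotypeMatrix.
#' @return integer matrix, animals by markers, with animal ids as rownames.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Phased gamete matrix of a panel
#' @param x a HaplotypePanel.
#' @return integer 0/1 matrix with two rows per animal.
#' @export
setGeneric("gametes", function(x) standardGeneric("gametes"))

#' @rdname nAnimals
setMethod("nAnimals", "Pedigree", function(x) length(x@id))
#' @rdname nAnimals
setMethod("nAnimals", "HaplotypePanel", function(x) length(x@animalIds))
#' @rdname nAnimals
setMethod("nAnimals", "GenotypeMatrix", function(x) length(x@animalIds))

#' @rdname nMarkers
setMethod("nMarkers", "HaplotypePanel", function(x) nrow(x@map))
#' @rdname nMarkers
setMethod("nMarkers", "GenotypeMatrix", function(x) nrow(x@map))

#' @rdname animalIds
setMethod("animalIds", "Pedigree", function(x) x@id)
#' @rdname animalIds
setMethod("animalIds", "HaplotypePanel", function(x) x@animalIds)
#' @rdname animalIds
setMethod("animalIds", "GenotypeMatrix", function(x) x@animalIds)

#' @rdname markerMap
setMethod("markerMap", "HaplotypePanel", function(x) x@map)
#' @rdname markerMap
setMethod("markerMap", "GenotypeMatrix", function(x) x@map)

#' @rdname dosages
setMethod("dosages", "GenotypeMatrix", function(x) {
  d <- x@dosages
  dimnames(d) <- list(x@animalIds, x@map$id)
  d
})
#' @rdname dosages
setMethod("dosages", "HaplotypePanel", function(x) {
  n <- length(x@animalIds)
  d <- x@alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       x@alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  dimnames(d) <- list(x@animalIds, x@map$id)
  d
})

#' @rdname gametes
setMethod("gametes", "HaplotypePanel", function(x) {
  g <- x@alleles
  rownames(g) <- rep(x@animalIds, each = 2L)
  colnames(g) <- x@map$id
  g
})

#' Pedigree as a data.frame
#' @param x a Pedigree.
#' @return data.frame with columns id, sire, dam, sex, generation.
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))
#' @rdname pedigreeTable
setMethod("pedigreeTable", "Pedigree", function(x)
  data.frame(id = x@id, sire = x@sire, dam = x@dam, sex = x@sex,
             generation = x@generation, stringsAsFactors = FALSE))

#' Provenance of pseudo-SNP columns
#' @param x a PseudoSNPSet.
#' @return data.frame, one row per pseudo-SNP column.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname provenance
setMethod("provenance", "PseudoSNPSet", function(x) x@provenance)

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d animals (%d founders)\n", length(object@id),
              sum(object@sire == "0" & object@dam == "0")))
})
setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d animals x %d markers on %d chromosome(s)\n",
              length(object@animalIds), nrow(object@map),
              length(unique(object@map$chrom))))
})
setMethod("show", "GenotypeMatrix", function(object) {
  miss <- mean(object@dosages == 5L)
  cat(sprintf("%s: %d animals x %d markers (%.1f%% missing)\n",
              class(object), length(object@animalIds), nrow(object@map),
              100 * miss))
})

## Subset a GenotypeMatrix / panel by marker column index (internal)
.subsetMarkers <- function(x, j) {
  map <- x@map[j, , drop = FALSE]
  rownames(map) <- NULL
  if (is(x, "PseudoSNPSet"))
    new("PseudoSNPSet", dosages = x@dosages[, j, drop = FALSE],
        animalIds = x@animalIds, map = map,
        provenance = x@provenance[j, , drop = FALSE])
  else if (is(x, "GenotypeMatrix"))
    GenotypeMatrix(x@dosages[, j, drop = FALSE], x@animalIds, map)
  else if (is(x, "HaplotypePanel"))
    HaplotypePanel(x@alleles[, j, drop = FALSE], x@animalIds, map)
  else stop("unsupported class")
}

.subsetAnimals <- function(x, keep) {
  idx <- match(keep, x@animalIds)
  if (anyNA(idx)) stop("unknown animal id in subset")
  if (is(x, "PseudoSNPSet"))
    new("PseudoSNPSet", dosages = x@dosages[idx, , drop = FALSE],
        animalIds = x@animalIds[idx], map = x@map, provenance = x@provenance)
  else if (is(x, "GenotypeMatrix"))
    GenotypeMatrix(x@dosages[idx, , drop = FALSE], x@animalIds[idx], x@map)
  else if (is(x, "HaplotypePanel")) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    HaplotypePanel(x@alleles[rows, , drop = FALSE], x@animalIds[idx], x@map)
  } else stop("unsupported class")
}

#' Subset markers or animals of a genotype container
#'
#' @param x a HaplotypePanel, GenotypeMatrix or PseudoSNPSet.
#' @param markers integer/logical marker column index (optional).
#' @param animals character animal ids to keep (optional).
#' @return An object of the same class.
#' @export
subsetGenotypes <- function(x, markers = NULL, animals = NULL) {
  if (!is.null(markers)) x <- .subsetMarkers(x, markers)
  if (!is.null(animals)) x <- .subsetAnimals(x, animals)
  x
}
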