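#' @include AllClasses.R
NULL

#' Accessors for PDCohort objects
#'
#' Slot access for [PDCohort-class] objects goes through these functions;
#' the slots themselves are internal.
#'
#' @param x A `PDCohort`.
#' @param value Replacement value.
#' @return `minorCounts` and `alleleTotals` return variants x populations
#'   integer matrices; `variantInfo` a data.frame; `geneIndex` a named
#'   list; `populations` and `genes` character vectors; `baseline` a
#'   single label; `variantMAF` the pooled per-variant MAF; `nVariants`
#'   an integer count; `genotypes` the samples x variants dosage matrix
#'   (possibly empty) and `sampleInfo` its sample table.
#' @name PDCohort-accessors
NULL

#' @rdname PDCohort-accessors
#' @export
setGeneric("minorCounts", function(x) standardGeneric("minorCounts"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("alleleTotals", function(x) standardGeneric("alleleTotals"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("geneIndex", function(x) standardGeneric("geneIndex"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("geneIndex<-", function(x, value) standardGeneric("geneIndex<-"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("baseline<-", function(x, value) standardGeneric("baseline<-"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("variantMAF", function(x) standardGeneric("variantMAF"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname PDCohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname PDCohort-accessors
setMethod("minorCounts", "PDCohort", function(x) x@minorCounts)
#' @rdname PDCohort-accessors
setMethod("alleleTotals", "PDCohort", function(x) x@alleleTotals)
#' @rdname PDCohort-accessors
setMethod("variantInfo", "PDCohort", function(x) x@variantInfo)
#' @rdname PDCohort-accessors
setMethod("geneIndex", "PDCohort", function(x) x@geneIndex)
#' @rdname PDCohort-accessors
setMethod("geneIndex<-", "PDCohort", function(x, value) {
  x@geneIndex <- value
  validObject(x)
  x
})
#' @rdname PDCohort-accessors
setMethod("populations", "PDCohort", function(x) x@populations)
#' @rdname PDCohort-accessors
setMethod("baseline", "PDCohort", function(x) x@baseline)
#' @rdname PDCohort-accessors
setMethod("baseline<-", "PDCohort", function(x, value) {
  x@baseline <- value
  validObject(x)
  x
})
#' @rdname PDCohort-accessors
setMethod("variantMAF", "PDCohort", function(x) {
  stats::setNames(x@variantInfo$maf, x@variantInfo$variant_id)
})
#' @rdname PDCohort-accessors
setMethod("nVariants", "PDCohort", function(x) nrow(x@variantInfo))
#' @rdname PDCohort-accessors
setMethod("genes", "PDCohort", function(x) names(x@geneIndex))
#' @rdname PDCohort-accessors
setMethod("genotypes", "PDCohort", function(x) x@genotypes)
#' @rdname PDCohort-accessors
setMethod("sampleInfo", "PDCohort", function(x) x@sampleInfo)

#' Extract the s x 2 contingency table of one variant
#'
#' Returns the population-by-allele table (rows = populations, columns =
#' minor/major allele counts) that the variant contributes to the gene
#' statistic.
#'
#' @param x A [PDCohort-class].
#' @param variant A variant id (or row index).
#' @return An s x 2 integer matrix with columns `minor`, `major`.
#' @export
variantTable <- function(x, variant) {
  stopifnot(is(x, "PDCohort"))
  if (is.character(variant))
    variant <- match(variant, x@variantInfo$variant_id)
  if (is.na(variant) || variant < 1 || variant > nVariants(x))
    stop("unknown variant")
  minor <- x@minorCounts[variant, ]
  total <- x@alleleTotals[variant, ]
  cbind(minor = minor, major = total - minor)
}

#' Subset a cohort to a set of variants
#'
#' @param x A `PDCohort`.
#' @param i Variant ids or indices.
#' @param j,drop Ignored (variants are rows; there is no column subsetting).
#' @param ... Ignored.
#' @return A `PDCohort` restricted to the selected variants; the gene
#'   index is pruned accordingly and the pooled MAF is left unchanged
#'   (it is a property of the full cohort's counts, which subsetting by
#'   variants does not alter).
#' @export
setMethod("[", "PDCohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@variantInfo$variant_id)
  if (anyNA(i)) stop("unknown variant id in subset")
  keep <- x@variantInfo$variant_id[i]
  gi <- lapply(x@geneIndex, function(ids) ids[ids %in% keep])
  gi <- gi[lengths(gi) > 0]
  geno <- x@genotypes
  if (nrow(geno)) geno <- geno[, i, drop = FALSE]
  new("PDCohort",
      minorCounts = x@minorCounts[i, , drop = FALSE],
      alleleTotals = x@alleleTotals[i, , drop = FALSE],
      variantInfo = x@variantInfo[i, , drop = FALSE],
      geneIndex = gi, populations = x@populations, baseline = x@baseline,
      genotypes = geno, sampleInfo = x@sampleInfo, metadata = x@metadata)
})
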