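#' @import methods
NULL

#' PDCohort: per-variant population-by-allele counts for a cohort
#'
#' `PDCohort` is the central container of the package.  For each biallelic
#' variant it stores the minor-allele count and the total allele count in
#' each of the `s` populations of the cohort, i.e. the s x 2 contingency
#' table (columns minor/major) that every downstream statistic consumes.
#' The minor allele is defined *globally*: it is the allele that is the
#' less frequent one in the pooled cohort, so the per-variant MAF stored in
#' [variantInfo()] is the pooled MAF.  When the pooled frequency is exactly
#' 0.5 the ALT allele is taken as minor (deterministic tie-break).
#'
#' Optionally the object carries the individual-level genotype dosage
#' matrix it was built from (needed for label-permutation inference) and a
#' gene index mapping gene identifiers to the ordered set of member
#' variants.
#'
#' @slot minorCounts integer matrix, variants x populations; minor-allele
#'   counts \eqn{n_{i1k}}.
#' @slot alleleTotals integer matrix, variants x populations; total number
#'   of successfully genotyped alleles \eqn{n_{i.k}} (twice the number of
#'   genotyped diploid samples).
#' @slot variantInfo data.frame with one row per variant: `variant_id`,
#'   `chrom`, `pos`, `maf` (pooled), `monomorphic`, `proteinAltering`
#'   (logical, `NA` when unannotated) and `gene` (comma-joined labels,
#'   `""` when unannotated).
#' @slot geneIndex named list mapping gene -> character vector of member
#'   variant ids (ordered, duplicate-free).
#' @slot populations character vector of the s population labels, in
#'   first-appearance order.
#' @slot baseline single population label used as the comparison baseline
#'   for Mantel-Haenszel odds ratios.
#' @slot genotypes integer matrix samples x variants of dosages 0/1/2 (NA
#'   for missing); may be empty when genotypes were not retained.
#' @slot sampleInfo data.frame with `sample_id` and `population` for each
#'   row of `genotypes`; empty when genotypes were not retained.
#' @slot metadata list of free-form provenance (input paths, simulation
#'   spec, counters).
#'
#' @seealso [readVcfCounts()], [simulateCohort()], [pdrcTest()]
#' @export
setClass("PDCohort",
  representation(
    minorCounts  = "matrix",
    alleleTotals = "matrix",
    variantInfo  = "data.frame",
    geneIndex    = "list",
    populations  = "character",
    baseline     = "character",
    genotypes    = "matrix",
    sampleInfo   = "data.frame",
    metadata     = "list"
  ),
  prototype(
    genotypes  = matrix(integer(), 0, 0),
    sampleInfo = data.frame(),
    metadata   = list()
  )
)

setValidity("PDCohort", function(object) {
  msg <- character()
  mc <- object@minorCounts
  at <- object@alleleTotals
  vi <- object@variantInfo
  if (!identical(dim(mc), dim(at)))
    msg <- c(msg, "minorCounts and alleleTotals must have identical dimensions")
  if (length(object@populations) < 2L)
    msg <- c(msg, "a cohort needs at least 2 populations")
  if (anyDuplicated(object@populations))
    msg <- c(msg, "population labels must be distinct")
  if (ncol(mc) != length(object@populations))
    msg <- c(msg, "one count column per population required")
  if (length(object@baseline) != 1L ||
      !(object@baseline %in% object@populations))
    msg <- c(msg, "baseline must be one of the population labels")
  if (nrow(vi) != nrow(mc))
    msg <- c(msg, "variantInfo must have one row per variant")
  if (length(msg) == 0L && nrow(mc) > 0L) {
    if (any(mc < 0) || any(at < 0) || any(mc > at))
      msg <- c(msg, "counts must satisfy 0 <= minor <= total")
    tot <- rowSums(at)
    ok <- tot > 0
    maf <- ifelse(ok, rowSums(mc) / pmax(tot, 1), NA_real_)
    if (any(ok & abs(maf - vi$maf) > 1e-8))
      msg <- c(msg, "variantInfo$maf must equal pooled minor count / pooled total")
    if (any(ok & maf > 0.5 + 1e-12))
      msg <- c(msg, "pooled MAF may not exceed 0.5 (minor allele is the rarer one)")
    bad <- !vapply(object@geneIndex, function(ids)
      all(ids %in% vi$variant_id) && !anyDuplicated(ids), logical(1))
    if (any(bad))
      msg <- c(msg, sprintf("geneIndex entries with unknown or duplicated variants: %s",
                            paste(names(object@geneIndex)[bad], collapse = ", ")))
  }
  if (nrow(object@genotypes) > 0L &&
      nrow(object@sampleInfo) != nrow(object@genotypes))
    msg <- c(msg, "sampleInfo must describe every genotype row")
  if (length(msg)) msg else TRUE
})

#' Construct a PDCohort from count matrices
#'
#' Low-level constructor used by the readers and the simulator.  Counts are
#' taken as-is; the pooled MAF column of `variantInfo` is recomputed.
#'
#' @param minorCounts,alleleTotals variants x populations count matrices.
#' @param variantInfo data.frame with at least `variant_id`; missing
#'   columns (`chrom`, `pos`, `gene`, `proteinAltering`) are filled with
#'   defaults.
#' @param populations character vector of population labels (defaults to
#'   `colnames(minorCounts)`).
#' @param baseline baseline population label (defaults to the last one, the
#'   conventional reference position).
#' @param geneIndex named list gene -> variant ids.
#' @param genotypes,sampleInfo optional individual-level dosages and their
#'   sample table.
#' @param metadata free-form list.
#' @return A [PDCohort-class] object.
#' @export
PDCohort <- function(minorCounts, alleleTotals, variantInfo = NULL,
                     populations = colnames(minorCounts),
                     baseline = NULL, geneIndex = list(),
                     genotypes = matrix(integer(), 0, 0),
                     sampleInfo = data.frame(), metadata = list()) {
  minorCounts <- as.matrix(minorCounts)
  alleleTotals <- as.matrix(alleleTotals)
  if (is.null(populations))
    populations <- paste0("POP", seq_len(ncol(minorCounts)))
  colnames(minorCounts) <- colnames(alleleTotals) <- populations
  q <- nrow(minorCounts)
  if (is.null(variantInfo))
    variantInfo <- data.frame(variant_id = paste0("v", seq_len(q)))
  variantInfo <- as.data.frame(variantInfo)
  if (is.null(variantInfo$variant_id))
    stop("variantInfo must contain a variant_id column")
  if (is.null(variantInfo$chrom)) variantInfo$chrom <- NA_character_
  if (is.null(variantInfo$pos)) variantInfo$pos <- NA_integer_
  if (is.null(variantInfo$gene)) variantInfo$gene <- ""
  if (is.null(variantInfo$proteinAltering)) variantInfo$proteinAltering <- NA
  tot <- rowSums(alleleTotals)
  variantInfo$maf <- ifelse(tot > 0, rowSums(minorCounts) / pmax(tot, 1), NA_real_)
  variantInfo$monomorphic <- !is.na(variantInfo$maf) & variantInfo$maf == 0
  rownames(minorCounts) <- rownames(alleleTotals) <- variantInfo$variant_id
  rownames(variantInfo) <- NULL
  if (is.null(baseline)) baseline <- populations[length(populations)]
  new("PDCohort",
      minorCounts = minorCounts, alleleTotals = alleleTotals,
      variantInfo = variantInfo, geneIndex = geneIndex,
      populations = populations, baseline = baseline,
      genotypes = genotypes, sampleInfo = sampleInfo, metadata = metadata)
}

setMethod("show", "PDCohort", function(object) {
  vi <- object@variantInfo
  cat("PDCohort with", nrow(vi), "variants across",
      length(object@populations), "populations\n")
  cat("  populations:", paste(object@populations, collapse = ", "),
      sprintf("(baseline: %s)\n", object@baseline))
  if (nrow(vi)) {
    poly <- !vi$monomorphic
    cat(sprintf("  polymorphic: %d (%.1f%% with MAF <= 0.05)\n",
                sum(poly),
                100 * mean(vi$maf[poly] <= 0.05)))
  }
  if (length(object@geneIndex))
    cat("  genes indexed:", length(object@geneIndex), "\n")
  if (nrow(object@genotypes))
    cat("  genotypes retained for", nrow(object@genotypes), "samples\n")
  invisible(NULL)
})
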