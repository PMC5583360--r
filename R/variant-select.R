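#' @include AllGenerics.R
NULL

#' Select a gene's member variants under a selection strategy
#'
#' Three strategies decide which variants of a gene enter the gene-level
#' statistic: `"all"` keeps every polymorphic variant, including common
#' ones; `"rare_less_common"` keeps variants with pooled MAF at or below
#' `commonThreshold` (common is defined as MAF > 0.05, so the boundary is
#' inclusive on the rare side); `"protein_altering"` keeps variants
#' flagged as protein-altering in the annotation.  Monomorphic variants
#' are removed under every strategy: an inverse-MAF weight is undefined
#' at MAF = 0 and a constant column carries no differentiation signal.
#' Input order is preserved and selection is idempotent.
#'
#' @param cohort A [PDCohort-class].
#' @param gene Gene id to look up in [geneIndex()].
#' @param variants Explicit variant ids (used instead of `gene`).
#' @param strategy One of `"all"`, `"rare_less_common"`,
#'   `"protein_altering"`.
#' @param commonThreshold MAF boundary in (0, 0.5); default 0.05.
#' @return Character vector of selected variant ids (possibly empty; an
#'   empty selection marks the gene untestable downstream, it is not an
#'   error).
#' @examples
#' spec <- cohortSpec(popSizes = rep(50, 3), nVariants = 10, seed = 1)
#' cohort <- simulateCohort(spec)
#' geneIndex(cohort) <- list(G1 = variantInfo(cohort)$variant_id)
#' selectVariants(cohort, "G1", strategy = "rare_less_common")
#' @export
selectVariants <- function(cohort, gene = NULL, variants = NULL,
                           strategy = c("all", "rare_less_common",
                                        "protein_altering"),
                           commonThreshold = 0.05) {
  stopifnot(is(cohort, "PDCohort"))
  strategy <- match.arg(strategy)
  if (!is.numeric(commonThreshold) || commonThreshold <= 0 ||
      commonThreshold >= 0.5)
    stop("commonThreshold must lie in (0, 0.5)")
  if (is.null(variants)) {
    if (is.null(gene)) stop("either a gene or explicit variants are required")
    variants <- cohort@geneIndex[[gene]]
    if (is.null(variants))
      stop(sprintf("gene '%s' is not in the gene index", gene))
  }
  vi <- cohort@variantInfo
  idx <- match(variants, vi$variant_id)
  if (anyNA(idx))
    stop("unknown variant ids: ",
         paste(variants[is.na(idx)], collapse = ", "))
  keep <- !vi$monomorphic[idx]
  keep <- keep & switch(strategy,
    all              = TRUE,
    rare_less_common = vi$maf[idx] <= commonThreshold,
    protein_altering = !is.na(vi$proteinAltering[idx]) &
                       vi$proteinAltering[idx])
  variants[keep]
}
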