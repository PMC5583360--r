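#' @include AllGenerics.R
NULL

## Weir-Cockerham variance components in the allele-count (haploid) form:
## the 2N_i successfully genotyped alleles of population i are the
## sampling units.  Returns per-variant components a (between-population)
## and b (within-population); theta-hat = a / (a + b).
.weirComponents <- function(minor, total) {
  q <- nrow(minor)
  a <- b <- rep(NA_real_, q)
  for (k in seq_len(q)) {
    n <- total[k, ]
    use <- n > 0
    n <- n[use]
    r <- length(n)
    if (r < 2L) next
    p <- minor[k, use] / n
    nsum <- sum(n)
    nbar <- nsum / r
    nc <- (nsum - sum(n^2) / nsum) / (r - 1)
    pbar <- sum(n * p) / nsum
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    within <- pbar * (1 - pbar) - (r - 1) / r * s2
    b[k] <- nbar / (nbar - 1) * within
    a[k] <- nbar / nc * (s2 - within / (nbar - 1))
  }
  list(a = a, b = b)
}

#' Per-variant Weir-Cockerham fixation index
#'
#' Estimates the fixation index (F_st) of each variant across the cohort's
#' populations with the Weir-Cockerham variance-component estimator, which
#' remains unbiased under unequal sample sizes.  The allele-count
#' (haploid) form is used: the successfully genotyped alleles of each
#' population are the sampling units, matching a pipeline that carries
#' allele counts rather than genotypic heterozygosity.  One multi-
#' population estimate is returned per variant (not pairwise values) and
#' negative estimates are reported as-is, not truncated at zero.
#'
#' @param x A [PDCohort-class], or a variants x populations minor-count
#'   matrix (then `total` is required).
#' @param total Matching matrix of total allele counts when `x` is a
#'   matrix.
#' @return Named numeric vector of F_st estimates; `NA` where fewer than
#'   two populations carry data or the variant is monomorphic.
#' @seealso [multiLocusFst()] for the ratio-of-sums estimate over a set
#'   of variants, [geneFstSummary()] for gene-level summaries.
#' @examples
#' weirFst(matrix(c(30, 10), 2, 1), total = matrix(c(200, 200), 2, 1))
#' @export
weirFst <- function(x, total = NULL) {
  if (is(x, "PDCohort")) {
    minor <- x@minorCounts
    total <- x@alleleTotals
    ids <- x@variantInfo$variant_id
  } else {
    minor <- as.matrix(x)
    if (is.null(total)) stop("total allele counts are required")
    total <- as.matrix(total)
    ids <- rownames(minor)
  }
  ## variants in rows; a single variant may be passed as an s x 1 column
  if (ncol(minor) == 1L && nrow(minor) > 1L) {
    minor <- t(minor)
    total <- t(total)
    ids <- NULL
  }
  cmp <- .weirComponents(minor, total)
  denom <- cmp$a + cmp$b
  fst <- ifelse(is.na(denom) | denom == 0, NA_real_, cmp$a / denom)
  stats::setNames(fst, ids)
}

#' Multi-locus Weir-Cockerham fixation index (ratio of sums)
#'
#' The standard way to combine the fixation index over a set of variants:
#' variance components are summed across loci before taking the ratio,
#' \eqn{\hat\theta = \sum_k a_k / \sum_k (a_k + b_k)}.  The arithmetic
#' mean of per-locus ratios is downward-biased (severely so with few
#' populations, where the between-population component has a single
#' degree of freedom); the ratio of sums is the estimator whose
#' expectation recovers the differentiation parameter of a
#' Balding-Nichols population model.
#'
#' @inheritParams weirFst
#' @return A single F_st estimate over the variant set.
#' @export
multiLocusFst <- function(x, total = NULL) {
  if (is(x, "PDCohort")) {
    minor <- x@minorCounts
    total <- x@alleleTotals
  } else {
    minor <- as.matrix(x)
    if (is.null(total)) stop("total allele counts are required")
    total <- as.matrix(total)
  }
  cmp <- .weirComponents(minor, total)
  ok <- !is.na(cmp$a)
  if (!any(ok)) return(NA_real_)
  sum(cmp$a[ok]) / sum(cmp$a[ok] + cmp$b[ok])
}

#' Gene-level fixation-index summary
#'
#' Summarises the per-variant F_st values of a gene: the maximum, the
#' median, and the number of variants exceeding the conventional
#' high-differentiation cutoff (0.25).  A gene is conventionally called
#' highly differentiated when at least one of its variants exceeds that
#' cutoff.
#'
#' @param fst Numeric vector of per-variant F_st values (`NA`s are
#'   dropped).
#' @param cutoff High-differentiation cutoff; default 0.25.
#' @return A list with `max`, `median`, `n_above` and `high_pd`
#'   (`TRUE` when `n_above >= 1`); all-`NA` input yields `NA` summaries.
#' @examples
#' geneFstSummary(c(0.1, 0.3, 0.02))
#' @export
geneFstSummary <- function(fst, cutoff = 0.25) {
  fst <- fst[!is.na(fst)]
  if (length(fst) == 0L)
    return(list(max = NA_real_, median = NA_real_,
                n_above = NA_integer_, high_pd = NA))
  n_above <- sum(fst > cutoff)
  list(max = max(fst), median = stats::median(fst),
       n_above = as.integer(n_above), high_pd = n_above >= 1L)
}
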