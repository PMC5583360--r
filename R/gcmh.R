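#' @include AllGenerics.R
NULL

## Weighting schemes for combining variant tables --------------------------

.SCHEMES <- c("equal", "inv_maf", "inv_maf_sq")

#' Per-variant weights for a weighting scheme
#'
#' The gene statistic combines variant tables with one positive weight per
#' variant.  Three schemes are supported: `equal` (w = 1), `inv_maf`
#' (w = 1/MAF) and `inv_maf_sq` (w = 1/MAF^2).  The MAF is the pooled
#' cohort MAF, so inverse-MAF schemes up-weight rare variants, countering
#' the tendency of unweighted chi-square statistics to be driven by
#' common variants.
#'
#' @param maf Numeric vector of pooled minor-allele frequencies, all > 0.
#' @param scheme One of `"equal"`, `"inv_maf"`, `"inv_maf_sq"`.
#' @return Numeric vector of weights, one per variant.
#' @examples
#' variantWeights(c(0.05, 0.5), "inv_maf")
#' @export
variantWeights <- function(maf, scheme = c("equal", "inv_maf", "inv_maf_sq")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(maf)) || any(maf <= 0))
    stop("weights require a strictly positive MAF for every variant ",
         "(monomorphic variants must be filtered out first)")
  switch(scheme,
         equal      = rep(1, length(maf)),
         inv_maf    = 1 / maf,
         inv_maf_sq = 1 / maf^2)
}

#' Conditional moments of one variant's contingency table
#'
#' Under the null hypothesis of no population differentiation, each
#' variant's s x 2 table follows a multiple hypergeometric distribution
#' conditional on its margins.  This returns the free-cell vector (the
#' minor-allele counts of the first s-1 populations), its conditional
#' expectation, the (s-1) x (s-1) conditional covariance and the
#' variant's weight.  The omitted row/column (last population, major
#' allele) is a convention; the gene statistic is invariant to it.
#'
#' @param counts s x 2 matrix with columns (minor, major), or a
#'   [PDCohort-class] together with a `variant` id.
#' @param weight Positive scalar weight for this variant.
#' @param variant Variant id, when `counts` is a `PDCohort`.
#' @return A list with elements `n` (free cells), `mu`, `V`, `w`.
#' @examples
#' gcmhComponents(cbind(minor = c(10, 20), major = c(90, 80)))
#' @export
gcmhComponents <- function(counts, weight = 1, variant = NULL) {
  if (is(counts, "PDCohort")) {
    if (is.null(variant)) stop("a variant id is required with a PDCohort")
    counts <- variantTable(counts, variant)
  }
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("counts must be an s x 2 table")
  s <- nrow(counts)
  rowTot <- rowSums(counts)
  N1 <- sum(counts[, 1L])
  N <- sum(counts)
  if (N1 == 0L || N1 == N)
    stop("variant is monomorphic (pooled MAF = 0); filter before combining")
  if (N <= 1L) stop("covariance undefined for a table with N <= 1")
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("weight must be a positive scalar")
  th <- rowTot[-s]
  mu <- th * N1 / N
  cc <- N1 * (N - N1) / (N^2 * (N - 1))
  V <- cc * (N * diag(th, nrow = s - 1L) - tcrossprod(th))
  list(n = unname(counts[-s, 1L]), mu = unname(mu),
       V = unname(V), w = weight)
}

## Fast matrix kernel shared by the test, the scan and the simulators.
## minor/total: q x s matrices, w: length-q weights.  Returns L2, the
## effective degrees of freedom (rank of the summed covariance) and the
## nominal df (s - 1).
.pdrcKernel <- function(minor, total, w, tol = 1e-10) {
  s <- ncol(minor)
  N1 <- rowSums(minor)
  N <- rowSums(total)
  th <- total[, -s, drop = FALSE]
  nh <- minor[, -s, drop = FALSE]
  mu <- th * (N1 / N)
  d <- colSums(w * (nh - mu))
  cc <- w^2 * N1 * (N - N1) / (N^2 * (N - 1))
  M <- diag(colSums(cc * N * th), s - 1L) - crossprod(th, cc * th)
  e <- eigen(M, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (lmax <= 0)
    return(list(L2 = NA_real_, df = 0L, rank = 0L))
  keep <- e$values > tol * lmax
  z <- crossprod(e$vectors[, keep, drop = FALSE], d)
  list(L2 = sum(z^2 / e$values[keep]), df = as.integer(sum(keep)),
       rank = as.integer(sum(keep)))
}

#' Gene-level generalized Cochran-Mantel-Haenszel statistic
#'
#' Combines the per-variant conditional moments into the weighted
#' quadratic form
#' \deqn{L^2 = d' M^{-} d, \quad
#'       d = \sum_k w_k (n_k - \mu_k), \quad
#'       M = \sum_k w_k^2 V_k,}
#' which under conditional independence is asymptotically chi-square with
#' \eqn{(s-1)} degrees of freedom (4 for five populations and two allele
#' categories).  `M` is inverted through a symmetric eigendecomposition;
#' eigenvalues below `tol` times the largest are treated as null
#' directions, so a rank-deficient `M` (possible when rare variants are
#' absent from some populations) yields a generalized inverse and an
#' effective `df` equal to the rank.
#'
#' @param components A list of per-variant moment lists as produced by
#'   [gcmhComponents()], all for the same set of populations.
#' @param tol Relative eigenvalue tolerance for the generalized inverse.
#' @return A list with `L2`, `df` (effective degrees of freedom = rank of
#'   `M`) and `p_value`.  When every direction is degenerate (`M = 0`)
#'   `L2` is `NA` and the gene is untestable.
#' @examples
#' comps <- lapply(1:3, function(k)
#'   gcmhComponents(cbind(c(5, 10), c(95, 90)), weight = 1))
#' pdrcStatistic(comps)
#' @export
pdrcStatistic <- function(components, tol = 1e-10) {
  if (length(components) == 0L) stop("no components supplied")
  p <- length(components[[1L]]$n)
  d <- numeric(p)
  M <- matrix(0, p, p)
  for (cp in components) {
    if (length(cp$n) != p)
      stop("all components must share the same number of populations")
    d <- d + cp$w * (cp$n - cp$mu)
    M <- M + cp$w^2 * cp$V
  }
  e <- eigen(M, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (lmax <= 0)
    return(list(L2 = NA_real_, df = 0L, p_value = NA_real_))
  keep <- e$values > tol * lmax
  z <- crossprod(e$vectors[, keep, drop = FALSE], d)
  L2 <- sum(z^2 / e$values[keep])
  df <- as.integer(sum(keep))
  list(L2 = L2, df = df, p_value = pdrcPvalue(L2, df))
}

#' Upper-tail chi-square p-value for the gene statistic
#'
#' @param L2 Non-negative statistic value.
#' @param df Degrees of freedom (>= 1); `(s-1)` for s populations and two
#'   allele categories, or the effective rank when the summed covariance
#'   was singular.
#' @return The upper-tail probability `P(X >= L2)` for `X ~ chi-square(df)`.
#' @examples
#' pdrcPvalue(9.488, 4)
#' @export
pdrcPvalue <- function(L2, df) {
  stopifnot(all(L2 >= 0 | is.na(L2)), all(df >= 1))
  stats::pchisq(L2, df = df, lower.tail = FALSE)
}

#' Gene-level population-differentiation test
#'
#' Runs the full per-gene pipeline on a cohort: select the gene's member
#' variants under a selection strategy, attach per-variant weights, and
#' evaluate the weighted generalized CMH statistic with its chi-square
#' p-value.
#'
#' @param cohort A [PDCohort-class].
#' @param gene A gene id present in [geneIndex()]; alternatively pass
#'   explicit `variants`.
#' @param variants Optional character vector of variant ids to combine
#'   (overrides `gene`).
#' @param strategy Variant selection strategy, see [selectVariants()].
#' @param scheme Weighting scheme, see [variantWeights()].
#' @param commonThreshold MAF boundary between rare/less-common and
#'   common variants (default 0.05).
#' @return A one-row data.frame with `gene`, `L2`, `df`, `p_value`,
#'   `n_variants_used`, `scheme`, `strategy` and `status`
#'   (`"ok"`/`"untestable"`).
#' @examples
#' spec <- cohortSpec(popSizes = rep(50, 3), nVariants = 20, seed = 1)
#' cohort <- simulateCohort(spec)
#' geneIndex(cohort) <- list(G1 = variantInfo(cohort)$variant_id)
#' pdrcTest(cohort, "G1", scheme = "inv_maf")
#' @export
pdrcTest <- function(cohort, gene = NULL, variants = NULL,
                     strategy = c("all", "rare_less_common", "protein_altering"),
                     scheme = c("equal", "inv_maf", "inv_maf_sq"),
                     commonThreshold = 0.05) {
  stopifnot(is(cohort, "PDCohort"))
  strategy <- match.arg(strategy)
  scheme <- match.arg(scheme)
  if (is.null(variants)) {
    if (is.null(gene)) stop("either a gene or explicit variants are required")
    variants <- selectVariants(cohort, gene, strategy = strategy,
                               commonThreshold = commonThreshold)
  } else {
    variants <- selectVariants(cohort, variants = variants,
                               strategy = strategy,
                               commonThreshold = commonThreshold)
  }
  label <- if (is.null(gene)) NA_character_ else gene
  untestable <- data.frame(
    gene = label, L2 = NA_real_, df = NA_integer_, p_value = NA_real_,
    n_variants_used = length(variants), scheme = scheme,
    strategy = strategy, status = "untestable",
    stringsAsFactors = FALSE)
  if (length(variants) == 0L) {
    untestable$n_variants_used <- 0L
    return(untestable)
  }
  idx <- match(variants, cohort@variantInfo$variant_id)
  minor <- cohort@minorCounts[idx, , drop = FALSE]
  total <- cohort@alleleTotals[idx, , drop = FALSE]
  w <- variantWeights(cohort@variantInfo$maf[idx], scheme)
  k <- .pdrcKernel(minor, total, w)
  if (k$rank == 0L) return(untestable)
  data.frame(gene = label, L2 = k$L2, df = k$df,
             p_value = pdrcPvalue(k$L2, k$df),
             n_variants_used = length(variants), scheme = scheme,
             strategy = strategy, status = "ok",
             stringsAsFactors = FALSE)
}
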