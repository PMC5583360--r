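#' @include AllGenerics.R
NULL

#' Site-frequency-spectrum presets
#'
#' Ancestral pooled-MAF generators for the cohort simulator.  Each preset
#' returns a function that draws `n` frequencies in (0, 0.5].
#'
#' `sfsRareHeavy()` emulates a whole-exome spectrum: with probability
#' 0.975 a rare/less-common frequency `0.03 * Beta(0.5, 5)` (median
#' around 3 per mille, with substantial mass at very rare frequencies)
#' and with probability 0.025 a common frequency `Uniform(0.03, 0.5)`,
#' so 97.5% of simulated variants have an ancestral MAF below 3%.
#' `sfsCommonHeavy()` draws `Uniform(0.05, 0.5)`, a spectrum made of
#' common variants only.  `sfsUniform()` spans `Uniform(lo, hi)`.
#'
#' @param rareWeight Probability mass of the rare component
#'   (default 0.975).
#' @param lo,hi Range for the uniform preset.
#' @return A function `f(n)` drawing `n` ancestral minor-allele
#'   frequencies, with a `label` attribute naming the spectrum.
#' @export
sfsRareHeavy <- function(rareWeight = 0.975) {
  stopifnot(rareWeight >= 0, rareWeight <= 1)
  f <- function(n) {
    rare <- stats::runif(n) < rareWeight
    p <- numeric(n)
    p[rare] <- 0.03 * stats::rbeta(sum(rare), 0.5, 5)
    p[!rare] <- stats::runif(sum(!rare), 0.03, 0.5)
    pmax(p, 1e-8)
  }
  structure(f, label = "rare_heavy")
}

#' @rdname sfsRareHeavy
#' @export
sfsCommonHeavy <- function() {
  structure(function(n) stats::runif(n, 0.05, 0.5), label = "common_heavy")
}

#' @rdname sfsRareHeavy
#' @export
sfsUniform <- function(lo = 0.01, hi = 0.5) {
  stopifnot(lo > 0, hi <= 0.5, lo < hi)
  structure(function(n) stats::runif(n, lo, hi),
            label = sprintf("uniform(%g,%g)", lo, hi))
}

## default population sizes mirror a five-ancestry whole-exome cohort
## (African American, East Asian, American Hispanic, South Asian,
## European); the European group is the baseline.
.DEFAULT_POPS <- c(AFR = 2025L, EAS = 2164L, HIS = 1938L,
                   SAS = 2199L, EUR = 4518L)

#' Specify a synthetic multi-population cohort
#'
#' Collects the parameters of the cohort simulator: diploid sample sizes
#' per population, number of variants, ancestral site-frequency spectrum,
#' the differentiation model (`"null"`: identical allele frequencies in
#' every population; `"balding_nichols"`: per-population frequencies
#' drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral
#' frequency `p`), and the linkage-disequilibrium model
#' (`"independent"`, or `"block"` with equicorrelated Gaussian-copula
#' haplotypes of correlation `rho` within consecutive blocks).
#'
#' @param popSizes Named vector of diploid sample sizes (default: the
#'   five-ancestry cohort 2025/2164/1938/2199/4518 with European
#'   baseline).
#' @param nVariants Number of polymorphic variants to simulate.
#' @param sfs Ancestral frequency generator, e.g. [sfsRareHeavy()].
#' @param pdModel `"null"` or `"balding_nichols"`.
#' @param F Balding-Nichols differentiation parameter in (0, 1)
#'   (required for `"balding_nichols"`).
#' @param ldModel `"independent"` or `"block"`.
#' @param blockSize,rho Block extent (variants) and intra-block latent
#'   correlation for the block model.
#' @param baseline Baseline population label (default: last).
#' @param seed Integer seed; the simulation is fully deterministic given
#'   the spec.
#' @return A list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(popSizes = .DEFAULT_POPS, nVariants = 200L,
                       sfs = sfsRareHeavy(),
                       pdModel = c("null", "balding_nichols"), F = NULL,
                       ldModel = c("independent", "block"),
                       blockSize = 10L, rho = 0.8,
                       baseline = NULL, seed = NULL) {
  pdModel <- match.arg(pdModel)
  ldModel <- match.arg(ldModel)
  stopifnot(all(popSizes >= 1), length(popSizes) >= 2, nVariants >= 1)
  if (pdModel == "balding_nichols") {
    if (is.null(F) || F <= 0 || F >= 1)
      stop("balding_nichols requires F in (0, 1)")
  } else F <- NULL
  if (ldModel == "block") {
    stopifnot(blockSize >= 2, rho >= 0, rho < 1)
  }
  if (is.null(names(popSizes)))
    names(popSizes) <- paste0("POP", seq_along(popSizes))
  if (is.null(baseline)) baseline <- names(popSizes)[length(popSizes)]
  stopifnot(baseline %in% names(popSizes))
  structure(list(popSizes = popSizes, nVariants = as.integer(nVariants),
                 sfs = sfs, pdModel = pdModel, F = F, ldModel = ldModel,
                 blockSize = as.integer(blockSize), rho = rho,
                 baseline = baseline, seed = seed),
            class = "CohortSpec")
}

## per-population allele frequencies for one batch of variants (q x s)
.popFreqs <- function(p, s, pdModel, F) {
  q <- length(p)
  if (pdModel == "null")
    return(matrix(p, q, s))
  shape1 <- p * (1 - F) / F
  shape2 <- (1 - p) * (1 - F) / F
  matrix(stats::rbeta(q * s, rep(shape1, s), rep(shape2, s)), q, s)
}

## haplotype-level Gaussian copula: nInd x q dosage block with
## equicorrelated latent correlation rho and per-variant, per-individual
## thresholds from the population frequencies.
.blockGenotypes <- function(nInd, thr, rho) {
  q <- ncol(thr)
  G <- matrix(0L, nInd, q)
  for (h in 1:2) {
    z0 <- stats::rnorm(nInd)
    z <- sqrt(rho) * z0 +
      sqrt(1 - rho) * matrix(stats::rnorm(nInd * q), nInd, q)
    G <- G + (z < thr)
  }
  G
}

#' Simulate a multi-population cohort
#'
#' Generates diploid genotypes (dosage 0/1/2) for every population of the
#' spec and tallies them into a [PDCohort-class].  Variants that come out
#' monomorphic in the pooled sample are regenerated (ancestral frequency
#' redrawn), so the returned cohort is conditioned on polymorphism; under
#' the block LD model whole blocks are regenerated to preserve the
#' dependence structure.  The minor allele is re-oriented to the pooled
#' sample, exactly as for VCF input.  Deterministic given the spec's
#' seed.
#'
#' @param spec A [cohortSpec()].
#' @param keepGenotypes Keep the sample x variant dosage matrix on the
#'   cohort (required for permutation inference).  With
#'   `keepGenotypes = FALSE` and independent variants, allele counts are
#'   drawn directly as binomial sums -- the same distribution at a
#'   fraction of the cost.
#' @return A [PDCohort-class]; the spec (minus the closure) is stored in
#'   the metadata, and the ancestral frequency of each variant in
#'   `variantInfo$p_ancestral`.
#' @export
simulateCohort <- function(spec, keepGenotypes = TRUE) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  s <- length(spec$popSizes)
  q <- spec$nVariants
  sizes2 <- 2L * as.integer(spec$popSizes)
  nInd <- sum(spec$popSizes)
  popLabels <- rep(names(spec$popSizes), times = spec$popSizes)

  if (!keepGenotypes && spec$ldModel == "independent") {
    sim <- .simulateCountsOnly(spec)
    return(.countsToCohort(sim$minor, sizes2, sim$p, spec,
                           geno = NULL, popLabels = popLabels))
  }
  if (!keepGenotypes && spec$ldModel == "block")
    stop("the block LD model requires keepGenotypes = TRUE")

  popIdx <- rep(seq_len(s), times = spec$popSizes)
  if (spec$ldModel == "independent") {
    geno <- matrix(0L, nInd, 0)
    p_all <- numeric(0)
    need <- q
    while (need > 0) {
      p <- spec$sfs(need)
      pf <- .popFreqs(p, s, spec$pdModel, spec$F)   # need x s
      probs <- t(pf)[popIdx, , drop = FALSE]        # nInd x need
      blk <- matrix(stats::rbinom(nInd * need, 2L, probs), nInd, need)
      cs <- colSums(blk)
      ok <- cs > 0 & cs < 2L * nInd
      geno <- cbind(geno, blk[, ok, drop = FALSE])
      p_all <- c(p_all, p[ok])
      need <- need - sum(ok)
    }
  } else {
    nBlocks <- ceiling(q / spec$blockSize)
    pieces <- vector("list", nBlocks)
    p_pieces <- vector("list", nBlocks)
    for (bl in seq_len(nBlocks)) {
      bq <- min(spec$blockSize, q - (bl - 1L) * spec$blockSize)
      repeat {
        p <- spec$sfs(bq)
        pf <- .popFreqs(p, s, spec$pdModel, spec$F)  # bq x s
        thr <- stats::qnorm(t(pf))[popIdx, , drop = FALSE]  # nInd x bq
        blk <- .blockGenotypes(nInd, thr, spec$rho)
        cs <- colSums(blk)
        if (all(cs > 0 & cs < 2L * nInd)) break
      }
      pieces[[bl]] <- blk
      p_pieces[[bl]] <- p
    }
    geno <- do.call(cbind, pieces)
    p_all <- unlist(p_pieces)
  }
  minor <- t(rowsum(geno, popIdx))                   # q x s ALT counts
  .countsToCohort(minor, sizes2, p_all, spec, geno = geno,
                  popLabels = popLabels)
}

## counts-only sampler for independent variants: population minor counts
## are binomial sums of the per-individual dosages, so they can be drawn
## directly.
.simulateCountsOnly <- function(spec, q = spec$nVariants) {
  s <- length(spec$popSizes)
  sizes2 <- 2L * as.integer(spec$popSizes)
  minor <- matrix(0L, q, s)
  p_all <- numeric(q)
  need <- rep(TRUE, q)
  while (any(need)) {
    nq <- sum(need)
    p <- spec$sfs(nq)
    pf <- .popFreqs(p, s, spec$pdModel, spec$F)
    cnt <- matrix(stats::rbinom(nq * s, rep(sizes2, each = nq), pf), nq, s)
    cs <- rowSums(cnt)
    ok <- cs > 0 & cs < sum(sizes2)
    idx <- which(need)[ok]
    minor[idx, ] <- cnt[ok, , drop = FALSE]
    p_all[idx] <- p[ok]
    need[idx] <- FALSE
  }
  list(minor = minor, p = p_all)
}

.countsToCohort <- function(altCounts, sizes2, p_ancestral, spec,
                            geno = NULL, popLabels = NULL) {
  q <- nrow(altCounts)
  s <- ncol(altCounts)
  totals <- matrix(sizes2, q, s, byrow = TRUE)
  flip <- rowSums(altCounts) / sum(sizes2) > 0.5
  minor <- altCounts
  minor[flip, ] <- totals[flip, , drop = FALSE] - altCounts[flip, , drop = FALSE]
  ids <- sprintf("sv%0*d", nchar(q), seq_len(q))
  vi <- data.frame(variant_id = ids, p_ancestral = p_ancestral,
                   minor_is_alt = !flip, stringsAsFactors = FALSE)
  md <- list(simulated = TRUE,
             spec = spec[setdiff(names(spec), "sfs")],
             sfs_label = attr(spec$sfs, "label"))
  genoM <- matrix(integer(), 0, 0)
  sinfo <- data.frame()
  if (!is.null(geno)) {
    colnames(geno) <- ids
    rownames(geno) <- NULL
    genoM <- geno
    sinfo <- data.frame(sample_id = paste0("S", seq_along(popLabels)),
                        population = popLabels, stringsAsFactors = FALSE)
  }
  PDCohort(minorCounts = minor, alleleTotals = totals, variantInfo = vi,
           populations = names(spec$popSizes), baseline = spec$baseline,
           genotypes = genoM, sampleInfo = sinfo, metadata = md)
}

#' Empirical type-I error of the gene test under the null
#'
#' Simulates genes of independent, identically-frequent variants (no
#' population differentiation), applies the gene test with one or more
#' weighting schemes to every replicate, and reports the fraction of
#' replicates rejected at level `alpha`.  All schemes are evaluated on
#' the same simulated replicates, which makes their rates directly
#' comparable.  Counts are drawn with the binomial counts-only sampler
#' (distributionally identical to per-individual genotypes for
#' independent variants).
#'
#' @param spec A null, LD-independent [cohortSpec()]; its `nVariants` is
#'   ignored in favour of `geneSize`.
#' @param geneSize Number of variants per simulated gene.
#' @param schemes Weighting scheme(s) to evaluate.
#' @param reps Number of replicate genes (>= 100 recommended; fewer
#'   triggers a warning).
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return Named numeric vector of empirical rejection rates, one per
#'   scheme, with attributes `reps`, `alpha` and `mc_se` (binomial
#'   Monte-Carlo standard error at the nominal level).
#' @export
type1Error <- function(spec, geneSize = 200L,
                       schemes = c("equal", "inv_maf", "inv_maf_sq"),
                       reps = 5000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (spec$pdModel != "null" || spec$ldModel != "independent")
    stop("type-I error is defined for a null, LD-independent spec")
  schemes <- match.arg(schemes, .SCHEMES, several.ok = TRUE)
  if (reps < 100L) warning("fewer than 100 replicates: unstable estimate")
  if (!is.null(seed)) set.seed(seed)
  sizes2 <- 2L * as.integer(spec$popSizes)
  total <- matrix(sizes2, geneSize, length(sizes2), byrow = TRUE)
  hits <- matrix(0L, reps, length(schemes),
                 dimnames = list(NULL, schemes))
  for (r in seq_len(reps)) {
    sim <- .simulateCountsOnly(spec, q = geneSize)
    maf <- rowSums(sim$minor) / rowSums(total)
    for (j in seq_along(schemes)) {
      w <- variantWeights(maf, schemes[j])
      k <- .pdrcKernel(sim$minor, total, w)
      hits[r, j] <- !is.na(k$L2) &&
        pdrcPvalue(k$L2, k$df) <= alpha
    }
  }
  structure(colMeans(hits), reps = reps, alpha = alpha,
            mc_se = sqrt(alpha * (1 - alpha) / reps))
}

#' Null-simulation draws of the gene statistic
#'
#' Simulates replicate genes under the null (no differentiation,
#' independent variants) and returns the gene statistic of every
#' replicate -- the raw material for calibration studies: the empirical
#' mean estimates the chi-square degrees of freedom, and the empirical
#' distribution can be compared against the chi-square reference.
#'
#' @param spec A null, LD-independent [cohortSpec()].
#' @param geneSize Variants per replicate gene.
#' @param scheme Weighting scheme.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `reps` statistic values (`NA` for the rare
#'   fully-degenerate replicate), with the common degrees of freedom as
#'   attribute `df`.
#' @export
nullStatistics <- function(spec, geneSize = 10L, scheme = "equal",
                           reps = 1000L, seed = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (spec$pdModel != "null" || spec$ldModel != "independent")
    stop("null statistics require a null, LD-independent spec")
  scheme <- match.arg(scheme, .SCHEMES)
  if (!is.null(seed)) set.seed(seed)
  sizes2 <- 2L * as.integer(spec$popSizes)
  total <- matrix(sizes2, geneSize, length(sizes2), byrow = TRUE)
  out <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- .simulateCountsOnly(spec, q = geneSize)
    w <- variantWeights(rowSums(sim$minor) / rowSums(total), scheme)
    out[r] <- .pdrcKernel(sim$minor, total, w)$L2
  }
  structure(out, df = length(sizes2) - 1L)
}

#' Label-permutation null for one gene
#'
#' Recomputes the gene statistic under random permutations of the
#' population labels over individuals.  Whole genotype vectors travel
#' with their individual, so within-individual dependence between
#' variants (linkage disequilibrium) is preserved, which the chi-square
#' reference distribution ignores.  The empirical p-value uses add-one
#' smoothing: `(1 + #{L2_perm >= L2_obs}) / (B + 1)`.
#'
#' @param cohort A [PDCohort-class] carrying genotypes (see
#'   `keepGenotypes` in [simulateCohort()] / [readVcfCounts()]).
#' @param gene Gene id, or `NULL` with explicit `variants`.
#' @param variants Optional explicit variant ids.
#' @param scheme Weighting scheme.
#' @param strategy,commonThreshold Variant selection, as in [pdrcTest()].
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return A list with `gene`, `observed_L2`, `df`, `p_chisq`
#'   (asymptotic), `B`, `empirical_p` and `perm_L2` (the permuted
#'   statistics).
#' @export
permutationNull <- function(cohort, gene = NULL, variants = NULL,
                            scheme = c("equal", "inv_maf", "inv_maf_sq"),
                            strategy = "all", commonThreshold = 0.05,
                            B = 999L, seed = NULL) {
  stopifnot(is(cohort, "PDCohort"))
  scheme <- match.arg(scheme)
  if (B < 1L) stop("B must be at least 1")
  if (nrow(cohort@genotypes) == 0L)
    stop("cohort carries no genotypes; rebuild with keepGenotypes = TRUE")
  if (is.null(variants)) {
    if (is.null(gene)) stop("either a gene or explicit variants are required")
    variants <- selectVariants(cohort, gene, strategy = strategy,
                               commonThreshold = commonThreshold)
  } else {
    variants <- selectVariants(cohort, variants = variants,
                               strategy = strategy,
                               commonThreshold = commonThreshold)
  }
  if (length(variants) == 0L) stop("no selectable variants for this gene")
  if (!is.null(seed)) set.seed(seed)
  vi <- cohort@variantInfo
  idx <- match(variants, vi$variant_id)
  geno <- cohort@genotypes[, idx, drop = FALSE]
  pops <- cohort@populations
  s <- length(pops)
  labels <- match(cohort@sampleInfo$population, pops)
  q <- length(idx)

  ## orient dosages to the pooled minor allele, then store each variant
  ## as the list of its minor-allele "carrier slots" (a dosage-2
  ## individual appears twice) plus its missing individuals; permuted
  ## counts are then a tabulate() over these short lists.
  pooled <- rowSums(cohort@minorCounts[idx, , drop = FALSE])
  totPerPopFull <- tabulate(labels, nbins = s)
  carriers <- vector("list", q)
  missers <- vector("list", q)
  for (k in seq_len(q)) {
    dos <- geno[, k]
    flipped <- sum(dos, na.rm = TRUE) != pooled[k]
    if (flipped) dos <- 2L - dos
    nz <- which(!is.na(dos) & dos > 0L)
    carriers[[k]] <- rep(nz, times = dos[nz])
    missers[[k]] <- which(is.na(dos))
  }
  w <- variantWeights(vi$maf[idx], scheme)

  statFor <- function(lab) {
    minor <- matrix(0L, q, s)
    total <- matrix(0L, q, s)
    base <- 2L * tabulate(lab, nbins = s)
    for (k in seq_len(q)) {
      minor[k, ] <- tabulate(lab[carriers[[k]]], nbins = s)
      total[k, ] <- if (length(missers[[k]]))
        base - 2L * tabulate(lab[missers[[k]]], nbins = s) else base
    }
    .pdrcKernel(minor, total, w)
  }
  obs <- statFor(labels)
  perm <- vapply(seq_len(B), function(i) statFor(sample(labels))$L2,
                 numeric(1))
  emp <- (1 + sum(perm >= obs$L2)) / (B + 1)
  list(gene = if (is.null(gene)) NA_character_ else gene,
       observed_L2 = obs$L2, df = obs$df,
       p_chisq = pdrcPvalue(obs$L2, obs$df),
       B = as.integer(B), empirical_p = emp, perm_L2 = perm)
}
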