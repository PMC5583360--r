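#' @include AllGenerics.R
NULL

#' Weighted Mantel-Haenszel odds ratio against a baseline population
#'
#' Pools, over a gene's variants, the 2 x 2 sub-tables formed by one
#' population of interest and the baseline population (rows) versus
#' minor/major allele (columns), into a weighted Mantel-Haenszel odds
#' ratio
#' \deqn{\hat\theta_{MH} =
#'   \frac{\sum_k w_k\, a_k d_k / T_k}{\sum_k w_k\, b_k c_k / T_k},}
#' where per variant \eqn{a_k,b_k} are the minor/major counts of the
#' population of interest, \eqn{c_k,d_k} those of the baseline and
#' \eqn{T_k} the combined allele total.  An estimate above 1 means the
#' population of interest carries minor alleles more often than the
#' baseline, aggregated over the gene.
#'
#' The variance of the log odds ratio uses a weighted extension of the
#' Robins-Breslow-Greenland estimator: with \eqn{R_k = w_k a_k d_k /
#' T_k}, \eqn{S_k = w_k b_k c_k / T_k}, \eqn{P_k = (a_k + d_k)/T_k},
#' \eqn{Q_k = (b_k + c_k)/T_k},
#' \deqn{\widehat{Var}(\log\hat\theta) =
#'   \frac{\sum_k w_k P_k R_k}{2R^2} +
#'   \frac{\sum_k w_k (P_k S_k + Q_k R_k)}{2RS} +
#'   \frac{\sum_k w_k Q_k S_k}{2S^2},}
#' with \eqn{R = \sum_k R_k}, \eqn{S = \sum_k S_k}.  Each stratum's
#' squared weight enters the variance exactly once (one factor inside
#' \eqn{R_k}/\eqn{S_k}, one explicit), so the estimator reduces to the
#' classical Robins-Breslow-Greenland form at unit weights and both the
#' estimate and the confidence interval are invariant to rescaling all
#' weights by a constant.
#'
#' Strata in which both cross-products are zero carry no information and
#' are skipped.  When one direction's sum is zero the odds ratio is 0 or
#' infinite, the interval is one-sided and the estimate is flagged.
#'
#' @param a,b Minor and major allele counts of the population of
#'   interest, one entry per variant.
#' @param c,d Minor and major allele counts of the baseline population.
#' @param weights Per-variant weights (default all 1).
#' @param conf Confidence level (default 0.95).
#' @return A list with `or_hat`, `log_or`, `se_log_or`, `ci_low`,
#'   `ci_high`, `n_tables_used` and `degenerate` (`TRUE` when no stratum
#'   was informative or one direction was empty).
#' @examples
#' mhOdds(a = 10, b = 90, c = 20, d = 80)   # single stratum: ad/bc
#' @export
mhOdds <- function(a, b, c, d, weights = rep(1, length(a)), conf = 0.95) {
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d), length(a) == length(weights),
            all(weights > 0), conf > 0, conf < 1)
  Ti <- a + b + c + d
  use <- Ti > 0 & (a * d > 0 | b * c > 0)
  empty <- list(or_hat = NA_real_, log_or = NA_real_,
                se_log_or = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_tables_used = 0L, degenerate = TRUE)
  if (!any(use)) return(empty)
  a <- a[use]; b <- b[use]; c <- c[use]; d <- d[use]
  w <- weights[use]; Ti <- Ti[use]
  Rk <- w * a * d / Ti
  Sk <- w * b * c / Ti
  R <- sum(Rk)
  S <- sum(Sk)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (R == 0 || S == 0) {
    ## all informative strata point in one direction: OR is 0 or +Inf
    or <- if (S == 0) Inf else 0
    return(list(or_hat = or, log_or = log(or), se_log_or = NA_real_,
                ci_low = if (S == 0) NA_real_ else 0,
                ci_high = if (S == 0) Inf else NA_real_,
                n_tables_used = length(Rk), degenerate = TRUE))
  }
  or <- R / S
  Pk <- (a + d) / Ti
  Qk <- (b + c) / Ti
  v <- sum(w * Pk * Rk) / (2 * R^2) +
       sum(w * (Pk * Sk + Qk * Rk)) / (2 * R * S) +
       sum(w * Qk * Sk) / (2 * S^2)
  se <- sqrt(v)
  list(or_hat = or, log_or = log(or), se_log_or = se,
       ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       n_tables_used = length(Rk), degenerate = FALSE)
}

#' Gene-level Mantel-Haenszel odds ratios for every population
#'
#' For each non-baseline population, pools the gene's selected variants
#' into a weighted Mantel-Haenszel odds ratio against the cohort's
#' baseline population, using the same variant selection and weighting
#' scheme as the gene statistic.
#'
#' @param cohort A [PDCohort-class].
#' @param gene Gene id, or `NULL` with explicit `variants`.
#' @param variants Optional explicit variant ids.
#' @param strategy,scheme,commonThreshold As in [pdrcTest()].
#' @param conf Confidence level.
#' @return A data.frame with one row per non-baseline population:
#'   `gene`, `population`, `baseline`, `or_hat`, `log_or`, `ci_low`,
#'   `ci_high`, `n_tables_used`, `degenerate`.
#' @examples
#' spec <- cohortSpec(popSizes = rep(100, 3), nVariants = 30, seed = 4,
#'                    pdModel = "balding_nichols", F = 0.05)
#' cohort <- simulateCohort(spec)
#' geneIndex(cohort) <- list(G1 = variantInfo(cohort)$variant_id)
#' mhOddsScan(cohort, "G1", scheme = "inv_maf")
#' @export
mhOddsScan <- function(cohort, gene = NULL, variants = NULL,
                       strategy = c("all", "rare_less_common",
                                    "protein_altering"),
                       scheme = c("equal", "inv_maf", "inv_maf_sq"),
                       commonThreshold = 0.05, conf = 0.95) {
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
  base <- cohort@baseline
  others <- setdiff(cohort@populations, base)
  label <- if (is.null(gene)) NA_character_ else gene
  out <- lapply(others, function(popn) {
    if (length(variants) == 0L) {
      est <- list(or_hat = NA_real_, log_or = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_,
                  n_tables_used = 0L, degenerate = TRUE)
    } else {
      idx <- match(variants, cohort@variantInfo$variant_id)
      w <- variantWeights(cohort@variantInfo$maf[idx], scheme)
      ai <- cohort@minorCounts[idx, popn]
      bi <- cohort@alleleTotals[idx, popn] - ai
      ci <- cohort@minorCounts[idx, base]
      di <- cohort@alleleTotals[idx, base] - ci
      est <- mhOdds(ai, bi, ci, di, weights = w, conf = conf)
    }
    data.frame(gene = label, population = popn, baseline = base,
               or_hat = est$or_hat, log_or = est$log_or,
               ci_low = est$ci_low, ci_high = est$ci_high,
               n_tables_used = est$n_tables_used,
               degenerate = est$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
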