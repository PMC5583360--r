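#' @include AllGenerics.R
NULL

#' Empirical percentile with linear interpolation
#'
#' The percentile convention used by the scan's top-percentile decision
#' rule: linear interpolation between order statistics (the default,
#' type-7 sample quantile).
#'
#' @param x Numeric vector (non-empty; `NA`s dropped).
#' @param pct Percentile in [0, 100]; default 95.
#' @return The interpolated empirical percentile.
#' @examples
#' percentileThreshold(1:100)        # 95.05
#' percentileThreshold(1:100, 100)   # the maximum
#' @export
percentileThreshold <- function(x, pct = 95) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to take a percentile of")
  stopifnot(pct >= 0, pct <= 100)
  unname(stats::quantile(x, probs = pct / 100, type = 7))
}

#' Per-gene variant composition
#'
#' Counts a gene's polymorphic variants by frequency class (common:
#' pooled MAF above `commonThreshold`; rare/less-common otherwise) and
#' the number of population-specific variants, i.e. variants whose minor
#' allele is observed in exactly one population.
#'
#' @param cohort A [PDCohort-class].
#' @param gene Gene id.
#' @param commonThreshold MAF boundary (default 0.05).
#' @return A list with `n_common`, `n_rare` and `n_population_specific`.
#' @export
geneVariantSummary <- function(cohort, gene, commonThreshold = 0.05) {
  stopifnot(is(cohort, "PDCohort"))
  ids <- selectVariants(cohort, gene, strategy = "all",
                        commonThreshold = commonThreshold)
  idx <- match(ids, cohort@variantInfo$variant_id)
  maf <- cohort@variantInfo$maf[idx]
  popsWith <- rowSums(cohort@minorCounts[idx, , drop = FALSE] > 0)
  list(n_common = sum(maf > commonThreshold),
       n_rare = sum(maf <= commonThreshold),
       n_population_specific = sum(popsWith == 1L))
}

#' Gene scan: differentiation statistics for every gene
#'
#' Runs the gene-level differentiation test for each annotated gene under
#' every requested selection strategy and weighting scheme, attaches
#' fixation-index summaries and variant composition, and applies two
#' decision rules: a Bonferroni-corrected p-value threshold (the
#' correction factor is the number of genes tested under that
#' strategy/scheme, overridable) and the empirical top-percentile rule
#' (a gene is flagged when its statistic exceeds the `pct`-th percentile
#' of the statistics of all testable genes under the same strategy and
#' scheme).
#'
#' @param cohort An annotated [PDCohort-class] (see
#'   [addGeneAnnotation()] or set [geneIndex()] directly).
#' @param strategies Selection strategies to run.
#' @param schemes Weighting schemes to run.
#' @param commonThreshold MAF boundary between rare and common.
#' @param bonferroniN Override for the Bonferroni correction factor
#'   (default: number of genes tested in this run for that
#'   strategy/scheme).
#' @param pct Percentile for the top-percentile rule (default 95).
#' @param fstCutoff High-differentiation F_st cutoff (default 0.25).
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @return A data.frame with one row per gene x strategy x scheme,
#'   ordered by (gene, strategy, scheme): the statistic (`L2`, `df`,
#'   `p_value`, `p_bonferroni`, `flag_bonferroni`, `flag_top5`), the
#'   composition (`n_variants_used`, `n_common`, `n_rare`,
#'   `n_population_specific`), the gene-level fixation index
#'   (`fst_max`, `fst_median`, `n_fst_above`) and `status`.
#' @export
pdrcScan <- function(cohort,
                     strategies = c("all", "rare_less_common",
                                    "protein_altering"),
                     schemes = c("equal", "inv_maf", "inv_maf_sq"),
                     commonThreshold = 0.05, bonferroniN = NULL,
                     pct = 95, fstCutoff = 0.25, alpha = 0.05) {
  stopifnot(is(cohort, "PDCohort"))
  strategies <- match.arg(strategies,
                          c("all", "rare_less_common", "protein_altering"),
                          several.ok = TRUE)
  schemes <- match.arg(schemes, .SCHEMES, several.ok = TRUE)
  gl <- genes(cohort)
  if (length(gl) == 0L)
    stop("cohort has no gene index; annotate it first")
  gl <- sort(gl)
  fstAll <- weirFst(cohort)

  rows <- list()
  for (g in gl) {
    summ <- geneVariantSummary(cohort, g, commonThreshold)
    gfst <- geneFstSummary(fstAll[cohort@geneIndex[[g]]], cutoff = fstCutoff)
    for (st in strategies) {
      for (sc in schemes) {
        r <- pdrcTest(cohort, g, strategy = st, scheme = sc,
                      commonThreshold = commonThreshold)
        r$n_common <- summ$n_common
        r$n_rare <- summ$n_rare
        r$n_population_specific <- summ$n_population_specific
        r$fst_max <- gfst$max
        r$fst_median <- gfst$median
        r$n_fst_above <- gfst$n_above
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$strategy, out$scheme), , drop = FALSE]
  rownames(out) <- NULL

  out$p_bonferroni <- NA_real_
  out$flag_bonferroni <- NA
  out$flag_top5 <- NA
  for (st in strategies) {
    for (sc in schemes) {
      sel <- out$strategy == st & out$scheme == sc
      ok <- sel & out$status == "ok"
      G <- if (is.null(bonferroniN)) sum(ok) else bonferroniN
      if (sum(ok) == 0L) next
      out$p_bonferroni[ok] <- pmin(1, out$p_value[ok] * G)
      out$flag_bonferroni[ok] <- out$p_bonferroni[ok] < alpha
      thr <- percentileThreshold(out$L2[ok], pct)
      out$flag_top5[ok] <- out$L2[ok] > thr
    }
  }
  attr(out, "pct") <- pct
  attr(out, "alpha") <- alpha
  out
}

#' Write a scan report to a TSV file
#'
#' Writes the scan table with a `#`-prefixed header block recording the
#' package version, the scan configuration and MD5 checksums of the
#' input files, so a report identifies the run that produced it.
#' Reports are byte-stable across runs on identical inputs.
#'
#' @param scan Output of [pdrcScan()].
#' @param path Output file path.
#' @param inputs Optional character vector of input file paths to
#'   checksum into the header.
#' @return `path`, invisibly.
#' @export
writeScanReport <- function(scan, path, inputs = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("pdrc")),
                  error = function(e) "unknown")
  writeLines(sprintf("# pdrc scan report (pdrc %s)", ver), con)
  writeLines(sprintf("# percentile=%s alpha=%s",
                     attr(scan, "pct"), attr(scan, "alpha")), con)
  for (f in inputs)
    writeLines(sprintf("# input %s md5=%s", f,
                       unname(tools::md5sum(f))), con)
  utils::write.table(scan, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a scan report
#'
#' Re-reads a TSV written by [writeScanReport()], skipping the header
#' block; numeric columns round-trip exactly at the printed precision.
#'
#' @param path Report path.
#' @return The scan data.frame.
#' @export
readScanReport <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
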