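# Builders for tiny in-code fixtures and independent oracle
# implementations used across the test files.

# cohort straight from count matrices (variants x populations)
makeCohort <- function(minor, total, pops = paste0("P", seq_len(ncol(minor))),
                       baseline = NULL, ...) {
  PDCohort(minorCounts = minor, alleleTotals = total,
           populations = pops, baseline = baseline, ...)
}

# write a small VCF to a temp file; gts is a variants x samples character
# matrix of GT strings, fix a data.frame with chrom/pos/id/ref/alt
writeTestVcf <- function(fix, gts, samples = colnames(gts)) {
  path <- tempfile(fileext = ".vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(nrow(fix))) {
    lines <- c(lines, paste(c(fix$chrom[i], fix$pos[i], fix$id[i],
                              fix$ref[i], fix$alt[i], ".", "PASS", ".",
                              "GT", gts[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

writePopmapFile <- function(samples, pops) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}

writeAnnotFile <- function(variant_id, gene, protein_altering) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = variant_id, gene = gene,
                   protein_altering = protein_altering)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# ---- independent oracles ------------------------------------------------

# fixation index through the ANOVA mean-square formulation for binary
# (allele-level) data -- an algebraically different route to the
# variance-component estimator than the package's a/b accumulation
fstAnovaOracle <- function(minor, total) {
  n <- total[total > 0]
  p <- minor[total > 0] / n
  r <- length(n)
  nsum <- sum(n)
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  pbar <- sum(n * p) / nsum
  msb <- sum(n * (p - pbar)^2) / (r - 1)
  msw <- sum(n * p * (1 - p)) / (nsum - r)
  (msb - msw) / (msb + (nc - 1) * msw)
}

# single-stratum Pearson chi-square (no continuity correction)
pearsonChisq <- function(tab) {
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

# random s x 2 tables with all-positive margins
randomTable <- function(s = 5, lambda = 30) {
  repeat {
    tab <- matrix(rpois(2 * s, lambda), s, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# small null cohort used by several files
smallNullCohort <- function(seed = 1, nVariants = 40, popSize = 100,
                            s = 3, ...) {
  simulateCohort(cohortSpec(popSizes = rep(popSize, s),
                            nVariants = nVariants, seed = seed, ...))
}
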