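#' @include AllGenerics.R
NULL

#' Read a sample-to-population map
#'
#' Reads a two-column whitespace- or tab-delimited file mapping sample ids
#' to population labels.  An optional header line is recognised when the
#' first line does not reappear among the sample ids and looks like
#' column names (`sample`/`id` and `pop`-like tokens).  Population labels
#' are recorded in first-appearance order.
#'
#' @param path Path to the map file.
#' @param baseline Baseline population label; defaults to the last label
#'   in first-appearance order.
#' @return A data.frame with columns `sample_id` and `population`, plus
#'   attributes `populations` (label order) and `baseline`.
#' @export
readPopulationMap <- function(path, baseline = NULL) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("sample_id", "population"),
                           stringsAsFactors = FALSE)
  if (nrow(raw) > 0 &&
      grepl("^(sample|id|iid)", raw$sample_id[1], ignore.case = TRUE) &&
      grepl("^pop", raw$population[1], ignore.case = TRUE))
    raw <- raw[-1, , drop = FALSE]
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s) in population map: ",
         paste(unique(dup), collapse = ", "))
  pops <- unique(raw$population)
  if (length(pops) < 2L)
    stop("population map must contain at least 2 distinct labels")
  if (is.null(baseline)) baseline <- pops[length(pops)]
  if (!baseline %in% pops)
    stop(sprintf("baseline '%s' is not a population label in the map",
                 baseline))
  rownames(raw) <- NULL
  structure(raw, populations = pops, baseline = baseline)
}

## Map diploid GT strings to dosage of the ALT allele; anything not in
## this table (half-missing like "0/.", malformed strings) is missing.
.GT_DOSAGE <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)

.SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24")

#' Build per-population allele counts from a VCF
#'
#' Reads a VCF (plain or bgzipped), keeps biallelic SNV records, and
#' tallies for every variant the minor- and total-allele counts per
#' population.  Missing genotypes (`./.` and half-calls) are excluded
#' from that variant's denominators; the minor allele is the globally
#' rarer allele in the pooled cohort (ties at 0.5 resolved to ALT).
#' Monomorphic variants are retained but flagged; they are filtered by
#' [selectVariants()] before any statistic is computed.  Multiallelic
#' records, non-SNVs and (by default) sex-chromosome records are skipped
#' with counters recorded in the result's metadata.
#'
#' @param vcfPath Path to the VCF file.
#' @param popmap Output of [readPopulationMap()].  Samples present in the
#'   VCF but absent from the map are dropped with a warning; every mapped
#'   sample must be present in the VCF.
#' @param baseline Optional baseline override (defaults to the map's).
#' @param excludeSexChrom Drop X/Y records (default `TRUE`).
#' @param keepGenotypes Retain the sample x variant dosage matrix (needed
#'   later for label permutation); default `TRUE`.
#' @return A [PDCohort-class].
#' @export
readVcfCounts <- function(vcfPath, popmap, baseline = NULL,
                          excludeSexChrom = TRUE, keepGenotypes = TRUE) {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_records <- nrow(fix)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  snv <- !is.na(alt) & !multi & nchar(ref) == 1L & nchar(alt) == 1L &
         ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  sex <- fix[, "CHROM"] %in% .SEX_CHROMS
  keep <- snv & (!excludeSexChrom | !sex)
  if (sum(multi))
    warning(sum(multi), " multiallelic record(s) skipped")
  if (!any(keep))
    stop("no biallelic SNV records retained from ", vcfPath)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  vcf_samples <- colnames(gt)
  extra <- setdiff(vcf_samples, popmap$sample_id)
  if (length(extra)) {
    warning(length(extra), " VCF sample(s) absent from the population ",
            "map were dropped")
    gt <- gt[, setdiff(vcf_samples, extra), drop = FALSE]
  }
  missing_samples <- setdiff(popmap$sample_id, colnames(gt))
  if (length(missing_samples))
    stop("mapped sample(s) missing from the VCF: ",
         paste(missing_samples, collapse = ", "))
  gt <- gt[, popmap$sample_id, drop = FALSE]
  pops <- attr(popmap, "populations")
  if (is.null(baseline)) baseline <- attr(popmap, "baseline")

  ## strip any trailing fields and map to ALT dosage
  gt <- sub(":.*$", "", gt)
  dos <- matrix(.GT_DOSAGE[gt], nrow = nrow(gt),
                dimnames = dimnames(gt))
  recognised <- gt %in% c(names(.GT_DOSAGE), "./.", ".|.", ".")
  n_malformed <- sum(!recognised & !is.na(gt))
  if (n_malformed)
    warning(n_malformed, " unrecognised GT value(s) treated as missing")

  popf <- factor(popmap$population, levels = pops)
  altCounts <- t(rowsum(t(ifelse(is.na(dos), 0L, dos)), popf))
  called <- t(rowsum(t(1L - is.na(dos)), popf))
  totals <- 2L * called

  ids <- fix[, "ID"]
  fallback <- paste(fix[, "CHROM"], fix[, "POS"], ref[keep], alt[keep],
                    sep = "_")
  ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  ## minor allele from pooled counts; ties at 0.5 resolve to ALT
  pooledTot <- rowSums(totals)
  altFreq <- ifelse(pooledTot > 0, rowSums(altCounts) / pmax(pooledTot, 1), 0)
  flip <- altFreq > 0.5
  minor <- altCounts
  minor[flip, ] <- totals[flip, , drop = FALSE] - altCounts[flip, , drop = FALSE]

  vi <- data.frame(variant_id = ids,
                   chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]),
                   stringsAsFactors = FALSE)
  geno <- matrix(integer(), 0, 0)
  sinfo <- data.frame()
  if (keepGenotypes) {
    geno <- t(dos)
    colnames(geno) <- ids
    sinfo <- data.frame(sample_id = popmap$sample_id,
                        population = popmap$population,
                        stringsAsFactors = FALSE)
  }
  PDCohort(minorCounts = minor, alleleTotals = totals, variantInfo = vi,
           populations = pops, baseline = baseline,
           genotypes = geno, sampleInfo = sinfo,
           metadata = list(source = vcfPath,
                           n_records = n_records,
                           n_multiallelic = sum(multi),
                           n_non_snv = sum(!snv & !multi),
                           n_sex_excluded = sum(snv & sex & excludeSexChrom),
                           n_malformed_gt = n_malformed))
}

#' Attach gene and protein-altering annotation to a cohort
#'
#' Reads a tab-delimited annotation table with columns `variant_id`,
#' `gene` and `protein_altering` (0/1), builds the gene index (a variant
#' annotated to several genes on separate rows appears in each gene's
#' list) and attaches the protein-altering flag to matching variants.
#' Annotated variants absent from the cohort are counted and ignored.
#'
#' @param cohort A [PDCohort-class].
#' @param annotation Path to the annotation file, or an equivalent
#'   data.frame.
#' @return The cohort with `geneIndex` and `variantInfo$proteinAltering`
#'   filled in; the number of ignored annotation rows is stored in the
#'   metadata as `n_annot_unmatched`.
#' @export
addGeneAnnotation <- function(cohort, annotation) {
  stopifnot(is(cohort, "PDCohort"))
  ann <- if (is.character(annotation)) {
    utils::read.table(annotation, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else as.data.frame(annotation)
  needed <- c("variant_id", "gene", "protein_altering")
  if (nrow(ann) == 0L) {
    warning("empty annotation: gene index is empty")
    cohort@geneIndex <- list()
    return(cohort)
  }
  if (!all(needed %in% names(ann)))
    stop("annotation needs columns: ", paste(needed, collapse = ", "))
  vi <- cohort@variantInfo
  known <- ann$variant_id %in% vi$variant_id
  if (any(!known))
    message(sum(!known), " annotated variant(s) not present in the ",
            "cohort were ignored")
  ann <- ann[known, , drop = FALSE]
  idx <- split(ann$variant_id, ann$gene)
  cohort@geneIndex <- lapply(idx, unique)
  pa <- tapply(as.logical(ann$protein_altering), ann$variant_id, any)
  m <- match(vi$variant_id, names(pa))
  vi$proteinAltering <- ifelse(is.na(m), NA, unname(pa[m]))
  genemap <- vapply(split(ann$gene, ann$variant_id),
                    function(g) paste(unique(g), collapse = ","), character(1))
  mg <- match(vi$variant_id, names(genemap))
  vi$gene <- ifelse(is.na(mg), "", unname(genemap[mg]))
  cohort@variantInfo <- vi
  cohort@metadata$n_annot_unmatched <- sum(!known)
  validObject(cohort)
  cohort
}
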