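test_that("cohort specs validate their parameters", {
  expect_error(cohortSpec(pdModel = "balding_nichols"), "F in \\(0, 1\\)")
  expect_error(cohortSpec(pdModel = "balding_nichols", F = 1.2), "F in")
  expect_error(cohortSpec(popSizes = 100), "length")
  sp <- cohortSpec(popSizes = c(10, 10), nVariants = 5, seed = 1)
  expect_s3_class(sp, "CohortSpec")
  expect_equal(sp$baseline, "POP2")
})

test_that("simulation is bit-identical given the same spec and seed", {
  for (ld in c("independent", "block")) {
    spec <- cohortSpec(popSizes = rep(60, 3), nVariants = 30,
                       ldModel = ld, blockSize = 5, rho = 0.6, seed = 42)
    a <- simulateCohort(spec)
    b <- simulateCohort(spec)
    expect_identical(genotypes(a), genotypes(b))
    expect_identical(minorCounts(a), minorCounts(b))
  }
  # counts-only path is deterministic too
  spec <- cohortSpec(popSizes = rep(60, 3), nVariants = 30, seed = 43)
  expect_identical(minorCounts(simulateCohort(spec, keepGenotypes = FALSE)),
                   minorCounts(simulateCohort(spec, keepGenotypes = FALSE)))
})

test_that("every simulated variant is polymorphic with a valid pooled MAF", {
  spec <- cohortSpec(popSizes = rep(40, 4), nVariants = 120,
                     sfs = sfsRareHeavy(), seed = 7)
  co <- simulateCohort(spec)
  vi <- variantInfo(co)
  expect_true(all(!vi$monomorphic))
  expect_true(all(vi$maf > 0 & vi$maf <= 0.5))
  # counts agree with the retained genotypes
  g <- genotypes(co)
  pops <- sampleInfo(co)$population
  alt <- t(rowsum(g, pops))[, populations(co), drop = FALSE]
  flip <- !vi$minor_is_alt
  expected <- alt
  expected[flip, ] <- alleleTotals(co)[flip, , drop = FALSE] - alt[flip, , drop = FALSE]
  expect_equal(unname(minorCounts(co)), unname(expected[, populations(co)]))
})

test_that("the rare-heavy spectrum is dominated by sub-3% frequencies", {
  set.seed(3)
  p <- sfsRareHeavy()(20000)
  expect_lt(abs(mean(p < 0.03) - 0.975), 0.01)
  expect_true(all(p > 0 & p <= 0.5))
  pc <- sfsCommonHeavy()(1000)
  expect_true(all(pc >= 0.05 & pc <= 0.5))
})

test_that("null cohorts are exchangeable across populations", {
  # per-variant 2x2 allele-count tables between two equally sized
  # populations under the null give uniform chi-square p-values
  spec <- cohortSpec(popSizes = c(400, 400), nVariants = 400,
                     sfs = sfsUniform(0.1, 0.5), seed = 13)
  co <- simulateCohort(spec, keepGenotypes = FALSE)
  m <- minorCounts(co); tt <- alleleTotals(co)
  pv <- vapply(seq_len(nrow(m)), function(k) {
    tab <- rbind(c(m[k, 1], tt[k, 1] - m[k, 1]),
                 c(m[k, 2], tt[k, 2] - m[k, 2]))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  # discrete counts produce tied p-values; the KS approximation is fine
  # at this scale
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("Balding-Nichols differentiation rises with F", {
  set.seed(17)
  ests <- vapply(c(0.01, 0.05, 0.1), function(F) {
    spec <- cohortSpec(popSizes = rep(300, 3), nVariants = 200,
                       sfs = sfsUniform(0.05, 0.5),
                       pdModel = "balding_nichols", F = F,
                       seed = round(1000 * F))
    multiLocusFst(simulateCohort(spec, keepGenotypes = FALSE))
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
  expect_lt(abs(ests[3] - 0.1), 0.03)
})

test_that("type-I error machinery behaves at the edges", {
  spec <- cohortSpec(popSizes = rep(100, 3), nVariants = 1)
  expect_warning(type1Error(spec, geneSize = 5, reps = 50, seed = 1),
                 "unstable")
  r <- suppressWarnings(
    type1Error(spec, geneSize = 5, schemes = "equal", reps = 120,
               alpha = 1, seed = 2))
  expect_equal(unname(r["equal"]), 1)
  bn <- cohortSpec(popSizes = rep(100, 3), nVariants = 1,
                   pdModel = "balding_nichols", F = 0.1)
  expect_error(type1Error(bn, geneSize = 5, reps = 200), "null")
})

test_that("statistical power grows with the differentiation parameter", {
  set.seed(23)
  power <- vapply(c(0.01, 0.05, 0.1), function(F) {
    hits <- vapply(1:150, function(r) {
      spec <- cohortSpec(popSizes = rep(100, 3), nVariants = 12,
                         sfs = sfsUniform(0.05, 0.3),
                         pdModel = "balding_nichols", F = F,
                         seed = round(1e5 * F) + r)
      co <- simulateCohort(spec, keepGenotypes = FALSE)
      p <- pdrcTest(co, variants = variantInfo(co)$variant_id,
                    scheme = "equal")$p_value
      p < 0.05
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(power) >= -0.05))  # non-decreasing up to MC slack
  expect_gt(power[3], power[1])
})

test_that("permutation p-values match exact enumeration at tiny n", {
  # 6 individuals, 2 populations of 3: compare the add-one smoothed
  # permutation p against the exact proportion over all 20 label
  # assignments, computed by brute force from explicit count tables
  set.seed(31)
  geno <- matrix(rbinom(6 * 4, 2, 0.4), 6, 4)
  storage.mode(geno) <- "integer"
  keep <- colSums(geno) > 0 & colSums(geno) < 12
  geno <- geno[, keep, drop = FALSE]
  q <- ncol(geno)
  labels <- rep(c("P1", "P2"), each = 3)
  alt <- t(rowsum(geno, labels))
  totals <- matrix(6L, q, 2)
  flip <- rowSums(alt) / 12 > 0.5
  minor <- alt; minor[flip, ] <- 6L - alt[flip, , drop = FALSE]
  co <- PDCohort(minor, totals, populations = c("P1", "P2"),
                 genotypes = geno,
                 sampleInfo = data.frame(sample_id = paste0("S", 1:6),
                                         population = labels))
  ids <- variantInfo(co)$variant_id
  res <- permutationNull(co, variants = ids, scheme = "equal",
                         B = 4000, seed = 5)

  # oracle: enumerate all assignments of 3 individuals to population 1
  combos <- utils::combn(6, 3)
  L2all <- apply(combos, 2, function(ix) {
    lab <- rep("P2", 6); lab[ix] <- "P1"
    altp <- t(rowsum(geno, lab))
    mp <- altp; mp[flip, ] <- 6L - altp[flip, , drop = FALSE]
    cop <- PDCohort(mp, totals, populations = c("P1", "P2"))
    pdrcTest(cop, variants = variantInfo(cop)$variant_id,
             scheme = "equal")$L2
  })
  exact <- mean(L2all >= res$observed_L2 - 1e-12)
  expect_lt(abs(res$empirical_p - exact), 0.03)
  expect_gte(res$empirical_p, 1 / 4001)
  expect_lte(res$empirical_p, 1)
})

test_that("permutation extremes give the boundary p-values", {
  # a strongly differentiated gene: the observed statistic beats every
  # permutation, so the smoothed p hits its floor 1/(B+1)
  spec <- cohortSpec(popSizes = rep(80, 3), nVariants = 15,
                     sfs = sfsUniform(0.1, 0.4),
                     pdModel = "balding_nichols", F = 0.4, seed = 61)
  co <- simulateCohort(spec)
  res <- permutationNull(co, variants = variantInfo(co)$variant_id,
                         scheme = "equal", B = 19, seed = 62)
  expect_equal(res$empirical_p, 1 / 20)
  expect_error(permutationNull(co, variants = variantInfo(co)$variant_id,
                               B = 0), "at least 1")
  co2 <- simulateCohort(spec, keepGenotypes = FALSE)
  expect_error(permutationNull(co2, variants = variantInfo(co2)$variant_id),
               "no genotypes")
})

test_that("simulation metadata records the generating conditions", {
  spec <- cohortSpec(popSizes = rep(30, 3), nVariants = 10, seed = 71)
  co <- simulateCohort(spec)
  md <- co@metadata
  expect_true(md$simulated)
  expect_equal(md$spec$seed, 71)
  expect_equal(md$sfs_label, "rare_heavy")
  expect_equal(md$spec$pdModel, "null")
})
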