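test_that("conditional moments match the scalar hand calculation", {
  # s=2 table [[10,90],[20,80]]: n=10, mu=100*30/200, V from the margins
  cp <- gcmhComponents(cbind(c(10, 20), c(90, 80)))
  expect_equal(cp$n, 10)
  expect_equal(cp$mu, 100 * 30 / 200)
  expect_equal(cp$V[1, 1], 100 * (200 - 100) * 30 * (200 - 30) /
                 (200^2 * 199))

  # identical row proportions: free cells equal their expectation
  cp2 <- gcmhComponents(cbind(c(10, 10), c(90, 90)))
  expect_equal(cp2$n, cp2$mu)

  # monomorphic tables are rejected (either allele fixed)
  expect_error(gcmhComponents(cbind(c(0, 0), c(10, 10))), "monomorphic")
  expect_error(gcmhComponents(cbind(c(5, 5), c(0, 0))), "monomorphic")
})

test_that("weights follow the scheme definitions and reject MAF = 0", {
  expect_equal(variantWeights(c(0.05, 0.1), "equal"), c(1, 1))
  expect_equal(variantWeights(0.05, "inv_maf"), 20)
  expect_equal(variantWeights(0.05, "inv_maf_sq"), 400)
  expect_error(variantWeights(c(0.1, 0), "inv_maf"), "positive MAF")
})

test_that("single-stratum statistic equals (N-1)/N times Pearson chi-square", {
  set.seed(101)
  for (i in 1:50) {
    s <- sample(2:6, 1)
    tab <- randomTable(s = s)
    res <- pdrcStatistic(list(gcmhComponents(tab)))
    N <- sum(tab)
    expect_equal(res$L2, (N - 1) / N * pearsonChisq(tab), tolerance = 1e-12)
    expect_equal(res$df, s - 1L)
  }
})

test_that("the statistic is invariant to variant order, weight scale and
           population relabelling", {
  set.seed(7)
  tabs <- replicate(6, randomTable(s = 4), simplify = FALSE)
  mafs <- vapply(tabs, function(t) sum(t[, 1]) / sum(t), numeric(1))
  comps <- function(order, wmult = 1, perm = 1:4) {
    lapply(order, function(k)
      gcmhComponents(tabs[[k]][perm, ], weight = wmult / mafs[k]))
  }
  base <- pdrcStatistic(comps(1:6))
  # variant order
  expect_equal(pdrcStatistic(comps(sample(1:6)))$L2, base$L2)
  # weight scale
  expect_equal(pdrcStatistic(comps(1:6, wmult = 10))$L2, base$L2,
               tolerance = 1e-12)
  # consistent relabelling of the populations across all tables
  for (i in 1:5) {
    perm <- sample(1:4)
    expect_equal(pdrcStatistic(comps(1:6, perm = perm))$L2, base$L2,
                 tolerance = 1e-9)
  }
})

test_that("identical row proportions across the board give L2 = 0, p = 1", {
  tab <- cbind(c(10, 20, 30), c(90, 180, 270))
  res <- pdrcStatistic(list(gcmhComponents(tab)))
  expect_equal(res$L2, 0)
  expect_equal(res$p_value, 1)
})

test_that("p-values come from the upper chi-square tail with df = s - 1", {
  expect_equal(pdrcPvalue(0, 4), 1)
  expect_lt(abs(pdrcPvalue(9.488, 4) - 0.050), 2e-4)
  # five populations, two allele categories -> df 4
  tab5 <- randomTable(s = 5)
  expect_equal(pdrcStatistic(list(gcmhComponents(tab5)))$df, 4L)
  expect_error(pdrcPvalue(-1, 4))
})

test_that("pdrcTest agrees with the explicit component route", {
  co <- smallNullCohort(seed = 21, nVariants = 15, s = 4)
  ids <- variantInfo(co)$variant_id
  geneIndex(co) <- list(G = ids)
  for (sc in c("equal", "inv_maf", "inv_maf_sq")) {
    r <- pdrcTest(co, "G", scheme = sc)
    w <- variantWeights(variantInfo(co)$maf, sc)
    comps <- lapply(seq_along(ids), function(k)
      gcmhComponents(variantTable(co, ids[k]), weight = w[k]))
    expect_equal(r$L2, pdrcStatistic(comps)$L2, tolerance = 1e-10)
    expect_equal(r$df, 3L)
  }
})

test_that("rank deficiency yields a generalized inverse and reduced df", {
  # a population with zero alleles at every variant removes one free cell
  minor <- rbind(c(5L, 0L, 3L), c(2L, 0L, 8L))
  total <- rbind(c(50L, 0L, 50L), c(50L, 0L, 50L))
  co <- makeCohort(minor, total, geneIndex = list(G = c("v1", "v2")))
  r <- pdrcTest(co, "G")
  expect_equal(r$status, "ok")
  # the empty population contributes a null direction: df 2 -> 1
  expect_equal(r$df, 1L)
  expect_gte(r$L2, 0)
})

test_that("genes with no usable signal are untestable, not numeric", {
  minor <- matrix(0L, 2, 3)
  total <- matrix(100L, 2, 3)
  co <- makeCohort(minor, total, geneIndex = list(G = c("v1", "v2")))
  r <- pdrcTest(co, "G")   # both variants monomorphic -> empty selection
  expect_equal(r$status, "untestable")
  expect_true(is.na(r$L2))
  expect_equal(r$n_variants_used, 0L)
})

test_that("under the null the statistic has mean df for every scheme", {
  set.seed(31)
  spec <- cohortSpec(popSizes = rep(250, 5), nVariants = 1,
                     sfs = sfsUniform(0.02, 0.5))
  sizes2 <- rep(500L, 5)
  total <- matrix(sizes2, 20, 5, byrow = TRUE)
  reps <- 600
  L2 <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    sim <- pdrc:::.simulateCountsOnly(spec, q = 20)
    maf <- rowSums(sim$minor) / rowSums(total)
    for (j in 1:3) {
      w <- variantWeights(maf, c("equal", "inv_maf", "inv_maf_sq")[j])
      L2[r, j] <- pdrc:::.pdrcKernel(sim$minor, total, w)$L2
    }
  }
  # E[L2] = df exactly (the summed covariance is the exact conditional
  # covariance); Monte-Carlo tolerance ~ 4 SE of a chi-square(4) mean
  for (j in 1:3)
    expect_lt(abs(mean(L2[, j]) - 4), 4 * sqrt(8 / reps))
})

test_that("equal-weight extremes grow with MAF while 1/MAF contributions do not", {
  # fixed-margin extremal tables: two equal populations, every minor
  # allele in the first one
  mafGrid <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
  nAll <- 2000L
  L2max <- dev_equal <- dev_inv <- numeric(length(mafGrid))
  for (i in seq_along(mafGrid)) {
    m <- as.integer(2 * nAll * mafGrid[i])
    tab <- cbind(c(m, 0L), c(nAll - m, nAll))
    cp <- gcmhComponents(tab)
    L2max[i] <- pdrcStatistic(list(cp))$L2
    dev_equal[i] <- abs(cp$n - cp$mu)            # B_k(n_k - mu_k), w = 1
    dev_inv[i] <- abs(cp$n - cp$mu) / mafGrid[i] # w = 1/MAF
  }
  # maximum attainable statistic rises with MAF under equal weights
  expect_true(all(diff(L2max) > 0))
  # the equal-weight deviation grows linearly with MAF ...
  expect_true(all(diff(dev_equal) > 0))
  expect_gt(max(dev_equal) / min(dev_equal), 20)
  # ... while the inverse-MAF weighted deviation is flat (attenuated)
  expect_lt(max(dev_inv) / min(dev_inv), 1.2)
})
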