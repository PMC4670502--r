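makeFit <- function(gamma, rss, n, theta = numeric(0)) {
  new("BridgeFit", gamma = gamma, theta = theta, intercept = 0,
      kappa = 0.5, nu = 0.01, activeSet = which(gamma != 0),
      rss = rss, n = as.integer(n), bic = NA_real_, converged = TRUE)
}

test_that("the LR statistic is the Gaussian profile likelihood ratio", {
  set.seed(31)
  y <- rnorm(10)
  rss0 <- sum((y - mean(y))^2)
  fit <- makeFit(c(0.5, 0), rss = rss0 / 2, n = 10)
  lr <- lrStatistic(y, NULL, fit)
  expect_equal(lr$statistic, 10 * log(2), tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  # equal fits give a zero statistic; empty active sets give (0, 0)
  expect_equal(lrStatistic(y, NULL, makeFit(c(1), rss0, 10))$statistic, 0)
  empty <- lrStatistic(y, NULL, makeFit(c(0, 0), rss0 * 2, 10))
  expect_equal(empty$statistic, 0)
  expect_equal(empty$df, 0L)
  expect_error(lrStatistic(y, NULL, makeFit(c(1), rss0 + 1, 10)),
               "worse than the null")
})

test_that("chi-square reference matches quantile oracles", {
  expect_equal(regionPvalue(0, 3), 1)
  expect_equal(regionPvalue(5, 0), 1)
  expect_equal(regionPvalue(3.8415, 1), 0.05, tolerance = 1e-4)
  expect_equal(regionPvalue(5.9915, 2), 0.05, tolerance = 1e-4)
  expect_error(regionPvalue(-1, 1), "non-negative")
})

test_that("permutation p-values are reproducible lattice values", {
  set.seed(32)
  d <- simulationDesign(n = 120, nRegions = 1, variantsPerRegion = 20,
                        nBlocks = 2, seed = 32L)
  X <- dosages(simulateGenotypes(d)$G)
  y <- rnorm(120)
  B <- 33L
  p1 <- permutationPvalue(X, y, B = B, seed = 5)
  p2 <- permutationPvalue(X, y, B = B, seed = 5)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_equal((B + 1) * as.numeric(p1), round((B + 1) * as.numeric(p1)),
               tolerance = 1e-9)
  expect_error(permutationPvalue(X, y, B = 0), "one permutation")
  # a strong signal exhausts the add-one bound 1/(B+1)
  ysig <- y + 5 * X[, 3]
  expect_equal(as.numeric(permutationPvalue(X, ysig, B = 19, seed = 5)),
               1 / 20)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(33)
  d <- simulationDesign(n = 60, nRegions = 1, variantsPerRegion = 8,
                        nBlocks = 1, blockSize = 4, seed = 33L)
  ctl <- ccrsControl()
  pv <- vapply(1:150, function(i) {
    X <- dosages(simulateGenotypes(d, seed = 1000 + i)$G)
    y <- rnorm(60)
    as.numeric(permutationPvalue(X, y, control = ctl, B = 99,
                                 seed = 2000 + i))
  }, numeric(1))
  # lattice p-values tie; the KS distance is still the right summary
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.05)
})

test_that("the statistic is invariant to phenotype shifts and covariate recoding", {
  set.seed(34)
  d <- simulationDesign(n = 100, nRegions = 1, variantsPerRegion = 15,
                        nBlocks = 2, seed = 34L)
  X <- dosages(simulateGenotypes(d)$G)
  Tm <- cbind(rnorm(100), rbinom(100, 1, 0.5))
  y <- rnorm(100) + Tm %*% c(1, -2) + X[, 4]
  r1 <- runCCRSWindow(X, y, Tm, seed = 1)
  r2 <- runCCRSWindow(X, y + 17.3, Tm, seed = 1)
  Trecode <- sweep(Tm %*% matrix(c(2, 1, 0.5, -1), 2, 2), 2, c(3, -4), "+")
  r3 <- runCCRSWindow(X, y, Trecode, seed = 1)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
  expect_equal(r1$statistic, r3$statistic, tolerance = 1e-6)
  expect_equal(r1$pvalue, r3$pvalue, tolerance = 1e-6)
})

test_that("constant windows are skipped with p-value 1", {
  X <- matrix(1, 30, 5)
  r <- runCCRSWindow(X, rnorm(30))
  expect_true(r$skipped)
  expect_equal(r$pvalue, 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$n_selected, 0L)
})

test_that("a strongly causal variant is detected", {
  set.seed(9)
  d <- simulationDesign(n = 400, nRegions = 1, seed = 9L)
  X <- dosages(simulateGenotypes(d)$G)
  y <- 5 * X[, 17] + rnorm(400)
  r <- runCCRSWindow(X, y, seed = 4)
  expect_lt(r$pvalue, 1e-3)
  expect_gt(r$n_selected, 0)
})

test_that("chi-square and permutation p-values agree in rank order", {
  set.seed(35)
  d <- simulationDesign(n = 150, nRegions = 30, variantsPerRegion = 20,
                        nBlocks = 2, model = 4, propInfluential = 0.5,
                        seed = 35L)
  sim <- simulateDataset(d)
  pc <- pp <- numeric(30)
  for (r in 0:29) {
    X <- dosages(sim$G)[, (r * 20 + 1):((r + 1) * 20)]
    pc[r + 1] <- runCCRSWindow(X, sim$y, regionId = r, seed = r)$pvalue
    pp[r + 1] <- runCCRSWindow(X, sim$y,
                               control = ccrsControl(pvalue = "perm",
                                                     B = 200),
                               regionId = r, seed = r)$pvalue
  }
  expect_gt(stats::cor(pc, pp, method = "spearman"), 0.9)
})

test_that("the scan ties results to window coordinates", {
  set.seed(36)
  d <- simulationDesign(n = 80, nRegions = 2, variantsPerRegion = 40,
                        seed = 36L)
  sim <- simulateDataset(d)
  scan <- ccrsScan(sim$G, sim$y, windowSize = 30, step = 20, minSize = 10,
                   methods = c("ccrs", "cast"))
  wins <- makeWindows(sim$G, 30, 20, 10)
  expect_equal(nrow(scan), 2 * nrow(wins))
  expect_setequal(unique(scan$method), c("ccrs", "cast"))
  expect_true(all(scan$pvalue >= 0 & scan$pvalue <= 1))
  expect_equal(scan$n_variants,
               wins$n_variants[match(scan$region_id, wins$region_id)])
  path <- tempfile(fileext = ".tsv")
  writeScanResults(scan, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(scan))
})

test_that("the genome-wide threshold is a reproducible min-p quantile", {
  set.seed(37)
  d <- simulationDesign(n = 80, nRegions = 3, variantsPerRegion = 25,
                        seed = 37L)
  sim <- simulateDataset(d)
  th1 <- genomewideThreshold(sim$G, sim$y, nWindows = 4, B = 50,
                             windowSize = 25, step = 25, seed = 2)
  th2 <- genomewideThreshold(sim$G, sim$y, nWindows = 4, B = 50,
                             windowSize = 25, step = 25, seed = 2)
  expect_identical(th1$threshold, th2$threshold)
  expect_true(th1$threshold > 0 && th1$threshold <= 1)
  expect_lte(th1$threshold, 0.05 + 1e-12)
  expect_equal(th1$bonferroni, 0.05 / 3)
})
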