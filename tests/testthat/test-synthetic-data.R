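test_that("simulated genotypes respect dimensions and rare MAFs", {
  d <- simulationDesign(n = 150, nRegions = 4, variantsPerRegion = 30,
                        nBlocks = 3, seed = 51L)
  out <- simulateGenotypes(d)
  D <- dosages(out$G)
  expect_equal(dim(D), c(150L, 4L * 30L))
  expect_true(all(D %in% 0:2))
  mafs <- variants(out$G)$maf
  expect_true(all(mafs > 0 & mafs <= 0.05))
  expect_length(out$blockMap, 120L)
  # same seed, bitwise-identical genotypes
  out2 <- simulateGenotypes(d)
  expect_identical(dosages(out2$G), D)
})

test_that("empirical MAFs track their targets", {
  d <- simulationDesign(n = 5000, nRegions = 1, mafLow = 0.03,
                        mafHigh = 0.03, seed = 52L)
  G <- simulateGenotypes(d)$G
  hit <- abs(variants(G)$maf - 0.03) <= 0.01
  expect_gte(mean(hit), 0.95)
})

test_that("LD blocks create correlation and independence elsewhere", {
  # rhoLD = 0: essentially uncorrelated dosages within a region
  d0 <- simulationDesign(n = 2000, nRegions = 1, variantsPerRegion = 30,
                         rhoLD = 0, nBlocks = 3, seed = 53L)
  D0 <- dosages(simulateGenotypes(d0)$G)
  C0 <- abs(stats::cor(D0))
  expect_lt(mean(C0[upper.tri(C0)]), 0.05)
  # rhoLD = 0.7: within-block correlation exceeds cross-block
  d1 <- simulationDesign(n = 2000, nRegions = 1, variantsPerRegion = 30,
                         rhoLD = 0.7, nBlocks = 3, seed = 54L)
  out <- simulateGenotypes(d1)
  C1 <- stats::cor(dosages(out$G))
  bm <- out$blockMap
  same <- outer(bm, bm, "==") & !is.na(outer(bm, bm, "+"))
  ut <- upper.tri(C1)
  expect_gt(mean(C1[same & ut]), mean(C1[!same & ut], na.rm = TRUE))
  expect_gt(mean(C1[same & ut]), 0.2)
})

test_that("architectures place causal variants per the six models", {
  d <- simulationDesign(n = 100, nRegions = 10, seed = 55L)
  bm <- simulateGenotypes(d)$blockMap
  for (model in 1:6) {
    dm <- simulationDesign(n = 100, nRegions = 10, model = model,
                           seed = 55L)
    tr <- assignArchitecture(dm, bm, seed = 60 + model)
    cz <- causalVariants(tr)
    expect_equal(length(influentialRegions(tr)), 5L)
    expect_true(all(cz$region %in% influentialRegions(tr)))
    perRegion <- table(cz$region)
    expect_true(all(perRegion == if (model <= 4) 5L else 10L))
    inBlock <- !is.na(bm[cz$column])
    if (model %in% 1:2) expect_true(all(inBlock))
    if (model %in% 3:4) expect_false(any(inBlock))
    if (model %in% 5:6)
      expect_true(all(tapply(inBlock, cz$region, sum) == 5L))
    if (model == 1) expect_true(all(cz$effect == 1))
    if (model == 2) {
      expect_true(all(cz$effect %in% c(-1, 1)))
      expect_true(all(abs(tapply(cz$effect, cz$region, sum)) <= 1))
    }
    if (model == 3) expect_true(all(cz$effect == 1))
    if (model == 4) expect_true(all(cz$effect %in% c(-1, 1)))
    if (model %in% 5:6)
      expect_true(all(abs(cz$effect) >= 0.5 & abs(cz$effect) <= 1))
    if (model == 5) expect_true(all(cz$effect > 0))
    if (model == 6) {
      signs <- tapply(sign(cz$effect), cz$region, sum)
      expect_true(all(abs(signs) <= 1))
    }
    if (model %in% 1:2) {
      # every causal variant keeps at least one neutral block-mate
      for (i in seq_len(nrow(cz))) {
        mates <- which(bm == bm[cz$column[i]])
        expect_true(length(setdiff(mates, cz$column)) >= 1)
      }
    }
  }
})

test_that("infeasible designs and placements error", {
  expect_error(simulationDesign(blockSize = 10, nBlocks = 6,
                                variantsPerRegion = 50),
               "exceed")
  expect_error(simulationDesign(mafHigh = 0.2), "mafHigh")
  expect_error(simulationDesign(rhoLD = 1), "rhoLD")
  # all columns in blocks leaves nowhere to put uncorrelated causals
  d <- simulationDesign(n = 60, nRegions = 2, variantsPerRegion = 20,
                        blockSize = 5, nBlocks = 4, model = 3, seed = 56L)
  bm <- simulateGenotypes(d)$blockMap
  expect_error(assignArchitecture(d, bm, seed = 1), "out-of-block")
})

test_that("phenotypes follow the linear model", {
  d <- simulationDesign(n = 200, nRegions = 4, model = 5, seed = 57L)
  out <- simulateGenotypes(d)
  tr <- assignArchitecture(d, out$blockMap, seed = 58L)
  # vanishing noise and no causal signal leaves the constant mean
  empty <- new("SimulationTruth", influentialRegions = integer(0),
               causal = data.frame(region = integer(0),
                                   column = integer(0),
                                   effect = numeric(0)),
               correlatedFlags = !is.na(out$blockMap))
  y0 <- simulatePhenotype(out$G, empty, alpha = 2.5, sigma = 1e-12,
                          seed = 1)
  expect_equal(y0, rep(2.5, 200), tolerance = 1e-6)
  # reproducibility is bitwise
  y1 <- simulatePhenotype(out$G, tr, sigma = 1, seed = 9)
  y2 <- simulatePhenotype(out$G, tr, sigma = 1, seed = 9)
  expect_identical(y1, y2)
  # covariates enter linearly
  Tm <- cbind(rnorm(200))
  y3 <- simulatePhenotype(out$G, empty, T = Tm, theta = 2, alpha = 0,
                          sigma = 1e-12, seed = 2)
  expect_equal(y3, drop(2 * Tm), tolerance = 1e-6)
  expect_error(simulatePhenotype(out$G, tr, T = Tm, theta = c(1, 2)),
               "dimensions")
})

test_that("phenotype variance matches the causal model at large n", {
  d <- simulationDesign(n = 20000, nRegions = 2, model = 5,
                        propInfluential = 0.5, seed = 59L)
  out <- simulateGenotypes(d)
  tr <- assignArchitecture(d, out$blockMap, seed = 60L)
  y <- simulatePhenotype(out$G, tr, sigma = 1, seed = 61L)
  cz <- causalVariants(tr)
  Xc <- dosages(out$G)[, cz$column, drop = FALSE]
  predicted <- drop(t(cz$effect) %*% stats::cov(Xc) %*% cz$effect) + 1
  expect_equal(var(y), predicted, tolerance = 0.1)
})

test_that("a simulated dataset round-trips through the VCF path", {
  d <- simulationDesign(n = 60, nRegions = 2, variantsPerRegion = 25,
                        seed = 62L)
  sim <- simulateDataset(d)
  dir <- file.path(tempdir(), "simout")
  writeSimulatedData(sim, dir)
  G2 <- readGenotypes(file.path(dir, "genotypes.vcf"), maf = 0.05)
  expect_equal(unname(dosages(G2)), unname(dosages(sim$G)))
  expect_equal(variants(G2)$pos, variants(sim$G)$pos)
  y2 <- readPhenotype(file.path(dir, "phenotype.tsv"))
  expect_equal(unname(y2), sim$y, tolerance = 1e-6)
})
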