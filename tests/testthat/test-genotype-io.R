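test_that("computeMAF folds the alternate frequency", {
  expect_equal(computeMAF(c(0, 0, 1, 1)), 0.25)
  expect_equal(computeMAF(c(2, 2, 2, 1)), 0.125)
  expect_equal(computeMAF(c(0, 0, 0, 0)), 0)
  expect_error(computeMAF(numeric(0)), "empty")
  expect_error(computeMAF(c(0, NA, 1)), "missing")
  set.seed(1)
  for (i in 1:20) {
    d <- rbinom(30, 2, runif(1, 0.05, 0.95))
    expect_identical(computeMAF(d), computeMAF(sample(d)))
  }
})

test_that("MAF filter keeps 0 < maf <= threshold, boundary inclusive", {
  n <- 50
  # alt allele counts 1, 4, 5, 20, 50 of 100 -> MAFs .01 .04 .05 .20 .50
  D <- cbind(dosageColumn(n, het = 1), dosageColumn(n, het = 4),
             dosageColumn(n, het = 5), dosageColumn(n, het = 20),
             dosageColumn(n, het = 50))
  v <- data.frame(chrom = "1", pos = 1:5 * 100,
                  vid = paste0("v", 1:5), ref = "A", alt = "T")
  G <- GenotypeMatrix(D, v)
  expect_equal(variants(G)$maf, c(0.01, 0.04, 0.05, 0.20, 0.50))
  path <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(G, path)
  got <- readGenotypes(path, maf = 0.05)
  expect_equal(nVariants(got), 3L)
  expect_equal(variants(got)$maf, c(0.01, 0.04, 0.05))
  expect_equal(unname(dosages(got)), unname(D[, 1:3]))
})

test_that("monomorphic sites are dropped and empty filters error", {
  path <- tempfile(fileext = ".vcf")
  writeVcfText(path, chrom = c("1", "1"), pos = c(100, 200),
               id = c("mono", "poly"), ref = c("A", "C"),
               alt = c("T", "G"),
               gt = list(rep("0/0", 8),
                         c("0/1", rep("0/0", 7))))
  got <- readGenotypes(path, maf = 0.5)
  expect_equal(variants(got)$vid, "poly")
  path2 <- tempfile(fileext = ".vcf")
  writeVcfText(path2, "1", 100, "mono", "A", "T",
               gt = list(rep("0/0", 8)))
  expect_error(readGenotypes(path2, maf = 0.5), "MAF filter")
  expect_error(readGenotypes(path, maf = 0.7), "threshold")
})

test_that("missing genotypes follow the imputation policy", {
  path <- tempfile(fileext = ".vcf")
  writeVcfText(path, "1", 100, "v1", "A", "T",
               gt = list(c("0/0", "0/1", "1/1", "./.")))
  expect_equal(unname(dosages(readGenotypes(path, maf = 0.5))[, 1]),
               c(0, 1, 2, 0))
  expect_equal(unname(dosages(readGenotypes(path, maf = 0.5,
                                            missing = "mean"))[, 1]),
               c(0, 1, 2, 1))  # mean(0,1,2) = 1 rounds to a het call
})

test_that("multi-allelic sites split into one column per alt allele", {
  path <- tempfile(fileext = ".vcf")
  writeVcfText(path, "1", 100, "v1", "A", "T,G",
               gt = list(c("0/1", "0/2", "1/2", "0/0")))
  got <- readGenotypes(path, maf = 0.5)
  expect_equal(nVariants(got), 2L)
  expect_equal(variants(got)$alt, c("T", "G"))
  expect_equal(unname(dosages(got)[, 1]), c(1, 0, 1, 0))
  expect_equal(unname(dosages(got)[, 2]), c(0, 1, 1, 0))
})

test_that("phased separators are accepted", {
  path <- tempfile(fileext = ".vcf")
  writeVcfText(path, "1", 100, "v1", "A", "T",
               gt = list(c("0|1", "1|1", "0|0", "0|0")))
  expect_equal(unname(dosages(readGenotypes(path, maf = 0.5))[, 1]),
               c(1, 2, 0, 0))
})

test_that("window enumeration matches the derived layout", {
  w <- makeWindows(120, windowSize = 50, step = 25, minSize = 10)
  expect_equal(nrow(w), 4L)
  expect_equal(w$col_start, c(0L, 25L, 50L, 75L))
  expect_equal(w$col_end - w$col_start, c(50L, 50L, 50L, 45L))
  expect_equal(w$region_id, 0:3)
  w1 <- makeWindows(50, 50, 25, 10)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$col_start, w1$col_end), c(0L, 50L))
  expect_equal(nrow(makeWindows(9, 50, 25, 10)), 0L)
  expect_error(makeWindows(100, windowSize = 5, step = 10, minSize = 2))
})

test_that("window ranges tile the matrix with the expected overlap", {
  for (m in c(37, 50, 63, 75, 101, 120, 200)) {
    w <- makeWindows(m, windowSize = 50, step = 25, minSize = 10)
    covered <- rep(FALSE, m)
    for (i in seq_len(nrow(w)))
      covered[(w$col_start[i] + 1):w$col_end[i]] <- TRUE
    expect_true(all(covered))
    full <- which(w$col_end - w$col_start == 50)
    if (length(full) > 1) {
      i <- full[1]
      expect_equal(w$col_end[i] - w$col_start[i + 1], 25L)
    }
  }
})

test_that("genotype windows carry genomic spans and a manifest writes", {
  set.seed(3)
  D <- randomDosageMatrix(30, 60)
  v <- data.frame(chrom = "7", pos = seq_len(60) * 50,
                  vid = paste0("v", 1:60), ref = "A", alt = "T")
  G <- GenotypeMatrix(D, v)
  w <- makeWindows(G, windowSize = 25, step = 20, minSize = 5)
  expect_equal(w$pos_start[1], 50)
  expect_equal(w$pos_end[1], 25 * 50)
  expect_equal(w$n_variants, w$col_end - w$col_start)
  path <- tempfile(fileext = ".tsv")
  writeWindowManifest(w, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(w))
  expect_equal(back$n_variants, w$n_variants)
})

test_that("samples are harmonized to the genotype order", {
  set.seed(4)
  D <- randomDosageMatrix(10, 5)
  rownames(D) <- sprintf("id%02d", 1:10)
  G <- GenotypeMatrix(D, data.frame(chrom = "1", pos = 1:5, vid = paste0("v", 1:5),
                                    ref = "A", alt = "T"))
  pheno <- setNames(rnorm(8), sprintf("id%02d", sample(3:10)))
  covar <- matrix(rnorm(16), 8, 2,
                  dimnames = list(names(pheno), c("age", "sex")))
  al <- alignSamples(G, pheno, covar)
  expect_equal(sampleIds(al$G), sprintf("id%02d", 3:10))
  expect_equal(al$y, unname(pheno[sampleIds(al$G)]))
  expect_equal(rownames(al$T), sampleIds(al$G))
  expect_error(alignSamples(G, setNames(rnorm(2), c("zz1", "zz2"))),
               "fewer than two")
})

test_that("phenotype and covariate tables round-trip", {
  pf <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = c("a", "b"), value = c(1.5, -2)),
              pf, sep = "\t", quote = FALSE, row.names = FALSE)
  y <- readPhenotype(pf)
  expect_equal(unname(y), c(1.5, -2))
  cf <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = c("a", "b"), age = c(30, 40)),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  Tm <- readCovariates(cf)
  expect_equal(dim(Tm), c(2L, 1L))
  expect_equal(rownames(Tm), c("a", "b"))
})
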