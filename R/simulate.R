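#' @include AllGenerics.R
NULL

# Draw one region's dosage columns: a latent Gaussian per haplotype with
# compound-symmetric correlation rhoLD inside each block (shared block
# factor + idiosyncratic noise), independent outside; an allele is
# carried when the latent value exceeds the (1 - maf) normal quantile.
# Columns whose empirical MAF is 0 or exceeds 0.05 are redrawn
# idiosyncratic-part-only, so the block factors -- and with them the LD
# structure -- are preserved.
.simulateRegion <- function(n, p, mafs, blockOf, rhoLD) {
  thr <- qnorm(1 - mafs)
  okCol <- function(d) { m <- computeMAF(d); m > 0 && m <= 0.05 }
  drawCol <- function(j, f1, f2) {
    mix <- function(f) {
      e <- rnorm(n)
      if (!is.null(f) && rhoLD > 0) sqrt(rhoLD) * f + sqrt(1 - rhoLD) * e
      else e
    }
    (mix(f1) > thr[j]) + (mix(f2) > thr[j])
  }
  # an independent column only needs its own redraws
  fillCol <- function(j, f1 = NULL, f2 = NULL, tries = 30L) {
    for (t in seq_len(tries)) {
      d <- drawCol(j, f1, f2)
      if (okCol(d)) return(d)
    }
    NULL
  }
  D <- matrix(0L, n, p)
  for (j in which(is.na(blockOf))) {
    d <- fillCol(j, tries = 200L)
    if (is.null(d))
      stop("could not realize a polymorphic rare column; target MAF ",
           mafs[j], " infeasible at n = ", n)
    D[, j] <- d
  }
  # a block shares its latent factors, so a stuck column (an unlucky
  # factor draw can make the MAF bound unreachable) triggers a redraw
  # of the whole block with fresh factors
  for (b in unique(blockOf[!is.na(blockOf)])) {
    idx <- which(blockOf == b)
    done <- FALSE
    for (attempt in 1:200) {
      f1 <- rnorm(n); f2 <- rnorm(n)
      cols <- lapply(idx, fillCol, f1 = f1, f2 = f2)
      if (!any(vapply(cols, is.null, logical(1)))) {
        D[, idx] <- do.call(cbind, cols)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not realize a polymorphic rare LD block at n = ", n)
  }
  D
}

#' Simulate genotypes with block LD at rare frequencies
#'
#' Latent-Gaussian threshold model: per region, target MAFs are drawn
#' uniformly on [mafLow, mafHigh]; each haplotype is a latent Gaussian
#' vector with compound-symmetric correlation rhoLD inside each of
#' nBlocks disjoint blocks of blockSize consecutive variants (the rest
#' independent); an allele is carried when the latent value exceeds the
#' (1 - maf) quantile, and the dosage is the sum over the two haplotypes.
#' Columns that come out monomorphic or with empirical MAF above 0.05
#' are redrawn.
#'
#' @param design a [SimulationDesign-class].
#' @param seed RNG seed (falls back to the design's stored seed).
#' @return list with \code{G} (a [GenotypeMatrix-class]) and
#'   \code{blockMap} (integer per column: LD block id, NA outside
#'   blocks).
#' @export
simulateGenotypes <- function(design, seed = design@seed) {
  if (!is.na(seed)) set.seed(seed)
  n <- design@n; p <- design@variantsPerRegion; R <- design@nRegions
  blockOf <- rep(NA_integer_, p)
  for (b in seq_len(design@nBlocks))
    blockOf[((b - 1) * design@blockSize + 1):(b * design@blockSize)] <- b
  cols <- vector("list", R)
  blockMap <- integer(0)
  for (r in seq_len(R)) {
    mafs <- runif(p, design@mafLow, design@mafHigh)
    cols[[r]] <- .simulateRegion(n, p, mafs, blockOf, design@rhoLD)
    blockMap <- c(blockMap, ifelse(is.na(blockOf), NA_integer_,
                                   (r - 1L) * design@nBlocks + blockOf))
  }
  D <- do.call(cbind, cols)
  rownames(D) <- sprintf("sample%05d", seq_len(n))
  m <- ncol(D)
  region <- rep(seq_len(R) - 1L, each = p)
  idx <- rep(seq_len(p), R)
  v <- data.frame(chrom = "1",
                  pos = region * 100000L + idx * 100L,
                  vid = sprintf("r%03d_v%02d", region, idx),
                  ref = "A", alt = "T",
                  maf = apply(D, 2, computeMAF),
                  stringsAsFactors = FALSE)
  list(G = GenotypeMatrix(D, v), blockMap = blockMap)
}

# Pick k causal columns from a candidate pool, never exhausting any LD
# block completely (each causal variant must keep at least one neutral
# block-mate, so "correlated with some neutral variants" holds).
.pickInBlock <- function(pool, blockMap, blockSize, k) {
  picked <- integer(0)
  for (j in sample(pool)) {
    b <- blockMap[j]
    if (sum(blockMap[picked] == b, na.rm = TRUE) < blockSize - 1) {
      picked <- c(picked, j)
      if (length(picked) == k) break
    }
  }
  if (length(picked) < k)
    stop("not enough in-block variants to place ", k, " causal variants")
  sort(picked)
}

.balancedSigns <- function(k) {
  sample(rep(c(1, -1), length.out = k))
}

#' Assign a genetic architecture (models 1-6)
#'
#' Splits the regions into influential and non-influential subsets
#' (proportion \code{propInfluential}) and places causal variants in
#' each influential region according to the architecture:
#' \describe{
#'   \item{Model 1}{10\% of variants causal, effect +1, each placed
#'     inside an LD block with at least one neutral block-mate
#'     (causal correlated with neutral variants).}
#'   \item{Model 2}{as model 1 with balanced random signs (+-1).}
#'   \item{Model 3}{10\% causal, effect +1, placed outside the LD blocks
#'     (uncorrelated with other variants).}
#'   \item{Model 4}{as model 3 with balanced +-1 signs.}
#'   \item{Model 5}{20\% causal, effects drawn from U(0.5, 1); half
#'     placed inside blocks, half outside.}
#'   \item{Model 6}{as model 5 with effect magnitudes U(0.5, 1) and
#'     balanced random signs.}
#' }
#'
#' @param design a [SimulationDesign-class].
#' @param blockMap per-column block ids from [simulateGenotypes()].
#' @param seed RNG seed.
#' @return A [SimulationTruth-class].
#' @export
assignArchitecture <- function(design, blockMap, seed = NULL) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  R <- design@nRegions; p <- design@variantsPerRegion
  propCausal <- if (design@model <= 4) 0.1 else 0.2
  k <- round(propCausal * p)
  nInf <- round(design@propInfluential * R)
  influential <- sort(sample.int(R, nInf)) - 1L
  causal <- list()
  for (r in influential) {
    colsOfRegion <- (r * p + 1L):((r + 1L) * p)
    inBlock <- colsOfRegion[!is.na(blockMap[colsOfRegion])]
    outBlock <- colsOfRegion[is.na(blockMap[colsOfRegion])]
    if (design@model %in% c(1, 2)) {
      picked <- .pickInBlock(inBlock, blockMap, design@blockSize, k)
      effects <- if (design@model == 1) rep(1, k) else .balancedSigns(k)
    } else if (design@model %in% c(3, 4)) {
      if (length(outBlock) < k)
        stop("not enough out-of-block variants for model ", design@model)
      picked <- sort(sample(outBlock, k))
      effects <- if (design@model == 3) rep(1, k) else .balancedSigns(k)
    } else {
      kIn <- ceiling(k / 2); kOut <- k - kIn
      if (length(outBlock) < kOut)
        stop("not enough out-of-block variants for model ", design@model)
      picked <- c(.pickInBlock(inBlock, blockMap, design@blockSize, kIn),
                  sort(sample(outBlock, kOut)))
      mag <- runif(k, 0.5, 1)
      effects <- if (design@model == 5) mag else mag * .balancedSigns(k)
    }
    causal[[length(causal) + 1L]] <-
      data.frame(region = r, column = picked, effect = effects)
  }
  causal <- if (length(causal)) do.call(rbind, causal) else
    data.frame(region = integer(0), column = integer(0),
               effect = numeric(0))
  new("SimulationTruth", influentialRegions = influential,
      causal = causal, correlatedFlags = !is.na(blockMap))
}

#' Simulate a phenotype from genotypes and truth
#'
#' y = alpha + sum over causal variants of dosage * effect + T theta +
#' epsilon, with epsilon iid N(0, sigma^2).
#'
#' @param G a [GenotypeMatrix-class].
#' @param truth a [SimulationTruth-class].
#' @param T optional covariate matrix (n x q).
#' @param theta covariate effects (length q).
#' @param alpha overall mean, default 0.
#' @param sigma residual standard deviation, default 1.
#' @param seed RNG seed.
#' @return numeric phenotype vector of length n.
#' @export
simulatePhenotype <- function(G, truth, T = NULL, theta = NULL,
                              alpha = 0, sigma = 1, seed = NULL) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- nSamples(G)
  y <- rep(alpha, n)
  cz <- causalVariants(truth)
  if (nrow(cz)) {
    if (max(cz$column) > nVariants(G))
      stop("causal columns exceed the genotype matrix")
    y <- y + drop(dosages(G)[, cz$column, drop = FALSE] %*% cz$effect)
  }
  if (!is.null(T)) {
    T <- as.matrix(T)
    if (nrow(T) != n || length(theta) != ncol(T))
      stop("covariate dimensions do not match")
    y <- y + drop(T %*% theta)
  }
  unname(y + rnorm(n, 0, sigma))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genotypes, architecture and phenotype in one
#' call, with sub-seeds derived deterministically from \code{seed}.
#'
#' @param design a [SimulationDesign-class].
#' @param seed RNG seed.
#' @param T,theta,alpha optional covariate structure, see
#'   [simulatePhenotype()].
#' @return list with \code{G}, \code{blockMap}, \code{truth}, \code{y}.
#' @export
simulateDataset <- function(design, seed = design@seed, T = NULL,
                            theta = NULL, alpha = 0) {
  if (is.na(seed)) seed <- 1L
  geno <- simulateGenotypes(design, seed = seed)
  truth <- assignArchitecture(design, geno$blockMap, seed = seed + 1L)
  y <- simulatePhenotype(geno$G, truth, T = T, theta = theta,
                         alpha = alpha, sigma = design@sigma,
                         seed = seed + 2L)
  list(G = geno$G, blockMap = geno$blockMap, truth = truth, y = y)
}

#' Write simulated genotypes as a minimal VCF
#'
#' Emits a GT-only VCF (v4.2, unphased diploid calls) so the full
#' file-based scan path can be exercised end to end on simulated data.
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output file (plain text).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(G, path) {
  v <- variants(G)
  D <- dosages(G)
  gtCode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=CCRS-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sampleIds(G)),
                     collapse = "\t")), con)
  for (j in seq_len(nVariants(G))) {
    writeLines(paste(c(v$chrom[j], v$pos[j], v$vid[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT",
                       gtCode[D[, j] + 1]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the phenotype, covariates and truth of a simulated dataset
#'
#' @param sim list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Files: \code{genotypes.vcf},
#'   \code{phenotype.tsv}, \code{truth.tsv}.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypeVcf(sim$G, file.path(dir, "genotypes.vcf"))
  write.table(data.frame(sample_id = sampleIds(sim$G), value = sim$y),
              file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cz <- causalVariants(sim$truth)
  truthTab <- data.frame(region = cz$region, column = cz$column,
                         effect = cz$effect)
  write.table(truthTab, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(region = sim$truth@influentialRegions),
              file.path(dir, "influential.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
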