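#' @include CCRS-package.R
NULL

.checkDosages <- function(d) {
  if (!is.matrix(d) || !is.numeric(d))
    return("dosages must be a numeric matrix")
  if (anyNA(d)) return("dosages must not contain missing values")
  if (!all(d %in% c(0, 1, 2)))
    return("dosage entries must be 0, 1 or 2")
  NULL
}

#' GenotypeMatrix: rare-variant dosages with variant metadata
#'
#' An n x m matrix of allele dosages (0/1/2 copies of the minor-coded
#' alternate allele) for n samples and m variants, plus per-variant
#' metadata: chromosome, 1-based position, identifier, ref/alt alleles and
#' minor allele frequency. Row names of the dosage matrix are the sample
#' identifiers. The MAF column reflects the cohort the object was built
#' from; subsetting does not recompute it.
#'
#' @slot dosages numeric matrix, entries in \{0, 1, 2\}, samples in rows.
#' @slot variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{vid}, \code{ref}, \code{alt}, \code{maf}; one row per column of
#'   \code{dosages}.
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosages = "matrix", variants = "data.frame"),
  validity = function(object) {
    msg <- .checkDosages(object@dosages)
    if (!is.null(msg)) return(msg)
    v <- object@variants
    need <- c("chrom", "pos", "vid", "ref", "alt", "maf")
    if (!all(need %in% names(v)))
      return(paste("variants must have columns:", paste(need, collapse = ", ")))
    if (nrow(v) != ncol(object@dosages))
      return("one variant record per dosage column required")
    ids <- rownames(object@dosages)
    if (is.null(ids) || anyDuplicated(ids))
      return("dosage rows must carry unique sample identifiers")
    if (any(v$pos < 1)) return("positions must be >= 1")
    if (any(v$maf <= 0 | v$maf > 0.5))
      return("variant MAF must lie in (0, 0.5]")
    TRUE
  })

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric n x m matrix with entries in \{0,1,2\};
#'   row names are sample ids (generated if absent).
#' @param variants data.frame of variant metadata (chrom, pos, vid, ref,
#'   alt, maf). If \code{maf} is missing it is computed from the dosages.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, variants) {
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("sample%04d", seq_len(nrow(dosages)))
  if (is.null(variants$maf))
    variants$maf <- apply(dosages, 2, computeMAF)
  colnames(dosages) <- variants$vid
  rownames(variants) <- NULL
  new("GenotypeMatrix", dosages = dosages, variants = variants)
}

#' SparseFactorization: constrained low-rank genotype decomposition
#'
#' The triple (U, d, V) approximating a (column-centered) genotype window
#' X as U diag(d) V', where the columns of U are orthonormal, the columns
#' of V have unit-bounded L2 norm and L1 norm at most the sparsity bound
#' c, and d is positive and non-increasing. Loadings are stored with
#' variants in rows and components in columns (p x r).
#'
#' @slot U n x r matrix, orthonormal columns (left vectors).
#' @slot d length-r positive non-increasing scale factors.
#' @slot V p x r sparse loading matrix.
#' @slot c sparsity bound applied to each loading column.
#' @slot r retained rank.
#' @slot center length-p vector of column means removed before fitting
#'   (zeros when centering was disabled).
#' @exportClass SparseFactorization
setClass("SparseFactorization",
  representation(U = "matrix", d = "numeric", V = "matrix",
                 c = "numeric", r = "integer", center = "numeric"),
  validity = function(object) {
    r <- object@r
    if (ncol(object@U) != r || ncol(object@V) != r || length(object@d) != r)
      return("U, V and d must agree with the retained rank r")
    if (length(object@center) != nrow(object@V))
      return("center must have one entry per variant")
    G <- crossprod(object@U)
    if (max(abs(G - diag(r))) > 1e-6)
      return("columns of U must be orthonormal")
    if (any(diff(object@d) > 1e-8)) return("d must be non-increasing")
    if (any(object@d <= 0)) return("d must be positive")
    l2 <- sqrt(colSums(object@V^2))
    if (any(l2 > 1 + 1e-6)) return("loading columns must have L2 norm <= 1")
    l1 <- colSums(abs(object@V))
    if (any(l1 > object@c + 1e-6))
      return("loading columns must satisfy the L1 bound c")
    TRUE
  })

#' BridgeFit: one concave penalized regression fit
#'
#' Coefficients of the bridge-penalized regression of a phenotype on the
#' sparse principal components, for a single (nu, kappa). Covariates and
#' the intercept are unpenalized.
#'
#' @slot gamma length-r component coefficients (exact zeros possible).
#' @slot theta covariate coefficients (length 0 when no covariates).
#' @slot intercept fitted intercept.
#' @slot kappa concavity exponent in (0, 1).
#' @slot nu penalty weight (>= 0).
#' @slot activeSet integer indices j with gamma_j != 0.
#' @slot rss residual sum of squares of the fit.
#' @slot n sample count.
#' @slot bic BIC value log(rss/n) + log(n) d/n with d = |activeSet| + q + 1.
#' @slot converged logical; FALSE when coordinate descent hit the
#'   iteration cap.
#' @exportClass BridgeFit
setClass("BridgeFit",
  representation(gamma = "numeric", theta = "numeric", intercept = "numeric",
                 kappa = "numeric", nu = "numeric", activeSet = "integer",
                 rss = "numeric", n = "integer", bic = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (object@rss < 0) return("rss must be non-negative")
    if (object@kappa <= 0 || object@kappa >= 1)
      return("kappa must lie in (0, 1)")
    if (object@nu < 0) return("nu must be non-negative")
    if (!identical(object@activeSet, which(object@gamma != 0)))
      return("activeSet must index the nonzero entries of gamma")
    TRUE
  })

#' SimulationDesign: study conditions for synthetic data
#'
#' Parameters of the synthetic genotype/phenotype generator: sample size,
#' number of regions and variants per region, the proportion of regions
#' carrying signal, the genetic architecture (models 1-6), the target MAF
#' range, the latent within-block LD correlation and block layout, and the
#' residual standard deviation.
#'
#' @slot n samples.
#' @slot nRegions regions (each a window of consecutive variants).
#' @slot variantsPerRegion variants per region.
#' @slot propInfluential proportion of regions that are influential, in
#'   [0, 1).
#' @slot model architecture 1-6 (see [assignArchitecture()]).
#' @slot mafLow,mafHigh target MAF range, 0 < mafLow <= mafHigh <= 0.05.
#' @slot rhoLD latent Gaussian correlation within an LD block, in [0, 1).
#' @slot blockSize,nBlocks LD-block layout within each region.
#' @slot sigma residual standard deviation of the phenotype (> 0).
#' @slot seed optional default seed recorded with the design.
#' @exportClass SimulationDesign
setClass("SimulationDesign",
  representation(n = "integer", nRegions = "integer",
                 variantsPerRegion = "integer", propInfluential = "numeric",
                 model = "integer", mafLow = "numeric", mafHigh = "numeric",
                 rhoLD = "numeric", blockSize = "integer", nBlocks = "integer",
                 sigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@n < 2) return("need at least two samples")
    if (object@model < 1 || object@model > 6) return("model must be 1..6")
    if (object@propInfluential < 0 || object@propInfluential >= 1)
      return("propInfluential must lie in [0, 1)")
    if (object@mafLow <= 0 || object@mafLow > object@mafHigh ||
        object@mafHigh > 0.05)
      return("need 0 < mafLow <= mafHigh <= 0.05")
    if (object@rhoLD < 0 || object@rhoLD >= 1)
      return("rhoLD must lie in [0, 1)")
    if (object@sigma <= 0) return("sigma must be positive")
    if (object@blockSize < 2) return("blockSize must be >= 2")
    if (object@blockSize * object@nBlocks > object@variantsPerRegion)
      return("LD blocks exceed the region size")
    TRUE
  })

#' Construct a SimulationDesign
#'
#' Defaults mirror the benchmark study conditions: 50-variant regions,
#' target MAFs uniform on [0.005, 0.05], five 5-variant LD blocks per
#' region with latent correlation 0.7 (so half of each region sits inside
#' a block), half of the regions influential, and unit residual standard
#' deviation.
#'
#' @param n,nRegions,variantsPerRegion dimensions of the dataset.
#' @param propInfluential proportion of influential regions, default 0.5.
#' @param model genetic architecture 1-6, see [assignArchitecture()].
#' @param mafLow,mafHigh target MAF range (defaults 0.005 and 0.05).
#' @param rhoLD latent within-block correlation, default 0.7.
#' @param blockSize,nBlocks LD-block layout, defaults 5 blocks of 5.
#' @param sigma residual standard deviation, default 1.
#' @param seed optional seed stored with the design.
#' @return A [SimulationDesign-class] object.
#' @export
simulationDesign <- function(n = 400L, nRegions = 200L,
                             variantsPerRegion = 50L,
                             propInfluential = 0.5, model = 1L,
                             mafLow = 0.005, mafHigh = 0.05, rhoLD = 0.7,
                             blockSize = 5L, nBlocks = 5L, sigma = 1,
                             seed = NA_integer_) {
  new("SimulationDesign", n = as.integer(n), nRegions = as.integer(nRegions),
      variantsPerRegion = as.integer(variantsPerRegion),
      propInfluential = propInfluential, model = as.integer(model),
      mafLow = mafLow, mafHigh = mafHigh, rhoLD = rhoLD,
      blockSize = as.integer(blockSize), nBlocks = as.integer(nBlocks),
      sigma = sigma, seed = as.integer(seed))
}

#' SimulationTruth: ground truth of a simulated dataset
#'
#' @slot influentialRegions 0-based ids of the influential regions.
#' @slot causal data.frame with columns \code{region}, \code{column}
#'   (1-based column in the full genotype matrix) and \code{effect}.
#' @slot correlatedFlags logical per genotype column: TRUE when the
#'   variant sits inside an LD block.
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  representation(influentialRegions = "integer", causal = "data.frame",
                 correlatedFlags = "logical"),
  validity = function(object) {
    if (nrow(object@causal) &&
        !all(object@causal$region %in% object@influentialRegions))
      return("causal variants must lie in influential regions")
    TRUE
  })
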