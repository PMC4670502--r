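#' @include AllClasses.R
NULL

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @export
setGeneric("sparsityBound", function(x) standardGeneric("sparsityBound"))
#' @export
setGeneric("reconstruct", function(x) standardGeneric("reconstruct"))
#' @export
setGeneric("activeSet", function(x) standardGeneric("activeSet"))

#' Accessors for GenotypeMatrix
#'
#' \code{dosages} returns the n x m dosage matrix, \code{variants} the
#' metadata data.frame, \code{sampleIds} the row (sample) identifiers,
#' \code{nSamples}/\code{nVariants} the dimensions.
#'
#' @param x a [GenotypeMatrix-class].
#' @name GenotypeMatrix-accessors
#' @aliases dosages variants sampleIds nSamples nVariants
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("variants", "GenotypeMatrix", function(x) x@variants)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))

#' Subset a GenotypeMatrix
#'
#' Standard \code{x[i, j]} subsetting over samples (i) and variants (j).
#' The stored MAF column is not recomputed for the subset.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i,j sample and variant indices.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosages
  v <- x@variants
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) {
    d <- d[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
    rownames(v) <- NULL
  }
  new("GenotypeMatrix", dosages = d, variants = v)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants\n",
              nrow(object@dosages), ncol(object@dosages)))
  m <- object@variants$maf
  cat(sprintf("  MAF range [%.4g, %.4g]; chrom: %s\n", min(m), max(m),
              paste(unique(object@variants$chrom), collapse = ", ")))
})

#' Accessors for SparseFactorization
#'
#' \code{loadings} returns the p x r sparse loading matrix V,
#' \code{scores} the component matrix Z = U diag(d),
#' \code{singularValues} the scale vector d, \code{sparsityBound} the L1
#' bound c, and \code{reconstruct} the implied approximation
#' U diag(d) V' + centering.
#'
#' @param x a [SparseFactorization-class].
#' @name SparseFactorization-accessors
#' @aliases loadings scores singularValues sparsityBound reconstruct
NULL

#' @rdname SparseFactorization-accessors
#' @export
setMethod("loadings", "SparseFactorization", function(x) x@V)
#' @rdname SparseFactorization-accessors
#' @export
setMethod("scores", "SparseFactorization",
          function(x) x@U %*% diag(x@d, nrow = x@r))
#' @rdname SparseFactorization-accessors
#' @export
setMethod("singularValues", "SparseFactorization", function(x) x@d)
#' @rdname SparseFactorization-accessors
#' @export
setMethod("sparsityBound", "SparseFactorization", function(x) x@c)
#' @rdname SparseFactorization-accessors
#' @export
setMethod("reconstruct", "SparseFactorization", function(x) {
  out <- x@U %*% (x@d * t(x@V))
  sweep(out, 2, x@center, "+")
})

setMethod("show", "SparseFactorization", function(object) {
  cat(sprintf("SparseFactorization: rank %d, sparsity bound c = %.4g\n",
              object@r, object@c))
  cat("  d:", paste(sprintf("%.4g", utils::head(object@d, 8)),
                    collapse = " "),
      if (object@r > 8) "...\n" else "\n")
  cat(sprintf("  nonzero loadings per component: %s\n",
              paste(colSums(object@V != 0), collapse = " ")))
})

#' @describeIn BridgeFit-class indices of the nonzero component
#'   coefficients.
#' @param x,object a [BridgeFit-class].
#' @export
setMethod("activeSet", "BridgeFit", function(x) x@activeSet)

#' @describeIn BridgeFit-class coefficients as a list with elements
#'   \code{intercept}, \code{theta} and \code{gamma}.
#' @export
setMethod("coef", "BridgeFit", function(object) {
  list(intercept = object@intercept, theta = object@theta,
       gamma = object@gamma)
})

setMethod("show", "BridgeFit", function(object) {
  cat(sprintf("BridgeFit: nu = %.4g, kappa = %.3g, %d of %d components active\n",
              object@nu, object@kappa, length(object@activeSet),
              length(object@gamma)))
  cat(sprintf("  rss = %.6g, n = %d, BIC = %.6g%s\n", object@rss, object@n,
              object@bic,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf("SimulationDesign: model %d, %d samples, %d regions x %d variants\n",
              object@model, object@n, object@nRegions,
              object@variantsPerRegion))
  cat(sprintf("  MAF in [%.3g, %.3g], %d LD blocks of %d (rho = %.2g), propInfluential = %.2g, sigma = %.2g\n",
              object@mafLow, object@mafHigh, object@nBlocks,
              object@blockSize, object@rhoLD, object@propInfluential,
              object@sigma))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf("SimulationTruth: %d influential regions, %d causal variants\n",
              length(object@influentialRegions), nrow(object@causal)))
})

#' @describeIn SimulationTruth-class ids of the influential regions.
#' @param x a [SimulationTruth-class].
#' @export
setGeneric("influentialRegions",
           function(x) standardGeneric("influentialRegions"))
#' @rdname SimulationTruth-class
#' @export
setMethod("influentialRegions", "SimulationTruth",
          function(x) x@influentialRegions)
#' @describeIn SimulationTruth-class data.frame of causal variants
#'   (region, column, effect).
#' @export
setGeneric("causalVariants", function(x) standardGeneric("causalVariants"))
#' @rdname SimulationTruth-class
#' @export
setMethod("causalVariants", "SimulationTruth", function(x) x@causal)
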