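#' @include AllGenerics.R
NULL

#' Univariate bridge minimizer
#'
#' Global minimizer of g(gamma) = a (gamma - b)^2 / 2 + nu |gamma|^kappa,
#' the scalar subproblem of bridge-penalized coordinate descent. The
#' candidates are gamma = 0 and the local minimum of the smooth branch on
#' sign(b) (0, |b|), found by bisection on g' to tolerance 1e-10; ties go
#' to 0. For nu = 0 the unpenalized solution b is returned. Unlike the
#' lasso map, the shrinkage |gamma - b| vanishes as |b| grows: large
#' effects are essentially unbiased.
#'
#' @param a quadratic curvature, > 0.
#' @param b unpenalized minimizer.
#' @param nu penalty weight, >= 0.
#' @param kappa concavity exponent in (0, 1).
#' @return the minimizing gamma.
#' @export
univariateBridge <- function(a, b, nu, kappa = 0.5) {
  if (a <= 0) stop("curvature a must be positive")
  if (nu < 0) stop("nu must be non-negative")
  if (kappa <= 0 || kappa >= 1) stop("kappa must lie in (0, 1)")
  cpp_uni_bridge(a, b, nu, kappa)
}

# Projection machinery shared by the bridge fitters: residualize y and Z
# against span(1, T) (Frisch-Waugh), returning the Gram-form summaries
# the C++ coordinate descent consumes.
.projectOut <- function(Z, T, y) {
  n <- length(y)
  W <- if (is.null(T)) matrix(1, n, 1) else cbind(1, as.matrix(T))
  qw <- qr(W)
  if (qw$rank < ncol(W))
    stop("rank-deficient covariate design (1, T)")
  ytld <- qr.resid(qw, y)
  Ztld <- qr.resid(qw, Z)
  list(qw = qw, W = W, ytld = ytld, Ztld = Ztld,
       G = crossprod(Ztld), Zty = drop(crossprod(Ztld, ytld)),
       yty = sum(ytld^2), q = ncol(W) - 1L)
}

.makeBridgeFit <- function(gamma, proj, Z, y, nu, kappa, converged) {
  resid <- proj$ytld - proj$Ztld %*% gamma
  rss <- sum(resid^2)
  cf <- qr.coef(proj$qw, y - Z %*% gamma)
  cf[is.na(cf)] <- 0
  active <- which(gamma != 0)
  n <- length(y)
  fit <- new("BridgeFit", gamma = as.numeric(gamma),
             theta = as.numeric(cf[-1]), intercept = cf[1],
             kappa = kappa, nu = nu, activeSet = as.integer(active),
             rss = rss, n = as.integer(n), bic = NA_real_,
             converged = converged)
  fit@bic <- bridgeBIC(fit, proj$q)
  fit
}

#' Fit a bridge-penalized regression on sparse components
#'
#' Minimizes ||y - Z gamma - T theta||^2 / 2 + nu sum_j |gamma_j|^kappa
#' with the intercept and covariates unpenalized. Covariates are handled
#' by projecting y and Z onto the orthogonal complement of span(1, T);
#' the component coefficients are then found by cyclic coordinate descent
#' with exact scalar minimization ([univariateBridge()]) from two
#' deterministic starts (zero and the least-squares solution), keeping
#' the lower final objective. theta and the intercept are recovered by
#' least squares of y - Z gamma on (1, T).
#'
#' @param Z numeric n x r component matrix (Z = U diag(d) from
#'   [fitSparsePCA()]).
#' @param T optional n x q covariate matrix.
#' @param y length-n phenotype.
#' @param nu penalty weight, >= 0.
#' @param kappa concavity exponent in (0, 1), default 0.5.
#' @param tol convergence tolerance on max |change in gamma| per sweep.
#' @param maxIter sweep cap; hitting it flags the fit as not converged
#'   rather than erroring.
#' @return A [BridgeFit-class].
#' @export
fitBridge <- function(Z, T = NULL, y, nu, kappa = 0.5, tol = 1e-8,
                      maxIter = 200L) {
  Z <- as.matrix(Z)
  if (nu < 0) stop("nu must be non-negative")
  if (kappa <= 0 || kappa >= 1) stop("kappa must lie in (0, 1)")
  if (nrow(Z) != length(y)) stop("rows of Z must align with y")
  if (any(colSums(Z != 0) == 0)) stop("Z contains an all-zero column")
  proj <- .projectOut(Z, T, y)
  path <- cpp_bridge_path(proj$G, proj$Zty, proj$yty, nu, kappa, tol,
                          as.integer(maxIter))
  .makeBridgeFit(path$gamma[, 1], proj, Z, y, nu, kappa,
                 path$converged[1])
}

#' BIC of a bridge fit
#'
#' log(rss / n) + log(n) d / n with d = |active set| + q + 1 effective
#' parameters (the selected components, the covariates and the
#' intercept). A perfect fit (rss = 0) is guarded to a large negative
#' sentinel with a warning.
#'
#' @param fit a [BridgeFit-class].
#' @param q number of covariates counted as effective parameters.
#' @return the BIC value.
#' @export
bridgeBIC <- function(fit, q = length(fit@theta)) {
  n <- fit@n
  if (n <= 0) stop("fit must carry a positive sample count")
  if (fit@rss < 0) stop("negative rss")
  d <- length(fit@activeSet) + q + 1
  if (fit@rss == 0) {
    warning("zero residual sum of squares; BIC set to sentinel")
    return(-1e10)
  }
  log(fit@rss / n) + log(n) * d / n
}

#' Select the penalty weight nu by BIC
#'
#' Fits the bridge regression for every grid value and returns the fit
#' minimizing BIC; ties go to the larger nu (the sparser model).
#'
#' @inheritParams fitBridge
#' @param nuGrid non-empty vector of penalty weights; default
#'   \code{c(0.001, 0.005, 0.01, 0.02, 0.05)}.
#' @return list with elements \code{nu} and \code{fit} (the winning
#'   [BridgeFit-class]); the full per-nu table is attached as attribute
#'   \code{"path"} (nu, df, rss, bic).
#' @export
selectNu <- function(Z, T = NULL, y, nuGrid = c(0.001, 0.005, 0.01,
                                                0.02, 0.05),
                     kappa = 0.5, tol = 1e-8, maxIter = 200L) {
  if (!length(nuGrid)) stop("empty nu grid")
  if (any(nuGrid < 0)) stop("nu values must be non-negative")
  Z <- as.matrix(Z)
  nuGrid <- sort(nuGrid)
  proj <- .projectOut(Z, T, y)
  path <- cpp_bridge_path(proj$G, proj$Zty, proj$yty, nuGrid, kappa, tol,
                          as.integer(maxIter))
  n <- length(y)
  dpar <- path$nnz + proj$q + 1
  bic <- ifelse(path$rss <= 0, -1e10, log(pmax(path$rss, 1e-300) / n) +
                  log(n) * dpar / n)
  best <- max(which(bic <= min(bic) + 1e-12))  # ties -> larger nu
  fit <- .makeBridgeFit(path$gamma[, best], proj, Z, y, nuGrid[best],
                        kappa, path$converged[best])
  out <- list(nu = nuGrid[best], fit = fit)
  attr(out, "path") <- data.frame(nu = nuGrid, df = path$nnz,
                                  rss = path$rss, bic = bic)
  out
}
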