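#' @include ccrs-test.R
NULL

# Shared helper: two-sided t-test on the coefficient of a single region
# regressor in y ~ (1, T, g).
.singleRegressorTest <- function(g, y, T, regionId, method) {
  if (all(g == g[1]))
    return(.resultRow(regionId, method, 0, 0L, 1, skipped = TRUE))
  W <- if (is.null(T)) cbind(1, g) else cbind(1, as.matrix(T), g)
  qw <- qr(W)
  if (qw$rank < ncol(W))
    return(.resultRow(regionId, method, 0, 0L, 1, skipped = TRUE))
  cf <- qr.coef(qw, y)
  res <- qr.resid(qw, y)
  n <- length(y)
  dfres <- n - ncol(W)
  s2 <- sum(res^2) / max(dfres, 1)
  XtXinv <- chol2inv(qr.R(qw))
  se <- sqrt(s2 * XtXinv[ncol(W), ncol(W)])
  tval <- if (se > 0) cf[ncol(W)] / se else Inf
  pv <- if (is.finite(tval)) 2 * pt(abs(tval), dfres, lower.tail = FALSE)
        else 0
  row <- .resultRow(regionId, method, tval^2, 1L, pv)
  row$coefficient <- cf[ncol(W)]
  row
}

#' Collapsing (Col) region test
#'
#' Regresses the trait on the binary indicator that a sample carries any
#' minor allele in the region, I\{sum_j x_ij > 0\}, with covariates, and
#' tests the indicator coefficient (two-sided t; the reported statistic
#' is the squared t). Degenerate regions (all or no carriers) are
#' skipped with p-value 1.
#'
#' @param X dosage block (n x p).
#' @param y phenotype vector.
#' @param T optional covariate matrix.
#' @param regionId id recorded in the result row.
#' @return one-row result data.frame (schema of [runCCRSWindow()], plus
#'   the fitted coefficient).
#' @export
collapsingTest <- function(X, y, T = NULL, regionId = 0L) {
  X <- as.matrix(X)
  carrier <- as.numeric(rowSums(X) > 0)
  .singleRegressorTest(carrier, y, T, regionId, "col")
}

#' CAST burden region test
#'
#' Regresses the trait on the per-sample burden sum_j x_ij over all
#' variants in the region, with covariates, and tests the burden
#' coefficient. A constant burden is skipped with p-value 1.
#'
#' @inheritParams collapsingTest
#' @return one-row result data.frame.
#' @export
castTest <- function(X, y, T = NULL, regionId = 0L) {
  X <- as.matrix(X)
  burden <- rowSums(X)
  .singleRegressorTest(burden, y, T, regionId, "cast")
}

#' SKAT-O score statistic
#'
#' Q_rho = (y - mu)' X R_rho X' (y - mu) with mu the fitted values of the
#' covariate-only regression and R_rho = (1 - rho) I + rho 11', computed
#' as (1 - rho) sum_j (x_j'e)^2 + rho (sum_j x_j'e)^2. rho = 0 is the
#' dispersion (SKAT) kernel, rho = 1 the squared burden score; Q_rho is
#' exactly linear in rho.
#'
#' @inheritParams collapsingTest
#' @param rho kernel interpolation weight in [0, 1].
#' @return the statistic Q_rho.
#' @export
skatoStatistic <- function(X, y, T = NULL, rho) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  X <- as.matrix(X)
  W <- if (is.null(T)) matrix(1, length(y), 1) else cbind(1, as.matrix(T))
  e <- qr.resid(qr(W), y)
  xe <- drop(crossprod(X, e))
  (1 - rho) * sum(xe^2) + rho * sum(xe)^2
}

# Moment-matched (Liu-type) survival probability of a weighted chi-square
# mixture sum_i lambda_i chi^2_1 at value q: the mixture's mean, variance,
# skewness and kurtosis are matched to a scaled noncentral chi-square.
.liuPvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda, 0)]
  if (!length(lambda)) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + delta; sigmaX <- sqrt(2 * (l + 2 * delta))
  tstar <- (q - muQ) / sigmaQ
  pchisq(tstar * sigmaX + muX, df = l, ncp = delta, lower.tail = FALSE)
}

#' Simplified SKAT-O region test
#'
#' Computes Q_rho over a grid of kernel weights; each quadratic form's
#' null distribution (a weighted chi-square mixture scaled by the
#' residual variance) is approximated by moment matching to a scaled
#' noncentral chi-square, and the grid is combined by Bonferroni:
#' p = min(1, |grid| min_rho p_rho). This is a deliberately simplified,
#' self-contained version of SKAT-O -- it does not implement the exact
#' optimal-rho integration, and is conservative by construction. A
#' permutation combination (min-p referenced to residual permutations)
#' is available instead. The kernel is unweighted; \code{weights} hooks
#' in per-variant weights if wanted.
#'
#' @inheritParams collapsingTest
#' @param rhoGrid kernel weights in [0, 1], default
#'   \code{c(0, 0.25, 0.5, 0.75, 1)}.
#' @param method \code{"moment"} (default) or \code{"permutation"}.
#' @param B permutations when \code{method = "permutation"}.
#' @param weights optional per-variant weights (default 1).
#' @param seed RNG seed for the permutation path.
#' @return one-row result data.frame; \code{statistic} is Q at the
#'   best rho, \code{df} is NA (mixture reference).
#' @export
skatoTest <- function(X, y, T = NULL, rhoGrid = c(0, 0.25, 0.5, 0.75, 1),
                      method = c("moment", "permutation"), B = 200L,
                      weights = NULL, regionId = 0L, seed = NULL) {
  method <- match.arg(method)
  if (!length(rhoGrid)) stop("empty rho grid")
  if (any(rhoGrid < 0 | rhoGrid > 1)) stop("rho must lie in [0, 1]")
  X <- as.matrix(X)
  if (!is.null(weights)) X <- sweep(X, 2, weights, "*")
  if (.isConstantBlock(X))
    return(.resultRow(regionId, "skato", 0, NA_integer_, 1,
                      skipped = TRUE))
  n <- length(y)
  W <- if (is.null(T)) matrix(1, n, 1) else cbind(1, as.matrix(T))
  qw <- qr(W)
  e <- qr.resid(qw, y)
  sigma2 <- sum(e^2) / (n - ncol(W))
  xe <- drop(crossprod(X, e))
  q0 <- sum(xe^2); q1 <- sum(xe)^2
  Qs <- (1 - rhoGrid) * q0 + rhoGrid * q1
  Xt <- qr.resid(qw, X)            # P0 X: kernel seen by the residuals
  K <- crossprod(Xt)               # X' P0 X, p x p
  p <- ncol(X)
  pvals <- vapply(seq_along(rhoGrid), function(i) {
    rho <- rhoGrid[i]
    a <- sqrt(1 - rho)
    b <- (sqrt(1 - rho + p * rho) - a) / p
    S <- a * diag(p) + b            # analytic square root of R_rho
    lam <- eigen(S %*% K %*% S, symmetric = TRUE, only.values = TRUE)$values
    .liuPvalue(Qs[i] / sigma2, pmax(lam, 0))
  }, numeric(1))
  best <- which.min(pvals)
  if (method == "moment") {
    pv <- min(1, length(rhoGrid) * min(pvals))
  } else {
    if (!is.null(seed)) set.seed(seed)
    minObs <- min(pvals)
    permMin <- vapply(seq_len(as.integer(B)), function(b) {
      eb <- qr.resid(qw, e[sample.int(n)])
      s2b <- sum(eb^2) / (n - ncol(W))
      xeb <- drop(crossprod(X, eb))
      Qb <- (1 - rhoGrid) * sum(xeb^2) + rhoGrid * sum(xeb)^2
      min(vapply(seq_along(rhoGrid), function(i) {
        rho <- rhoGrid[i]
        a <- sqrt(1 - rho)
        bb <- (sqrt(1 - rho + p * rho) - a) / p
        S <- a * diag(p) + bb
        lam <- eigen(S %*% K %*% S, symmetric = TRUE,
                     only.values = TRUE)$values
        .liuPvalue(Qb[i] / s2b, pmax(lam, 0))
      }, numeric(1)))
    }, numeric(1))
    pv <- (1 + sum(permMin <= minObs + 1e-12)) / (B + 1)
  }
  row <- .resultRow(regionId, "skato", Qs[best], NA_integer_, pv)
  row$rho <- rhoGrid[best]
  row
}
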