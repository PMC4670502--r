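#' @include AllGenerics.R
NULL

#' Soft thresholding
#'
#' Elementwise sign(x) * max(|x| - delta, 0); the proximal step behind the
#' L1-constrained loading update.
#'
#' @param x numeric vector.
#' @param delta threshold, >= 0.
#' @return thresholded vector.
#' @export
softThreshold <- function(x, delta) {
  if (delta < 0) stop("delta must be non-negative")
  sign(x) * pmax(abs(x) - delta, 0)
}

# Leading right singular vector of X via the smaller Gram matrix; the
# deterministic initializer for the alternating rank-1 updates.
.leadingRightSV <- function(X) {
  n <- nrow(X); p <- ncol(X)
  if (p <= n) {
    v <- eigen(crossprod(X), symmetric = TRUE)$vectors[, 1]
  } else {
    u <- eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1]
    v <- drop(crossprod(X, u))
    v <- v / sqrt(sum(v^2))
  }
  v
}

.checkSparsityBound <- function(c, p) {
  if (!(c > 1 && c <= sqrt(p) + 1e-9))
    stop("sparsity bound c must lie in the feasible range (1, sqrt(p)]")
  min(c, sqrt(p))
}

#' Rank-1 constrained matrix decomposition
#'
#' Maximizes u'Xv over unit-norm u and loadings v with ||v||2 <= 1 and
#' ||v||1 <= c by alternating exact updates: v is the soft-thresholded,
#' renormalized X'u with the smallest threshold (bisection, tolerance
#' 1e-8) meeting the L1 bound; u is Xv renormalized. Iterates until the
#' largest elementwise change falls below \code{tol} (default 1e-7) or
#' \code{maxIter} alternations. The sign of the pair is fixed so the
#' largest-magnitude loading is positive.
#'
#' @param X numeric matrix, not identically zero.
#' @param c sparsity bound in (1, sqrt(p)]; c = sqrt(p) leaves the L1
#'   constraint inactive and recovers the leading singular triple.
#' @param v0 optional starting loading vector; default is the leading
#'   right singular vector of X.
#' @param tol,maxIter convergence controls of the alternation.
#' @return list with elements \code{u}, \code{v}, \code{d} (= u'Xv > 0),
#'   \code{objectiveTrace}, \code{converged}.
#' @export
rank1PMD <- function(X, c, v0 = NULL, tol = 1e-7, maxIter = 200L) {
  X <- as.matrix(X)
  c <- .checkSparsityBound(c, ncol(X))
  if (all(X == 0)) stop("cannot factorize the zero matrix")
  if (is.null(v0)) v0 <- .leadingRightSV(X)
  res <- cpp_rank1_pmd(X, c, v0, tol, as.integer(maxIter))
  j <- which.max(abs(res$v))
  if (res$v[j] < 0) { res$v <- -res$v; res$u <- -res$u }
  list(u = drop(res$u), v = drop(res$v), d = res$d,
       objectiveTrace = res$objective_trace, converged = res$converged)
}

#' Sparse principal component factorization of a genotype window
#'
#' Computes the constrained rank-r approximation X ~ U diag(d) V' with
#' L1-sparse loading columns and mutually orthogonal left vectors.
#' Component j is the rank-1 solution on the deflated matrix
#' (I - U_{j-1} U_{j-1}') X, which enforces u_j orthogonal to all earlier
#' left vectors. Components are retained while d_j >= rankTol * d_1, up to
#' min(n, p) or \code{rMax}.
#'
#' Columns are centered by default and no variance scaling is applied:
#' the dosage scale carries the allele-frequency information.
#'
#' @param X numeric n x p matrix (a genotype window).
#' @param c sparsity bound in (1, sqrt(p)]; default sqrt(p) (plain PCA
#'   limit).
#' @param rMax cap on the retained rank (default unlimited).
#' @param rankTol relative cutoff on d_j versus d_1, default 1e-8.
#' @param center center columns before factorizing (default TRUE).
#' @param tol,maxIter rank-1 alternation controls.
#' @return A [SparseFactorization-class].
#' @export
fitSparsePCA <- function(X, c = sqrt(ncol(X)), rMax = Inf, rankTol = 1e-8,
                         center = TRUE, tol = 1e-7, maxIter = 200L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  c <- .checkSparsityBound(c, p)
  ctr <- if (center) colMeans(X) else rep(0, p)
  Xres <- sweep(X, 2, ctr)
  if (all(abs(Xres) < 1e-300)) stop("cannot factorize the zero matrix")
  rCap <- min(n, p, rMax)
  U <- matrix(0, n, 0); V <- matrix(0, p, 0); d <- numeric(0)
  frob0 <- sqrt(sum(Xres^2))
  for (j in seq_len(rCap)) {
    if (sqrt(sum(Xres^2)) < max(1e-12 * frob0, 1e-300)) break
    r1 <- rank1PMD(Xres, c, tol = tol, maxIter = maxIter)
    if (j > 1 && r1$d < rankTol * d[1]) break
    U <- cbind(U, r1$u); V <- cbind(V, r1$v); d <- c(d, r1$d)
    Xres <- Xres - r1$u %*% crossprod(r1$u, Xres)
  }
  if (!length(d)) stop("no component exceeds the rank tolerance")
  # Components are extracted by deflation but reported in decreasing
  # order of d: with a binding L1 constraint the alternation can stop at
  # a local optimum, so the raw extraction order need not be monotone.
  ord <- order(d, decreasing = TRUE)
  new("SparseFactorization", U = U[, ord, drop = FALSE], d = d[ord],
      V = V[, ord, drop = FALSE], c = c, r = length(d), center = ctr)
}

#' Cross-validate the sparsity bound c
#'
#' Entry-holdout reconstruction cross-validation: in each fold a random
#' scattered subset of matrix entries (fraction \code{holdoutFrac}) is
#' masked and replaced by the column mean of the unmasked entries, the
#' factorization is fitted to the masked matrix, and the squared
#' reconstruction error on the held-out entries is recorded. The grid
#' value minimizing the mean held-out error wins; ties go to the smaller
#' (sparser) c.
#'
#' @param X numeric matrix.
#' @param cGrid candidate bounds, all in (1, sqrt(p)].
#' @param holdoutFrac fraction of entries masked per fold, in (0, 0.5).
#' @param nFolds number of random masks, default 5.
#' @param seed optional RNG seed.
#' @param rMax,center,rankTol passed to [fitSparsePCA()].
#' @return the selected c.
#' @export
chooseSparsityCV <- function(X, cGrid, holdoutFrac = 0.2, nFolds = 5L,
                             seed = NULL, rMax = Inf, center = TRUE,
                             rankTol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (!length(cGrid)) stop("empty grid of sparsity bounds")
  for (cc in cGrid) .checkSparsityBound(cc, p)
  if (!(holdoutFrac > 0 && holdoutFrac < 0.5))
    stop("holdoutFrac must lie in (0, 0.5)")
  cGrid <- sort(unique(cGrid))
  if (length(cGrid) == 1) return(cGrid)
  if (!is.null(seed)) set.seed(seed)
  err <- matrix(NA_real_, length(cGrid), nFolds)
  nEntry <- length(X)
  for (f in seq_len(nFolds)) {
    mask <- sample.int(nEntry, max(1L, round(holdoutFrac * nEntry)))
    Xm <- X
    Xm[mask] <- NA
    mu <- colMeans(Xm, na.rm = TRUE)
    mu[is.nan(mu)] <- mean(X)
    for (jj in seq_len(p)) {
      nas <- is.na(Xm[, jj])
      if (any(nas)) Xm[nas, jj] <- mu[jj]
    }
    for (ci in seq_along(cGrid)) {
      fit <- fitSparsePCA(Xm, c = cGrid[ci], rMax = rMax, center = center,
                          rankTol = rankTol)
      Xhat <- reconstruct(fit)
      err[ci, f] <- mean((Xhat[mask] - X[mask])^2)
    }
  }
  cGrid[which.min(rowMeans(err))]
}

#' Serialize a factorization to a columnar text file
#'
#' Debug helper: writes d, the loadings and the left vectors as
#' tab-separated blocks that [readFactorization()] can restore.
#'
#' @param fac a [SparseFactorization-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFactorization <- function(fac, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sparse factorization r=%d c=%.15g", fac@r, fac@c),
             con)
  writeLines(paste("d", paste(sprintf("%.15g", fac@d), collapse = "\t"),
                   sep = "\t"), con)
  writeLines(paste("center",
                   paste(sprintf("%.15g", fac@center), collapse = "\t"),
                   sep = "\t"), con)
  for (j in seq_len(fac@r)) {
    writeLines(paste(sprintf("v%d", j),
                     paste(sprintf("%.15g", fac@V[, j]), collapse = "\t"),
                     sep = "\t"), con)
    writeLines(paste(sprintf("u%d", j),
                     paste(sprintf("%.15g", fac@U[, j]), collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeFactorization
#' @param path input file written by [writeFactorization()].
#' @export
readFactorization <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  r <- as.integer(sub(".* r=([0-9]+).*", "\\1", header))
  cBound <- as.numeric(sub(".* c=([0-9.eE+-]+)", "\\1", header))
  getVec <- function(tag) {
    ln <- lines[startsWith(lines, paste0(tag, "\t"))]
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]][-1])
  }
  d <- getVec("d"); ctr <- getVec("center")
  V <- vapply(seq_len(r), function(j) getVec(sprintf("v%d", j)),
              numeric(length(ctr)))
  u1 <- getVec("u1")
  U <- vapply(seq_len(r), function(j) getVec(sprintf("u%d", j)),
              numeric(length(u1)))
  new("SparseFactorization", U = U, d = d, V = V, c = cBound,
      r = r, center = ctr)
}
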