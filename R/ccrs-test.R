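#' @include bridge.R sparse-pca.R
NULL

#' Control parameters for the CCRS region test
#'
#' @param c sparsity bound for the loading columns: a number in
#'   (1, sqrt(p)], \code{NULL} for the default
#'   \code{min(sqrt(p), max(1 + 1e-6, 0.5 sqrt(p)))} (moderately sparse
#'   loadings), or \code{"cv"} to select it per window by entry-holdout
#'   cross-validation over \code{cvGrid}.
#' @param rMax cap on the retained rank (default: full rank).
#' @param rankTol relative cutoff d_j / d_1 below which components are
#'   discarded.
#' @param center center window columns before factorizing.
#' @param kappa bridge concavity exponent, default 0.5.
#' @param nuGrid BIC grid for the penalty weight, default
#'   \code{c(0.001, 0.005, 0.01, 0.02, 0.05)}; larger values suit wider
#'   windows.
#' @param pvalue reference distribution for the region statistic:
#'   \code{"chisq"} (fast scan; chi-square with df = number of selected
#'   components, anti-conservative in principle because nu is selected on
#'   the same data) or \code{"perm"} (covariate-preserving residual
#'   permutation, the calibrated option).
#' @param B permutation count when \code{pvalue = "perm"}, default 200.
#' @param cvGrid,cvFolds,cvHoldout settings for \code{c = "cv"}; the
#'   default grid spans (1, sqrt(p)] at five points.
#' @param cdTol,cdMaxIter coordinate-descent controls.
#' @param pmdTol,pmdMaxIter rank-1 alternation controls.
#' @return named list of control values.
#' @export
ccrsControl <- function(c = NULL, rMax = Inf, rankTol = 1e-8,
                        center = TRUE, kappa = 0.5,
                        nuGrid = c(0.001, 0.005, 0.01, 0.02, 0.05),
                        pvalue = c("chisq", "perm"), B = 200L,
                        cvGrid = NULL, cvFolds = 3L, cvHoldout = 0.2,
                        cdTol = 1e-8, cdMaxIter = 200L,
                        pmdTol = 1e-7, pmdMaxIter = 200L) {
  list(c = c, rMax = rMax, rankTol = rankTol, center = center,
       kappa = kappa, nuGrid = nuGrid, pvalue = match.arg(pvalue),
       B = as.integer(B), cvGrid = cvGrid, cvFolds = as.integer(cvFolds),
       cvHoldout = cvHoldout, cdTol = cdTol,
       cdMaxIter = as.integer(cdMaxIter), pmdTol = pmdTol,
       pmdMaxIter = as.integer(pmdMaxIter))
}

.defaultSparsity <- function(p) min(sqrt(p), max(1 + 1e-6, 0.5 * sqrt(p)))

.resolveSparsity <- function(X, control, seed = NULL) {
  p <- ncol(X)
  cc <- control$c
  if (is.null(cc)) return(.defaultSparsity(p))
  if (identical(cc, "cv")) {
    grid <- control$cvGrid
    if (is.null(grid)) grid <- 1 + (sqrt(p) - 1) * c(0.2, 0.4, 0.6, 0.8, 1)
    return(chooseSparsityCV(X, grid, holdoutFrac = control$cvHoldout,
                            nFolds = control$cvFolds, seed = seed,
                            rMax = min(control$rMax, 5),
                            center = control$center,
                            rankTol = control$rankTol))
  }
  .checkSparsityBound(cc, p)
}

# Factorize a window into components Z; p = 1 windows bypass the
# decomposition (the single centered column is its own component).
.windowComponents <- function(X, control, seed = NULL) {
  p <- ncol(X)
  if (p == 1L) {
    z <- X[, 1] - if (control$center) mean(X[, 1]) else 0
    return(list(Z = matrix(z, ncol = 1), fac = NULL))
  }
  cc <- .resolveSparsity(X, control, seed)
  fac <- fitSparsePCA(X, c = cc, rMax = control$rMax,
                      rankTol = control$rankTol, center = control$center,
                      tol = control$pmdTol, maxIter = control$pmdMaxIter)
  list(Z = scores(fac), fac = fac)
}

.resultRow <- function(regionId, method, statistic, df, pvalue,
                       nSelected = NA_integer_, nu = NA_real_,
                       skipped = FALSE) {
  data.frame(region_id = as.integer(regionId), method = method,
             statistic = statistic, df = as.integer(df),
             n_selected = as.integer(nSelected), pvalue = pvalue,
             nu = nu, skipped = skipped, stringsAsFactors = FALSE)
}

.isConstantBlock <- function(X) {
  all(apply(X, 2, function(col) all(col == col[1])))
}

# Gram-form CCRS statistic for one response already projected off (1, T):
# run the bridge path over nuGrid, pick nu by BIC (ties -> larger nu),
# return the LR statistic n log(RSS0 / RSS1) and the selection size.
.gramStat <- function(G, Zty, yty, n, q, control) {
  path <- cpp_bridge_path(G, Zty, yty, control$nuGrid, control$kappa,
                          control$cdTol, control$cdMaxIter)
  dpar <- path$nnz + q + 1
  bic <- ifelse(path$rss <= 0, -1e10,
                log(pmax(path$rss, 1e-300) / n) + log(n) * dpar / n)
  best <- max(which(bic <= min(bic) + 1e-12))
  nnz <- path$nnz[best]
  rss1 <- path$rss[best]
  stat <- if (nnz == 0L || yty <= 0) 0 else
    n * log(yty / max(rss1, 1e-300))
  list(stat = max(stat, 0), df = nnz, nu = control$nuGrid[best],
       gamma = path$gamma[, best], rss = rss1,
       converged = path$converged[best])
}

#' Likelihood-ratio statistic of a selected bridge model
#'
#' Gaussian profile-likelihood ratio of the selected model against the
#' covariate-only null: stat = n log(RSS0 / RSS1), where RSS0 comes from
#' the least-squares fit of y on (1, T) and RSS1 from the bridge fit.
#' An empty active set yields (0, 0). The selected model must fit at
#' least as well as the null.
#'
#' @param y phenotype vector.
#' @param T optional covariate matrix.
#' @param fit a [BridgeFit-class] produced on the same (y, T).
#' @return list with \code{statistic} and \code{df} (= active set size).
#' @export
lrStatistic <- function(y, T = NULL, fit) {
  n <- length(y)
  W <- if (is.null(T)) matrix(1, n, 1) else cbind(1, as.matrix(T))
  rss0 <- sum(qr.resid(qr(W), y)^2)
  if (length(fit@activeSet) == 0L)
    return(list(statistic = 0, df = 0L))
  rss1 <- fit@rss
  if (rss1 > rss0 + 1e-9)
    stop("selected model fits worse than the null; fit/data mismatch")
  list(statistic = n * log(rss0 / max(rss1, 1e-300)),
       df = length(fit@activeSet))
}

#' Chi-square p-value for a region statistic
#'
#' Upper-tail probability of a chi-square distribution with \code{df}
#' degrees of freedom; df = 0 (nothing selected) gives p = 1.
#'
#' @param stat non-negative statistic.
#' @param df degrees of freedom (number of selected components).
#' @return p-value in [0, 1].
#' @export
regionPvalue <- function(stat, df) {
  if (stat < 0) stop("statistic must be non-negative")
  if (df <= 0 || stat == 0) return(1)
  pchisq(stat, df = df, lower.tail = FALSE)
}

# Permuted CCRS statistics for one window. The genotype factorization
# (and hence G) depends only on X and is reused; nu is reselected for
# every permutation. Residuals of y on (1, T) are permuted and
# re-projected, preserving the covariate structure.
.permStats <- function(proj, n, control, B, seed = NULL) {
  if (B < 1) stop("need at least one permutation")
  if (!is.null(seed)) set.seed(seed)
  e <- proj$ytld
  E <- vapply(seq_len(B), function(b) e[sample.int(n)], numeric(n))
  Etld <- qr.resid(proj$qw, E)
  ZtE <- crossprod(proj$Ztld, Etld)
  ytyB <- colSums(Etld^2)
  vapply(seq_len(B), function(b)
    .gramStat(proj$G, ZtE[, b], ytyB[b], n, proj$q, control)$stat,
    numeric(1))
}

#' Permutation p-value for the CCRS region test
#'
#' Runs the full CCRS pipeline on the observed data, then on \code{B}
#' covariate-preserving permutations (residuals of y on (1, T) permuted
#' and added back to the covariate fit). The genotype factorization is
#' reused across permutations -- it depends only on X -- while the
#' penalty weight nu is reselected each time, so the selection step is
#' part of what is calibrated. The add-one estimator
#' (1 + #\{perm >= obs\}) / (B + 1) is returned.
#'
#' @param X dosage block of the window (n x p).
#' @param y phenotype vector.
#' @param T optional covariate matrix.
#' @param control a [ccrsControl()] list.
#' @param B number of permutations, >= 1.
#' @param seed RNG seed; identical seeds give identical p-values.
#' @return the permutation p-value, with the observed statistic and df
#'   attached as attributes \code{"statistic"} and \code{"df"}.
#' @export
permutationPvalue <- function(X, y, T = NULL, control = ccrsControl(),
                              B = 200L, seed = NULL) {
  B <- as.integer(B)
  if (B < 1) stop("need at least one permutation")
  comp <- .windowComponents(as.matrix(X), control, seed)
  proj <- .projectOut(comp$Z, T, y)
  n <- length(y)
  obs <- .gramStat(proj$G, proj$Zty, proj$yty, n, proj$q, control)
  perm <- .permStats(proj, n, control, B, seed)
  p <- (1 + sum(perm >= obs$stat - 1e-12)) / (B + 1)
  structure(p, statistic = obs$stat, df = obs$df)
}

#' Run the CCRS pipeline on one window
#'
#' Centers the window, fits the constrained sparse factorization, forms
#' the components Z = U diag(d), selects the bridge penalty by BIC, and
#' tests the selected model against the covariate-only null with the
#' likelihood-ratio statistic. The p-value reference is chi-square with
#' df equal to the number of selected components (default) or the
#' permutation distribution, per \code{control$pvalue}. A window whose
#' columns are all constant is skipped (statistic 0, p-value 1).
#'
#' @param X dosage block (n x p, p >= 1).
#' @param y phenotype vector.
#' @param T optional covariate matrix.
#' @param control a [ccrsControl()] list.
#' @param regionId id recorded in the result row.
#' @param seed RNG seed used for permutations (and CV of c, if enabled).
#' @return one-row data.frame: region_id, method, statistic, df,
#'   n_selected, pvalue, nu, skipped.
#' @export
runCCRSWindow <- function(X, y, T = NULL, control = ccrsControl(),
                          regionId = 0L, seed = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("window must contain at least one variant")
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (.isConstantBlock(X))
    return(.resultRow(regionId, "ccrs", 0, 0L, 1, nSelected = 0L,
                      skipped = TRUE))
  comp <- .windowComponents(X, control, seed)
  proj <- .projectOut(comp$Z, T, y)
  n <- length(y)
  obs <- .gramStat(proj$G, proj$Zty, proj$yty, n, proj$q, control)
  pv <- if (control$pvalue == "perm") {
    perm <- .permStats(proj, n, control, control$B, seed)
    (1 + sum(perm >= obs$stat - 1e-12)) / (control$B + 1)
  } else {
    regionPvalue(obs$stat, obs$df)
  }
  .resultRow(regionId, "ccrs", obs$stat, obs$df, pv,
             nSelected = obs$df, nu = obs$nu)
}

#' Sliding-window CCRS scan over a genotype matrix
#'
#' Enumerates count-based windows with [makeWindows()] and applies the
#' requested region tests to each. Results follow the scan TSV schema.
#'
#' @param G a [GenotypeMatrix-class] (already MAF-filtered).
#' @param y phenotype vector aligned to \code{sampleIds(G)}.
#' @param T optional covariate matrix aligned the same way.
#' @param windowSize,step,minSize window layout (defaults 50 / 25 / 10).
#' @param methods subset of \code{c("ccrs", "col", "cast", "skato",
#'   "spc")}.
#' @param control a [ccrsControl()] list (CCRS and SPC settings).
#' @param rhoGrid SKAT-O kernel interpolation grid.
#' @param seed base seed; window w uses seed + region id.
#' @return data.frame with one row per window and method: region_id,
#'   chrom, pos_start, pos_end, n_variants, method, statistic, df,
#'   n_selected, pvalue, nu, skipped.
#' @export
ccrsScan <- function(G, y, T = NULL, windowSize = 50L, step = 25L,
                     minSize = 10L, methods = "ccrs",
                     control = ccrsControl(),
                     rhoGrid = c(0, 0.25, 0.5, 0.75, 1), seed = 1L) {
  methods <- match.arg(methods, c("ccrs", "col", "cast", "skato", "spc"),
                       several.ok = TRUE)
  if (nSamples(G) != length(y))
    stop("phenotype length must match the sample count")
  wins <- makeWindows(G, windowSize = windowSize, step = step,
                      minSize = minSize)
  if (!nrow(wins)) stop("no window of at least ", minSize, " variants")
  out <- vector("list", nrow(wins) * length(methods))
  k <- 0L
  for (w in seq_len(nrow(wins))) {
    cols <- (wins$col_start[w] + 1L):wins$col_end[w]
    X <- dosages(G)[, cols, drop = FALSE]
    rid <- wins$region_id[w]
    for (m in methods) {
      row <- switch(m,
        ccrs = runCCRSWindow(X, y, T, control, regionId = rid,
                             seed = seed + rid),
        col = collapsingTest(X, y, T, regionId = rid),
        cast = castTest(X, y, T, regionId = rid),
        skato = skatoTest(X, y, T, rhoGrid = rhoGrid, regionId = rid),
        spc = spcFirstKTest(X, y, T, control = control, regionId = rid))
      k <- k + 1L
      # method-specific extras (coefficient, rho) are dropped so the
      # scan table has one uniform schema
      out[[k]] <- row[, c("region_id", "method", "statistic", "df",
                          "n_selected", "pvalue", "nu", "skipped")]
    }
  }
  res <- do.call(rbind, out)
  info <- wins[match(res$region_id, wins$region_id),
               c("chrom", "pos_start", "pos_end", "n_variants")]
  cbind(res[, "region_id", drop = FALSE], info,
        res[, setdiff(names(res), "region_id")], row.names = NULL)
}

#' Write a scan result TSV
#'
#' @param scan data.frame from [ccrsScan()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScanResults <- function(scan, path) {
  write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical genome-wide significance threshold
#'
#' Mirrors the permutation construction used for sliding-window scans:
#' a set of windows is sampled, the same residual permutations are
#' applied to all of them, each permuted statistic is converted to a
#' within-window rank p-value, and the alpha-quantile of the per-
#' permutation minimum p across windows is returned (a min-p family-wise
#' threshold). A Bonferroni alternative (alpha divided by the number of
#' windows the scan would test) is also reported.
#'
#' @param G a [GenotypeMatrix-class].
#' @param y phenotype vector.
#' @param T optional covariates.
#' @param nWindows number of windows sampled for the permutation null.
#' @param B permutations shared across windows.
#' @param alpha family-wise level, default 0.05.
#' @param windowSize,step,minSize window layout.
#' @param control a [ccrsControl()] list.
#' @param seed RNG seed.
#' @return list with \code{threshold} (min-p quantile),
#'   \code{bonferroni}, and the \code{minP} sample.
#' @export
genomewideThreshold <- function(G, y, T = NULL, nWindows = 100L, B = 200L,
                                alpha = 0.05, windowSize = 50L,
                                step = 25L, minSize = 10L,
                                control = ccrsControl(), seed = 1L) {
  wins <- makeWindows(G, windowSize = windowSize, step = step,
                      minSize = minSize)
  if (!nrow(wins)) stop("no testable window")
  set.seed(seed)
  pick <- sort(sample.int(nrow(wins), min(nWindows, nrow(wins))))
  n <- length(y)
  perms <- replicate(B, sample.int(n))
  pmat <- matrix(NA_real_, B, length(pick))
  for (i in seq_along(pick)) {
    w <- pick[i]
    cols <- (wins$col_start[w] + 1L):wins$col_end[w]
    X <- dosages(G)[, cols, drop = FALSE]
    if (.isConstantBlock(X)) { pmat[, i] <- 1; next }
    comp <- .windowComponents(X, control, seed)
    proj <- .projectOut(comp$Z, T, y)
    e <- proj$ytld
    E <- apply(perms, 2, function(ix) e[ix])
    Etld <- qr.resid(proj$qw, E)
    ZtE <- crossprod(proj$Ztld, Etld)
    ytyB <- colSums(Etld^2)
    stats <- vapply(seq_len(B), function(b)
      .gramStat(proj$G, ZtE[, b], ytyB[b], n, proj$q, control)$stat,
      numeric(1))
    # within-window rank p-value of each permuted statistic
    r <- rank(-stats, ties.method = "max")
    pmat[, i] <- r / B
  }
  minP <- apply(pmat, 1, min)
  list(threshold = as.numeric(quantile(minP, alpha, type = 1)),
       bonferroni = alpha / nrow(wins), minP = minP)
}
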