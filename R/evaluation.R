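#' @include ccrs-test.R baselines.R simulate.R
NULL

#' Sparse-principal-component comparator (first k components)
#'
#' The SPC-style comparator: the same constrained factorization as the
#' CCRS pipeline, but the phenotype is regressed on the FIRST k
#' components (no concave selection) and tested with a standard F-test
#' against the covariate-only null. By default k is the smallest number
#' of components explaining \code{varExplained} of the factorized
#' variance (sum of d_j^2).
#'
#' @param X dosage block (n x p).
#' @param y phenotype vector.
#' @param T optional covariate matrix.
#' @param k number of leading components; overrides \code{varExplained}.
#'   Values above the retained rank are truncated with a warning.
#' @param varExplained variance-explained threshold used when k is NULL,
#'   default 0.8.
#' @param control a [ccrsControl()] list (factorization settings).
#' @param regionId id recorded in the result row.
#' @return one-row result data.frame; \code{statistic} is the F value,
#'   \code{df} the numerator degrees of freedom k.
#' @export
spcFirstKTest <- function(X, y, T = NULL, k = NULL, varExplained = 0.8,
                          control = ccrsControl(), regionId = 0L) {
  X <- as.matrix(X)
  if (.isConstantBlock(X))
    return(.resultRow(regionId, "spc", 0, 0L, 1, skipped = TRUE))
  comp <- .windowComponents(X, control)
  Z <- comp$Z
  r <- ncol(Z)
  if (is.null(k)) {
    d2 <- colSums(Z^2)
    k <- which(cumsum(d2) / sum(d2) >= varExplained)[1]
  } else if (k > r) {
    warning("k = ", k, " exceeds the retained rank ", r, "; truncated")
    k <- r
  }
  if (k < 1) stop("k must be at least 1")
  Zk <- Z[, seq_len(k), drop = FALSE]
  df0 <- if (is.null(T)) data.frame(y = y) else
    data.frame(y = y, as.data.frame(as.matrix(T)))
  fit0 <- lm(y ~ ., data = df0)
  fit1 <- lm(y ~ ., data = cbind(df0, as.data.frame(Zk)))
  an <- anova(fit0, fit1)
  fstat <- an$F[2]
  pv <- an$`Pr(>F)`[2]
  if (is.na(fstat)) { fstat <- 0; pv <- 1 }
  .resultRow(regionId, "spc", fstat, k, pv, nSelected = k)
}

#' Score one simulated replicate against the truth
#'
#' Counts, over M regions, the significant regions R = #\{p <= alpha\},
#' the true discoveries T (significant and influential) and the false
#' positives F = R - T, and forms the rates: \code{fdr_est} = F/R (0
#' when R = 0, the convention induced by E[F/R | R>0] P[R>0]);
#' \code{tpr_conventional} = T / #influential; and \code{tpr_printed} =
#' T / (M - R) (the display-equation form, retained verbatim for
#' fidelity; NA when M = R). \code{tpr_conventional} is the quantity
#' reported and plotted by default.
#'
#' @param results data.frame with one row per region (columns
#'   \code{region_id}, \code{pvalue}) for a single method.
#' @param truth a [SimulationTruth-class].
#' @param alpha significance level in (0, 1).
#' @return one-row data.frame: alpha, F, T, R, M, fdr_est,
#'   tpr_conventional, tpr_printed.
#' @export
scoreReplicate <- function(results, truth, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (anyDuplicated(results$region_id))
    stop("results must contain one row per region")
  M <- nrow(results)
  sig <- results$pvalue <= alpha
  inf <- results$region_id %in% influentialRegions(truth)
  R <- sum(sig)
  Tn <- sum(sig & inf)
  Fn <- R - Tn
  nInf <- length(influentialRegions(truth))
  data.frame(alpha = alpha, F = Fn, T = Tn, R = R, M = M,
             fdr_est = if (R > 0) Fn / R else 0,
             tpr_conventional = if (nInf > 0) Tn / nInf else NA_real_,
             tpr_printed = if (M > R) Tn / (M - R) else NA_real_)
}

.studyMethods <- c("ccrs", "spc", "spc_first_k", "col", "cast", "skato")

# Apply one method to one region block.
.applyMethod <- function(m, X, y, T, control, rhoGrid, rid, seed) {
  switch(m,
    ccrs = runCCRSWindow(X, y, T, control, regionId = rid, seed = seed),
    spc = ,
    spc_first_k = spcFirstKTest(X, y, T, control = control,
                                regionId = rid),
    col = collapsingTest(X, y, T, regionId = rid),
    cast = castTest(X, y, T, regionId = rid),
    skato = skatoTest(X, y, T, rhoGrid = rhoGrid, regionId = rid))
}

#' Run the FDR/TPR simulation study
#'
#' For each replicate, a fresh dataset (genotypes, architecture,
#' phenotype) is generated from the design; each requested method is
#' applied region by region; and each (method, alpha) pair is scored
#' with [scoreReplicate()]. Per-replicate FDR/TPR are averaged across
#' replicates to estimate the corresponding expectations. The run is
#' fully reproducible from \code{seed}.
#'
#' @param design a [SimulationDesign-class].
#' @param methods subset of \code{c("ccrs", "spc", "col", "cast",
#'   "skato")} (\code{"spc_first_k"} is accepted as an alias).
#' @param alphas significance levels, default \code{c(0.01, 0.05)}.
#' @param replicates number of replicate datasets.
#' @param seed base seed; replicate i uses seed + 1000 i.
#' @param control a [ccrsControl()] list for the CCRS/SPC pipelines.
#' @param rhoGrid SKAT-O kernel grid.
#' @return data.frame with one row per method and alpha: Monte-Carlo
#'   means and standard errors of fdr_est, tpr_conventional and
#'   tpr_printed. The per-replicate table is attached as attribute
#'   \code{"replicates"}.
#' @export
runSimulationStudy <- function(design, methods = c("ccrs", "col", "cast",
                                                   "skato"),
                               alphas = c(0.01, 0.05), replicates = 1L,
                               seed = 1L, control = ccrsControl(),
                               rhoGrid = c(0, 0.25, 0.5, 0.75, 1)) {
  bad <- setdiff(methods, .studyMethods)
  if (length(bad)) stop("unknown method label: ", paste(bad, collapse = ", "))
  if (replicates < 1) stop("need at least one replicate")
  p <- design@variantsPerRegion
  perRep <- list()
  for (rep in seq_len(as.integer(replicates))) {
    repSeed <- as.integer(seed) + 1000L * rep
    sim <- simulateDataset(design, seed = repSeed)
    D <- dosages(sim$G)
    for (m in methods) {
      rows <- vector("list", design@nRegions)
      for (r in seq_len(design@nRegions)) {
        rid <- r - 1L
        X <- D[, (rid * p + 1L):(r * p), drop = FALSE]
        rows[[r]] <- .applyMethod(m, X, sim$y, NULL, control, rhoGrid,
                                  rid, seed = repSeed + r)
      }
      res <- do.call(rbind, rows)
      for (a in alphas) {
        sc <- scoreReplicate(res, sim$truth, a)
        sc$method <- if (m == "spc_first_k") "spc" else m
        sc$replicate <- rep
        perRep[[length(perRep) + 1L]] <- sc
      }
    }
  }
  tab <- do.call(rbind, perRep)
  agg <- do.call(rbind, lapply(split(tab, list(tab$method, tab$alpha),
                                     drop = TRUE), function(g) {
    data.frame(method = g$method[1], alpha = g$alpha[1],
               fdr = mean(g$fdr_est),
               fdr_se = sd(g$fdr_est) / sqrt(nrow(g)),
               tpr = mean(g$tpr_conventional),
               tpr_se = sd(g$tpr_conventional) / sqrt(nrow(g)),
               tpr_printed = mean(g$tpr_printed),
               replicates = nrow(g))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$method, agg$alpha), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- tab
  agg
}
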