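# Shared fixture builders: all data are generated in code at test time.

# Write a VCF from explicit record fields; gt is a list of per-site
# genotype-string vectors (one element per sample).
writeVcfText <- function(path, chrom, pos, id, ref, alt, gt,
                         samples = sprintf("s%d", seq_along(gt[[1]]))) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (s in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[s], pos[s], id[s], ref[s], alt[s],
                              ".", "PASS", ".", "GT", gt[[s]]),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# A dosage column of length n with a given number of heterozygote and
# homozygote-alt carriers (the rest homozygous reference).
dosageColumn <- function(n, het = 0, hom = 0) {
  c(rep(2, hom), rep(1, het), rep(0, n - het - hom))
}

# Random dosage matrix with all columns polymorphic at MAF <= maxMaf.
randomDosageMatrix <- function(n, p, maxMaf = 0.05) {
  D <- matrix(0, n, p)
  for (j in seq_len(p)) {
    repeat {
      maf <- runif(1, min(1 / n, maxMaf / 2), maxMaf)
      d <- rbinom(n, 2, maf)
      m <- computeMAF(d)
      if (m > 0 && m <= maxMaf) break
    }
    D[, j] <- d
  }
  D
}

# Independent brute-force oracle for the univariate bridge objective.
gridBridgeOracle <- function(a, b, nu, kappa, step = 1e-6) {
  hi <- abs(b)
  if (hi == 0) return(0)
  g <- seq(0, hi, by = step)
  obj <- 0.5 * a * (g - abs(b))^2 + nu * g^kappa
  sign(b) * g[which.min(obj)]
}

# Independent recount oracle for FDR/TPR scoring.
recountOracle <- function(pvalues, regionIds, influential, alpha) {
  M <- length(pvalues)
  R <- 0L; Tn <- 0L
  for (i in seq_len(M)) {
    if (pvalues[i] <= alpha) {
      R <- R + 1L
      if (regionIds[i] %in% influential) Tn <- Tn + 1L
    }
  }
  list(F = R - Tn, T = Tn, R = R, M = M,
       fdr = if (R > 0) (R - Tn) / R else 0,
       tpr = if (length(influential) > 0) Tn / length(influential)
             else NA_real_,
       tpr_printed = if (M > R) Tn / (M - R) else NA_real_)
}
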