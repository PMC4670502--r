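#' @include AllGenerics.R
NULL

#' Minor allele frequency of a dosage vector
#'
#' Folds the alternate-allele frequency f = sum(dosages) / (2n) onto
#' min(f, 1 - f), so the value is always the frequency of the rarer
#' allele.
#'
#' @param dosages integer vector with entries in \{0, 1, 2\}, no missing
#'   values.
#' @return MAF in [0, 0.5].
#' @examples
#' computeMAF(c(0, 0, 1, 1))  # 0.25
#' computeMAF(c(2, 2, 2, 1))  # 0.125 (alt frequency 7/8 folds back)
#' @export
computeMAF <- function(dosages) {
  if (length(dosages) == 0) stop("empty dosage vector")
  if (anyNA(dosages)) stop("dosage vector contains missing values")
  f <- sum(dosages) / (2 * length(dosages))
  min(f, 1 - f)
}

# Parse one site's GT strings into per-alt-allele dosage columns.
# Returns a list with one n-vector per alternate allele plus the missing
# mask. "." alleles or absent GT mark the whole genotype missing.
.parseSiteGT <- function(gt, nAlt) {
  gt[is.na(gt)] <- "."
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  missing <- vapply(alleles, function(a) length(a) == 0 || any(a == "."),
                    logical(1))
  lapply(seq_len(nAlt), function(k) {
    d <- vapply(alleles, function(a) sum(a == as.character(k)), numeric(1))
    d[missing] <- NA_real_
    d
  })
}

#' Read rare-variant genotypes from a VCF
#'
#' Parses GT calls with \pkg{vcfR}, converts them to alternate-allele
#' dosages, splits multi-allelic sites into one biallelic column per
#' alternate allele, imputes missing genotypes, and retains variants with
#' dosage-derived MAF in (0, maf] (the boundary is inclusive). Variant
#' order follows the file, which for a valid VCF is position order.
#'
#' @param vcfPath path to a plain or bgzipped VCF with GT fields.
#' @param maf MAF filter threshold in (0, 0.5]; default 0.05 (rare and
#'   low-frequency variants).
#' @param missing imputation policy for missing genotypes: \code{"zero"}
#'   (homozygous reference, the default -- rare-variant dosages are
#'   overwhelmingly 0) or \code{"mean"} (column mean of observed dosages
#'   rounded to \{0,1,2\}).
#' @return A [GenotypeMatrix-class] with the retained variants.
#' @export
readGenotypes <- function(vcfPath, maf = 0.05,
                          missing = c("zero", "mean")) {
  missing <- match.arg(missing)
  if (!(maf > 0 && maf <= 0.5)) stop("maf threshold must lie in (0, 0.5]")
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  if (nrow(vcf@fix) == 0) stop("no variant records in ", vcfPath)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT", IDtoRowNames = FALSE)
  samples <- colnames(gt)
  cols <- list()
  meta <- list()
  for (s in seq_len(nrow(fix))) {
    alts <- strsplit(fix[s, "ALT"], ",", fixed = TRUE)[[1]]
    dlist <- .parseSiteGT(gt[s, ], length(alts))
    for (k in seq_along(alts)) {
      d <- dlist[[k]]
      if (anyNA(d)) {
        if (missing == "zero") {
          d[is.na(d)] <- 0
        } else {
          mu <- mean(d, na.rm = TRUE)
          if (is.nan(mu)) mu <- 0
          d[is.na(d)] <- min(2, max(0, round(mu)))
        }
      }
      vid <- fix[s, "ID"]
      if (is.na(vid) || vid == ".")
        vid <- sprintf("%s:%s:%s:%s", fix[s, "CHROM"], fix[s, "POS"],
                       fix[s, "REF"], alts[k])
      else if (length(alts) > 1) vid <- sprintf("%s_alt%d", vid, k)
      cols[[length(cols) + 1L]] <- d
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = fix[s, "CHROM"], pos = as.integer(fix[s, "POS"]),
        vid = vid, ref = fix[s, "REF"], alt = alts[k],
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(cbind, cols)
  rownames(d) <- samples
  v <- do.call(rbind, meta)
  v$maf <- apply(d, 2, computeMAF)
  keep <- v$maf > 0 & v$maf <= maf + 1e-12
  if (!any(keep))
    stop("no variant passes the MAF filter (0, ", maf, "]")
  GenotypeMatrix(d[, keep, drop = FALSE], v[keep, , drop = FALSE])
}

.enumerateWindows <- function(m, windowSize, step, minSize) {
  stopifnot(windowSize >= minSize, minSize >= 1, step >= 1,
            step <= windowSize)
  empty <- data.frame(region_id = integer(0), col_start = integer(0),
                      col_end = integer(0))
  if (m < minSize) return(empty)
  starts <- seq.int(0L, m - 1L, by = step)
  ends <- pmin(starts + windowSize, m)
  reach <- which(ends == m)  # stop once a window touches the end
  if (length(reach)) {
    starts <- starts[seq_len(reach[1])]
    ends <- ends[seq_len(reach[1])]
  }
  keep <- (ends - starts) >= minSize
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)
  data.frame(region_id = seq_along(starts) - 1L,
             col_start = as.integer(starts), col_end = as.integer(ends))
}

#' Enumerate sliding windows over variant columns
#'
#' Windows are count-based: they start at column offsets 0, step, 2*step,
#' ... and span \code{windowSize} variants (half-open 0-based column
#' ranges, the package-internal convention). Enumeration stops at the
#' first window that reaches the last variant, and a trailing window
#' narrower than \code{minSize} is dropped. For a [GenotypeMatrix-class]
#' input the genomic span (chrom, pos_start, pos_end taken from the first
#' and last variant of the window) and variant count are added.
#'
#' @param x variant count m, or a [GenotypeMatrix-class].
#' @param windowSize variants per window (default 50).
#' @param step offset between consecutive windows (default 25).
#' @param minSize smallest window retained (default 10).
#' @param ... unused.
#' @return data.frame of windows; empty (zero rows) when m < minSize.
#' @examples
#' makeWindows(120)  # 4 windows at offsets 0, 25, 50, 75
#' @export
setGeneric("makeWindows", function(x, windowSize = 50L, step = 25L,
                                   minSize = 10L, ...)
  standardGeneric("makeWindows"))

#' @rdname makeWindows
#' @export
setMethod("makeWindows", "numeric",
          function(x, windowSize = 50L, step = 25L, minSize = 10L, ...)
  .enumerateWindows(as.integer(x), as.integer(windowSize),
                    as.integer(step), as.integer(minSize)))

#' @rdname makeWindows
#' @export
setMethod("makeWindows", "GenotypeMatrix",
          function(x, windowSize = 50L, step = 25L, minSize = 10L, ...) {
  w <- .enumerateWindows(nVariants(x), as.integer(windowSize),
                         as.integer(step), as.integer(minSize))
  if (!nrow(w)) return(w)
  v <- variants(x)
  w$chrom <- v$chrom[w$col_start + 1L]
  w$pos_start <- v$pos[w$col_start + 1L]
  w$pos_end <- v$pos[w$col_end]
  w$n_variants <- w$col_end - w$col_start
  w
})

#' Write a window manifest TSV
#'
#' @param windows window data.frame from [makeWindows()] on a
#'   [GenotypeMatrix-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeWindowManifest <- function(windows, path) {
  cols <- intersect(c("region_id", "chrom", "pos_start", "pos_end",
                      "n_variants"), names(windows))
  write.table(windows[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column TSV with a header: \code{sample_id} and \code{value}.
#'
#' @param path file path.
#' @return named numeric vector of phenotype values.
#' @export
readPhenotype <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(tab)))
    stop("phenotype table needs columns sample_id and value")
  setNames(as.numeric(tab$value), tab$sample_id)
}

#' Read a covariate table
#'
#' TSV with a header: \code{sample_id} plus one numeric column per
#' covariate.
#'
#' @param path file path.
#' @return numeric matrix with sample ids as row names.
#' @export
readCovariates <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!("sample_id" %in% names(tab)))
    stop("covariate table needs a sample_id column")
  m <- as.matrix(tab[, setdiff(names(tab), "sample_id"), drop = FALSE])
  rownames(m) <- tab$sample_id
  storage.mode(m) <- "double"
  m
}

#' Harmonize genotypes, phenotype and covariates by sample id
#'
#' Intersects the sample ids and orders everything to the VCF (genotype)
#' sample order.
#'
#' @param G a [GenotypeMatrix-class].
#' @param pheno named phenotype vector from [readPhenotype()].
#' @param covar optional covariate matrix from [readCovariates()].
#' @return list with elements \code{G}, \code{y} and \code{T} (NULL when
#'   no covariates).
#' @export
alignSamples <- function(G, pheno, covar = NULL) {
  ids <- sampleIds(G)
  common <- ids[ids %in% names(pheno)]
  if (!is.null(covar)) common <- common[common %in% rownames(covar)]
  if (length(common) < 2)
    stop("fewer than two samples shared between genotypes and phenotype")
  list(G = G[match(common, ids), ],
       y = unname(pheno[common]),
       T = if (is.null(covar)) NULL else covar[common, , drop = FALSE])
}
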