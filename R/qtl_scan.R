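# per-marker squared correlation with the phenotype, vectorised;
# monomorphic markers get r2 = 0 and are flagged
marker_r2 <- function(geno, pheno) {
  yc <- pheno - mean(pheno)
  gc <- sweep(geno, 2, colMeans(geno))
  ssg <- colSums(gc^2)
  mono <- ssg == 0
  ssg[mono] <- 1
  r2 <- as.vector(crossprod(gc, yc))^2 / (ssg * sum(yc^2))
  r2[mono] <- 0
  list(r2 = r2, mono = mono)
}

# LOD from per-marker r2; numerically perfect fits (RSS1 ~ 0, where the
# log ratio is infinite or dominated by rounding) are capped at the ceiling
lod_from_r2 <- function(r2, n, lod_cap) {
  lod <- -(n / 2) * log10(1 - r2)
  lod[!is.finite(lod) | (1 - r2) < 1e-12] <- lod_cap
  lod
}

#' Genome-wide single-marker LOD scan
#'
#' Regresses the per-line phenotype on the genotype code (0/1/2, with
#' residual heterozygotes included as 1) marker by marker and reports
#' `LOD = (n/2) log10(RSS0 / RSS1)`, equivalently
#' `-(n/2) log10(1 - r^2)`. A marker-regression scan of this kind is the
#' dense-map limit of interval mapping: with thousands of bin markers
#' there is essentially no between-marker position to impute. Lines with
#' a missing phenotype are dropped; markers with missing genotypes drop
#' those lines marker-wise. Monomorphic markers get `LOD = 0` and a flag.
#' A perfect fit (`RSS1 = 0`) is capped at `lod_cap`.
#'
#' @param genotypes lines x markers genotype matrix (codes 0/1/2).
#' @param phenotype numeric per-line phenotype, in the row order of
#'   `genotypes` (or named by line id).
#' @param map marker map (`marker`, `chrom`, `cM`, `bp`) matching the
#'   genotype columns.
#' @param lod_cap ceiling for degenerate perfect fits (default 50).
#' @return Object of class `lod_scan`: the map data.frame plus `LOD` and
#'   logical `monomorphic` columns; attributes carry `n` (lines used).
#' @export
lod_scan <- function(genotypes, phenotype, map, lod_cap = 50) {
  if (!is.null(names(phenotype)) && !is.null(rownames(genotypes)))
    phenotype <- phenotype[rownames(genotypes)]
  if (nrow(genotypes) < 3L) stop("need at least 3 lines")
  if (nrow(genotypes) < 50L)
    warning("fewer than 50 lines: LOD scan will have little power")
  if (!identical(colnames(genotypes), map$marker))
    stop("genotype columns must match map$marker (same order)")
  keep <- is.finite(phenotype)
  geno <- genotypes[keep, , drop = FALSE]
  pheno <- phenotype[keep]
  n <- length(pheno)
  if (anyNA(geno)) {
    lod <- numeric(ncol(geno)); mono <- logical(ncol(geno))
    for (k in seq_len(ncol(geno))) {
      ok <- !is.na(geno[, k])
      res <- marker_r2(geno[ok, k, drop = FALSE], pheno[ok])
      lod[k] <- lod_from_r2(res$r2, sum(ok), lod_cap)
      mono[k] <- res$mono
    }
  } else {
    res <- marker_r2(geno, pheno)
    lod <- lod_from_r2(res$r2, n, lod_cap)
    mono <- res$mono
  }
  out <- map
  out$LOD <- lod
  out$monomorphic <- mono
  attr(out, "n") <- n
  attr(out, "phenotype") <- deparse(substitute(phenotype))[1L]
  class(out) <- c("lod_scan", "data.frame")
  out
}

#' @export
print.lod_scan <- function(x, ...) {
  cat("LOD scan: ", nrow(x), " markers on ", length(unique(x$chrom)),
      " chromosome(s), n = ", attr(x, "n"), " lines\n", sep = "")
  top <- x[which.max(x$LOD), c("marker", "chrom", "cM", "bp", "LOD")]
  cat("max LOD ", format(top$LOD, digits = 4), " at ", top$marker,
      " (", top$chrom, ", ", format(top$cM, digits = 4), " cM)\n", sep = "")
  thr <- attr(x, "threshold")
  if (!is.null(thr)) cat("genome-wide threshold: ", format(thr, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.lod_scan <- function(x, threshold = attr(x, "threshold"), ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(tapply(x$cM, factor(x$chrom, chroms), max) + 5))
  pos <- x$cM + offs[match(x$chrom, chroms)]
  plot(pos, x$LOD, type = "l", xlab = "genome position (cM, chromosomes laid end to end)",
       ylab = "LOD", ...)
  graphics::abline(v = offs[-1] - 2.5, col = "grey80")
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}

#' Permutation threshold for a genome-wide LOD scan
#'
#' Shuffles the phenotype vector over lines (preserving the genotype
#' correlation structure, after Churchill & Doerge), rescans, and returns
#' the `1 - alpha` quantile of the per-permutation maximum LOD.
#'
#' @inheritParams lod_scan
#' @param n_perm number of permutations (>= 100; the study profile is 1000).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed optional integer seed.
#' @return Numeric threshold, with the max-LOD null sample in the
#'   `"max_lods"` attribute.
#' @export
permutation_threshold <- function(genotypes, phenotype, map, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, lod_cap = 50) {
  if (n_perm < 100) stop("use at least 100 permutations")
  if (!is.null(names(phenotype)) && !is.null(rownames(genotypes)))
    phenotype <- phenotype[rownames(genotypes)]
  keep <- is.finite(phenotype)
  geno <- genotypes[keep, , drop = FALSE]
  pheno <- phenotype[keep]
  if (anyNA(geno)) { # mean-impute for the permutation pass only
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2L]]
  }
  n <- length(pheno)
  if (!is.null(seed)) set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(pheno), numeric(n))
  Yc <- sweep(Y, 2, colMeans(Y))
  gc <- sweep(geno, 2, colMeans(geno))
  ssg <- colSums(gc^2)
  poly <- ssg > 0
  ssy <- colSums(Yc^2)
  r2 <- crossprod(gc[, poly, drop = FALSE], Yc)^2 / outer(ssg[poly], ssy)
  lod <- lod_from_r2(r2, n, lod_cap)
  max_lods <- apply(lod, 2L, max)
  thr <- stats::quantile(max_lods, 1 - alpha, names = FALSE)
  attr(thr, "max_lods") <- max_lods
  thr
}

#' Call QTL peaks with 1.5-LOD support intervals
#'
#' Identifies, per chromosome, local LOD maxima above the genome-wide
#' threshold. Neighbouring maxima count as distinct QTLs only when the
#' LOD between them both drops by more than `drop` below the lower of
#' the two peaks and returns below the significance threshold; otherwise
#' they are merged into one QTL (leftmost marker of a maximal plateau is
#' the reported peak).
#' The support interval runs from the peak outward while the LOD stays at
#' or above `peak - drop` (a 1.5-LOD support interval by default); its bp
#' bounds are rounded outward to the next flanking bin marker where one
#' exists. Per peak, the percent variance explained is
#' `PVE = 100 (1 - 10^(-2 LOD / n))` (the regression R-squared) and the
#' additive effect is `a = (mean of code-0 lines - mean of code-2
#' lines)/2`, so alleles from the parent coded 2 that raise the trait
#' yield negative `a`.
#'
#' @param scan a [lod_scan()] result.
#' @param threshold genome-wide LOD threshold (from
#'   [permutation_threshold()]).
#' @param genotypes,phenotype the scan inputs, used for the additive
#'   effect at each peak.
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return Object of class `qtl_peaks`: data.frame with one row per QTL
#'   (`chrom`, `peak_marker`, `peak_cM`, `peak_bp`, `LOD`, `PVE`,
#'   `additive`, `ci_lo_cM`, `ci_hi_cM`, `start`, `end`). Empty when no
#'   marker exceeds the threshold.
#' @export
call_qtls <- function(scan, threshold, genotypes = NULL, phenotype = NULL,
                      drop = 1.5) {
  n <- attr(scan, "n")
  rows <- list()
  if (!is.null(phenotype) && !is.null(names(phenotype)) && !is.null(rownames(genotypes)))
    phenotype <- phenotype[rownames(genotypes)]
  for (chrom in unique(scan$chrom)) {
    idx <- which(scan$chrom == chrom)
    lod <- scan$LOD[idx]
    above <- which(lod > threshold)
    if (length(above) == 0L) next
    # local maxima above threshold (leftmost marker of any plateau)
    is_peak <- vapply(above, function(i) {
      (i == 1L || lod[i] > lod[i - 1L]) && (i == length(lod) || lod[i] >= lod[i + 1L])
    }, logical(1))
    peaks <- above[is_peak]
    if (length(peaks) == 0L) peaks <- above[which.max(lod[above])]
    # adjacent maxima are distinct QTLs only when the profile both drops
    # by > `drop` below the lower of the two and returns below the
    # significance threshold in between; otherwise they are one QTL
    merged <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- merged[length(merged)]
      valley <- min(lod[last:p])
      if (valley > min(lod[last], lod[p]) - drop || valley > threshold) {
        if (lod[p] > lod[last]) merged[length(merged)] <- p
      } else merged <- c(merged, p)
    }
    for (p in merged) {
      lo <- p
      while (lo > 1L && lod[lo - 1L] >= lod[p] - drop) lo <- lo - 1L
      hi <- p
      while (hi < length(lod) && lod[hi + 1L] >= lod[p] - drop) hi <- hi + 1L
      bp_lo <- scan$bp[idx[max(lo - 1L, 1L)]]      # rounded outward
      bp_hi <- scan$bp[idx[min(hi + 1L, length(idx))]]
      pve <- 100 * (1 - 10^(-2 * lod[p] / n))
      add <- NA_real_
      if (!is.null(genotypes) && !is.null(phenotype)) {
        g <- genotypes[, scan$marker[idx[p]]]
        ok <- is.finite(phenotype) & !is.na(g)
        m0 <- mean(phenotype[ok & g == 0])
        m2 <- mean(phenotype[ok & g == 2])
        add <- (m0 - m2) / 2
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, peak_marker = scan$marker[idx[p]],
        peak_cM = scan$cM[idx[p]], peak_bp = scan$bp[idx[p]],
        LOD = lod[p], PVE = pve, additive = add,
        ci_lo_cM = scan$cM[idx[lo]], ci_hi_cM = scan$cM[idx[hi]],
        start = bp_lo, end = bp_hi, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), peak_marker = character(0),
               peak_cM = numeric(0), peak_bp = numeric(0), LOD = numeric(0),
               PVE = numeric(0), additive = numeric(0), ci_lo_cM = numeric(0),
               ci_hi_cM = numeric(0), start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "drop") <- drop
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

#' @export
print.qtl_peaks <- function(x, ...) {
  thr <- attr(x, "threshold"); drp <- attr(x, "drop")
  cat(nrow(x), " QTL(s)",
      if (!is.null(thr)) paste0(" above LOD threshold ", format(thr, digits = 4)),
      if (!is.null(drp)) paste0(" (", format(drp, digits = 3), "-LOD support intervals)"),
      "\n", sep = "")
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lod_scan <- function(object, threshold = attr(object, "threshold"), ...) {
  if (is.null(threshold))
    stop("no threshold stored; pass `threshold =` (see permutation_threshold)")
  call_qtls(object, threshold, ...)
}
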