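#' Per-bulk SNP index
#'
#' The SNP index of a bulk at a site is the fraction of reads carrying the
#' alternative allele, `alt / (alt + ref)`. Zero-depth sites get `NA`
#' (they are removed by the depth filter downstream).
#'
#' @param counts bulk allele-depth table (`chrom`, `pos`, `ref_mul`,
#'   `alt_mul`, `ref_tri`, `alt_tri`), e.g. from [read_bulk_vcf()] or
#'   [simulate_bulk_reads()].
#' @return The table with added columns `depth_mul`, `depth_tri`,
#'   `index_mul`, `index_tri`.
#' @export
snp_index <- function(counts) {
  counts$depth_mul <- counts$ref_mul + counts$alt_mul
  counts$depth_tri <- counts$ref_tri + counts$alt_tri
  counts$index_mul <- ifelse(counts$depth_mul > 0, counts$alt_mul / counts$depth_mul, NA_real_)
  counts$index_tri <- ifelse(counts$depth_tri > 0, counts$alt_tri / counts$depth_tri, NA_real_)
  counts
}

#' Depth and index filters for the SNP-index track
#'
#' Removes SNPs whose total sequencing depth in either bulk is below
#' `min_depth` (default 3), and SNPs whose SNP index is below `min_index`
#' (default 0.3) in *both* bulks — low-index-everywhere sites carry no
#' bulk contrast and are dominated by reference-biased or erroneous
#' calls. Removal counts per rule are reported in a message and kept in
#' the `"removed"` attribute. The filter is idempotent.
#'
#' @param track output of [snp_index()].
#' @param min_depth minimum per-bulk total depth (sites with less are
#'   dropped).
#' @param min_index index threshold; a site is dropped when the index is
#'   below this in both bulks.
#' @return The filtered track.
#' @export
filter_snps <- function(track, min_depth = 3, min_index = 0.3) {
  bad_depth <- is.na(track$index_mul) | is.na(track$index_tri) |
    track$depth_mul < min_depth | track$depth_tri < min_depth
  bad_index <- !bad_depth &
    track$index_mul < min_index & track$index_tri < min_index
  out <- track[!(bad_depth | bad_index), , drop = FALSE]
  rownames(out) <- NULL
  removed <- c(depth = sum(bad_depth), index = sum(bad_index))
  if (any(removed > 0))
    message("filter_snps: removed ", removed["depth"], " SNP(s) by depth, ",
            removed["index"], " by low index in both bulks")
  attr(out, "removed") <- removed
  out
}

#' Delta SNP index
#'
#' Adds `delta = index_tri - index_mul` (low-trait bulk minus high-trait
#' bulk); values near +-1 indicate near-fixation of opposite alleles in
#' the two bulks, i.e. tight linkage to the selected trait.
#'
#' @param track filtered SNP-index track.
#' @return The track with a `delta` column.
#' @export
delta_index <- function(track) {
  track$delta <- track$index_tri - track$index_mul
  track
}

# per chromosome: window start grid (anchored at position 1, step-aligned)
# and the [lo, hi] index range of SNPs in each window, given sorted positions
window_grid <- function(pos, window, step) {
  starts <- seq(1, max(pos), by = step)
  hi <- findInterval(starts + window - 1, pos)
  lo <- findInterval(starts - 1, pos)
  data.frame(start = starts, end = starts + window - 1, lo = lo, hi = hi)
}

#' Sliding-window smoothing of the delta SNP index
#'
#' Averages `delta` in windows of `window` bp advanced by `step` bp
#' (defaults 1 Mbp and 10 kbp), with the window grid anchored at position
#' 1 of each chromosome. Windows containing fewer than `min_snps` SNPs
#' (default 10) are skipped.
#'
#' @param track filtered track with `delta` (see [delta_index()]),
#'   sorted by position within chromosomes.
#' @param window,step window size and increment in bp.
#' @param min_snps minimum SNPs for a window to be retained.
#' @return Object of class `window_track`: data.frame with `chrom`,
#'   `start`, `end`, `n_snps`, `mean_delta`.
#' @export
window_scan <- function(track, window = 1e6, step = 1e4, min_snps = 10) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    t_c <- track[track$chrom == chrom, ]
    if (is.unsorted(t_c$pos)) stop("track must be sorted by position within chromosomes")
    grid <- window_grid(t_c$pos, window, step)
    n <- grid$hi - grid$lo
    keep <- which(n >= min_snps)
    if (length(keep) == 0L) next
    means <- vapply(keep, function(w)
      mean(t_c$delta[(grid$lo[w] + 1L):grid$hi[w]]), numeric(1))
    out[[chrom]] <- data.frame(chrom = chrom, start = grid$start[keep],
                               end = grid$end[keep], n_snps = n[keep],
                               mean_delta = means, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_snps = integer(0), mean_delta = numeric(0))
  rownames(res) <- NULL
  attr(res, "window") <- window
  attr(res, "step") <- step
  attr(res, "min_snps") <- min_snps
  class(res) <- c("window_track", "data.frame")
  res
}

#' Permutation-style null cutoff for window mean delta SNP indices
#'
#' Computes genome-wide two-sided cutoffs as the `quantile` (default 99%)
#' of the absolute null window mean over `n_iter` Monte Carlo iterations.
#' Three null models are available:
#'
#' * `"block"` (default): per retained window and iteration, the allele
#'   count of each bulk is redrawn as `Binomial(bulk_size, 1/2)` — the
#'   segregation expectation for an unselected RIL-derived bulk — shared
#'   by all SNPs in the window (SNPs within one window are effectively
#'   completely linked in an inbred RIL population), plus per-window
#'   read-sampling noise (normal approximation of the mean of the
#'   per-SNP binomial read draws, using each window's observed depths).
#'   This propagates both bulk-composition and sequencing noise, per the
#'   QTL-seq framework.
#' * `"snp"`: per-SNP alt counts redrawn as `Binomial(observed depth,
#'   1/2)` independently across SNPs (read noise only; anti-conservative
#'   for linked SNPs).
#' * `"label"`: bulk labels swapped SNP-wise at random (sign-flip of
#'   `delta`).
#'
#' @param track filtered SNP-index track with `delta`.
#' @param windows retained [window_scan()] track computed from `track`.
#' @param n_iter Monte Carlo iterations (>= 1000; the study profile is
#'   100,000, a reduced profile of a few thousand is adequate for a 99%
#'   cutoff).
#' @param quantile cutoff quantile of the absolute null window mean.
#' @param bulk_size number of lines per bulk (for the `"block"` null).
#' @param null null model, see above.
#' @param seed optional integer seed.
#' @return Object of class `bsa_cutoff`: list with `lower`, `upper`,
#'   `quantile`, `n_iter`, `null`.
#' @export
permutation_cutoff <- function(track, windows, n_iter = 2000, quantile = 0.99,
                               bulk_size = 30, null = c("block", "snp", "label"),
                               seed = NULL) {
  null <- match.arg(null)
  if (n_iter < 1000) stop("use at least 1000 iterations")
  if (nrow(windows) == 0L) stop("no retained windows")
  if (!is.null(seed)) set.seed(seed)
  n_win <- nrow(windows)
  # per-chromosome [lo, hi] SNP index ranges of each retained window
  ranges <- list()
  for (chrom in unique(windows$chrom)) {
    pos <- track$pos[track$chrom == chrom]
    w_c <- windows[windows$chrom == chrom, ]
    ranges[[chrom]] <- list(idx = which(track$chrom == chrom),
                            win = which(windows$chrom == chrom),
                            lo = findInterval(w_c$start - 1, pos),
                            hi = findInterval(w_c$end, pos),
                            n = w_c$n_snps)
  }
  win_sums <- function(values) { # per-window sums of a per-SNP vector
    out <- numeric(n_win)
    for (r in ranges) {
      cs <- c(0, cumsum(values[r$idx]))
      out[r$win] <- cs[r$hi + 1L] - cs[r$lo + 1L]
    }
    out
  }
  if (null == "block") {
    # per-window read-noise scale: Var(mean_s alt_s/dep_s) = f(1-f) * sum(1/dep_s) / n^2
    si_mul <- win_sums(1 / track$depth_mul) / windows$n_snps^2
    si_tri <- win_sums(1 / track$depth_tri) / windows$n_snps^2
    abs_means <- numeric(n_win * n_iter)
    for (it in seq_len(n_iter)) {
      f_mul <- stats::rbinom(n_win, bulk_size, 0.5) / bulk_size
      f_tri <- stats::rbinom(n_win, bulk_size, 0.5) / bulk_size
      m <- (f_tri - f_mul) +
        stats::rnorm(n_win, 0, sqrt(f_tri * (1 - f_tri) * si_tri)) -
        stats::rnorm(n_win, 0, sqrt(f_mul * (1 - f_mul) * si_mul))
      abs_means[((it - 1L) * n_win + 1L):(it * n_win)] <- abs(m)
    }
  } else {
    abs_means <- numeric(n_win * n_iter)
    for (it in seq_len(n_iter)) {
      if (null == "snp") {
        d_null <- stats::rbinom(nrow(track), track$depth_tri, 0.5) / track$depth_tri -
          stats::rbinom(nrow(track), track$depth_mul, 0.5) / track$depth_mul
      } else {
        d_null <- track$delta * sample(c(-1, 1), nrow(track), replace = TRUE)
      }
      abs_means[((it - 1L) * n_win + 1L):(it * n_win)] <-
        abs(win_sums(d_null) / windows$n_snps)
    }
  }
  cut <- stats::quantile(abs_means, quantile, names = FALSE)
  structure(list(lower = -cut, upper = cut, quantile = quantile,
                 n_iter = n_iter, null = null, bulk_size = bulk_size),
            class = "bsa_cutoff")
}

#' @export
print.bsa_cutoff <- function(x, ...) {
  cat(sprintf("delta SNP-index cutoff (+-%.4f) at the %.0f%% level, %s null, %d iterations\n",
              x$upper, 100 * x$quantile, x$null, x$n_iter))
  invisible(x)
}

#' Call significant delta-SNP-index regions
#'
#' Flags retained windows whose mean delta exceeds the upper cutoff
#' (low-trait-bulk enriched for the alternative allele, direction
#' `"TRI"`) or falls below the lower cutoff (direction `"MUL"`), and
#' merges flagged windows of the same direction whose intervals overlap
#' or abut into regions (interval = union of member windows).
#'
#' @param windows a [window_scan()] track.
#' @param cutoffs a [permutation_cutoff()] result (or a single positive
#'   number used as `+-cutoff`).
#' @return Object of class `bsa_regions`: data.frame with `chrom`,
#'   `start`, `end`, `direction`, `n_windows`, `peak_delta`, `cutoff`.
#' @export
call_regions <- function(windows, cutoffs) {
  if (is.numeric(cutoffs))
    cutoffs <- list(lower = -abs(cutoffs), upper = abs(cutoffs))
  sig <- windows[windows$mean_delta > cutoffs$upper |
                 windows$mean_delta < cutoffs$lower, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      direction = character(0), n_windows = integer(0),
                      peak_delta = numeric(0), cutoff = numeric(0))
    class(out) <- c("bsa_regions", "data.frame")
    return(out)
  }
  sig$direction <- ifelse(sig$mean_delta > 0, "TRI", "MUL")
  sig <- sig[order(sig$chrom, sig$start), ]
  rows <- list()
  cur <- sig[1L, ]
  cur$n_windows <- 1L
  cur$peak_delta <- cur$mean_delta
  for (i in seq_len(nrow(sig))[-1L]) {
    w <- sig[i, ]
    if (w$chrom == cur$chrom && w$direction == cur$direction &&
        w$start <= cur$end + 1) {
      cur$end <- max(cur$end, w$end)
      cur$n_windows <- cur$n_windows + 1L
      if (abs(w$mean_delta) > abs(cur$peak_delta)) cur$peak_delta <- w$mean_delta
    } else {
      rows[[length(rows) + 1L]] <- cur
      cur <- w; cur$n_windows <- 1L; cur$peak_delta <- w$mean_delta
    }
  }
  rows[[length(rows) + 1L]] <- cur
  out <- do.call(rbind, rows)[, c("chrom", "start", "end", "direction",
                                  "n_windows", "peak_delta")]
  out$cutoff <- cutoffs$upper
  rownames(out) <- NULL
  class(out) <- c("bsa_regions", "data.frame")
  out
}

#' Run the full delta-SNP-index pipeline
#'
#' Convenience wrapper: [snp_index()] -> [filter_snps()] ->
#' [delta_index()] -> [window_scan()] -> [permutation_cutoff()] ->
#' [call_regions()].
#'
#' @inheritParams snp_index
#' @inheritParams filter_snps
#' @inheritParams window_scan
#' @inheritParams permutation_cutoff
#' @return Object of class `bsa_scan`: list with `snps` (filtered track),
#'   `windows`, `cutoff`, `regions`.
#' @export
bsa_scan <- function(counts, min_depth = 3, min_index = 0.3, window = 1e6,
                     step = 1e4, min_snps = 10, n_iter = 2000,
                     quantile = 0.99, bulk_size = 30,
                     null = c("block", "snp", "label"), seed = NULL) {
  track <- delta_index(filter_snps(snp_index(counts), min_depth, min_index))
  windows <- window_scan(track, window, step, min_snps)
  cutoff <- permutation_cutoff(track, windows, n_iter = n_iter,
                               quantile = quantile, bulk_size = bulk_size,
                               null = match.arg(null), seed = seed)
  regions <- call_regions(windows, cutoff)
  structure(list(snps = track, windows = windows, cutoff = cutoff,
                 regions = regions), class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("delta SNP-index scan: ", nrow(x$snps), " SNPs after filtering, ",
      nrow(x$windows), " retained windows\n", sep = "")
  print(x$cutoff)
  cat(nrow(x$regions), " significant region(s)\n", sep = "")
  if (nrow(x$regions)) print.data.frame(x$regions, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bsa_scan <- function(x, ...) {
  w <- x$windows
  chroms <- unique(w$chrom)
  offs <- c(0, cumsum(tapply(w$end, factor(w$chrom, chroms), max) + 1e6))
  pos <- (w$start + w$end) / 2 + offs[match(w$chrom, chroms)]
  plot(pos / 1e6, w$mean_delta, type = "p", pch = 16, cex = 0.3,
       xlab = "genome position (Mb, chromosomes laid end to end)",
       ylab = "window mean delta SNP index", ylim = c(-1, 1), ...)
  graphics::abline(h = c(x$cutoff$lower, x$cutoff$upper), col = "red", lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
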