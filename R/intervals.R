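#' Construct a table of genomic intervals
#'
#' Intervals use the 1-based, fully inclusive convention throughout the
#' package, so physical positions printed in QTL tables map verbatim onto
#' interval bounds. BED output converts to 0-based half-open coordinates
#' (see [write_bed()]).
#'
#' @param chrom character vector of chromosome identifiers (opaque strings,
#'   e.g. `"Gm02"`).
#' @param start,end integer-like vectors of 1-based inclusive bounds,
#'   `start <= end`.
#' @param name optional character vector of interval names.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and `name`
#'   when supplied).
#' @export
genomic_interval <- function(chrom, start, end, name = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) stop("interval bounds must be numeric")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start > end)) stop("interval start must be <= end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- as.character(name)
  out
}

#' Interval width in megabases
#'
#' Width is defined as `(end - start) / 1e6`, the convention used when QTL
#' confidence regions are reported as a "range" in Mb between two printed
#' physical positions.
#'
#' @param intervals data.frame with `start` and `end` columns (bp).
#' @return Numeric vector of widths in Mb.
#' @export
interval_width_mb <- function(intervals) {
  (intervals$end - intervals$start) / 1e6
}

#' Common region of overlapping intervals
#'
#' Reduces a set of pairwise-overlapping intervals on one chromosome to
#' their common (intersection) region: maximum of starts to minimum of
#' ends. This is the rule used to reduce QTL support intervals detected in
#' several biological replicates to a single confidence region.
#'
#' @param intervals data.frame of intervals (`chrom`, `start`, `end`), all
#'   on the same chromosome.
#' @return One-row interval data.frame.
#' @export
common_region <- function(intervals) {
  if (nrow(intervals) < 1L) stop("need at least one interval")
  if (length(unique(intervals$chrom)) != 1L)
    stop("all intervals must be on one chromosome")
  s <- max(intervals$start)
  e <- min(intervals$end)
  if (s > e)
    stop("intervals are disjoint: no common region (QTL not replicate-consistent)")
  genomic_interval(intervals$chrom[1L], s, e)
}

#' Write intervals to a BED file
#'
#' Converts from the package's 1-based inclusive convention to BED's
#' 0-based half-open convention (`start - 1`, `end`).
#'
#' @param intervals data.frame of intervals (`chrom`, `start`, `end`,
#'   optional `name`), sorted within each chromosome.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(chrom = intervals$chrom,
                   start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                   end = format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) df$name <- intervals$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into the internal interval convention
#'
#' @param path BED file path (3 or more columns; the 4th, when present, is
#'   taken as the interval name).
#' @return Interval data.frame in 1-based inclusive coordinates.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(genomic_interval(character(0), numeric(0), numeric(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  genomic_interval(df[[1L]], df[[2L]] + 1, df[[3L]],
                   name = if (ncol(df) >= 4L) df[[4L]] else NULL)
}
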