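#' Intersect linkage QTL regions with BSA regions
#'
#' Pairs every linkage-mapping QTL interval with every bulked-segregant
#' region and reports each non-empty intersection
#' (`[max(starts), min(ends)]`), optionally attaching the genes falling
#' in the intersection.
#'
#' @param qtl_regions interval data.frame with a `name` column (QTL names)
#'   plus `chrom`, `start`, `end`.
#' @param bsa_regions interval data.frame (`chrom`, `start`, `end`;
#'   an optional `source` column, e.g. the bulk stage, is carried over).
#' @param genes optional gene table from [read_gff_genes()]; when given,
#'   each record lists the overlapping gene ids and their count.
#' @return data.frame with one row per overlapping pair: `name`, `chrom`,
#'   linkage and BSA bounds, intersection `start`/`end` and, with `genes`,
#'   `n_genes` and a comma-separated `gene_ids`.
#' @export
intersect_regions <- function(qtl_regions, bsa_regions, genes = NULL) {
  rows <- list()
  for (i in seq_len(nrow(qtl_regions))) for (j in seq_len(nrow(bsa_regions))) {
    if (qtl_regions$chrom[i] != bsa_regions$chrom[j]) next
    s <- max(qtl_regions$start[i], bsa_regions$start[j])
    e <- min(qtl_regions$end[i], bsa_regions$end[j])
    if (s > e) next
    rec <- data.frame(name = qtl_regions$name[i], chrom = qtl_regions$chrom[i],
                      qtl_start = qtl_regions$start[i], qtl_end = qtl_regions$end[i],
                      bsa_start = bsa_regions$start[j], bsa_end = bsa_regions$end[j],
                      start = s, end = e, stringsAsFactors = FALSE)
    if (!is.null(bsa_regions$source)) rec$source <- bsa_regions$source[j]
    if (!is.null(genes)) {
      ids <- genes_in(data.frame(chrom = rec$chrom, start = s, end = e), genes)
      rec$n_genes <- length(ids)
      rec$gene_ids <- paste(ids, collapse = ",")
    }
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows))
    return(data.frame(name = character(0), chrom = character(0),
                      qtl_start = numeric(0), qtl_end = numeric(0),
                      bsa_start = numeric(0), bsa_end = numeric(0),
                      start = numeric(0), end = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$name), , drop = FALSE]
}

#' Genes overlapping an interval
#'
#' By default a gene is counted when its interval overlaps the query by
#' at least 1 bp (1-based inclusive, so a gene ending exactly at the
#' query start is included); `rule = "within"` requires full containment.
#'
#' @param interval one-row interval data.frame (`chrom`, `start`, `end`).
#' @param genes gene table from [read_gff_genes()].
#' @param rule `"any"` (default) or `"within"`.
#' @return Character vector of gene ids, ordered by start position.
#' @export
genes_in <- function(interval, genes, rule = c("any", "within")) {
  rule <- match.arg(rule)
  hit <- genes$chrom == interval$chrom[1L] &
    if (rule == "any") {
      genes$start <= interval$end[1L] & genes$end >= interval$start[1L]
    } else {
      genes$start >= interval$start[1L] & genes$end <= interval$end[1L]
    }
  g <- genes[hit, ]
  g$gene_id[order(g$start, g$gene_id)]
}

#' Classify a variant position relative to a gene model
#'
#' Strand-aware classification: `"genic"` inside the gene interval;
#' `"upstream"` within `flank` bp beyond the transcription start site
#' (before the gene on `+`, after it on `-`); `"downstream"` within
#' `flank` bp beyond the transcription termination site; `"intergenic"`
#' otherwise.
#'
#' @param position variant bp position (vectorised).
#' @param gene one-row gene record (`start`, `end`, `strand`).
#' @param flank flank size in bp (default 1000).
#' @return Character vector of classes.
#' @export
classify_variant <- function(position, gene, flank = 1000) {
  start <- gene$start[1L]; end <- gene$end[1L]
  fwd <- gene$strand[1L] != "-"
  before <- position >= start - flank & position < start
  after <- position > end & position <= end + flank
  ifelse(position >= start & position <= end, "genic",
         ifelse(if (fwd) before else after, "upstream",
                ifelse(if (fwd) after else before, "downstream", "intergenic")))
}

#' Filter candidate genes by expression in both bulks
#'
#' Marks a gene as expressed only when its FPKM strictly exceeds
#' `threshold` (default 1) in *every* listed bulk sample of the stage.
#' Genes absent from the matrix are flagged unexpressed with a warning.
#'
#' @param gene_ids character vector of candidate gene ids.
#' @param fpkm FPKM matrix from [read_fpkm()] (genes x samples).
#' @param bulk_samples column names of the two bulks at the stage.
#' @param threshold FPKM threshold (strict inequality).
#' @return data.frame with `gene_id`, one FPKM column per bulk sample,
#'   and logical `expressed`.
#' @export
expression_filter <- function(gene_ids, fpkm, bulk_samples, threshold = 1) {
  missing_s <- setdiff(bulk_samples, colnames(fpkm))
  if (length(missing_s))
    stop("bulk sample(s) not in FPKM matrix: ", paste(missing_s, collapse = ", "))
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  present <- gene_ids %in% rownames(fpkm)
  if (any(!present))
    warning("gene(s) missing from FPKM matrix, flagged unexpressed: ",
            paste(gene_ids[!present], collapse = ", "))
  for (s in bulk_samples) {
    out[[s]] <- NA_real_
    out[[s]][present] <- fpkm[gene_ids[present], s]
  }
  vals <- as.matrix(out[, bulk_samples, drop = FALSE])
  out$expressed <- present & apply(vals > threshold, 1L, all)
  out$expressed[is.na(out$expressed)] <- FALSE
  out
}

#' Write the candidate-gene report
#'
#' Joins overlap records with candidate-gene expression calls and writes
#' a TSV report (one row per candidate gene per overlap region, with QTL
#' provenance, intervals, expression flag and observed variant classes)
#' plus a BED file of the candidate gene intervals. Output ordering is
#' deterministic: chromosome, start, gene id.
#'
#' @param overlaps output of [intersect_regions()] (with `genes`
#'   attached).
#' @param candidates output of [expression_filter()].
#' @param genes gene table from [read_gff_genes()].
#' @param path output TSV path; the BED is written next to it with a
#'   `.bed` extension.
#' @param variant_classes optional named character vector (gene id ->
#'   comma-separated classes observed) merged into the report.
#' @return Invisibly, the report data.frame.
#' @export
candidate_report <- function(overlaps, candidates, genes, path,
                             variant_classes = NULL) {
  rows <- list()
  for (i in seq_len(nrow(overlaps))) {
    ids <- strsplit(overlaps$gene_ids[i], ",", fixed = TRUE)[[1L]]
    ids <- ids[nzchar(ids)]
    if (!length(ids)) next
    g <- genes[match(ids, genes$gene_id), ]
    rec <- data.frame(gene_id = ids, chrom = g$chrom, start = g$start,
                      end = g$end, qtl = overlaps$name[i],
                      source = if (!is.null(overlaps$source)) overlaps$source[i] else NA_character_,
                      region_start = overlaps$start[i],
                      region_end = overlaps$end[i], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rec
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), qtl = character(0),
               source = character(0), region_start = numeric(0),
               region_end = numeric(0), stringsAsFactors = FALSE)
  report$expressed <- candidates$expressed[match(report$gene_id, candidates$gene_id)]
  report$variant_classes <- if (!is.null(variant_classes))
    unname(variant_classes[report$gene_id]) else rep(NA_character_, nrow(report))
  report <- report[order(report$chrom, report$start, report$gene_id), , drop = FALSE]
  rownames(report) <- NULL
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- report[!duplicated(report$gene_id), , drop = FALSE]
  write_bed(genomic_interval(bed$chrom, bed$start, bed$end, name = bed$gene_id),
            sub("\\.[^.]*$", ".bed", path))
  invisible(report)
}
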