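#' Read per-bulk allele depths from a two-sample VCF
#'
#' Parses a VCF carrying variant calls for two pooled extreme bulks (a
#' high-trait bulk, conventionally named `MUL`, and a low-trait bulk,
#' `TRI`) and returns the per-SNP REF/ALT read depths taken from the
#' `FORMAT/AD` field. Only biallelic SNP records are kept: multiallelic
#' records and indels are skipped and their count is reported in a message
#' and in the `"n_skipped"` attribute of the result.
#'
#' @param path path to a VCF 4.x file with exactly the two named samples
#'   and an `AD` (allelic depth) FORMAT field.
#' @param mul_sample,tri_sample sample names of the high- and low-trait
#'   bulks in the VCF (defaults `"MUL"`, `"TRI"`).
#' @return A `data.frame` with one row per retained SNP and columns
#'   `chrom`, `pos`, `ref_mul`, `alt_mul`, `ref_tri`, `alt_tri`.
#' @export
read_bulk_vcf <- function(path, mul_sample = "MUL", tri_sample = "TRI") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcf@gt
  samples <- colnames(gt)[-1L]
  for (s in c(mul_sample, tri_sample))
    if (!s %in% samples) stop("sample '", s, "' not found in VCF (has: ",
                              paste(samples, collapse = ", "), ")")
  pos <- as.numeric(fix$POS)
  # positions must be sorted within each chromosome
  if (any(unlist(tapply(pos, factor(fix$CHROM, levels = unique(fix$CHROM)),
                        function(p) diff(p) < 0))))
    stop("VCF positions are not sorted within chromosomes")
  no_ad <- !vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "AD" %in% f, logical(1))
  if (any(no_ad))
    stop("record ", fix$CHROM[which(no_ad)[1L]], ":", pos[which(no_ad)[1L]],
         " has no AD field")
  biallelic_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_skipped <- sum(!biallelic_snp)
  if (n_skipped > 0L)
    message("read_bulk_vcf: skipped ", n_skipped,
            " multiallelic/indel record(s)")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    ref <- as.numeric(vapply(parts, `[`, character(1), 1L))
    alt <- as.numeric(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1)))
    cbind(ref, alt)
  }
  keep <- which(biallelic_snp)
  ad_mul <- parse_ad(ad[keep, mul_sample])
  ad_tri <- parse_ad(ad[keep, tri_sample])
  out <- data.frame(chrom = fix$CHROM[keep], pos = pos[keep],
                    ref_mul = ad_mul[, 1L], alt_mul = ad_mul[, 2L],
                    ref_tri = ad_tri[, 1L], alt_tri = ad_tri[, 2L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write bulk allele depths as a minimal two-sample VCF
#'
#' Inverse of [read_bulk_vcf()] for simulated data: emits one biallelic
#' SNP record per row with the per-bulk depths in `FORMAT/AD`. REF/ALT
#' bases are placeholders (`A`/`C`); depths round-trip exactly.
#'
#' @param counts data.frame as returned by [read_bulk_vcf()] or
#'   [simulate_bulk_reads()].
#' @param path output path.
#' @param mul_sample,tri_sample sample names to write.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(counts, path, mul_sample = "MUL", tri_sample = "TRI") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", mul_sample, tri_sample, sep = "\t")), con)
  if (nrow(counts) > 0L) {
    pos <- format(counts$pos, scientific = FALSE, trim = TRUE)
    writeLines(paste(counts$chrom, pos, ".", "A", "C", ".", "PASS", ".", "AD",
                     paste0(counts$ref_mul, ",", counts$alt_mul),
                     paste0(counts$ref_tri, ",", counts$alt_tri),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features and derives the transcription start (TSS) and
#' termination (TTS) sites from the strand: on `+` the TSS is the interval
#' start, on `-` it is the interval end.
#'
#' @param path GFF3 file path.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tts`.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GFF3 line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), tss = numeric(0), tts = numeric(0)))
  df <- as.data.frame(gr)
  ids <- df$ID
  if (is.null(ids)) ids <- df$Name
  if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(df)))
  if (anyDuplicated(ids)) stop("duplicate gene identifiers in GFF3")
  strand <- as.character(df$strand)
  data.frame(gene_id = as.character(ids),
             chrom = as.character(df$seqnames),
             start = df$start, end = df$end, strand = strand,
             tss = ifelse(strand == "-", df$end, df$start),
             tts = ifelse(strand == "-", df$start, df$end),
             stringsAsFactors = FALSE)
}

#' Read/write the long-format phenotype table
#'
#' The phenotype table records, per line and biological replicate, the
#' number of seedlings expressing the trait (`count`) out of the number
#' scored (`n`).
#'
#' @param path TSV path with header `line`, `rep`, `count`, `n` and
#'   `#`-comments allowed.
#' @return `read_phenotypes()`: the phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("line", "rep", "count", "n")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0 | df$count > df$n))
    stop("affected counts must lie in [0, n]")
  df
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype data.frame to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' @param path TSV with a `gene_id` column followed by one numeric column
#'   per sample.
#' @return Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (any(m < 0)) stop("FPKM values must be non-negative")
  m
}

#' Published QTL confidence regions for the soybean multifoliolate trait
#'
#' Confidence regions of ten multifoliolate-leaf QTLs mapped in a C08 x
#' W05 soybean RIL population (common regions across biological
#' replicates), with the ranges in Mb as printed in the source study, plus
#' the regions where linkage mapping and BSR-seq bulks agreed. Bundled as
#' worked-example input for the interval arithmetic and integration steps.
#'
#' @return A `data.frame` of intervals: `mf_qtl_regions()` has columns
#'   `name`, `chrom`, `start`, `end`, `range_mb_printed`, `n_genes`;
#'   `mf_joint_regions()` has `chrom`, `name`, `source`, `start`, `end`.
#' @export
mf_qtl_regions <- function() {
  utils::read.delim(system.file("extdata", "multifoliolate_qtl_regions.tsv",
                                package = "bsrqtl"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname mf_qtl_regions
#' @export
mf_joint_regions <- function() {
  utils::read.delim(system.file("extdata", "multifoliolate_joint_regions.tsv",
                                package = "bsrqtl"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
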