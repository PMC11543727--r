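# in-code fixtures shared across test files

# write a small two-sample VCF; `records` is a data.frame with columns
# chrom, pos, ref, alt, ad_mul, ad_tri (AD strings), optional format
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           samples = c("MUL", "TRI"), format = "GT:AD") {
  gt_prefix <- if (startsWith(format, "GT")) "0/1:" else ""
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_len(nrow(records)), function(i) {
      paste(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", format,
            paste0(gt_prefix, records$ad_mul[i]),
            paste0(gt_prefix, records$ad_tri[i]), sep = "\t")
    }, character(1)))
  writeLines(lines, path)
  path
}

# minimal GFF3 with the given gene rows (data.frame: chrom, start, end,
# strand, id, type defaults to "gene")
write_test_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  if (is.null(genes$type)) genes$type <- "gene"
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(genes)), function(i) {
               paste(genes$chrom[i], "test", genes$type[i], genes$start[i],
                     genes$end[i], ".", genes$strand[i], ".",
                     paste0("ID=", genes$id[i]), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}

# brute-force double-loop oracle for sliding-window delta means
oracle_window_means <- function(track, window = 1e6, step = 1e4, min_snps = 10) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    t_c <- track[track$chrom == chrom, ]
    for (s in seq(1, max(t_c$pos), by = step)) {
      vals <- c()
      for (i in seq_len(nrow(t_c)))
        if (t_c$pos[i] >= s && t_c$pos[i] <= s + window - 1)
          vals <- c(vals, t_c$delta[i])
      if (length(vals) >= min_snps)
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = s,
                                              end = s + window - 1,
                                              n_snps = length(vals),
                                              mean_delta = mean(vals))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# random filtered SNP-index track for oracle comparisons
random_delta_track <- function(n_snps, n_chrom = 1, span = 5e6) {
  chrom <- sprintf("Gm%02d", sample(n_chrom, n_snps, replace = TRUE))
  pos <- sample(span, n_snps)
  ord <- order(chrom, pos)
  data.frame(chrom = chrom[ord], pos = pos[ord],
             delta = round(stats::runif(n_snps, -1, 1), 3))
}

# 6-row hand fixture for the depth / index filters; survivors enumerated
# by hand: row 1 fails MUL depth (2 < 3); row 2 passes (depths 3/3,
# indices 1/3); row 3 fails the both-bulks index rule (0.2, 0.1);
# row 4 passes (MUL index 0.5); row 5 fails MUL depth (2 < 3);
# row 6 passes (MUL index exactly 0.3)
filter_fixture <- function() {
  data.frame(
    chrom = "Gm01", pos = c(100, 200, 300, 400, 500, 600),
    ref_mul = c(1, 2, 8, 5, 0, 7), alt_mul = c(1, 1, 2, 5, 2, 3),
    ref_tri = c(15, 2, 9, 9, 10, 8), alt_tri = c(15, 1, 1, 1, 10, 2))
}
filter_fixture_survivors <- c(200, 400, 600)
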