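#' Null calibration of the delta-SNP-index cutoff
#'
#' Simulation study: RIL populations with *no* genetic effect on the
#' trait are generated, extreme bulks selected on the (purely
#' environmental) phenotype, pooled read depths simulated, and the full
#' window scan plus permutation cutoff run. Reports the fraction of
#' retained windows whose mean delta exceeds the 99% cutoff, averaged
#' over seeds — for a calibrated cutoff this should stay near (and for a
#' slightly conservative one below) 1% per tail, i.e. a few percent at
#' most. Overlapping windows are strongly correlated, so single-seed
#' fractions are highly variable; the average is the meaningful figure.
#'
#' The default genome is a reduced profile: 2 chromosomes of 50 cM /
#' 20 Mb carrying 2000 SNPs in total, 400 lines, 30-line bulks, mean
#' depth 30, 2000 cutoff iterations.
#'
#' @param n_seeds number of independent simulated populations.
#' @param seed base seed; per-population seeds are derived from it.
#' @param n_lines,bulk_size,mean_depth,n_iter study-design knobs.
#' @return List with `fraction` (mean exceedance fraction) and the
#'   per-seed `fractions`.
#' @export
calibrate_bsa_null <- function(n_seeds = 10, seed = 1, n_lines = 400,
                               bulk_size = 30, mean_depth = 30,
                               n_iter = 2000) {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 50,
                      markers_per_chrom = 1000, bp_per_cM = 4e5)
  fractions <- vapply(seq_len(n_seeds), function(i) {
    base <- seed * 1000 + i * 7
    geno <- simulate_ril_genotypes(map, n_lines, seed = base)
    ph <- simulate_phenotypes(geno, qtl_model(), seed = base + 1)
    bulks <- select_bulks(ph, bulk_size)
    counts <- simulate_bulk_reads(geno, bulks, map, mean_depth = mean_depth,
                                  seed = base + 2)
    scan <- suppressMessages(
      bsa_scan(counts, n_iter = n_iter, bulk_size = bulk_size,
               seed = base + 3))
    mean(abs(scan$windows$mean_delta) > scan$cutoff$upper)
  }, numeric(1))
  list(fraction = mean(fractions), fractions = fractions)
}

#' Planted-QTL recovery by both genome scans
#'
#' Simulation study: one QTL of given additive liability effect is
#' planted in the middle of the first chromosome; per seed, the study
#' runs (i) the bulked-segregant pipeline and asks whether a significant
#' region contains the true locus, and (ii) the LOD scan on the per-line
#' BLUP and asks whether the genome-wide peak lies within `cm_tol` cM of
#' the true marker.
#'
#' @param n_seeds number of replicate populations (default 20).
#' @param seed base seed.
#' @param effect additive liability effect of the planted QTL.
#' @param n_lines population size; `replicate_design` fixed at three
#'   replicates of 10 seedlings.
#' @param bulk_size,mean_depth,n_iter bulked-segregant design.
#' @param cm_tol LOD peak tolerance in cM.
#' @return List with `bsa_rate`, `lod_rate` and per-seed logical vectors.
#' @export
recover_planted_qtl <- function(n_seeds = 20, seed = 1, effect = 1.0,
                                n_lines = 400, bulk_size = 30,
                                mean_depth = 30, n_iter = 2000,
                                cm_tol = 5) {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 50,
                      markers_per_chrom = 1000, bp_per_cM = 4e5)
  true_marker <- "Gm01_m0500"
  true_bp <- map$bp[map$marker == true_marker]
  true_cm <- map$cM[map$marker == true_marker]
  design <- data.frame(rep = c("Rep1", "Rep2", "Rep3"), n = c(10L, 10L, 10L))
  model <- qtl_model(qtl_markers = true_marker, effects = effect)
  bsa_hit <- lod_hit <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    base <- seed * 1000 + i * 11
    geno <- simulate_ril_genotypes(map, n_lines, seed = base)
    ph <- simulate_phenotypes(geno, model, replicate_design = design,
                              seed = base + 1)
    bulks <- select_bulks(ph, bulk_size)
    counts <- simulate_bulk_reads(geno, bulks, map, mean_depth = mean_depth,
                                  seed = base + 2)
    scan <- suppressMessages(
      bsa_scan(counts, n_iter = n_iter, bulk_size = bulk_size,
               seed = base + 3))
    reg <- scan$regions
    bsa_hit[i] <- any(reg$chrom == "Gm01" & reg$start <= true_bp &
                      reg$end >= true_bp)
    vc <- suppressWarnings(variance_components(ph))
    b <- blup(ph, vc)
    lods <- lod_scan(geno, b, map)
    peak <- lods[which.max(lods$LOD), ]
    lod_hit[i] <- peak$chrom == "Gm01" && abs(peak$cM - true_cm) <= cm_tol
  }
  list(bsa_rate = mean(bsa_hit), lod_rate = mean(lod_hit),
       bsa_hit = bsa_hit, lod_hit = lod_hit)
}

#' Genome-wide false-positive rate of the permutation LOD threshold
#'
#' Estimates the permutation threshold once (on a null phenotype) and
#' applies it to fresh null scans on the same genotypes; under correct
#' calibration the fraction of scans whose maximum LOD exceeds the
#' threshold matches `alpha`.
#'
#' @param n_scans fresh null scans (default 200).
#' @param seed base seed.
#' @param n_lines,n_markers genotype panel size (markers split over two
#'   chromosomes).
#' @param n_perm,alpha threshold settings.
#' @return List with `fpr`, `threshold` and the per-scan `max_lods`.
#' @export
calibrate_lod_threshold <- function(n_scans = 200, seed = 1, n_lines = 200,
                                    n_markers = 200, n_perm = 1000,
                                    alpha = 0.05) {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 100,
                      markers_per_chrom = n_markers / 2, bp_per_cM = 4e5)
  geno <- simulate_ril_genotypes(map, n_lines, seed = seed * 1000 + 1)
  set.seed(seed * 1000 + 2)
  y0 <- stats::rnorm(n_lines)
  thr <- permutation_threshold(geno, y0, map, n_perm = n_perm, alpha = alpha,
                               seed = seed * 1000 + 3)
  set.seed(seed * 1000 + 4)
  gc <- sweep(geno, 2, colMeans(geno))
  ssg <- colSums(gc^2)
  Y <- matrix(stats::rnorm(n_lines * n_scans), n_lines, n_scans)
  Yc <- sweep(Y, 2, colMeans(Y))
  r2 <- crossprod(gc[, ssg > 0], Yc)^2 / outer(ssg[ssg > 0], colSums(Yc^2))
  max_lods <- apply(matrix(-(n_lines / 2) * log10(1 - r2), nrow(r2)), 2L, max)
  list(fpr = mean(max_lods > thr), threshold = as.numeric(thr),
       max_lods = max_lods)
}

#' Heritability recovery on balanced trials with known components
#'
#' Generates balanced Gaussian line-by-environment trials with known
#' variance components (see [sim_balanced_trial()]), estimates the
#' components and broad-sense heritability, and reports the mean absolute
#' error against the closed-form truth
#' `H2 = V_g / (V_g + V_ge/L + V_e/(R L))`.
#'
#' @param n_seeds replicate trials (default 20).
#' @param seed base seed.
#' @param n_lines,n_env,n_rep trial layout.
#' @param V_g,V_ge,V_e true components.
#' @return List with `mean_abs_error`, `h2_true` and per-seed `h2_est`.
#' @export
recover_heritability <- function(n_seeds = 20, seed = 1, n_lines = 500,
                                 n_env = 3, n_rep = 2, V_g = 2, V_ge = 1,
                                 V_e = 3) {
  h2_true <- heritability(V_g = V_g, V_ge = V_ge, V_e = V_e,
                          R = n_rep, L = n_env)
  h2_est <- vapply(seq_len(n_seeds), function(i) {
    ph <- sim_balanced_trial(n_lines, n_env, n_rep, V_g, V_ge, V_e,
                             seed = seed * 1000 + i * 13)
    heritability(variance_components(ph, response = "count"))
  }, numeric(1))
  list(mean_abs_error = mean(abs(h2_est - h2_true)), h2_true = h2_true,
       h2_est = h2_est)
}
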