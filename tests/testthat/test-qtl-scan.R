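tiny_map <- function(n, chrom = "Gm01") {
  data.frame(marker = sprintf("%s_m%03d", chrom, seq_len(n)), chrom = chrom,
             cM = seq(0, by = 2, length.out = n),
             bp = seq(1, by = 1e5, length.out = n))
}

# scan object constructed directly, for exercising the peak caller
fake_scan <- function(lod, map = tiny_map(length(lod)), n = 200) {
  map$LOD <- lod
  map$monomorphic <- FALSE
  attr(map, "n") <- n
  class(map) <- c("lod_scan", "data.frame")
  map
}

test_that("LOD at a marker equals the hand-computed least-squares value", {
  # 8-line worked example
  x <- c(0, 0, 2, 2, 0, 2, 1, 0)
  y <- c(1.2, 0.8, 3.1, 2.7, 1.5, 3.4, 2.0, 1.1)
  geno <- cbind(m1 = x, m2 = rep(1, 8))  # m2 monomorphic
  rownames(geno) <- paste0("L", 1:8)
  map <- tiny_map(2)
  colnames(geno) <- map$marker
  sc <- suppressWarnings(lod_scan(geno, y, map))
  rss0 <- sum((y - mean(y))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  rss1 <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  expect_equal(sc$LOD[1], (8 / 2) * log10(rss0 / rss1), tolerance = 1e-10)
  expect_equal(sc$LOD[2], 0)
  expect_true(sc$monomorphic[2])
})

test_that("the vectorised scan matches a per-marker lm() oracle", {
  set.seed(41)
  for (trial in 1:3) {
    n <- sample(10:20, 1)
    m <- sample(4:10, 1)
    geno <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE), n, m)
    geno[, 1] <- c(0L, 2L, rep(0L, n - 2))  # guarantee polymorphism
    map <- tiny_map(m)
    colnames(geno) <- map$marker
    rownames(geno) <- sprintf("L%02d", 1:n)
    y <- rnorm(n)
    sc <- suppressWarnings(lod_scan(geno, y, map))
    for (k in seq_len(m)) {
      if (sc$monomorphic[k]) next
      fit <- lm(y ~ geno[, k])
      rss1 <- sum(resid(fit)^2)
      rss0 <- sum((y - mean(y))^2)
      expect_equal(sc$LOD[k], (n / 2) * log10(rss0 / rss1), tolerance = 1e-8)
      # PVE identity at any marker: 100 (1 - 10^(-2 LOD / n)) = 100 R^2
      expect_equal(100 * (1 - 10^(-2 * sc$LOD[k] / n)),
                   100 * summary(fit)$r.squared, tolerance = 1e-8)
    }
  }
})

test_that("a perfect genotype-phenotype fit is capped, not infinite", {
  map <- tiny_map(3)
  set.seed(42)
  geno <- matrix(sample(c(0L, 2L), 60 * 3, replace = TRUE), 60, 3,
                 dimnames = list(sprintf("L%02d", 1:60), map$marker))
  y <- as.numeric(geno[, 2])
  sc <- lod_scan(geno, y, map)
  expect_equal(sc$LOD[2], 50)
  sc25 <- lod_scan(geno, y, map, lod_cap = 25)
  expect_equal(sc25$LOD[2], 25)
})

test_that("null scans produce small LOD scores genome-wide", {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 100, markers_per_chrom = 50)
  med <- vapply(1:20, function(s) {
    geno <- simulate_ril_genotypes(map, 200, seed = 700 + s)
    set.seed(800 + s)
    median(lod_scan(geno, rnorm(200), map)$LOD)
  }, numeric(1))
  expect_lt(median(med), 0.5)
})

test_that("permutation thresholds are deterministic and monotone in alpha", {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 100, markers_per_chrom = 50)
  geno <- simulate_ril_genotypes(map, 200, seed = 51)
  set.seed(52)
  y <- rnorm(200)
  t1 <- permutation_threshold(geno, y, map, n_perm = 200, seed = 53)
  t2 <- permutation_threshold(geno, y, map, n_perm = 200, seed = 53)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_strict <- permutation_threshold(geno, y, map, n_perm = 200, alpha = 0.01, seed = 53)
  t_loose <- permutation_threshold(geno, y, map, n_perm = 200, alpha = 0.5, seed = 53)
  t_all <- permutation_threshold(geno, y, map, n_perm = 200, alpha = 1, seed = 53)
  expect_gte(t_strict, t1)
  expect_gte(t1, t_loose)
  expect_equal(as.numeric(t_all), min(attr(t1, "max_lods")))
  expect_error(permutation_threshold(geno, y, map, n_perm = 50), "100")
})

test_that("a flat significant profile yields one QTL spanning the chromosome", {
  sc <- fake_scan(rep(4, 10))
  pk <- call_qtls(sc, threshold = 3)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_marker, "Gm01_m001")  # leftmost of the plateau
  expect_equal(pk$ci_lo_cM, sc$cM[1])
  expect_equal(pk$ci_hi_cM, sc$cM[10])
})

test_that("peaks merge unless separated by a deep, sub-threshold valley", {
  # shallow valley (drop < 1.5): one QTL
  sc <- fake_scan(c(1, 5, 4.2, 5.5, 1, 1, 1, 1, 1, 1))
  expect_equal(nrow(call_qtls(sc, threshold = 3)), 1L)
  # deep valley but still above the threshold: still one QTL
  sc2 <- fake_scan(c(1, 8, 3.5, 8.5, 1, 1, 1, 1, 1, 1))
  expect_equal(nrow(call_qtls(sc2, threshold = 3)), 1L)
  # deep valley below the threshold: two QTLs
  sc3 <- fake_scan(c(1, 8, 1.5, 8.5, 1, 1, 1, 1, 1, 1))
  pk3 <- call_qtls(sc3, threshold = 3)
  expect_equal(nrow(pk3), 2L)
  # nothing above threshold: empty, not an error
  expect_equal(nrow(call_qtls(fake_scan(rep(1, 10)), threshold = 3)), 0L)
})

test_that("support intervals cover the peak and round bp bounds outward", {
  sc <- fake_scan(c(1, 1, 2, 6, 2, 1, 1, 1, 1, 1))
  pk <- call_qtls(sc, threshold = 3)
  expect_equal(pk$peak_marker, "Gm01_m004")
  expect_equal(c(pk$ci_lo_cM, pk$ci_hi_cM), c(6, 6))  # only the peak stays
  # bp bounds step one marker outward from the cM bounds
  expect_equal(c(pk$start, pk$end), c(sc$bp[3], sc$bp[5]))
  expect_true(pk$start <= pk$peak_bp && pk$peak_bp <= pk$end)
})

test_that("additive effects are negative when the code-2 parent raises the trait", {
  map <- simulate_map(n_chrom = 1, chrom_length_cM = 50, markers_per_chrom = 20)
  geno <- simulate_ril_genotypes(map, 300, seed = 61)
  qtl <- map$marker[10]
  y <- (geno[, qtl] - 1) * 0.9 + rnorm(300, 0, 0.8)
  sc <- lod_scan(geno, y, map)
  pk <- call_qtls(sc, threshold = 3, genotypes = geno, phenotype = y)
  expect_gte(nrow(pk), 1L)
  expect_lt(pk$additive[which.max(pk$LOD)], 0)
})

test_that("common_region reduces replicate intervals by intersection", {
  reps <- genomic_interval(c("Gm02", "Gm02"), c(5500000, 5550000),
                           c(5900000, 5850000))
  cr <- common_region(reps)
  expect_equal(c(cr$start, cr$end), c(5550000, 5850000))
  expect_equal(interval_width_mb(cr), 0.3)
  same <- genomic_interval("Gm01", 10, 20)
  expect_equal(common_region(rbind(same, same)), same)
  nested <- genomic_interval(c("Gm01", "Gm01"), c(10, 12), c(30, 20))
  expect_equal(common_region(nested)$start, 12)
  expect_equal(common_region(nested)$end, 20)
  disjoint <- genomic_interval(c("Gm01", "Gm01"), c(10, 50), c(20, 60))
  expect_error(common_region(disjoint), "disjoint")
  mixed <- genomic_interval(c("Gm01", "Gm02"), c(10, 10), c(20, 20))
  expect_error(common_region(mixed), "one chromosome")
})
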