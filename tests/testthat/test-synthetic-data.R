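test_that("simulate_map lays out even grids and is deterministic", {
  m <- simulate_map(n_chrom = 1, chrom_length_cM = 100, markers_per_chrom = 11)
  expect_equal(m$cM, seq(0, 100, by = 10))
  expect_true(all(diff(m$bp) > 0))
  big <- simulate_map(n_chrom = 20, markers_per_chrom = 320)
  expect_equal(nrow(big), 6400L)
  expect_equal(length(unique(big$chrom)), 20L)
  u1 <- simulate_map(2, 50, 30, spacing = "uniform", seed = 9)
  u2 <- simulate_map(2, 50, 30, spacing = "uniform", seed = 9)
  expect_identical(u1, u2)
  expect_error(simulate_map(0), "positive")
  expect_error(simulate_map(markers_per_chrom = 1), "positive")
})

test_that("RIL transmission follows the selfing effective recombination R*", {
  # completely linked markers: identical genotype columns
  map0 <- data.frame(marker = c("a", "b"), chrom = "Gm01", cM = c(5, 5),
                     bp = c(100, 200))
  g0 <- simulate_ril_genotypes(map0, 500, residual_het = 0, seed = 3)
  expect_identical(g0[, "a"], g0[, "b"])

  n <- 2000
  # unlinked markers: switch rate ~ 0.5
  map_far <- data.frame(marker = c("a", "b"), chrom = "Gm01",
                        cM = c(0, 2e4), bp = c(1, 2e9))
  g <- simulate_ril_genotypes(map_far, n, residual_het = 0, seed = 4)
  rate <- mean(g[, "a"] != g[, "b"])
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(rate - 0.5), 3 * se)

  # 10 cM gap: r = (1 - exp(-0.2))/2, R* = 2r/(1+2r)
  map10 <- data.frame(marker = c("a", "b"), chrom = "Gm01", cM = c(0, 10),
                      bp = c(1, 4e6))
  r <- (1 - exp(-0.2)) / 2
  Rstar <- 2 * r / (1 + 2 * r)
  g10 <- simulate_ril_genotypes(map10, n, residual_het = 0, seed = 5)
  rate10 <- mean(g10[, "a"] != g10[, "b"])
  expect_lt(abs(rate10 - Rstar), 3 * sqrt(Rstar * (1 - Rstar) / n))
})

test_that("segregation and residual heterozygosity match expectation", {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 50, markers_per_chrom = 25)
  g <- simulate_ril_genotypes(map, 2000, residual_het = 0.01, seed = 6)
  # per-marker mean genotype ~ 1 (3 SE of the per-marker mean of codes 0/2)
  se <- sqrt(1 / 2000)  # sd of code is ~1 for a 50:50 {0,2} mix
  worst <- max(abs(colMeans(g) - 1))
  expect_lt(worst, 3 * se + 0.02)  # small allowance for het injection
  expect_lt(abs(mean(g == 1L) - 0.01), 0.005)
  expect_error(simulate_ril_genotypes(map, 10, residual_het = 0.2), "residual_het")
})

test_that("sporadic phenotype model hits its binomial expectation and saturates", {
  map <- simulate_map(n_chrom = 1, chrom_length_cM = 50, markers_per_chrom = 10)
  geno <- simulate_ril_genotypes(map, 400, seed = 7)
  null_model <- qtl_model(mu = qlogis(0.2), rep_effects = 0,
                          sigma_ge = 0, sigma_eps = 0)
  design <- data.frame(rep = "Rep1", n = 10L)
  ph <- simulate_phenotypes(geno, null_model, design, seed = 8)
  se <- sqrt(10 * 0.2 * 0.8 / 400)
  expect_lt(abs(mean(ph$count) - 2), 3 * se)

  # enormous positive effect: code-2 lines always affected
  big <- qtl_model(qtl_markers = map$marker[5], effects = 50,
                   mu = 0, rep_effects = 0, sigma_ge = 0, sigma_eps = 0)
  ph_big <- simulate_phenotypes(geno, big, design, seed = 9)
  code2 <- rownames(geno)[geno[, 5] == 2L]
  expect_true(all(ph_big$count[ph_big$line %in% code2] == 10L))

  expect_identical(simulate_phenotypes(geno, null_model, design, seed = 11),
                   simulate_phenotypes(geno, null_model, design, seed = 11))
})

test_that("planted QTLs raise the trait in carriers of the coded-2 allele", {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 50, markers_per_chrom = 25)
  geno <- simulate_ril_genotypes(map, 400, seed = 12)
  model <- qtl_model(qtl_markers = "Gm01_m0013", effects = 0.8)
  ph <- simulate_phenotypes(geno, model, seed = 13)
  tot <- tapply(ph$count, ph$line, sum)[rownames(geno)]
  g <- geno[, "Gm01_m0013"]
  expect_gt(mean(tot[g == 2L]), mean(tot[g == 0L]))
})

test_that("select_bulks returns disjoint extreme sets with deterministic ties", {
  set.seed(14)
  ph <- data.frame(line = sprintf("L%03d", 1:407), rep = "Rep1",
                   count = rbinom(407, 10, 0.3), n = 10L)
  b <- select_bulks(ph, 30)
  expect_length(b$mul, 30L)
  expect_length(b$tri, 30L)
  expect_length(intersect(b$mul, b$tri), 0L)
  expect_gte(min(b$freq[b$mul]), max(b$freq[b$tri]))

  tied <- data.frame(line = sprintf("L%03d", 1:10), rep = "Rep1",
                     count = 5L, n = 10L)
  bt <- select_bulks(tied, 3)
  expect_equal(bt$mul, sprintf("L%03d", 1:3))   # first k by id among ties
  expect_equal(bt$tri, sprintf("L%03d", 8:10))  # last k by id among ties
  half <- select_bulks(ph, floor(407 / 2))
  expect_length(union(half$mul, half$tri), 2 * floor(407 / 2))
  expect_error(select_bulks(ph, 0), ">= 1")
  expect_error(select_bulks(ph, 300), "n_lines")
})

test_that("simulated bulk depths track the bulk allele frequency", {
  map <- simulate_map(n_chrom = 1, chrom_length_cM = 50, markers_per_chrom = 200)
  # two-line bulks engineered to fixed frequencies
  geno <- matrix(0L, 4, nrow(map),
                 dimnames = list(c("A", "B", "C", "D"), map$marker))
  geno[c("A", "B"), ] <- 2L  # MUL bulk fixed for the alt allele
  geno["C", ] <- 2L          # TRI bulk at f = 0.5
  bulks <- list(mul = c("A", "B"), tri = c("C", "D"))
  counts <- simulate_bulk_reads(geno, bulks, map, mean_depth = 50,
                                error_rate = 0, seed = 15)
  expect_equal(counts$ref_mul, rep(0, nrow(map)))  # f = 1: all reads alt
  f_hat <- sum(counts$alt_tri) / sum(counts$alt_tri + counts$ref_tri)
  tot <- sum(counts$alt_tri + counts$ref_tri)
  expect_lt(abs(f_hat - 0.5), 3 * sqrt(0.25 / tot))
  expect_identical(counts,
                   simulate_bulk_reads(geno, bulks, map, mean_depth = 50,
                                       error_rate = 0, seed = 15))
  expect_error(simulate_bulk_reads(geno, list(mul = character(0), tri = "C"),
                                   map, 30), "empty bulk")
})

test_that("bulk allele-frequency contrast concentrates at the planted QTL", {
  map <- simulate_map(n_chrom = 2, chrom_length_cM = 50, markers_per_chrom = 50)
  qtl <- "Gm01_m0025"
  contrast_qtl <- contrast_null <- numeric(20)
  for (s in 1:20) {
    geno <- simulate_ril_genotypes(map, 200, seed = 500 + s)
    ph <- simulate_phenotypes(geno, qtl_model(qtl_markers = qtl, effects = 1),
                              seed = 600 + s)
    b <- select_bulks(ph, 30)
    f_mul <- colMeans(geno[b$mul, ]) / 2
    f_tri <- colMeans(geno[b$tri, ]) / 2
    d <- abs(f_mul - f_tri)
    contrast_qtl[s] <- d[qtl]
    contrast_null[s] <- mean(d[map$chrom == "Gm02"])
  }
  expect_gt(mean(contrast_qtl), mean(contrast_null))
})
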