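#' Simulate a genetic/physical marker map
#'
#' Builds an ordered bin-marker map over `n_chrom` chromosomes. Genetic
#' positions are either an even grid or uniformly random over
#' `[0, chrom_length_cM]`; physical positions follow a constant
#' `bp_per_cM` scaling, so genetic and physical order agree.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length_cM genetic length of each chromosome in cM.
#' @param markers_per_chrom markers per chromosome (>= 2).
#' @param bp_per_cM physical bp per genetic cM (default 4e5, roughly the
#'   genome-wide average for soybean: ~40 Mb per ~100 cM chromosome).
#' @param spacing `"even"` (default) or `"uniform"` random spacing.
#' @param seed optional integer seed (used only for `"uniform"` spacing).
#' @return data.frame with columns `marker`, `chrom`, `cM`, `bp`.
#' @export
simulate_map <- function(n_chrom = 20, chrom_length_cM = 100,
                         markers_per_chrom = 320, bp_per_cM = 4e5,
                         spacing = c("even", "uniform"), seed = NULL) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1 || markers_per_chrom < 2 || chrom_length_cM <= 0 || bp_per_cM <= 0)
    stop("map sizes must be positive (and >= 2 markers per chromosome)")
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- function(i) {
    cm <- if (spacing == "even") {
      seq(0, chrom_length_cM, length.out = markers_per_chrom)
    } else {
      sort(stats::runif(markers_per_chrom, 0, chrom_length_cM))
    }
    chrom <- sprintf("Gm%02d", i)
    data.frame(marker = sprintf("%s_m%04d", chrom, seq_len(markers_per_chrom)),
               chrom = chrom, cM = cm, bp = round(cm * bp_per_cM) + 1,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_chrom), per_chrom))
  rownames(out) <- NULL
  out
}

# Haldane map function: cM gap -> single-meiosis recombination fraction
haldane_r <- function(d_cM) (1 - exp(-d_cM / 50)) / 2

# effective recombination between adjacent markers in a selfing-derived RIL
# (F-infinity): R* = 2r / (1 + 2r)
ril_R <- function(r) 2 * r / (1 + 2 * r)

#' Simulate RIL genotypes along a map
#'
#' Each line is simulated as a Markov chain of homozygous parental blocks
#' along each chromosome. Adjacent-marker switch probabilities use the
#' selfing-RIL effective recombination `R* = 2r/(1+2r)`, with `r` from
#' Haldane's map function on the cM gap; this is the standard closed form
#' for fully inbred selfed RILs and stands in for simulating the
#' individual generations. Residual heterozygosity (expected to be ~1% at
#' F7) is injected afterwards as independent per-call replacements.
#'
#' Genotypes are coded `0` (parent-A homozygote, e.g. the cultivated
#' parent C08), `2` (parent-B homozygote, the wild parent W05) and `1`
#' (residual heterozygote). Coding the trait-raising wild parent as 2
#' makes its additive effects positive on the liability scale while the
#' conventional (A minus B)/2 substitution effect is negative.
#'
#' @param map marker map from [simulate_map()].
#' @param n_lines number of RILs.
#' @param residual_het residual heterozygosity rate in `[0, 0.05]`.
#' @param seed optional integer seed.
#' @return Integer matrix, lines x markers, with line ids as rownames and
#'   marker names as colnames.
#' @export
simulate_ril_genotypes <- function(map, n_lines, residual_het = 0.01, seed = NULL) {
  if (residual_het < 0 || residual_het > 0.05)
    stop("residual_het must be in [0, 0.05]")
  if (!is.null(seed)) set.seed(seed)
  geno <- matrix(0L, nrow = n_lines, ncol = nrow(map),
                 dimnames = list(sprintf("RIL%04d", seq_len(n_lines)), map$marker))
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    state <- stats::rbinom(n_lines, 1L, 0.5)
    geno[, idx[1L]] <- 2L * state
    if (length(idx) > 1L) {
      Rstar <- ril_R(haldane_r(diff(map$cM[idx])))
      for (j in seq_along(Rstar)) {
        state <- (state + stats::rbinom(n_lines, 1L, Rstar[j])) %% 2L
        geno[, idx[j + 1L]] <- 2L * state
      }
    }
  }
  if (residual_het > 0) {
    het <- stats::runif(length(geno)) < residual_het
    geno[het] <- 1L
  }
  geno
}

#' Define a liability-scale QTL model for a sporadic trait
#'
#' The phenotype model treats per-seedling trait expression as a Bernoulli
#' event whose probability is a logistic function of a line-by-replicate
#' liability: baseline `mu`, additive marker effects `a_k (x_ik - 1)`
#' (so homozygote classes sit at `mu - a` and `mu + a`), a fixed replicate
#' (environment) effect, a line-by-replicate interaction deviate
#' (genotype-by-environment, SD `sigma_ge`) and a residual deviate
#' (SD `sigma_eps`). The defaults plant five QTLs of unequal effect and
#' give a sporadic, incompletely penetrant trait with mean incidence
#' around 20%, matching a low-frequency developmental phenotype.
#'
#' @param qtl_markers character vector of marker names (or integer column
#'   indices) carrying QTLs.
#' @param effects additive liability effects `a_k`, one per QTL; positive
#'   values mean the parent coded 2 raises the trait.
#' @param mu baseline liability (logit of the per-seedling probability for
#'   a line with genotype code 1 everywhere, in an average replicate).
#' @param rep_effects named or unnamed numeric vector of fixed replicate
#'   effects (recycled/zero-padded against the replicate design).
#' @param sigma_ge SD of the line-by-replicate interaction deviate.
#' @param sigma_eps SD of the residual liability deviate.
#' @return A list of class `qtl_model`.
#' @export
qtl_model <- function(qtl_markers = character(0), effects = numeric(0),
                      mu = -1.4, rep_effects = c(0, 0.2, -0.2),
                      sigma_ge = 0.7, sigma_eps = 0.5) {
  if (length(qtl_markers) != length(effects))
    stop("qtl_markers and effects must have equal length")
  if (!all(is.finite(effects)) || !is.finite(mu))
    stop("effects and mu must be finite")
  structure(list(qtl_markers = qtl_markers, effects = effects, mu = mu,
                 rep_effects = rep_effects, sigma_ge = sigma_ge,
                 sigma_eps = sigma_eps), class = "qtl_model")
}

#' Simulate sporadic seedling-count phenotypes
#'
#' For line `i` in replicate `j`, the liability is
#' `eta_ij = mu + sum_k a_k (x_ik - 1) + rep_j + gamma_ij + eps_ij` with
#' `gamma ~ N(0, sigma_ge^2)` and `eps ~ N(0, sigma_eps^2)`; the affected
#' count is `Binomial(n_seedlings_j, logistic(eta_ij))`. The default
#' replicate design mirrors a three-season trial scoring 5, 10 and 20
#' seedlings per line.
#'
#' @param genotypes matrix from [simulate_ril_genotypes()].
#' @param model a [qtl_model()].
#' @param replicate_design data.frame with columns `rep` and `n`
#'   (seedlings scored per line in that replicate).
#' @param seed optional integer seed.
#' @return Long-format phenotype data.frame (`line`, `rep`, `count`, `n`).
#' @export
simulate_phenotypes <- function(genotypes, model = qtl_model(),
                                replicate_design = data.frame(
                                  rep = c("Rep1", "Rep2", "Rep3"),
                                  n = c(5L, 10L, 20L)),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_lines <- nrow(genotypes)
  g <- rep(0, n_lines)
  if (length(model$qtl_markers) > 0L) {
    x <- genotypes[, model$qtl_markers, drop = FALSE]
    g <- as.vector((x - 1) %*% model$effects)
  }
  rep_eff <- rep_len(c(model$rep_effects, 0), nrow(replicate_design))
  out <- vector("list", nrow(replicate_design))
  for (j in seq_len(nrow(replicate_design))) {
    eta <- model$mu + g + rep_eff[j] +
      stats::rnorm(n_lines, 0, model$sigma_ge) +
      stats::rnorm(n_lines, 0, model$sigma_eps)
    p <- stats::plogis(eta)
    n_seed <- replicate_design$n[j]
    out[[j]] <- data.frame(line = rownames(genotypes),
                           rep = replicate_design$rep[j],
                           count = stats::rbinom(n_lines, n_seed, p),
                           n = n_seed, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select extreme phenotypic bulks
#'
#' Ranks lines by their overall trait frequency (total affected count over
#' total seedlings scored across replicates) and returns the `k` highest
#' (the high-trait `MUL` bulk) and the `k` lowest (the low-trait `TRI`
#' bulk). A single global ranking with ties broken by line identifier is
#' used, so the two bulks are always disjoint and runs are reproducible.
#'
#' @param phenotypes long-format phenotype table.
#' @param k bulk size (default 30).
#' @return List with character vectors `mul` and `tri` of line ids, and
#'   the per-line ranking frequencies in `freq`.
#' @export
select_bulks <- function(phenotypes, k = 30) {
  if (k < 1) stop("bulk size k must be >= 1")
  tot_count <- tapply(phenotypes$count, phenotypes$line, sum)
  tot_n <- tapply(phenotypes$n, phenotypes$line, sum)
  freq <- as.vector(tot_count / tot_n)
  ids <- names(tot_count)
  if (2 * k > length(ids)) stop("k must be <= n_lines / 2")
  ord_id <- order(ids)
  freq <- freq[ord_id]; ids <- ids[ord_id]
  # one global ranking (ties by line id) so the two bulks never overlap
  ranked <- ids[order(-freq, ids)]
  mul <- ranked[seq_len(k)]
  tri <- rev(ranked)[seq_len(k)]
  list(mul = sort(mul), tri = sort(tri), freq = stats::setNames(freq, ids))
}

#' Simulate pooled allele depths for two bulks
#'
#' Treats every marker of the map as an assayable SNP between the parents.
#' For each SNP and bulk, the true alternative-allele frequency is the
#' mean genotype code over the bulk's lines divided by 2; sequencing is
#' modelled as `depth ~ Poisson(mean_depth)` reads of which
#' `alt ~ Binomial(depth, f(1-e) + (1-f)e)` carry the alternative allele
#' (`e` = per-read error/misassignment rate).
#'
#' @param genotypes RIL genotype matrix.
#' @param bulks list with `mul` and `tri` line-id vectors
#'   (from [select_bulks()]).
#' @param map marker map giving SNP coordinates.
#' @param mean_depth mean per-bulk read depth per SNP (default 30).
#' @param error_rate per-read error rate in `[0, 0.05)`.
#' @param seed optional integer seed.
#' @return data.frame with columns `chrom`, `pos`, `ref_mul`, `alt_mul`,
#'   `ref_tri`, `alt_tri` (the [read_bulk_vcf()] layout).
#' @export
simulate_bulk_reads <- function(genotypes, bulks, map, mean_depth = 30,
                                error_rate = 0.001, seed = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.05) stop("error_rate must be in [0, 0.05)")
  if (length(bulks$mul) == 0L || length(bulks$tri) == 0L) stop("empty bulk")
  if (!is.null(seed)) set.seed(seed)
  one_bulk <- function(lines) {
    f <- colMeans(genotypes[lines, , drop = FALSE]) / 2
    p_alt <- f * (1 - error_rate) + (1 - f) * error_rate
    depth <- stats::rpois(nrow(map), mean_depth)
    alt <- stats::rbinom(nrow(map), depth, p_alt)
    cbind(ref = depth - alt, alt = alt)
  }
  dm <- one_bulk(bulks$mul)
  dt <- one_bulk(bulks$tri)
  data.frame(chrom = map$chrom, pos = map$bp,
             ref_mul = dm[, "ref"], alt_mul = dm[, "alt"],
             ref_tri = dt[, "ref"], alt_tri = dt[, "alt"],
             stringsAsFactors = FALSE)
}

#' Simulate a balanced Gaussian multi-environment trial
#'
#' Generates a line x environment (x replicate) table from the additive
#' random-effects model `y = mu + g_i + env_j + (ge)_ij + eps_ijk` with
#' known variance components, for validating the variance-component and
#' heritability estimators against ground truth.
#'
#' @param n_lines,n_env,n_rep layout sizes (lines, environments,
#'   replicates per line within an environment).
#' @param V_g,V_ge,V_e genotypic, genotype-by-environment and residual
#'   variances.
#' @param mu grand mean; environment fixed effects are drawn once as
#'   `N(0, 1)` per environment.
#' @param seed optional integer seed.
#' @return Long-format data.frame (`line`, `rep`, `count`, `n`) with
#'   `n = 1`, so `count` is the (continuous) response and the
#'   frequency-scale response equals it.
#' @export
sim_balanced_trial <- function(n_lines = 500, n_env = 3, n_rep = 1,
                               V_g = 2, V_ge = 1, V_e = 3, mu = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lines <- sprintf("L%04d", seq_len(n_lines))
  envs <- sprintf("Rep%d", seq_len(n_env))
  g <- stats::rnorm(n_lines, 0, sqrt(V_g))
  env_eff <- stats::rnorm(n_env, 0, 1)
  ge <- matrix(stats::rnorm(n_lines * n_env, 0, sqrt(V_ge)), n_lines, n_env)
  out <- vector("list", n_env * n_rep)
  k <- 1L
  for (j in seq_len(n_env)) {
    for (r in seq_len(n_rep)) {
      y <- mu + g + env_eff[j] + ge[, j] + stats::rnorm(n_lines, 0, sqrt(V_e))
      out[[k]] <- data.frame(line = lines, rep = envs[j], count = y, n = 1,
                             stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
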