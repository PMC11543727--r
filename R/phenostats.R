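# cast the long phenotype table to a line x replicate response matrix;
# cells with several observations keep them all (list of matrices by rep index)
response_value <- function(phenotypes, response = c("freq", "count")) {
  response <- match.arg(response)
  if (response == "freq") phenotypes$count / phenotypes$n else phenotypes$count
}

response_matrix <- function(phenotypes, response = c("freq", "count")) {
  y <- response_value(phenotypes, response)
  lines <- sort(unique(phenotypes$line))
  reps <- unique(phenotypes$rep)
  m <- matrix(NA_real_, length(lines), length(reps),
              dimnames = list(lines, reps))
  cell_n <- table(factor(phenotypes$line, lines), factor(phenotypes$rep, reps))
  if (any(cell_n > 1L))
    stop("more than one observation per line x replicate cell; aggregate first")
  m[cbind(match(phenotypes$line, lines), match(phenotypes$rep, reps))] <- y
  m
}

#' Pairwise Pearson correlations between biological replicates
#'
#' Correlates the per-line response (trait frequency by default) between
#' every pair of replicates, over the lines scored in both. A replicate
#' pair where either side has zero variance gets an `NA` entry and is
#' listed in the `"undefined"` attribute rather than propagating `NaN`.
#'
#' @param phenotypes long-format phenotype table (`line`, `rep`, `count`, `n`).
#' @param response `"freq"` (affected/scored, default) or `"count"`.
#' @return Symmetric correlation matrix, one row/column per replicate.
#' @export
replicate_correlations <- function(phenotypes, response = c("freq", "count")) {
  m <- response_matrix(phenotypes, response)
  if (ncol(m) < 2L) stop("need at least two replicates")
  reps <- colnames(m)
  r <- diag(1, ncol(m))
  dimnames(r) <- list(reps, reps)
  undef <- character(0)
  for (i in seq_len(ncol(m) - 1L)) for (j in seq(i + 1L, ncol(m))) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < 3L) stop("fewer than 3 shared lines between replicates")
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      undef <- c(undef, paste(reps[i], reps[j], sep = ":"))
    } else {
      r[i, j] <- r[j, i] <- stats::cor(m[ok, i], m[ok, j])
    }
  }
  attr(r, "undefined") <- undef
  r
}

#' Population-level phenotype summary
#'
#' Per-line mean response across replicates, the population coefficient of
#' variation (CV, percent: 100 * sd / mean of line means) and the
#' replicate correlation matrix.
#'
#' @inheritParams replicate_correlations
#' @return List with `line_means`, `cv_percent`, `correlations`.
#' @export
phenotype_summary <- function(phenotypes, response = c("freq", "count")) {
  m <- response_matrix(phenotypes, response)
  lm_ <- rowMeans(m, na.rm = TRUE)
  list(line_means = lm_,
       cv_percent = 100 * stats::sd(lm_) / mean(lm_),
       correlations = replicate_correlations(phenotypes, response))
}

#' Estimate variance components of the line x environment model
#'
#' Fits `y_ijk = mu + env_j + g_i + (ge)_ij + eps_ijk` with environments
#' (biological replicates) fixed and line and line-by-environment effects
#' random. Balanced layouts are solved by the closed-form
#' expected-mean-squares equations of the two-way ANOVA; negative
#' solutions are truncated at zero. With a single observation per
#' line-by-environment cell the interaction is confounded with the
#' residual and `V_ge` is reported as 0 with a warning (its variance is
#' absorbed into `V_e`). Unbalanced layouts fall back to a REML fit via
#' \pkg{lme4}.
#'
#' @inheritParams replicate_correlations
#' @return Object of class `mf_varcomp`: list with `V_g`, `V_ge`, `V_e`,
#'   `R` (replications per environment), `L` (environments), `mu`,
#'   `method`.
#' @export
variance_components <- function(phenotypes, response = c("freq", "count")) {
  y <- response_value(phenotypes, response)
  line <- factor(phenotypes$line)
  env <- factor(phenotypes$rep)
  L <- nlevels(env)
  if (nlevels(line) < 2L) stop("need at least two lines")
  cell_n <- table(line, env)
  balanced <- length(unique(as.vector(cell_n))) == 1L && all(cell_n > 0L)
  if (balanced) {
    R <- as.vector(cell_n[1L, 1L])
    G <- nlevels(line)
    grand <- mean(y)
    mean_i <- tapply(y, line, mean)             # line means
    mean_j <- tapply(y, env, mean)              # environment means
    mean_ij <- tapply(y, list(line, env), mean) # cell means
    ss_g <- L * R * sum((mean_i - grand)^2)
    ss_ge <- R * sum((sweep(sweep(mean_ij, 1, mean_i), 2, mean_j) + grand)^2)
    ss_res <- sum((y - mean_ij[cbind(line, env)])^2)
    if (stats::var(y) == 0) {
      vc <- list(V_g = 0, V_ge = 0, V_e = 0)
      if (L == 1L || R == 1L) warning("V_ge inestimable for this layout; reported as 0")
    } else if (L == 1L) {
      warning("single environment: V_ge inestimable, reported as 0")
      ms_g <- ss_g / (G - 1)
      ms_e <- if (R > 1L) ss_res / (G * (R - 1)) else 0
      vc <- list(V_g = max(0, (ms_g - ms_e) / R), V_ge = 0, V_e = ms_e)
    } else if (R == 1L) {
      warning("one observation per line x environment cell: ",
              "V_ge inestimable, reported as 0 (absorbed into V_e)")
      ms_g <- ss_g / (G - 1)
      ms_e <- ss_ge / ((G - 1) * (L - 1))  # interaction + residual pooled
      vc <- list(V_g = max(0, (ms_g - ms_e) / L), V_ge = 0, V_e = ms_e)
    } else {
      ms_g <- ss_g / (G - 1)
      ms_ge <- ss_ge / ((G - 1) * (L - 1))
      ms_e <- ss_res / (G * L * (R - 1))
      vc <- list(V_g = max(0, (ms_g - ms_ge) / (R * L)),
                 V_ge = max(0, (ms_ge - ms_e) / R),
                 V_e = ms_e)
    }
    method <- "expected mean squares (balanced)"
  } else {
    R <- max(cell_n)
    has_dup <- any(cell_n > 1L)
    form <- if (has_dup && L > 1L) y ~ env + (1 | line) + (1 | line:env)
            else y ~ env + (1 | line)
    fit <- lme4::lmer(form, data = data.frame(y = y, line = line, env = env),
                      REML = TRUE)
    vcs <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) { v <- vcs$vcov[vcs$grp == g]; if (length(v)) v else 0 }
    vc <- list(V_g = get("line"), V_ge = get("line:env"),
               V_e = get("Residual"))
    if (!has_dup || L == 1L)
      warning("V_ge inestimable for this layout; reported as 0")
    method <- "REML (lme4, unbalanced)"
  }
  structure(c(vc, list(R = R, L = L, mu = mean(y), method = method,
                       response = match.arg(response))),
            class = "mf_varcomp")
}

#' @export
print.mf_varcomp <- function(x, ...) {
  cat("Variance components (", x$method, ")\n", sep = "")
  cat(sprintf("  V_g  = %.6g\n  V_ge = %.6g\n  V_e  = %.6g\n", x$V_g, x$V_ge, x$V_e))
  cat(sprintf("  layout: L = %d environment(s), R = %d replication(s)\n", x$L, x$R))
  h2 <- tryCatch(heritability(x), error = function(e) NA_real_)
  if (!is.na(h2)) cat(sprintf("  broad-sense H2 = %.4f\n", h2))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Evaluates `H2 = V_g / (V_g + V_ge / L + V_e / (R L))`, where `V_g`,
#' `V_ge` and `V_e` are the genotypic, genotype-by-environment and
#' residual variances, `L` the number of environments and `R` the number
#' of replications per environment.
#'
#' @param vc an `mf_varcomp` object, or `NULL` when the components are
#'   given directly.
#' @param V_g,V_ge,V_e,R,L components and layout (override `vc` when given).
#' @return `H2` in `[0, 1]`.
#' @export
heritability <- function(vc = NULL, V_g = vc$V_g, V_ge = vc$V_ge,
                         V_e = vc$V_e, R = vc$R, L = vc$L) {
  if (any(c(V_g, V_ge, V_e) < 0)) stop("variance components must be >= 0")
  if (R < 1 || L < 1) stop("R and L must be >= 1")
  denom <- V_g + V_ge / L + V_e / (R * L)
  if (denom <= 0) stop("all variance components are zero: H2 undefined")
  V_g / denom
}

#' Per-line BLUPs of the genetic value
#'
#' In the balanced setting the best linear unbiased prediction of a
#' line's genetic effect is a uniform shrinkage of its deviation from the
#' grand mean, `g_i = s (ybar_i - ybar)` with
#' `s = V_g / (V_g + V_ge/L + V_e/(RL))` (i.e. `s = H2` on an entry-mean
#' basis); the reported value is `mu + g_i`, directly usable as a mapping
#' phenotype.
#'
#' @param phenotypes long-format phenotype table.
#' @param vc variance components (an `mf_varcomp` object); computed from
#'   `phenotypes` when missing.
#' @inheritParams replicate_correlations
#' @return Named numeric vector of per-line BLUP values (`mu + g_i`).
#' @export
blup <- function(phenotypes, vc = NULL, response = c("freq", "count")) {
  response <- match.arg(response)
  if (is.null(vc)) vc <- variance_components(phenotypes, response)
  m <- response_matrix(phenotypes, response)
  line_means <- rowMeans(m, na.rm = TRUE)
  grand <- mean(line_means)
  shrink <- if (is.infinite(vc$V_g)) 1 else
    tryCatch(heritability(vc), error = function(e) 0)
  grand + shrink * (line_means - grand)
}
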