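---
title: "Models and methods behind bsrqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bsrqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the numerical choices and
the known limitations of the package, in the order a typical analysis
runs: phenotype model → phenotype statistics → LOD scan → ΔSNP-index scan
→ integration. It also explains what the synthetic-data generator does
and does not emulate, which bounds what the test suite can demonstrate
about real data.

## The sporadic-trait phenotype model

The package targets traits scored as *counts of affected seedlings*: line
`i` in biological replicate (environment) `j` contributes `count_ij` out
of `n_j` seedlings. Nothing in the package requires the trait to be
developmental or even plant-based; what matters is the binomial scoring
and the incomplete penetrance.

The simulator formalises this with a liability-scale logistic model:

```
eta_ij = mu + sum_k a_k (x_ik - 1) + rep_j + gamma_ij + eps_ij
p_ij   = logistic(eta_ij)
count_ij ~ Binomial(n_j, p_ij)
```

with `x_ik` the genotype code (0 = parent-A homozygote, 2 = parent-B
homozygote, 1 = residual heterozygote), `gamma ~ N(0, sigma_ge^2)` a
line-by-environment interaction and `eps ~ N(0, sigma_eps^2)` residual
noise. This is a *stand-in*: sporadic expression data rarely identify the
within-line variance structure, and nothing in the field fixes a
penetrance model for such traits. The binomial-logistic choice was made
because (i) it guarantees valid per-seedling probabilities for arbitrary
effect sizes, (ii) it separates genotype, genotype-by-environment and
residual variation in direct correspondence with the `V_g`, `V_ge`, `V_e`
decomposition used for heritability, and (iii) it produces the defining
phenomenology — lines with identical genotypes and very different
per-season expression.

Defaults: `mu = -1.4` (mean incidence around 20%, a visibly sporadic but
scoreable trait), `sigma_ge = 0.7`, `sigma_eps = 0.5` (replicate
correlations in the 0.4–0.6 range and entry-mean heritability around
0.65–0.75 for a moderate QTL set — the regime of interest, where the trait
is clearly genetic but noisily expressed), replicate effects
`(0, +0.2, -0.2)`, and a replicate design of 5/10/20 seedlings over three
seasons, mirroring a realistic multi-season greenhouse trial. The wild
parent is coded 2 and positive `a_k` raises the trait, so the
conventional additive effect reported by the QTL caller,
`(mean of code-0 - mean of code-2)/2`, is negative for wild-parent
trait-raising alleles.

## RIL genotypes

Lines are fully inbred (F∞ approximation of F7:8): each chromosome is a
Markov chain over homozygous parental blocks with switch probability
`R* = 2r/(1+2r)` between adjacent markers, the classical effective
recombination fraction for selfing-derived RILs, with `r` from Haldane's
map function on the cM gap. Residual heterozygosity is injected as
independent per-call replacements at rate 0.01 (the expectation around
F7) rather than by simulating seven explicit generations; this loses the
block structure of real residual heterozygosity, which is irrelevant at
the 1%, single-marker level the pipeline uses.

## Variance components, heritability, BLUP

`variance_components()` fits `y_ijk = mu + env_j + g_i + (ge)_ij +
eps_ijk` (environments fixed; line and interaction effects random). On
balanced layouts the components come from the closed-form expected mean
squares of the two-way ANOVA, with negative solutions truncated at zero.
With one observation per line-by-environment cell — the usual situation
when the response is one count per line per season — the interaction is
confounded with the residual; `V_ge` is then reported as 0 with a
warning, and its variance is absorbed into `V_e`. Since the heritability
denominator adds `V_ge/L + V_e/(R L)`, this absorption *underestimates*
H² slightly when a true interaction exists (the absorbed part is divided
by `R L` instead of `L`); this is the price of the design, not of the
estimator. Unbalanced layouts (missing lines, unequal cell counts) are
fitted by REML via `lme4::lmer` with the same model.

The default response is the affected-seedling *frequency* `count/n`, so
replicates scoring different numbers of seedlings are comparable; raw
counts are available via `response = "count"`.

Heritability is the entry-mean formula `H2 = V_g/(V_g + V_ge/L +
V_e/(RL))`, and `blup()` applies the matching balanced-case shrinkage
`mu + H2 * (line mean - grand mean)` — a rank-preserving contraction of
the line means, suitable directly as a mapping phenotype. For unbalanced
data the same uniform shrinkage is applied to the available line means;
this is an approximation (true BLUPs shrink lines with fewer
observations harder), acceptable at the 1-cell-in-1200 levels of
imbalance typical here.

## LOD scan and permutation threshold

The scan is single-marker regression of the phenotype on the genotype
code, `LOD = (n/2) log10(RSS0/RSS1)`; heterozygotes enter as code 1,
i.e. additively. With thousands of bin markers the dense-map limit of
interval mapping is reached and between-marker imputation adds
essentially nothing, so marker regression is used as the engine
throughout. Numerical choices:

* Monomorphic markers get `LOD = 0` and a flag (rather than `NaN`).
* Numerically perfect fits (`RSS1` at rounding level, `1 - r^2 < 1e-12`)
  are capped at `lod_cap = 50`. The cap is *not* applied as a blanket
  ceiling: truncating genuinely large LODs flattens the peak into a
  plateau and biases the reported peak position toward the plateau's
  left edge.
* The genome-wide threshold is the `1 - alpha` quantile of the maximum
  LOD over phenotype permutations (genotypes fixed, phenotype shuffled
  across lines), 1000 permutations and `alpha = 0.05` by default.
* Peak calling: local maxima above the threshold, leftmost marker of any
  plateau. Two maxima on one chromosome are distinct QTLs only when the
  LOD between them *both* drops by more than 1.5 below the lower peak
  *and* returns below the significance threshold. The second condition
  is deliberate: on dense maps the LOD profile around a single strong
  QTL is locally jagged, and a bare 1.5-drop rule fragments one locus
  into several. The cost is that two genuinely distinct QTLs close
  enough that the profile never becomes non-significant between them are
  reported as one; a single-marker scan has no information to split that
  case reliably anyway.
* The 1.5-LOD support interval runs outward from the peak while the LOD
  stays at or above `peak - 1.5`; its bp bounds step one bin marker
  beyond the cM bounds on each side (rounded outward), so the physical
  interval never understates the genetic one.
* Replicate-consistent confidence regions are reduced with
  `common_region()` (max of starts, min of ends); disjoint replicate
  intervals raise an error, leaving the consistency decision to the
  caller.

## ΔSNP-index scan

Per SNP and bulk, the index is `alt/(alt+ref)`; ΔSNP = index(TRI) −
index(MUL). Filters follow standard QTL-seq practice: a site is dropped
when either bulk's total depth is below 3, or when the index is below
0.3 in *both* bulks (such sites are dominated by reference bias and
sequencing error and carry no contrast). The depth rule reads "depth of
each bulk", i.e. per-bulk total depth. The filter is idempotent and logs
removal counts per rule.

Window smoothing uses 1-Mbp windows advanced by 10 kbp. The window grid
is anchored at position 1 of each chromosome (step-aligned) rather than
at the first SNP: the output is reproducible across SNP subsets and
differs from first-SNP anchoring by at most one step. Windows with fewer
than 10 SNPs are skipped. Window means are computed by direct summation
over each window's members, so they agree exactly (not just to
tolerance) with a naive double loop.

### The null model behind the 99% cutoff

The cutoff must answer: *how large can a window-mean ΔSNP index get when
the locus has nothing to do with the trait?* Two noise sources
contribute: **read sampling** (binomial at each SNP's depth) and **bulk
composition** (each bulk contains a finite number of lines, 30 here, so
its local allele frequency wanders around 0.5 even without selection).
Within a 1-Mbp window of an inbred RIL population the SNPs are
effectively completely linked, so the bulk-composition deviation is
*shared* by all SNPs of a window — averaging over the window removes read
noise but not composition noise.

The default null (`null = "block"`) therefore draws, per window and
iteration, each bulk's allele count as `Binomial(bulk_size, 1/2)` — the
segregation expectation for an unselected RIL bulk, as in the QTL-seq
simulation framework — shared across the window's SNPs, and adds
window-level read noise (the exact binomial read-sampling variance
`f(1-f)/depth` averaged over the window's observed depths enters through
a normal approximation, justified by the ≥ 10-SNP window rule). The
cutoff is the 99% quantile of the absolute null window mean, pooled over
windows and iterations, applied genome-wide and two-sided — regions can
be skewed toward either bulk.

A read-only null (`null = "snp"`: per-SNP `Binomial(depth, 1/2)`
independently across SNPs) is provided for comparison but is strongly
anti-conservative for window means, precisely because it lets the
windows average away the only noise it models. A label-swap null
(`null = "label"`) is also available. The hypergeometric correction for
drawing 30 lines from ~400 without replacement (factor ≈ 0.93 on the
composition variance) is deliberately ignored; it is almost exactly
offset by the variance of the population allele frequency itself, and
the residual error is conservative.

The study-scale profile is 100,000 iterations; a reduced profile of
2,000 iterations (the package default) estimates the same 99% pooled
quantile with ample precision, since every iteration contributes one
value per window.

Significant-region calling merges retained windows beyond the cutoff
when they overlap or abut on the step grid and agree in direction; the
region interval is the union of member windows. Merging across gaps
(e.g. a sub-threshold window between two significant ones) is *not*
performed; such loci appear as separate regions.

## Integration

Linkage and BSA regions are intersected pairwise (`[max starts, min
ends]`, non-empty pairs only). Gene membership uses any-overlap (≥ 1 bp,
1-based inclusive, so a gene ending exactly at a region start counts);
full containment is available behind `rule = "within"`. Variant
classification relative to a gene model is strand-aware: genic within
the gene interval, upstream/downstream in the 1000 bp beyond the
TSS/TTS. A variant inside several genes' windows receives one class per
gene; no priority collapsing is attempted. The expression filter is a
strict `FPKM > 1` in *every* bulk sample of the stage, with genes absent
from the matrix flagged unexpressed (with a warning) rather than
dropped silently.

## What the simulator does and does not emulate

Emulated: the RIL design (~400 lines, three replicates of 5/10/20
seedlings), sporadic per-seedling expression, several QTLs of unequal
effect, 30-line extreme bulks, pooled allele depths at thousands of SNPs
with Poisson depth variation and a small read-error rate, residual
heterozygosity.

Not emulated: linkage disequilibrium structure beyond the Markov chain
(no segregation distortion, no genotyping error), expression variation
(allele depths are simulated directly, not via RNA abundance — in real
BSR-seq, depth tracks expression level and genes silent in a tissue
contribute no SNPs), multiallelic sites and indels (the index is defined
for two alleles; the VCF reader drops the rest), and epistasis. Passing
tests therefore demonstrate correctness of the computations and
calibration under the stated model, not robustness to, e.g.,
expression-driven depth heterogeneity.

## Test and validation profiles

The package's simulation studies (exported as `calibrate_bsa_null()`,
`recover_planted_qtl()`, `calibrate_lod_threshold()`,
`recover_heritability()`) run at reduced profiles chosen to finish in a
few minutes on one CPU while keeping the Monte Carlo error well inside
the margins they are checked against: 2-chromosome genomes of 1000
markers each, 400 lines, 2000 cutoff iterations, 10–20 seeds for
averaged rates, 200 fresh scans for the LOD false-positive rate, and
500-line × 3-environment × 2-replicate balanced trials for heritability
recovery. The corresponding study-scale parameters (20 chromosomes, 6384
bin markers, 100,000 cutoff iterations, 1000 permutations) are the
defaults or documented options of the user-facing functions.

## Known limitations

* The heritability of a binomial trait depends on the response scale;
  `H2` computed on frequencies is not numerically comparable to one
  computed on counts when seedling numbers differ across replicates.
  Both are offered; frequency is the default.
* With one observation per line-environment cell, `V_ge` is not
  estimable and H² is mildly conservative (see above).
* The BLUP shrinkage is uniform; under imbalance it is an approximation
  to the mixed-model BLUP.
* The block null treats windows as internally fully linked and mutually
  independent; real window means are positively correlated along a
  chromosome, so the *count* of significant windows is over-dispersed
  relative to independence even though the per-window level is right.
* Marker regression does not model QTL between markers, multiple linked
  QTLs, or epistasis; two QTLs whose joint LOD profile never dips below
  the significance threshold between them are reported as one locus.
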