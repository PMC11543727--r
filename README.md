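# bsrqtl

Genetic dissection of **sporadic, incompletely penetrant traits** in
biparental recombinant inbred line (RIL) populations, combining classical
linkage mapping with bulked segregant RNA-seq (BSR-seq). The motivating
use case is a trait such as multifoliolate leaves in soybean: each line
carries a fixed genotype, but only a fraction of its seedlings express the
phenotype in any given season, so the phenotype is a count of affected
seedlings out of the number scored, replicated across growing seasons.

The package provides, as composable functions with classed results:

* **Phenotype statistics** — per-line trait frequencies, population CV,
  pairwise replicate correlations, variance components of the
  line-by-environment model, broad-sense heritability on an entry-mean
  basis,

  H² = V_g / (V_g + V_ge/L + V_ε/(R·L)),

  and per-line BLUPs (shrunken line means) for use as a mapping phenotype.
* **LOD scan** (`lod_scan`, `permutation_threshold`, `call_qtls`) —
  genome-wide single-marker regression, LOD = (n/2)·log₁₀(RSS₀/RSS₁),
  genome-wide significance by phenotype permutation (Churchill–Doerge),
  QTL peaks with 1.5-LOD support intervals, PVE and additive effects.
* **ΔSNP-index bulked segregant scan** (`bsa_scan` and its parts) — per-bulk
  SNP index alt/(alt+ref) from two-sample VCF allele depths, a per-bulk
  depth ≥ 3 filter and an index < 0.3-in-both-bulks exclusion,
  ΔSNP index = index(TRI) − index(MUL), 1-Mbp sliding windows advanced by
  10 kbp (windows with < 10 SNPs skipped), a two-sided 99% Monte Carlo
  cutoff, and merged significant regions.
* **Integration** (`intersect_regions`, `genes_in`, `classify_variant`,
  `expression_filter`, `candidate_report`) — intersect linkage and
  bulked-segregant regions, enumerate genes (GFF3), classify variants as
  genic / 1-kb-upstream / 1-kb-downstream / intergenic relative to gene
  models, and keep candidates expressed (FPKM > 1) in both bulks.
* **A synthetic-data module** — RIL genotypes along a genetic map
  (selfing-RIL effective recombination R\* = 2r/(1+2r), Haldane map
  function), a liability-scale binomial-logistic model for sporadic
  phenotypes with planted QTLs, extreme-bulk selection, and pooled
  Poisson/binomial read depths, so the whole pipeline runs and is tested
  without any external data.

## Worked example

A two-chromosome demo genome with one planted QTL whose wild-parent
allele raises the per-seedling liability by 1.0:

```r
library(bsrqtl)
map  <- simulate_map(n_chrom = 2, chrom_length_cM = 50,
                     markers_per_chrom = 500, bp_per_cM = 4e5)
geno <- simulate_ril_genotypes(map, n_lines = 400, seed = 1)
model <- qtl_model(qtl_markers = "Gm01_m0250", effects = 1.0)
pheno <- simulate_phenotypes(geno, model, seed = 2)

variance_components(pheno)
#> Variance components (expected mean squares (balanced))
#>   V_g  = 0.0270127
#>   V_ge = 0
#>   V_e  = 0.0358841
#>   layout: L = 3 environment(s), R = 1 replication(s)
#>   broad-sense H2 = 0.6931
```

The trait is strongly heritable at the line level (H² ≈ 0.69) even though
replicate correlations are only moderate (0.40–0.50) — the signature of a
sporadic trait. Mapping the per-line BLUP:

```r
b    <- blup(pheno, variance_components(pheno))
scan <- lod_scan(geno, b, map)
thr  <- permutation_threshold(geno, b, map, n_perm = 1000, seed = 3)
call_qtls(scan, thr, geno, b)
#> 1 QTL(s) above LOD threshold 2.352 (1.5-LOD support intervals)
#>  chrom peak_marker peak_cM peak_bp   LOD   PVE additive ...   start      end
#>   Gm01  Gm01_m0250   24.95 9979961 81.17 60.72  -0.1072 ... 9939881 10020041
```

The scan finds the planted marker exactly; the additive effect is
negative because the trait-raising allele comes from the parent coded 2
(the effect is reported as (mean of code-0 − mean of code-2)/2). The
bulked-segregant arm of the analysis:

```r
bulks  <- select_bulks(pheno, k = 30)
counts <- simulate_bulk_reads(geno, bulks, map, mean_depth = 30, seed = 4)
bsa    <- bsa_scan(counts, n_iter = 2000, seed = 5)
bsa
#> delta SNP-index scan: 1000 SNPs after filtering, 3928 retained windows
#> delta SNP-index cutoff (+-0.3376) at the 99% level, block null, 2000 iterations
#> 2 significant region(s)
#>  chrom start      end direction n_windows peak_delta cutoff
#>   Gm01 90001 20630000       MUL      1955    -0.9668 0.3376
#>   Gm02     1  9010000       TRI       682     0.4203 0.3376
```

The QTL chromosome shows a near-saturated ΔSNP index (the 30 high-trait
lines are almost fixed for the wild allele around the locus); the weaker
Gm02 region is allele-frequency drift in the bulks, which the joint
analysis removes — intersecting linkage and BSA evidence keeps only the
region supported by both:

```r
qtl_iv <- data.frame(name = "demoQTL", chrom = "Gm01",
                     start = 9939881, end = 10020041)
intersect_regions(qtl_iv, bsa$regions)
#>      name chrom qtl_start  qtl_end bsa_start  bsa_end   start      end
#> 1 demoQTL  Gm01   9939881 10020041     90001 20630000 9939881 10020041
```

With a GFF3 annotation and an FPKM table, `genes_in()`,
`classify_variant()`, `expression_filter()` and `candidate_report()`
narrow such an intersection down to expressed candidate genes; bundled
interval tables from a published soybean multifoliolate study
(`mf_qtl_regions()`, `mf_joint_regions()`) give a real-coordinate example.

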