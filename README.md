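# gradscan

Selection-signature scans that map loci for a *specific* quantitative
trait by contrasting nested extreme-phenotype subpopulations.

Classical selective-sweep scans (F_ST outliers, EHH-family statistics)
find regions under selection, but in a livestock panel those regions mix
the footprints of every trait that breeders have pushed on. `gradscan`
implements an extreme-phenotype contrast design that ties signatures to
one trait: a panel of phenotyped, genotyped individuals is split into
three nested **phenotypic gradient differential population pairs** —
high vs low halves, then the 75-per-side and 45-per-side extremes (for a
233-sample panel) — and each pair is scanned with two inter-population
statistics. A SNP is called a **trait-specific selection signature**
when it is genome-wide top-1% in *all three* pairs and its statistic
strengthens monotonically as the phenotypic contrast sharpens.

## Statistics

For each pair the package computes, per SNP:

* **Weir–Cockerham F_ST** — the 1984 two-level variance-component
  estimator, `theta = a / (a + b + c)`, with the observed-heterozygosity
  correction, per locus (no ratio-of-sums averaging); negative estimates
  are kept for ranking.
* **Unnormalized XP-EHH** — `ln(iHH_obs / iHH_ref)` where iHH is the
  trapezoidal integral of site-EHH (both alleles pooled) against
  physical distance, integrated over the interval where the pooled
  two-population EHH stays above 0.05, so both populations integrate the
  same interval. Observed = low-phenotype side, reference =
  high-phenotype side: positive scores mean selection toward the low
  phenotype.
* **Unstandardized iHS** (panel-wide, within-population) —
  `ln(iHH_minor / iHH_major)`, with |iHS| averaged in non-overlapping
  50 kb windows and the 99th-percentile windows called significant.

Significance is empirical-rank based throughout: `p = rank / N` over the
genome-wide scan, with ties sharing the smallest rank, so the top 1% of
37,061 SNPs is exactly 370 SNPs and the 99th percentile of 44,559
windows is exactly 445 windows. Called SNPs chain into regions at a
400 kb gap, regions take 200 kb flanks, and flanked F_ST and XP-EHH
regions intersect to give the loci supported by both methods.

The package also ships SNP-chip quality control (strict call-rate, exact
Hardy–Weinberg, MAF, and autosome filters applied in a fixed order with
per-filter accounting), LD-decay/MAF/He diagnostics, and a seeded
founder-mosaic simulator that generates phased panels with planted swept
QTL so the whole pipeline is testable without external data.

## Worked example

```r
library(gradscan)

cfg <- sim_config(seed = 42,
  qtl_spec = tibble::tibble(chromosome = "7", position_bp = 6e7,
    effect_size = qtl_effect_for_ve(0.3), swept = TRUE,
    sweep_strength = 0.9))
sim <- simulate_panel(cfg)
sim$haplotypes
#> <haplotype_set> 233 samples (466 haplotypes) x 37080 SNPs on 18 chromosome(s)
sim$truth[, c("marker_id", "chromosome", "position_bp", "realized_ve")]
#> # A tibble: 1 x 4
#>   marker_id chromosome position_bp realized_ve
#> 1 snp_7_989 7             60008878       0.309

scan <- scan_trait(sim$haplotypes, sim$phenotypes, "BF1", g = sim$genotypes)
glance(scan)
#> # A tibble: 1 x 6
#>   trait n_fst_snps n_xpehh_snps n_fst_regions n_xpehh_regions n_joint_regions
#> 1 BF1           47           74            44              45               7

pair_summary(scan$pairs, sim$phenotypes)
#>   level n_per_side mean_high mean_low t_statistic  p_value
#> 1     1        116      1.81   -0.151        19.4 8.34e-50
#> 2     2         75      2.22   -0.521        24.3 2.70e-51
#> 3     3         45      2.64   -0.859        25.9 8.52e-40

head(tidy(scan$fst), 2)
#>   marker_id      s1     s2     s3       p1       p2       p3 direction region_id
#> 1 snp_1_1779 0.0356 0.0618 0.0731 0.00226  0.00120  0.00608  <NA>             1
#> 2 snp_1_1878 0.0611 0.0940 0.114  0.000164 0.000218 0.000627 <NA>             2
```

The simulated trait plants one swept QTL explaining ~31% of the
phenotypic variance on chromosome 7; the scan calls 47 F_ST and 74
XP-EHH trait-specific SNPs, and the called set includes SNPs at the
planted locus (the `s1 < s2 < s3` columns above are the statistic's
strict gradient across the three nested pairs; `p1..p3` the per-level
empirical p-values). `autoplot()`/`plot_scan()` render LD-decay curves,
gradient-pair boxplots and Manhattan-style scan views; `pipeline_qc()` /
`pipeline_scan()` and the `exec/gradscan` script run the same pipeline
from files (PLINK trio or phased VCF + TSV phenotypes) to TSV/BED
outputs.

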