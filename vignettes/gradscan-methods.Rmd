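---
title: "Methods: trait-specific selection scans from phenotypic gradient pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-specific selection scans from phenotypic gradient pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design

`gradscan` targets a common situation in livestock genomics: a
single-breed panel genotyped on a medium-density SNP chip (tens of
thousands of markers, tens-of-kb spacing) with quantitative phenotypes,
where intense directional selection is expected to have left haplotype
and allele-frequency footprints, but a plain genome-wide sweep scan
cannot say *which* trait a footprint belongs to.

The design answers that with nested extreme-phenotype contrasts. For a
trait, samples are ranked by phenotype and split three times:

1. **Pair 1** — the high half vs the low half (`floor(n/2)` per side;
   with an odd sample count the median individual is dropped so the pair
   stays balanced — the reference design with 233 samples leaves this
   unstated, and a balanced pair keeps the two scans comparable).
2. **Pair 2** — the most extreme 75-per-side subset of pair 1 (for
   `n = 233`; otherwise the 75/116 ratio of the half panel, rounded).
3. **Pair 3** — the most extreme 45-per-side subset of pair 2 (45/116
   scaled likewise).

Each pair is scanned with per-SNP Weir–Cockerham F_ST and unnormalized
XP-EHH, statistics are converted to genome-wide empirical rank
p-values, and a SNP is a **trait-specific selection signature** iff

* its empirical p is at or below 0.01 in all three pairs, and
* the statistic follows a strict gradient: `s1 < s2 < s3` for F_ST, and
  for XP-EHH a constant sign with strictly growing magnitude. A sign
  flip would mean the population under selection changes between
  levels, which contradicts a trait-driven signal, so mixed-sign chains
  are never called. Strictness has no tolerance: a gradient is a chain of
  strict inequalities, and ties in floating-point
  statistics are effectively impossible.

Direction of selection comes from the XP-EHH sign. The package fixes
the role convention *observed = low-phenotype side, reference =
high-phenotype side*, so positive scores label selection toward the low
phenotype ("low") and negative toward the high phenotype ("high");
F_ST is direction-blind (`NA`).

## Statistics and numerical choices

**EHH.** EHH at distance x from a core SNP is the probability that two
haplotypes drawn from the considered set are identical at every marker
from the core to x. The value at the core is 1 (zero-width window); the
partition is refined by the core allele before the first outward
marker. The curve is evaluated at marker positions only and is
non-increasing outward.

**iHH and the integration rule.** iHH is the trapezoidal integral of
EHH against physical distance in bp (the chip provides no genetic map),
upstream plus downstream. Integration stops at the first marker whose
EHH drops below the decay cutoff and *includes* that marker's
trapezoid. The cutoff defaults to 0.05, the de facto default of the
EHH-scan implementations this design builds on. Two guards handle chip
reality: an extension that reaches a chromosome end before the cutoff,
or that would cross an inter-marker gap larger than `max_gap_bp`
(default 200 kb, ~3x the mean spacing of a 60k porcine chip), is
*truncated*. Truncated SNPs are dropped from iHS (a one-sided integral
would bias the log-ratio) but kept and flagged in XP-EHH, where both
populations truncate identically and the shared interval keeps the
ratio meaningful.

**iHS.** Chip data carries no ancestral-allele annotation, so the major
allele plays the ancestral role; `ihs_unstd = ln(iHH_minor /
iHH_major)`, and an `ancestral` argument lets callers supply real
ancestral states, which swaps the roles (and exactly negates the
score). Note that recoding the alleles of a SNP does *not* change the
score — minor stays minor — which is the invariance the tests assert.
SNPs with MAF below 0.05 are excluded. |iHS| is averaged in
non-overlapping 50 kb windows (`[k*50000 + 1, (k+1)*50000]`, 1-based);
windows without scored SNPs are absent rather than imputed.

**XP-EHH.** Site-EHH (both alleles pooled) is computed within each
population, but the integration bounds are set where the EHH of the
*pooled two-population* panel falls below the cutoff, so
`ln(iHH_obs/iHH_ref)` compares integrals over one interval. Scores are
left unnormalized: within a single biological comparison the empirical
genome-wide ranking replaces frequency-bin standardization.

**F_ST.** The Weir–Cockerham (1984) two-level estimator for r = 2
populations, per locus, from the a (among-population), b
(among-individual) and c (within-individual) components with the
observed-heterozygosity correction. Negative estimates are retained —
clipping would distort the empirical ranking — even though the
idealized range is [0, 1]. Missing genotypes are excluded per SNP per
population; a SNP needs two genotyped individuals per side, and SNPs
monomorphic across both sides are excluded with a reason.

**Empirical p-values.** `p = rank / N` with rank 1 the most extreme and
ties sharing the block's smallest rank. F_ST ranks on the upper tail;
XP-EHH and window |iHS| on absolute value. This rule, not `rank/(N+1)`,
makes the top 1% of 37,061 SNPs exactly `floor(0.01 * N) = 370` and the
99th percentile of 44,559 windows exactly 445.

**Regions.** Called SNPs on one chromosome chain into a region when
consecutive positions are at most 400 kb apart (single-linkage; the
span of a chain is not capped). Regions are flanked by 200 kb per side,
floored at position 1, and overlapping flanked regions union.
Significant iHS windows merge at a 200 kb edge gap. Loci "detected by
both methods" are the base-pair intersections of the flanked F_ST and
XP-EHH regions. Internally all coordinates are 1-based inclusive; BED
input/output converts to 0-based half-open, and interval overlap
requires at least one shared base.

**Quality control.** Five filters in a fixed order — individual call
rate > 0.90, SNP call rate > 0.95, exact Hardy–Weinberg p > 1e-6,
MAF > 0.05, autosomes 1–18 with known positions — all strict
inequalities, each SNP attributed to the first filter that removes it,
and HWE/MAF recomputed after individual removal. The HWE test is the
standard conditional exact test (full enumeration of heterozygote
counts, two-sided by probability ordering, no mid-p), the default of
the standard GWAS toolkit.

## The synthetic panel generator

`simulate_panel()` emulates the panel the design was built for: 233
diploid samples, 18 autosomes, ~2,060 SNPs each (~37k total), mean
spacing 62 kb. It is a founder-mosaic generator, not a coalescent
simulator: per chromosome, 40 founder haplotypes are drawn with
per-SNP allele frequencies from a Beta(0.5, 0.5) spectrum truncated to
[0.05, 0.95] (the U-shape of an ascertained, MAF-filtered chip), and
each sample haplotype is a mosaic of founders with switch probability
1e-6 per bp between adjacent markers (~1 Mb segments, which reproduces
strong short-range LD that decays over a few hundred kb). The founder
count, segment length and truncated spectrum were fixed once as
plausible for a closed commercial line; they are configurable but the
defaults define the package's study conditions.

A hard sweep is planted by choosing a favoured allele at 0.3 founder
frequency and copying one donor founder's background over a
geometric-length window (mean 1 Mb per side) into each favoured-allele
carrier with probability `sweep_strength` (0.9 in the validation
scenario). The phenotype is `effect x dosage + N(0, sd)`;
`qtl_effect_for_ve()` converts a target variance explained into an
effect size, and the truth record reports the realized fraction.

What the generator does *not* model: demography and pedigree structure,
genotyping error beyond uniform missingness, multiple interacting QTL,
and a proper neutral coalescent. Passing tests therefore demonstrate
that the machinery recovers planted signals under chip-like LD — not
that the statistics have any particular power on real populations.

Validation scenarios (used by the test suite and the acceptance
script): the default panel with one swept QTL at ~0.3 variance
explained, 50 seeded replicates, asserts that a called trait-specific
SNP lies within 200 kb of the QTL in at least 80% of replicates and
that F_ST at the QTL rises strictly across the three pairs in at least
90%; oracle checks (exact-test enumeration, pair-counting EHH,
ANOVA-route F_ST, quadratic interval overlap) run at small n where
brute force is feasible.

## Known limitations

* **The null is not as quiet as the nesting suggests.** Because the
  three pairs are nested samples and the per-level sampling variance
  grows as the pairs shrink (116 to 75 to 45 per side), the per-level
  statistics are substantially correlated under a no-QTL null, and
  shared sampling outliers tend to satisfy the strict gradient
  automatically. Measured on no-QTL panels, the trait-specific call
  rate is roughly 0.2% of SNPs per method — about four-fold below the
  nominal 1% level, but far from negligible. Trait-specific calls
  should be read as enrichment candidates around which the planted-QTL
  recovery holds, not as family-wise-error-controlled discoveries.
* Empirical rank p-values are outlier statistics, not calibrated tail
  probabilities; alpha = 0.01 is a selection fraction.
* Unnormalized XP-EHH and iHS retain frequency-dependent variance;
  extreme-frequency SNPs are over-represented in the tails.
* Integration over physical distance ignores recombination-rate
  variation; a genetic map, if available, is not used.
* The PLINK reader handles the SNP-major binary layout only, and phased
  input is taken as given — no phasing or imputation is performed.
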