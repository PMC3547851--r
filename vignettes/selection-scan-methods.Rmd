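---
title: "Breed-level selection scans with windowed F_ST and d_i: models and methods"
author: "breedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-level selection scans with windowed F_ST and d_i}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

## The problem

Domestic animal breeds are closed populations under intense artificial
selection. A trait fixed in one breed — sprinting muscle, an ambling
gait, a coat color — leaves a genomic footprint: a haplotype driven to
high frequency locally, inflating that breed's allelic divergence from
every other breed around the selected locus while the rest of the
genome drifts at a background rate. `breedscan` scans multi-breed
diploid SNP-array panels for exactly this signal, and carries the
companion analyses such a scan needs: relatedness pruning before the
scan, haplotype-sharing analysis after it, and candidate-variant
association with a quantitative phenotype (here, muscle fiber-type
composition).

## The divergence statistic

For each unordered pair of breeds $(i, j)$ and each genomic window
$w$, the package computes the two-population Weir–Cockerham $\theta$
(the standard moment estimator of $F_{ST}$, robust to unequal sample
sizes). Per SNP, the estimator decomposes allelic variance into
between-population ($a$), between-individual ($b$) and
within-individual ($c$) components from the two breeds' sample sizes,
allele frequencies and heterozygote proportions; the window estimate
is the ratio of averages

$$\hat F_{ST}^{ij}(w) \;=\; \frac{\sum_{s \in w} a_s}{\sum_{s \in w} (a_s + b_s + c_s)},$$

which weights SNPs by their information content rather than averaging
per-SNP ratios. Sample sizes are per-SNP counts of called genotypes; a
SNP enters a pair's sums only when both breeds have at least two
called genotypes and the pooled pair is polymorphic there. Negative
window estimates are retained — truncation at zero would bias the
genome-wide standardization that follows.

The locus-specific divergence statistic for breed $i$ at window $w$ is

$$d_i(w) \;=\; \sum_{j \ne i}
  \frac{\hat F_{ST}^{ij}(w) - \mathbb{E}[\hat F_{ST}^{ij}]}
       {\mathrm{sd}[\hat F_{ST}^{ij}]},$$

where the expectation and standard deviation are taken over all
analyzed windows of that pair (sample sd, $n-1$ denominator). Each
pair term is a genome-standardized z-score, so a large $d_i(w)$ means
breed $i$ is more diverged from the other breeds at $w$ than is
typical for it genome-wide — the expected footprint of breed-specific
selection. By construction each pair's z-scores average to zero, so
each breed's $d_i$ averages to zero over fully covered windows; the
package asserts this to $10^{-8}$ in its tests.

Windows are non-overlapping tiles of 500 kb (configurable) anchored at
bp 1 on every chromosome, so each SNP belongs to exactly one tile.
Tiles with fewer than 4 SNPs are dropped: with array densities of a
few SNPs per 100 kb, sparser tiles produce noisy ratio estimates.
Terminal partial tiles are retained when they meet the SNP minimum.
Windows are reported by their center, `start + window/2`.

### Outlier calling

Significance is empirical, not parametric: per breed, the windows in
the upper 1% of that breed's own $d_i$ distribution are flagged. The
package implements the percentile as a count rule,
$k = \lceil (1 - 0.99) \, W \rceil$ for $W$ analyzed windows, with
ties at the cut broken by genome position, so the flagged set size is
deterministic (for example, $W = 3{,}229$ gives exactly $k = 33$
windows per breed). A small epsilon guards the ceiling against
floating-point error in $(1 - p)$. Empirical thresholds make no
distributional claim about $d_i$; they rank a breed's windows against
its own genome, which is the appropriate null when breeds differ in
effective population size and drift.

## Relatedness pruning

Close relatives inside a breed panel distort allele frequencies and
inflate apparent divergence, so pairs sharing too much of the genome
are pruned first. Genome sharing $\hat\pi = k_2 + k_1/2$ is estimated
by the classical method of moments on identity-by-state counts: per
SNP the probabilities of IBS 0/1/2 conditional on sharing 0/1/2
alleles identical by descent are computed from allele frequencies,
and the IBD mass functions are solved sequentially from the observed
IBS counts, clipped to $[0,1]$ and renormalized onto the simplex.
Allele frequencies are taken per breed, because pooled frequencies
overstate relatedness inside differentiated populations. Pruning is
greedy: while any within-breed pair sits at or above the threshold
(default $\hat\pi \ge 0.25$, half-way between first- and
second-degree; 0.3 is a common looser choice and is exposed as a
parameter), the sample in the most offending pairs is removed, ties
broken by lower call rate then sample id — removing one member of
each flagged pair with as few removals as the greedy order allows.

## QC defaults

SNP filters (pooled minor allele frequency $\ge$ 0.01, per-SNP
missingness $\le$ 0.05) follow the conventions of array-based
relatedness estimation; the per-sample missingness default of 0.02
reflects the high call rates of modern arrays. MAF is computed on
called alleles pooled across all samples — per-breed MAF filtering
would discard exactly the breed-restricted variants the scan looks
for. All thresholds are exposed because no single setting suits both
relatedness estimation and the scan itself; the defaults are the
package's choice, applied consistently in its tests. Filters are
single-pass: SNP statistics are computed on the input, then sample
missingness on the retained SNPs.

## Haplotype sharing

Downstream of the scan, phased data (from any phasing tool, or
simulator truth) supports the haplotype questions: how long is the
shared haplotype under an outlier window, how breed-restricted is it,
and does a candidate variant ride on it?

Haplotype identity is exact string match over a SNP interval — no
mismatch tolerance — because the footprint of interest is a recent,
essentially unrecombined segment. The extension procedure starts from
the modal haplotype of a seed window in one breed and its carrier
chromosomes, then grows outward one SNP at a time, alternating sides:
the appended allele is the carriers' majority allele (ties to the
reference allele), carriers not matching it drop out, and a side
closes when the carrier frequency would fall below `f_min` (default
0.5). Because the majority allele maximizes the surviving carrier
count, a closed side certifies that *no* allele choice could keep the
frequency at `f_min` — the record is maximal, and the tests verify
this against exhaustive one-SNP extensions. The procedure is
deterministic, so nested "minimal / shared / extended" haplotype
reports are reproducible.

Variant–haplotype concordance is summarized as the percentage of
haplotype-bearing chromosomes that carry the variant, with a
two-sided Fisher exact test on the 2×2 chromosome table — exact and
order-invariant, appropriate at the few-hundred-chromosome scale
where asymptotic tests are unnecessary.

## Fiber-type association

The association module tests a candidate variant, coded additively as
its allele count 0/1/2, against muscle fiber-type composition with age
and sex as covariates.

The three fiber-type proportions sum to 100, so their covariance is
singular and a trivariate MANOVA is undefined. The package's response
is the bivariate (Type 1, Type 2B) — the slow-oxidative and
fast-glycolytic extremes, which carry the biological contrast — and
the middle category is dropped. The test statistic is Pillai's trace,
the most robust of the standard MANOVA statistics to mild assumption
violations; the genotype term is fitted after the covariates so its
sequential sum of squares is covariate-adjusted. Effect sizes and
95% confidence intervals per fiber type come from multiple linear
regression on the same design; because the three responses share the
design and sum to a constant, the three additive slopes sum to zero
exactly, a useful internal check.

The genotypic (3-level factor) model yields least-squares means:
model predictions per genotype at the covariate means, with
categorical covariates weighted by their observed proportions.
Pairwise genotype differences use unadjusted t-tests on the model's
residual variance (Fisher's LSD), displayed as letter groups — levels
sharing a letter are not significantly different at $\alpha = 0.05$ —
and flagged "protected" only when the overall genotypic F-test is
itself significant. The tests cross-check the LS-means against
`emmeans` with proportional weighting.

## The synthetic-data generator

Every stage is testable without real data via a generator whose
defaults describe the panel the scan targets: 33 breeds of ~22
diploids, ~23,400 SNPs uniform over 31 autosomes of 75 Mb (≈5 SNPs
per 500-kb tile, so a realistic fraction of tiles passes the 4-SNP
minimum), ancestral allele frequencies uniform on (0.05, 0.95) — an
ascertained-array spectrum, not neutral-site — per-breed drift
parameters $F$ uniform on (0.05, 0.25), and a 1% missing-call rate.

Breed structure follows the Balding–Nichols model: per SNP an
ancestral frequency $p$, then per breed a frequency drawn from
$\mathrm{Beta}\!\big(p\,(1-F)/F,\ (1-p)(1-F)/F\big)$, which has mean
$p$ and variance $F\,p(1-p)$ — so $F$ is the expected divergence of
the breed from the ancestral pool, and the realized pairwise
$F_{ST}$ between two breeds tracks their $F$ values (verified in the
tests: two breeds at $F = 0.10$ recover a genome-wide estimate within
±0.02). Chromosomes are independent Bernoulli draws, so truth phase is
known and the unphased dataset is the chromosome sum with missingness
masked on it only.

What the generator deliberately omits: background linkage
disequilibrium, recombination maps, ascertainment bias beyond the
frequency floor, and mutation. Sweep-like LD is injected explicitly:
`inject_sweep` overwrites a deterministic `round(q · 2N)` of a target
breed's chromosomes with a founder haplotype over an interval
(deterministic counts make frequency assertions exact; which
chromosomes are overwritten is random). Consequently, passing tests
demonstrate that the scan detects breed-restricted high-frequency
haplotypes against a drift background — they do not demonstrate
robustness to background LD, allele surfing, or bottleneck-driven
false positives in real panels, where empirical thresholds (top 1%
per breed) are precisely the guard the method relies on.

Relatives are spiked by Mendelian gamete sampling from two existing
samples (a missing parental genotype transmits an allele at the breed
frequency), giving expectation $\hat\pi \approx 0.5$ for
parent–offspring and full sibs, with $k_2 > 0$ only for sibs.

Fiber-type phenotypes are baseline + additive effect × allele count +
Gaussian noise per type, clipped to $[0, 100]$ and renormalized to
sum 100. Clip-then-renormalize is the simplest generator that
preserves the sum constraint; with baselines well inside the simplex
and residual sd ~6 points, clipping is rare and the recovered slopes
are unbiased to Monte-Carlo precision (the tests verify recovery over
hundreds of replicate cohorts of 79 horses with genotype counts
18/31/30, the default design). A logistic-normal compositional model
would respect the simplex geometry more cleanly but adds nothing at
these noise levels.

## Numerical and edge-case decisions

* Coordinates are 1-based as in MAP/VCF; internal window intervals are
  half-open `[start, end)`, so tiles partition the chromosome without
  double-counting boundary SNPs.
* Missing genotypes are excluded SNP-wise; per-SNP per-breed sample
  sizes vary accordingly. A pair term with no usable SNP in a window
  is undefined, and a window's $d_i$ is reported with a completeness
  flag rather than silently rescaled.
* A breed pair with zero sd (degenerate, e.g. constant $F_{ST}$) or
  fewer than two defined windows contributes no term, with a warning —
  never an infinity.
* PED alleles are recoded against the declared ref/alt; a 4-column MAP
  falls back to pooled-major-allele inference with alphabetical tie
  break. Half-missing PED genotypes are structural errors, not data.
* Greedy pruning and percentile calling both use deterministic tie
  breaks (call rate then id; genome position), so identical inputs
  give byte-identical outputs.

## Problem sizes used in the test suite

Unit and property tests run on panels of 2–10 breeds, 10–25 diploids
per breed, and 300–13,000 SNPs; the full-scale sweep-detection
property uses 50 replicates of a 10-breed × 20-diploid panel on 31
autosomes (~2,000 analyzed windows) with one 2-Mb sweep at carrier
frequency 0.95, asserting the swept window is the target breed's
genome-wide $d_i$ maximum — and the extended haplotype recovers ≥90%
of the injected span — in at least 90% of replicates. Effect-recovery
and type-I-error simulations use 100–1,000 replicate cohorts. These
sizes were chosen so the suite exercises the asymptotic behavior the
method relies on while remaining a desk-scale computation.

## Worked example

```{r example, eval = FALSE}
library(breedscan)

sim <- simulate_breeds(sim_config(n_breeds = 6, samples_per_breed = 20,
                                  n_chromosomes = 8,
                                  chromosome_length_bp = 20e6,
                                  n_snps = 2500, seed = 1))
sw <- inject_sweep(sim$phased,
                   sweep_spec("breed01", chrom = "2",
                              start_bp = 5e6, end_bp = 7e6, q = 0.95))
res <- run_scan(pipeline_config(input = collapse_phased(sw$phased),
                                out_dir = tempfile("scan"), seed = 1))
head(res$di[res$di$significant, ])
render_di_plot(res$di, res$windows, "breed01", "breed01_di.png")
```

## Limitations

The scan detects differentiation, not its cause: drift in small
breeds, founder effects and ascertainment can all produce outlier
windows, and the empirical threshold guarantees a fixed number of
outliers per breed regardless of whether any selection occurred.
Haplotype extension assumes dense, accurately phased markers; phase
error truncates records. The association module assumes additivity
and Gaussian residuals on proportions — adequate mid-simplex, poor
near the boundaries. None of the methods model background LD, and
the simulator does not generate it.
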