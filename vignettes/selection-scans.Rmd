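---
title: "Detecting selection signatures with haploSweep: methods and design"
author: "haploSweep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection signatures with haploSweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploSweep)
```

## The problem

Strong directional selection — artificial selection in livestock being the
canonical case — drives a favourable allele up in frequency faster than
recombination can shuffle its background. Two complementary footprints
result. Within a population, the selected allele sits on an unusually long
shared haplotype; across populations, divergent selection leaves loci whose
allele frequencies are far more differentiated than drift alone explains.
haploSweep implements one scan for each footprint, on phased, complete,
biallelic genotypes:

* the **integrated haplotype score (iHS)**, a within-population statistic
  built on extended haplotype homozygosity (EHH) decay, aggregated into
  fixed genome windows and called by false-discovery-rate control; and
* the **global Weir–Cockerham fixation index** $F_{ST}$, a single
  multi-population estimate per SNP, thresholded at an empirical top
  fraction.

Both scans end in gene annotation, and the intersection of their gene hits
is reported per population, the strongest candidates being genes flagged by
both.

## The iHS statistic

For a core SNP with ancestral allele $A$ and derived allele $D$, EHH at a
flanking position $x$ is the probability that two randomly chosen carrier
haplotypes are identical at every marker between the core and $x$. With
carriers partitioned into groups $g$ of identical stretches,

$$\mathrm{EHH}(x) = \frac{\sum_g \binom{n_g}{2}}{\binom{n_c}{2}},$$

the sample (pairwise) form without small-sample correction. EHH is 1 at
the core and non-increasing outward. Integrating EHH over physical
position (bp) across both flanks gives the integrated haplotype
homozygosity $iHH_A$ and $iHH_D$ for the two core alleles, and the raw
score is $\ln(iHH_A / iHH_D)$. Because the raw score's distribution
depends on the derived allele frequency, scores are standardized within
derived-frequency bins:

$$\mathrm{iHS} = \frac{\ln(iHH_A/iHH_D) -
  \mathrm{E}[\ln(iHH_A/iHH_D)]}{\mathrm{SD}[\ln(iHH_A/iHH_D)]},$$

after which they are approximately standard normal under neutrality. A
sweep on the derived allele therefore produces large *negative* iHS (the
derived haplotypes are the long ones); all downstream calling uses
$|\mathrm{iHS}|$. The two-sided Gaussian p-value is
$p = 2\,(1 - \Phi(|\mathrm{iHS}|))$, with $-\log_{10} p$ kept as a display
transform (the untransformed $p$ is what downstream FDR consumes, so the
log base is display-only; base 10 is used).

Per-SNP scores are averaged as $|\mathrm{iHS}|$ within non-overlapping
windows (500 kb by default), and the window-level p-value is the same
Gaussian transform applied to the window mean — the convention under
which a window mean of 7.000 corresponds to $P = 2.56\times10^{-12}$ and
6.953 to $3.6\times10^{-12}$, as such scans report per-window P values.
Window-level values, not per-SNP values, are the default object of
significance calling; per-SNP p-values remain available.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `decayFloor` | 0.05 | EHH | stop/integration floor; common practice in EHH tools |
| `maxGap` | 200,000 | bp | an inter-marker gap this large makes the decay curve untrustworthy |
| `mafMin` | 0.05 | frequency | iHS is unstable at extreme frequencies; power is maximal at intermediate ones |
| `windowSize` | 500,000 | bp | matches the LD scale of dense livestock panels |
| `nBins` | 40 | — | derived-frequency bins of width 0.025 for standardization |
| `minPerBin` | 50 | records | bins below this are merged with the nearest occupied neighbour |
| `qThreshold` | 0.05 | q | window significance level |
| `topFraction` | 0.001 | fraction | top 0.1% of $F_{ST}$ values called |

### Numerical choices

* **Integration.** Trapezoidal, over physical bp, on each flank from the
  core outward; only the portion with $\mathrm{EHH} \ge$ `decayFloor` is
  integrated, closed by linear interpolation to the floor crossing.
* **Edges and gaps.** A flank that reaches a chromosome end before
  decaying to the floor would yield a downward-biased area; such cores are
  marked invalid (reason `"edge"`) rather than integrated. This is
  configurable (`edgeRule = "integrate"`). A flank stopped by a gap larger
  than `maxGap` is always invalid (reason `"gap"`).
* **Standardization bins** are left-closed; underfilled bins merge with
  the nearest occupied bin until every used bin holds `minPerBin` valid
  records; a bin with zero spread is an error rather than a silent
  division by zero.
* **Cores with fewer than two carriers** of either allele, or with zero
  integrated area, are flagged not-computable with a reason code instead
  of propagating `NaN`.

### A calibration caveat: window-level p-values and FDR

Per-SNP two-sided p-values are uniform under neutrality, because
standardized iHS is approximately standard normal. Window-level p-values
are **not**: the mean of $|N(0,1)|$ over $n$ SNPs concentrates near
$\sqrt{2/\pi} \approx 0.80$, so under pure neutrality the window p-values
pile up near $2(1-\Phi(0.80)) \approx 0.42$ instead of spreading
uniformly. Two consequences follow.

First, the Storey-type estimator offered here,
$\hat{\pi}_0 = \min\{1, \#\{p > \lambda\} / ((1-\lambda)m)\}$ with
$\lambda = 0.75$ (a simple analogue of the 75th-percentile
empirical-null estimation common in local-fdr tools), assumes uniform
null p-values above $\lambda$. On a panel with no p-values above 0.75 it
estimates $\hat{\pi}_0 = 0$ and returns $q = 0$ everywhere. Full
empirical-null density estimation (Grenander-type local fdr), which
recalibrates against the bulk of the distribution and so handles
non-uniform nulls, is deliberately out of scope.

Second, and consequently: for window-level calling on panels where the
null bulk may dominate, Benjamini–Hochberg (`method = "bh"`) is the
method whose guarantee actually applies, and it is what the package's
own validation uses for neutral false-call rates; Storey-$\lambda$ is
appropriate for per-SNP p-values, whose null is uniform. Both methods
are exposed everywhere an FDR choice exists.

## The global F_ST scan

Per SNP, the multi-population Weir–Cockerham (1984) method-of-moments
estimator is computed from variance components with sample-size weighting.
The default operates at the haplotype level — the input is phased, so each
haplotype is treated as a gamete and the within-individual component
collapses: with among- and within-population mean squares $MSP$ and
$MSG$ and the unequal-sample-size correction $n_c$,

$$\hat{\theta} = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG}.$$

A diploid mode implementing the full $a/b/c$ decomposition with observed
heterozygosity (from each sample's phased pair) is available. Negative
estimates, which have no biological interpretation, are clipped to 0 for
ranking (the unclipped $\hat{\theta}$ is kept in the output); SNPs
monomorphic across all populations have undefined $\hat{\theta}$ and are
excluded from ranking. The empirical p-value of a SNP is its rank over the
valid clipped values divided by their count, rank 1 for the largest and
ties sharing their block's maximum rank. The top-fraction call takes the
$\lfloor N f \rfloor$-th largest value as the boundary and flags
everything at or above it, so a tie block straddling the cutoff is
flagged whole, and with distinct values exactly $\lfloor N f \rfloor$
records are flagged. No multiple-testing adjustment is applied to
$F_{ST}$, by design. The genome mean of the clipped values is classified
on Wright's bands (little $< 0.05 \le$ moderate $\le 0.15 <$ great
$\le 0.25 <$ very great).

## Annotation

Gene models are accepted as BED (0-based half-open) or GFF3 (1-based
inclusive), both normalized at ingestion. Windows use 0-based half-open
coordinates anchored at 0 per chromosome; any-overlap ($\ge$ 1 bp) maps
genes to significant windows, counting each gene once, while top-FST SNPs
use strict containment within the gene span. The per-population
intersection of the two gene sets is the final candidate table.

## The synthetic-data generator

Every pipeline stage is testable without external data through seeded
generators that are pure functions of their configuration:

* **Neutral background** — founder haplotypes drawn at per-locus
  frequencies uniform on (0.05, 0.95); each present-day haplotype is a
  recombination mosaic of founders with geometric segment lengths (per-bp
  switch rate $10^{-6}$, mean segment 1 Mb — the LD scale that motivates
  500-kb windows). Mean SNP spacing defaults to 3,560 bp, emulating a
  high-density array panel. The recorded ancestral allele is the
  founder-majority allele, with an optional misassignment rate for
  polarization-robustness tests.
* **Hard sweep** — emulated structurally: a chosen fraction of haplotypes
  (0.6 in the validation conditions) receives the derived core allele and
  one shared donor segment across the configured width (1 Mb), exactly the
  long-shared-haplotype footprint iHS targets. Truth (core, carriers) is
  recorded exactly, and runtime is trivial compared with forward
  simulation.
* **F-model drift** — each population's per-locus frequency is drawn from
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around the ancestral frequency
  $p$, giving mean $p$ and variance $F p (1-p)$, so the expected
  Weir–Cockerham $F_{ST}$ is approximately $F$.

What the generator does **not** emulate: realistic bovine LD maps and
recombination hotspots, demographic history (bottlenecks, admixture,
crossbreeding), ascertainment bias of array SNPs, soft sweeps, and — in
the F-model arm — linkage structure at all (frequencies are resampled
independently per locus, which validates the frequency-based scan only).
Passing tests therefore demonstrate correctness of the statistics and
calling logic under a clean mechanistic null and a clean sweep footprint,
not power or false-positive behaviour on real livestock data.

## Validation conditions

The test suite validates each stage against independent oracles (pair
enumeration for EHH, explicit ANOVA sums of squares for Weir–Cockerham,
hand-computed trapezoids, textbook kinship arithmetic) and runs the
following study conditions: estimator-oracle equivalence on 200 random
panels of up to 5 populations × 40 haplotypes; F-model recovery with 7
populations × 100 haplotypes at ~5,000 loci and $F = 0.10$; neutral iHS
calibration on a 200-haplotype, ~20,000-SNP panel (overall and per
frequency bin, on width-0.1 check bins distinct from the standardization
bins, restricted to bins holding at least 200 records since smaller bins
cannot constrain a mean to ±0.05); sweep detection over 50 seeded
replicates of a 100-haplotype, 10-Mb panel with the sweep core placed
mid-window (the containment question is ill-posed for a core sitting on a
window boundary); and matched neutral panels for the false-call rate. The
same conditions are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The pairwise EHH form carries no small-sample correction; panels with
  very few carriers near `mafMin` are noisy (they are also where the
  statistic is least meaningful).
* Window-level FDR calibration inherits the non-uniform-null caveat
  above; single-SNP windows are particularly unstable and occasionally
  produce the top score on small neutral panels.
* The haploid $F_{ST}$ default ignores within-individual correlation; for
  unphased or inbreeding-heavy designs use the diploid mode.
* Pedigree inbreeding uses the recursive tabular method; pedigrees of
  hundreds of thousands of animals would need the dedicated large-scale
  algorithms this package does not attempt.
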