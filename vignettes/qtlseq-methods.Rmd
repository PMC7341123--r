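---
title: "QTL-seq bulked-segregant analysis: model, filters and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant analysis: model, filters and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The statistic

QTL-seq contrasts two DNA pools drawn from the extremes of a segregating
population. For a biparental cross with fully homozygous parents, every SNP
that distinguishes the parents is informative. Orienting each site to the
restorer parent's allele, the SNP-index of a bulk is

$$\mathrm{SNP\text{-}index} = \frac{\text{restorer-allele reads}}{\text{total reads}},$$

and the scan statistic is $\Delta = \mathrm{index}_{FR} - \mathrm{index}_{SM}$
(trait-positive minus trait-negative bulk). At a locus unlinked to the trait
both bulks are random samples of the F2 allele pool, the expected index is
0.5 in each, and $E[\Delta] = 0$; near a causal locus selection skews the two
bulks in opposite directions and $\Delta$ moves towards $\pm 1$.

`qtlseq()` is the single entry point: it reads or accepts a four-sample
variant table (parents P1/P2, bulks FR/SM), selects informative sites,
computes per-site indices, filters, averages in sliding windows, attaches
null confidence bands and calls candidate regions. It returns a classed
object with `print`, `summary` and `plot` methods.

## Filters and their semantics

* **Parental informativeness** (`select_informative`): both parents called
  homozygous for different alleles, and each parent's depth strictly
  greater than 5 reads. The depth rule is applied per parent; applying it
  jointly is a configuration choice (`min_parent_depth`), but per-parent is
  the stricter and safer reading. Sites failing the caller's FILTER column
  are also dropped by default (`use_filter`), and only biallelic SNPs are
  kept unless `snps_only = FALSE`.
* **Locus filters** (`apply_locus_filters`): a site is removed when either
  bulk's depth is below 7 reads, or when the SNP-index is below 0.3 or
  above 0.7 **in both bulks**. The depth rule guards the index's sampling
  noise; the both-bulks index rule removes loci that are jointly extreme —
  typically paralogous mis-mappings or residually monomorphic sites — while
  keeping contrasting loci, which are exactly the signal. Both rules admit
  per-bulk and joint readings; the implementation defaults to per-bulk for
  depth and joint for the index (the standard QTL-seq practice) and exposes
  both semantics (`depth_rule`, `index_rule`). Because any sensible
  `min_depth` exceeds zero, zero-depth sites never reach the index
  computation and division by zero cannot occur.

## Sliding windows

Windows span 5 Mb and advance by 10 kb, anchored at 0-based multiples of
the step from each chromosome start; a site at 1-based position $p$ belongs
to the window starting at $s$ iff $s \le p-1 < s + W$ (half-open). Window
means are unweighted arithmetic means over member sites. Windows with no
member sites are omitted: no statistic is invented for them, and the plot
simply shows the gap. Reported coordinates are 1-based inclusive in TSV
output and 0-based half-open in BED, with the conversion isolated in the
writers.

## Null confidence bands

Under the null hypothesis of no QTL, each of the $2n$ chromosomes in a bulk
of $n$ F2 plants carries the restorer allele independently with probability
1/2, so the bulk allele frequency is $p = B/(2n)$, $B \sim \mathrm{Bin}(2n,
\tfrac12)$ (for BC1 bulks, $B \sim \mathrm{Bin}(n, \tfrac12)$), and the
observed index at depth $d$ is $\mathrm{Bin}(d, p)/d$. `null_ci()` simulates
$\Delta$ this way (10,000 replicates per depth by default) and tabulates
empirical quantiles at the 95% and 99% levels over a depth grid that is
dense from 7 to 100 and sparse above (bands change slowly at high depth;
depths beyond the grid are clamped). By the law of total variance the
single-bulk index variance is

$$\mathrm{Var} = \frac{\tfrac14 - \tfrac{1}{8n}}{d} + \frac{1}{8n},$$

which equals 0.02875 at $n = 30$, $d = 10$ — the package's calibration
anchor (`null_index_draws()` reproduces it within Monte-Carlo error, and the
acceptance script checks it at $10^6$ replicates).

Each site looks its band up at its own effective depth — by default the
*smaller* of its two bulk depths, the conservative choice since the band
widens as depth falls (`depth_rule = "mean"` is available). Bounds are
linearly interpolated between tabulated depths. A window's band is the mean
of its member sites' bounds, mirroring how the window statistic is the mean
of the member deltas.

### Discreteness and the mid-P convention

$\Delta$ at depth $d$ lives on a lattice of spacing $1/d$, and the empirical
band quantiles land on lattice atoms. Counting only sites *strictly* outside
the band is therefore systematically conservative: exact enumeration gives
~4.3% exceedance of a nominal 95% band at $d = 30$, not 5%. The calibration
measure `ci_exceedance()` consequently defaults to the standard mid-P
convention — sites exactly on the boundary count with weight 1/2 — which
restores the nominal rate in the continuum limit (~5.1% averaged over
Poisson(30) depths). Strict and inclusive counting remain available via
`ties`. This affects only the calibration diagnostic; region calling always
uses the strict comparison of window means against window bands, where the
lattice is immaterial because a 5-Mb window averages hundreds of sites.

## Region calling

Windows whose mean $\Delta$ exceeds the upper band at the chosen level
(default 0.95, i.e. P < 0.05; the lower tail is the symmetric option for
maintainer-parent QTL) are merged when overlapping or separated by at most
`max_gap` (default: one step), and regions shorter than `min_span`
(default 1 Mb) are discarded to suppress isolated single-window calls. The
peak is the member window of largest $|\Delta|$. Because adjacent windows
share all but ~1/500 of their sites, window-level exceedances are strongly
correlated; the per-window band is a per-site-scale band, so only sustained
multi-megabase skews — not window-mean noise, whose standard deviation is
roughly $1/\sqrt{500}$ of a site's — can cross it. Null-chromosome false
calls arise almost exclusively from the few near-telomeric windows that
contain a handful of sites, which is why they are rare (a few percent of
simulated genomes) rather than absent.

## The simulator

`simulate_bsa_dataset()` chains the three stages; each draws from a named
substream of one master seed (`derive_seed`), so identical seeds give
byte-identical variant tables and any stage can be re-run in isolation.

* **Cross**: fully homozygous parents differing at every SNP; F1 selfed to
  F2 (`simulate_f2`) or backcrossed (`simulate_backcross`). Meiosis follows
  the Haldane model — crossovers are a Poisson process along the genetic
  map at 1 cM/Mb, no interference. The scan is insensitive to interference,
  so the simplest standard model is used.
* **Phenotype**: two restorer loci — a dominant, nearly fully penetrant
  main restorer (grade V with probability 0.997) and a second restorer QTL
  whose carriers are fully fertile with probability 0.8 by default
  (non-carriers without the main restorer are sterile). The penetrance
  table maps each joint genotype class to a distribution over the five
  fertility grades (I–II sterile, III–V fertile) and is pure configuration:
  real fertility-restoration systems of this kind involve an unknown number
  of loci with unknown penetrances, so the package asserts no particular
  model and every value can be replaced. Note that a single two-locus model
  with these defaults produces a higher sterile fraction among
  main-restorer non-carriers (~40%) than a multi-locus system would; the
  default is a deliberately simple, detectable signal, not a fit to any
  dataset.
* **Bulks**: uniform sampling without replacement among plants satisfying
  the bulk rule (default: 30 fully fertile grade-V vs 30 sterile grade-I/II
  plants, all non-carriers at the main restorer locus), with an explicit
  shortfall error naming the bulk. The default F2 size of 1,000 plants
  comfortably supplies both bulks under the default penetrance.
* **Reads**: per-sample depths Poisson around 10× (parents) and 30×
  (bulks); the restorer-allele read count is Binomial(depth, p′) where p′
  is the bulk's true allele frequency perturbed by a symmetric
  allele-flip error (default 0.001) — enough to exercise the 0.3/0.7
  filter without modelling read-level artefacts. REF/ALT orientation in the
  emitted VCF is randomised so the reader's re-orientation logic is always
  exercised.

The default genome is two 150-Mb chromosomes with one informative SNP every
10 kb — a deliberately scaled design (a full simulate-and-scan run takes a
few seconds) whose main restorer (chr1:25 Mb) and second QTL (chr1:130 Mb)
are ~105 cM apart on one chromosome, effectively unlinked, with the second
chromosome as a negative control; a ten-chromosome maize-sized genome is
just a larger `chromosomes` table. What the simulator does **not** emulate:
alignment and variant-calling artefacts, multiallelic sites and InDels,
depth heterogeneity beyond Poisson (GC bias, repeats), segregation
distortion, and cytoplasm genetics (all individuals implicitly carry the
sterile cytoplasm). Passing tests therefore demonstrate the pipeline's
statistical behaviour under the design assumptions, not robustness to every
artefact of real resequencing data.

## Numerical and design choices

* Coordinates are 1-based inclusive internally (VCF convention).
* Reported ratios and percentages are rounded half-up to two decimals
  (report parity); raw doubles are kept internally and in machine output.
* The goodness-of-fit χ² is the uncorrected Pearson statistic (the Yates
  continuity correction is deliberately not applied, matching standard
  segregation-analysis practice), with p-values from the χ² distribution;
  the statistic is invariant to rescaling the ratio weights.
* The restorer parent's identity is configuration (`sample_map`), never
  inferred from the data.
* Unsorted variant input is a fatal error naming the first out-of-order
  position rather than a silent re-sort, since silently re-sorting can mask
  sample-mapping mistakes.
* `null_ci()` requires at least 1,000 replicates; bands are stored per
  depth and interpolated, never extrapolated (clamped at the grid edges).

## Problem sizes used in the checks

The test-suite and acceptance experiments use the scaled defaults: 2 × 150
Mb genomes (30,000 SNPs), F2 populations of 1,000 plants, 30 + 30 bulks,
10,000-replicate band tables, a $10^6$-replicate variance check, a
200,000-site exceedance check, and 50 independent end-to-end recovery runs.
These sizes make every experiment reproducible in minutes while leaving
Monte-Carlo error well inside the asserted tolerances.

## Limitations

Window-level significance inherits the original QTL-seq logic of comparing
a window mean against a per-site-scale band; it is a detection heuristic,
not a calibrated window-level test, and the package makes no multiple-
testing claim across windows. Region boundaries are resolution-limited by
the window span (a 5-Mb window smears a point signal by ±5 Mb). The BC1
null design assumes the recurrent parent is the maintainer. Fertility
penetrance defaults are illustrative, not estimated from data.
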