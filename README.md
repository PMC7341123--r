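# bsaqtl

QTL-seq bulked-segregant analysis for biparental crosses, with the
Mendelian segregation statistics used in restorer-of-fertility genetics,
and a synthetic cross-and-sequencing simulator so the whole pipeline can be
exercised and calibrated without external data.

## The problem

In cytoplasmic male sterility (CMS) systems, nuclear *restorer-of-fertility*
(*Rf*) genes rescue pollen production in an otherwise sterile cytoplasm.
When a segregating F2 population shows a fertile:sterile ratio that a single
dominant restorer cannot explain (e.g. ~37:1 instead of 3:1), additional
restorer loci are acting. QTL-seq locates them by sequencing two pooled DNA
bulks of plants with extreme, contrasting phenotypes — here fully fertile vs
sterile plants that all lack the main restorer (*rf4rf4*) — together with
the two inbred parents.

At every SNP that distinguishes the parents, the **SNP-index** of a bulk is
the fraction of its reads carrying the restorer parent's allele:

    SNP-index = restorer-allele reads / total reads,

0.5 at loci unlinked to the trait, pushed towards 1 (or 0) near a causal
locus in the bulk selected for (or against) the restorer allele. The
contrast statistic is

    Δ(SNP-index) = SNP-index(FR bulk) − SNP-index(SM bulk),

near 0 under no linkage. Sites are filtered (parental depth > 5; bulk depth
< 7, or SNP-index < 0.3 or > 0.7 in *both* bulks, removed), Δ is averaged
in 5-Mb windows advanced by 10 kb, and windows are compared against
Monte-Carlo confidence bands for Δ computed under the null hypothesis of no
QTL at each site's own read depth. Runs of windows exceeding the P < 0.05
band are reported as candidate QTL regions.

The package also reproduces the classical genetics arithmetic around such a
study: fertility grading (I–V; I–II sterile), observed fertile:sterile
ratios, Pearson goodness-of-fit χ² against Mendelian ratios (1:2:1, 1:1,
3:1, ...), and genotype × fertility summaries.

## Worked example

Simulate an F2 cross (two 150-Mb chromosomes, SNP every 10 kb; a dominant
main restorer at chr1:25 Mb and a partially penetrant second restorer QTL
at chr1:130 Mb; bulks of 30 fully fertile and 30 sterile `rf4rf4` plants at
~30× depth, parents at ~10×), then scan it:

```r
library(bsaqtl)
d   <- simulate_bsa_dataset(seed = 11)
fit <- qtlseq(d$variants, seed = 11,
              chrom_lengths = c(chr1 = 150e6, chr2 = 150e6))
fit
#> QTL-seq bulked-segregant scan
#>   sites retained: 21034 of 30000 input records
#>   windows: 28840 (5.0 Mb span, 10 kb step)
#>   candidate regions at P < 0.05 : 1
#>     chr1:106.59-154.73 Mb  peak delta = 0.506 at 136.81 Mb
```

One region is called, on the correct chromosome, containing the simulated
130-Mb locus; the window of largest Δ sits ~7 Mb from the truth, and the
unlinked chromosome is clean. `plot(fit)` draws the three index tracks
(FR, SM, Δ with the 95%/99% bands); `summary(fit)` reports the filter
accounting; `run_qtlseq()` writes the per-SNP TSV, per-window TSV,
candidate-region BED and the track plot.

Segregation statistics take plain counts:

```r
gof_chisq(c(327, 628, 291), c(1, 2, 1))
#> Goodness of fit vs 1:2:1: X-squared = 2.16, df = 2, p = 0.34
observed_ratio(1213, 33)
#> 1213 fertile : 33 sterile = 36.76:1
```

`cms_example_counts()` ships the fertility-grade and marker-genotype count
tables of a maize CMS-C restorer cross (two populations × two
environments) used throughout the examples and tests.

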