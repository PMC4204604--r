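# wgbsbias

Simulation and quantification of PCR amplification bias in whole-genome
bisulfite sequencing (WGBS).

## The problem

WGBS reads DNA methylation by converting unmethylated cytosines to
thymines (via uracil) while 5-methylcytosine is protected. The converted,
uracil-rich library is then PCR amplified with a uracil-tolerant
polymerase, and amplification efficiency depends on template GC content.
Methylated DNA retains its cytosines — and hence higher GC — through
conversion, so GC-greedy amplification systematically over-represents
reads from methylated DNA. The bias grows with PCR cycle number and
differs between polymerases, and the same GC dependence depletes AT-rich
heterochromatin in ordinary genomic libraries.

`wgbsbias` is for people who analyse or benchmark WGBS pipelines: it
simulates bisulfite (and genomic) libraries with a known, injected
GC-dependent amplification bias and full per-cytosine ground truth, and
implements the statistics used to measure such bias on real data, so that
the whole measurement chain can be validated as parameter recovery.

## The model and the statistics

A fragment with post-conversion GC fraction *g* is duplicated per PCR
cycle with efficiency

> e(g) = clamp(e₀ + γ·(min(g, s) − 0.5), 0, 1)

and accrues copy weight (1 + e(g))^C over C cycles; a library of depth
*d* is a multinomial draw of *d* reads with probabilities proportional to
these weights. Enzyme presets `pfu-like` (γ = 0.8), `kapa-like` (γ = 0)
and `epimark-like` (γ = 0.4, saturating at GC 0.6) span strong, absent
and high-GC-saturating bias.

The analysis stack mirrors standard WGBS practice:

* exact-match read placement in fully C→T-converted (three-letter)
  sequence space, discarding ambiguous reads;
* per-cytosine basecall pileups (C = methylated call, T = unmethylated);
* the non-conversion rate estimated from an unmethylated control contig
  and used as the null of a one-sided exact binomial test per site, with
  Benjamini–Hochberg correction at 5% FDR;
* weighted methylation levels, Σ n_meth / Σ n_total;
* normalized read coverage — region counts over library total ×10⁵, and
  per-window counts scaled by the first tile (or library total) — with
  enrichment measured against a C→T-converted genomic baseline;
* Pearson correlation and linear regression of scaled window coverage on
  weighted methylation after Bonferroni outlier trimming (externally
  studentized residuals, capped at 5% of points), plus log2 cycle-ratio
  profiles against window GC.

## Worked example

Simulate the cycle-number experiment under the strongly biased enzyme:
one 200 kb genome with a heterochromatin-to-gene methylation gradient,
one bisulfite-converted fragment pool, and libraries amplified for 4, 8
and 15 cycles (110,000 reads each, 50× coverage, 200 × 1 kb windows):

```r
library(wgbsbias)

cfg <- scenarioConfig("bias-pfu", seed = 1)
series <- runCycleSeries(cfg)
rep <- biasReport(series)
rep[, c("cycles", "slope", "slope_se", "r_squared", "n_used", "n_outliers")]
#>   cycles slope slope_se r_squared n_used n_outliers
#> 1      4 0.190   0.0541    0.0588    200          0
#> 2      8 0.414   0.0537    0.2314    200          0
#> 3     15 0.723   0.0645    0.3880    200          0

round(attr(rep, "correlations"), 3)
#>           cycles_4 cycles_8 cycles_15
#> cycles_4     1.000    0.808     0.688
#> cycles_8     0.808    1.000     0.874
#> cycles_15    0.688    0.874     1.000

series$perCycle[[1]]$nonConversion
#> Non-conversion rate: 0.0045292 (730 / 161178 control basecalls)
```

The slope is the fitted enrichment of scaled window coverage per unit
weighted methylation (the methylation axis is fixed to the 4-cycle
reference library, so points move only vertically between conditions):
positive at 4 cycles and roughly quadrupling by 15 cycles — methylated
windows are progressively over-sequenced. The correlation matrix shows
coverage profiles decorrelating as the cycle gap grows (0.81 for 4 vs 8,
0.69 for 4 vs 15). The non-conversion estimate recovers the simulated
0.005 failure rate from the unmethylated control contig. Rerunning with
`scenarioConfig("null-kapa", seed = 1)` (flat efficiency) gives slopes
statistically indistinguishable from zero.

`runPipeline(scenarioConfig("demo", outputDir = "out"))` runs the same
machinery end-to-end and writes FASTA/FASTQ, truth tables, placements,
per-cytosine counts, methylation calls, window summaries, enrichment
profiles and the bias report as plain text (0-based half-open
coordinates throughout).

## Package layout

* `R/` — S4 classes (`BisGenome`, `EnzymeProfile`, `FragmentPool`,
  `SimulatedLibrary`, `ConvertedIndex`, `RegressionResult`) and the
  module functions; methylomes, cytosine counts and window summaries are
  `GRanges` with documented metadata columns.
* `vignettes/wgbsbias-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and the design decisions.
* `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for the binomial tail, BH step-up and Pearson
  correlation.
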