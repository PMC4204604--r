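---
title: "Modelling and quantifying PCR amplification bias in WGBS libraries"
author: "wgbsbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying PCR amplification bias in WGBS libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgbsbias)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reads methylation states by
chemistry: sodium bisulfite deaminates unmethylated cytosines to uracil
(read as T after PCR) while 5-methylcytosine is protected. The converted
library must then be PCR amplified — bisulfite treatment degrades DNA and
uracil-rich template requires engineered uracil-tolerant polymerases — and
amplification efficiency depends on template GC content. Because
methylated DNA retains its cytosines through conversion, it retains
higher GC content than unmethylated copies of the same locus, so
GC-dependent amplification becomes *methylation*-dependent amplification:
reads from methylated DNA are over-represented, increasingly so at higher
cycle numbers, with a magnitude that depends on the polymerase. The same
GC dependence depletes AT-rich heterochromatin in ordinary genomic
libraries.

`wgbsbias` packages both halves of the problem: a seeded simulator that
injects a known amplification bias into synthetic bisulfite (or genomic)
libraries with full ground truth, and the analysis stack that measures
the bias — methylation calling, weighted methylation levels, normalized
window coverage, and the coverage-versus-methylation and
log2-ratio-versus-GC regressions. Everything the analysis reports on real
data can therefore be validated as parameter recovery on data whose truth
is known.

## The amplification model

PCR is modelled at the expectation level. A fragment with
post-conversion GC fraction $g$ has per-cycle duplication efficiency

$$e(g) = \mathrm{clamp}\!\left(e_0 + \gamma\,(\min(g, s) - 0.5),\ 0,\ 1\right)$$

and accrues copy weight $(1+e(g))^{C}$ over $C$ cycles. A library of
depth $d$ is a multinomial sample of $d$ reads with probabilities
proportional to the copy weights, which reintroduces the sampling
variance that the deterministic weights leave out. Per-cycle stochastic
duplication trees would add within-fragment lineage variance but do not
change expected enrichment, which is what the downstream statistics
measure; the cheaper model is documented as replaceable.

The enzyme profile parameters are:

| parameter | meaning | default |
|---|---|---|
| `baseEfficiency` ($e_0$) | efficiency at GC 0.5 (dimensionless, per cycle) | 0.5 |
| `gcCoefficient` ($\gamma$) | slope per unit GC fraction | preset-specific |
| `saturationGC` ($s$) | GC above which efficiency stops rising | none |

Three presets span the qualitative behaviours seen across commercial
uracil-tolerant polymerases: `pfu-like` ($\gamma = 0.8$, strong bias),
`kapa-like` ($\gamma = 0$, flat — the null instrument), and
`epimark-like` ($\gamma = 0.4$ saturating at GC 0.6, bias confined below
high GC). No published quantitative efficiency curve exists for any of
these enzymes; the numbers are modelling choices made once, calibrated
only to be qualitatively distinguishable at desk scale, and are not
measurements.

Relative enrichment between two fragments is
$\left(\frac{1+e(g_1)}{1+e(g_2)}\right)^{C}$, so the log2 coverage ratio
between cycle conditions grows linearly in the cycle difference — the
mechanism behind both the cycle-number escalation and the
log2-ratio-versus-GC slope.

## What the generator emulates

`generateGenome()` builds a main contig of `nRegions` blocks whose
expected GC interpolates a gradient, plus an unmethylated control contig
(the chloroplast stand-in, default GC 0.36). `generateMethylome()`
assigns every cytosine on both strands a methylation probability by
region and context (CG/CHG/CHH, H ∈ {A, C, T}), emulating the
heterochromatin-to-gene organisation of a plant chromosome arm: region 1
is the AT-rich, highly methylated extreme (defaults CG 0.9 / CHG 0.7 /
CHH 0.3), the last region the gene-like extreme (0.1 / 0.05 / 0.02).

Two GC regimes are bundled as scenario presets, because the sign of the
coverage-versus-methylation relationship depends on which force dominates
post-conversion GC:

* **Bisulfite scenarios** (`demo`, `null-kapa`, `bias-pfu`) use a narrow
  raw GC range (0.34–0.40), as in the *Arabidopsis* genome where
  heterochromatin and euchromatin differ little in raw GC. There,
  methylation dominates post-conversion GC — the methylated AT-rich end
  retains ~0.25 GC after conversion versus ~0.21 for the gene-like end —
  so a GC-greedy polymerase enriches methylated windows.
* **The genomic scenario** (`at-depletion`) uses the wide 30%–51.5% GC
  range of *Neurospora* heterochromatin versus genes. With no bisulfite
  conversion, raw GC drives the weights and AT-rich windows are depleted
  at high cycle numbers.

Fragmentation is uniform over start positions and strands
(`simulateFragments()`); conversion realizes each fragment's cytosines
independently — a Bernoulli draw at the truth probability, then a
non-conversion failure with probability `nonConversionRate` (default
0.005, a typical plant WGBS value) — so molecules overlapping a site are
independent, as they are in a real library.

Deliberately **not** emulated: sequencing error, read trimming, paired
ends, indels/SNPs, strand-asymmetric library chemistry, per-cycle
duplication stochasticity, and insert-size variation (reads are whole
fragments of one length). Passing tests therefore demonstrate that the
statistics recover a bias of this mechanistic form; they do not
demonstrate robustness to alignment error or sequence polymorphism,
which real data add on top.

## The analysis stack

**Placement** is exact full-length matching in fully converted
(three-letter) space: each read is C→T converted and looked up in the
converted plus strand and converted reverse complement of every contig.
Zero or multiple hits discard the read (the unique-alignment convention);
on repeat-free simulated genomes ≥99% of reads place at their true
origin. Exactness is honest here because simulated reads are error-free;
mismatch tolerance would only blur the round-trip contract.

**Pileup and calling.** For each reference cytosine covered on its
strand, C basecalls count as methylated, T as unmethylated, anything else
is ignored. The non-conversion rate is the pooled methylated-basecall
fraction on the control contig, and is the null rate of a one-sided
exact binomial test per site — one-sided because conversion failure can
only inflate methylated calls, exact because WGBS coverage is small.
P-values are corrected by Benjamini–Hochberg step-up at 5% FDR, jointly
across all tested sites by default; per-context batching is available
(`byContext = TRUE`) since the original pipelines do not document their
batching. Sites below `minCoverage` (default 1) are reported untested
rather than silently dropped. Weighted methylation is
$\sum n_{meth} / \sum n_{total}$ — coverage-weighted, never the mean of
per-site fractions — and is reported as missing (not 0) for windows with
no basecalls.

**Coverage normalization.** Region-level normalized coverage is
reads-in-region over library total, ×10⁵. Windowed profiles divide each
window's read count (reads assigned by start coordinate, half-open
windows) by the first tile's count; because a zero or atypical first
window breaks that anchor, library-total scaling is provided as
`scaling = "total"`. Enrichment against a genomic baseline subtracts the
scaled window counts of a non-bisulfite library whose reads are fully
C→T converted and run through the same placement pipeline, isolating
conversion/amplification effects from mappability. The pipeline's
baseline library is sampled at 0 cycles — an unamplified, hence unbiased,
mappability control.

**Bias statistics.** The headline fit is scaled window coverage against
weighted methylation. When comparing cycle conditions the methylation
axis is taken from a designated reference condition (fewest cycles), so
points move only vertically between panels — higher coverage inflates
observed methylation, and a shared axis removes that coupling from the
comparison. Before the fit, outliers are flagged by Bonferroni-adjusted
externally studentized residuals (two-sided t, $n-3$ df, adjusted by the
current $n$), removed one at a time with refitting — standard
outlier-test practice — and capped at `ceiling(0.05 n)` points; a
one-shot mode flags from a single fit. The cap and the residual test are
two constraints honoured simultaneously because the original description
("Bonferroni test", "5% outliers") underdetermines their combination;
whether the published analysis refit between removals is equally
unstated, so both modes exist and the iterative one is the default.
All reported $R^2$ are squared Pearson coefficients, matching the
convention of the figure panels this reproduces.

## Numerical and convention choices

* Coordinates are 1-based closed inside R (the GRanges convention); every
  emitted file (BED, bedGraph, all TSVs) is 0-based half-open. A
  cross-file test asserts the convention.
* Window GC profiles use expected (probability-weighted) cytosine
  retention, not one Bernoulli realization: the profile is a property of
  the methylome, not of a particular library. Realized conversion lives
  in the simulator. Post-conversion GC is reported for the plus strand;
  it is not strand-symmetric after conversion.
* A cytosine whose context extends past the contig end is classed CHH.
* Terminal partial windows keep their true length as denominator.
* Zero-count windows are excluded from log-ratio fits (missing, not
  pseudocounted); a +0.5 pseudocount option exists.
* Degenerate inputs are reported as missing (`NA`) where the quantity is
  undefined — Pearson under zero variance, weighted methylation with no
  basecalls — and as errors where the computation cannot proceed (zero
  control-contig coverage, zero first tile).
* All stochastic steps take an explicit integer seed and restore the
  caller's RNG state; the whole pipeline is a pure function of its
  configuration, and reruns are byte-identical.

## Problem sizes

The bundled scenarios are sized so the full replicate experiments run in
minutes on one core: a 200 kb main contig (20 regions × 10 kb) plus a
20 kb control contig, 30,000 fragments of 100 bp per pool, 110,000 reads
per library (50× coverage), 200 analysis windows of 1 kb, cycle
conditions {4, 8, 15}, and 20 replicate library seeds per scenario
against a single fixed genome — one genome, many libraries, as in a
sequencing replicate design. The `demo` scenario (100 kb, 20,000 reads)
exercises the full pipeline end-to-end in seconds.

## Known limitations

* The efficiency function is linear-with-clamp by design; real
  polymerase GC response curves are smoother and enzyme-specific. The
  profile class isolates this choice so a measured curve could be dropped
  in.
* Exact-match placement understates the read loss real aligners incur;
  absolute coverage levels are therefore optimistic, though scaled
  comparisons are unaffected.
* First-tile scaling inherits the fragility of its anchor window; the
  total-count alternative changes the scale but not any correlation or
  slope sign.
* The simulator's uniform fragmentation ignores the sequence-dependent
  shearing and size selection of real library preparation.
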