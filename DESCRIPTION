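Package: wgbsbias
Title: Simulation and Quantification of PCR Amplification Bias in
    Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-genome bisulfite sequencing (WGBS) libraries are PCR
    amplified, and amplification efficiency depends on the GC content of
    the bisulfite-converted template; because methylated cytosines are
    protected from conversion, methylated DNA retains higher GC content
    and is preferentially amplified. wgbsbias provides a seeded simulator
    of bisulfite libraries with a GC-dependent per-cycle amplification
    model and full ground truth, together with the analysis stack used to
    quantify the resulting enrichment: in silico bisulfite conversion and
    windowed GC profiles, exact-match read placement in converted sequence
    space, per-cytosine basecall pileups, binomial methylation calling
    against a control-contig non-conversion null with Benjamini-Hochberg
    correction, weighted methylation levels, normalized window coverage
    with first-tile or library-size scaling, enrichment against a
    converted genomic baseline, log2 cycle-ratio profiles versus GC, and
    outlier-trimmed coverage-versus-methylation regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, Sequencing, Software
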