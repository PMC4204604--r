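test_that("tables, truth, counts and placements round-trip losslessly", {
  tmp <- withr::local_tempdir()
  g <- generateGenome(2, 500, c(0.35, 0.45), 300, seed = 121)
  truth <- generateMethylome(g, cbind(CG = c(0.9, 0.1), CHG = c(0.7, 0.05),
                                      CHH = c(0.3, 0.02)))
  f1 <- file.path(tmp, "truth.tsv")
  writeTruthTsv(truth, f1)
  back <- readTruthTsv(f1)
  expect_equal(start(back), start(truth))
  expect_equal(as.character(strand(back)), as.character(strand(truth)))
  expect_equal(mcols(back)$prob, mcols(truth)$prob)
  expect_equal(as.character(mcols(back)$context),
               as.character(mcols(truth)$context))

  pool <- simulateFragments(g, 300, 60, seed = 122)
  cp <- bisulfiteConvert(pool, truth, 0.01, seed = 123)
  idx <- buildConvertedIndex(g)
  pl <- placeReads(cp, idx)
  cts <- pileupCytosines(pl, cp, g)
  f2 <- file.path(tmp, "counts.tsv")
  writeCountsTsv(cts, f2)
  back2 <- readCountsTsv(f2)
  expect_equal(mcols(back2)$n_meth, mcols(cts)$n_meth)
  expect_equal(mcols(back2)$n_total, mcols(cts)$n_total)
  expect_equal(start(back2), start(cts))

  f3 <- file.path(tmp, "placements.tsv")
  writePlacementsTsv(pl, f3)
  back3 <- readPlacementsTsv(f3)
  expect_equal(back3$start, pl$start)
  expect_equal(back3$placed, pl$placed)

  sm <- summarizeWindows(pl, cts, g, truth, 250, contigs = "chr_sim")
  f4 <- file.path(tmp, "windows.tsv")
  writeWindowSummaryTsv(sm, f4)
  back4 <- readWindowSummaryTsv(f4)
  expect_equal(mcols(back4)$scaled_count, mcols(sm)$scaled_count)
  expect_equal(mcols(back4)$weighted_mC, mcols(sm)$weighted_mC)
  expect_equal(start(back4), start(sm))
})

test_that("FASTA and FASTQ round-trip and coordinates stay 0-based", {
  tmp <- withr::local_tempdir()
  g <- generateGenome(2, 500, c(0.35, 0.45), 300, seed = 131)
  fa <- file.path(tmp, "genome.fa")
  writeGenomeFasta(g, fa)
  g2 <- readGenomeFasta(fa, controlContig(g))
  expect_identical(as.character(genomeSequences(g2)),
                   as.character(genomeSequences(g)))

  truth <- generateMethylome(g, cbind(CG = c(1, 1), CHG = c(1, 1),
                                      CHH = c(1, 1)))
  ft <- file.path(tmp, "truth.tsv")
  writeTruthTsv(truth, ft)
  df <- readTsv(ft)
  # cross-file 0-based convention: pos0 + 1 lands on a C (+) or G (-)
  seqs <- as.character(genomeSequences(g2)[["chr_sim"]])
  onMain <- df[df$contig == "chr_sim", ]
  base <- substring(seqs, onMain$pos0 + 1, onMain$pos0 + 1)
  expect_true(all(base == ifelse(onMain$strand == "+", "C", "G")))

  pool <- newFragmentPool("chr_sim", c(1, 11), c("+", "+"),
                          c("ACGTACGTAA", "TTTTACGTAC"))
  lib <- new("SimulatedLibrary", reads = readSequences(pool),
             origins = data.frame(read_id = c("r1", "r2"),
                                  contig = "chr_sim", start = c(1L, 11L),
                                  strand = "+", stringsAsFactors = FALSE),
             cycles = 0L, enzyme = "none",
             nonConversionRate = NA_real_, seed = 0L)
  fq <- file.path(tmp, "reads.fastq")
  writeLibraryFastq(lib, fq)
  back <- readLibraryFastq(fq)
  expect_equal(back$sequence, readSequences(pool))
  expect_equal(back$read_id, c("r1", "r2"))

  writeLines(c("@bad", "ACGX", "+", "IIII"), file.path(tmp, "bad.fastq"))
  expect_error(readLibraryFastq(file.path(tmp, "bad.fastq")), "line 2")
})

test_that("BED windows are 0-based half-open", {
  tmp <- withr::local_tempdir()
  bed <- file.path(tmp, "w.bed")
  writeLines("chr1\t0\t10000", bed)
  w <- readBedWindows(bed)
  expect_equal(start(w), 1L)
  expect_equal(end(w), 10000L)
  expect_equal(width(w), 10000L)
  g <- literalGenome(c(main = strrep("ACGT", 250), ctrl = strrep("AT", 50)))
  w2 <- makeWindows(g, 500)
  bed2 <- file.path(tmp, "w2.bed")
  writeBedWindows(w2, bed2)
  back <- readBedWindows(bed2)
  expect_equal(start(back), start(w2))
  expect_equal(end(back), end(w2))
})

test_that("configs are validated before any stage runs", {
  expect_error(scenarioConfig("demo", fdr = 0), "fdr")
  expect_error(scenarioConfig("demo", nonConversionRate = 1), "nonConversionRate")
  expect_error(scenarioConfig("demo", cycles = c(4L, 4L)), "duplicate")
  expect_error(scenarioConfig("demo", scaling = "median"), "scaling")
  expect_error(runPipeline(scenarioConfig("demo", fdr = 0.5)), "outputDir")
  cfg <- scenarioConfig("demo", seed = 3)
  expect_s3_class(cfg, "RunConfig")
  expect_equal(cfg$cycles, c(4L, 8L, 15L))
})

test_that("the pipeline writes all artifacts and reruns byte-identically", {
  tmp <- withr::local_tempdir()
  cfg <- tinyConfig(cycles = c(0L, 8L), depth = 3000L,
                    outputDir = file.path(tmp, "run1"))
  res <- runPipeline(cfg, quiet = TRUE)
  expect_true(file.exists(file.path(tmp, "run1", "config.yaml")))
  expect_true(file.exists(file.path(tmp, "run1", "genome.fa")))
  expect_true(file.exists(file.path(tmp, "run1", "truth.tsv")))
  expect_true(file.exists(file.path(tmp, "run1", "windows.bed")))
  expect_true(file.exists(file.path(tmp, "run1", "bias_report.tsv")))
  expect_true(file.exists(file.path(tmp, "run1", "cycle_correlations.tsv")))
  expect_true(file.exists(file.path(tmp, "run1", "run.log")))
  expect_true(file.exists(file.path(tmp, "run1",
                                    "log2_ratio_8_vs_0.tsv")))
  for (d in c("cycles_00", "cycles_08")) {
    for (f in c("reads.fastq", "read_origins.tsv", "placements.tsv",
                "cytosine_counts.tsv", "methylation_calls.tsv",
                "methylation_fraction.bedGraph", "window_summary.tsv",
                "weighted_mC.bedGraph", "enrichment.tsv",
                "enrichment.bedGraph"))
      expect_true(file.exists(file.path(tmp, "run1", d, f)),
                  info = file.path(d, f))
  }
  expect_s3_class(res$biasReport, "data.frame")

  cfg2 <- cfg
  cfg2$outputDir <- file.path(tmp, "run2")
  runPipeline(cfg2, quiet = TRUE)
  rel <- list.files(file.path(tmp, "run1"), recursive = TRUE)
  rel <- rel[grepl("\\.(tsv|bed|bedGraph|fa|fastq)$", rel)]
  for (f in rel) {
    expect_identical(unname(tools::md5sum(file.path(tmp, "run1", f))),
                     unname(tools::md5sum(file.path(tmp, "run2", f))),
                     info = f)
  }
})
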