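test_that("region normalized coverage is reads/total scaled by 1e5", {
  expect_equal(regionNormalizedCoverage(20, 2e6), 1.0)
  expect_equal(regionNormalizedCoverage(0, 12345), 0.0)
  expect_equal(regionNormalizedCoverage(2e6, 2e6), 1e5)
  # invariance under duplicating every read
  expect_equal(regionNormalizedCoverage(37, 1000),
               regionNormalizedCoverage(74, 2000))
  expect_error(regionNormalizedCoverage(5, 0), "totalReads")
  expect_error(regionNormalizedCoverage(10, 5), "readsInRegion")
})

test_that("reads are assigned to windows by start coordinate, half-open", {
  g <- generateGenome(3, 10000, c(0.4, 0.4), 1000, seed = 111)
  windows <- makeWindows(g, 10000, contigs = "chr_sim")
  mkpl <- function(start1) data.frame(
    read_id = sprintf("r%d", seq_along(start1)), contig = "chr_sim",
    start = start1, strand = "+", width = 100L, placed = TRUE,
    reason = "unique", stringsAsFactors = FALSE)
  # 0-based 9,999 = 1-based 10,000 -> still the first window
  expect_equal(countReadsInWindows(mkpl(10000L), windows), c(1L, 0L, 0L))
  # 0-based 10,000 = 1-based 10,001 -> second window
  expect_equal(countReadsInWindows(mkpl(10001L), windows), c(0L, 1L, 0L))
  cnt <- countReadsInWindows(mkpl(rep(5L, 100)), windows)
  expect_equal(cnt, c(100L, 0L, 0L))
  expect_equal(sum(cnt), 100L)
})

test_that("window tiling covers each contig with a true-length last tile", {
  g <- literalGenome(c(main = strrep("ACGT", 260), ctrl = strrep("AT", 50)))
  w <- makeWindows(g, 400)
  main <- w[seqnames(w) == "main"]
  expect_equal(width(main), c(400L, 400L, 240L))
  expect_equal(start(main), c(1L, 401L, 801L))
})

test_that("first-tile scaling anchors the first window at 1", {
  expect_equal(scaleByFirstTile(c(100, 50, 200)), c(1, 0.5, 2))
  expect_equal(scaleByFirstTile(7), 1)
  expect_error(scaleByFirstTile(c(0, 5)), "scaleByTotal")
  expect_equal(scaleByTotal(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  # identical libraries scale identically
  expect_identical(scaleByFirstTile(c(10, 20, 30)),
                   scaleByFirstTile(c(10, 20, 30)))
})

test_that("enrichment is the windowwise difference of scaled counts", {
  g <- literalGenome(c(main = strrep("ACGT", 250), ctrl = strrep("AT", 50)))
  w <- makeWindows(g, 500, contigs = "main")
  e0 <- enrichmentVsGenomic(c(1, 2), c(1, 2), w)
  expect_equal(mcols(e0)$enrichment, c(0, 0))
  e1 <- enrichmentVsGenomic(c(1.5, 1), c(1.0, 1), w)
  expect_equal(mcols(e1)$enrichment[1], 0.5)
  expect_error(enrichmentVsGenomic(1, c(1, 2), w), "mismatch")
})

test_that("unbiased libraries show enrichment within the null band", {
  cfg <- tinyConfig(enzyme = "kapa-like", cycles = c(8L))
  g <- generateGenome(cfg$nRegions, cfg$regionLength, cfg$gcGradient,
                      cfg$controlLength, seed = 500)
  truth <- generateMethylome(g, wgbsbias:::defaultMethylation(4))
  idx <- buildConvertedIndex(g)
  enr <- sapply(1:20, function(s) {
    cfgS <- cfg
    cfgS$seed <- 1000L + s
    series <- runCycleSeries(cfgS, genome = g, truth = truth)
    bis <- mcols(series$perCycle[[1]]$summary)$scaled_count
    genPool <- simulateFragments(g, cfg$nFragments, cfg$fragmentLength,
                                 seed = 2000L + s)
    genPool@sequences <- convertFull(genPool@sequences)
    genPl <- placeReads(genPool, idx)
    genC <- countReadsInWindows(genPl, granges(series$perCycle[[1]]$summary))
    e <- enrichmentVsGenomic(bis, scaleByFirstTile(genC),
                             granges(series$perCycle[[1]]$summary))
    c(mean(abs(mcols(e)$enrichment)), sd(mcols(e)$bis_scaled))
  })
  expect_lt(mean(enr[1, ]), 3 * mean(enr[2, ]))
})

test_that("log2 cycle ratios handle equality, doubling and missing", {
  g <- literalGenome(c(main = strrep("ACGT", 250), ctrl = strrep("AT", 50)))
  w <- makeWindows(g, 500, contigs = "main")
  lr <- log2CycleRatio(c(1, 1), c(1, 2), w, gc = c(0.4, 0.5))
  expect_equal(mcols(lr)$log2_ratio, c(0, 1))
  lr0 <- log2CycleRatio(c(0, 1), c(1, 1), w, gc = c(0.4, 0.5))
  expect_true(is.na(mcols(lr0)$log2_ratio[1]))
  lrp <- log2CycleRatio(c(0, 1), c(1, 1), w, gc = c(0.4, 0.5),
                        pseudocount = 0.5)
  expect_false(anyNA(mcols(lrp)$log2_ratio))
})

test_that("window summaries report coverage even without cytosines", {
  g <- literalGenome(c(main = paste0(strrep("AT", 250),
                                     strrep("ACGT", 125)),
                       ctrl = strrep("AT", 50)),
                     regionLength = 500L)
  truth <- cytosineSites(g)
  mcols(truth)$prob <- ifelse(
    as.character(seqnames(truth)) == "ctrl", 0, 1)
  pl <- data.frame(read_id = c("a", "b"), contig = "main",
                   start = c(10L, 600L), strand = "+", width = 20L,
                   placed = TRUE, reason = "unique",
                   stringsAsFactors = FALSE)
  reads <- c(substring(as.character(genomeSequences(g)[["main"]]), 10, 29),
             substring(as.character(genomeSequences(g)[["main"]]), 600, 619))
  cts <- pileupCytosines(pl, reads, g)
  sm <- summarizeWindows(pl, cts, g, truth, 500, contigs = "main")
  expect_equal(mcols(sm)$read_count, c(1L, 1L))
  expect_true(is.na(mcols(sm)$weighted_mC[1]))  # AT-only window
  expect_equal(mcols(sm)$weighted_mC[2], 1.0)   # fully methylated window
  expect_equal(mcols(sm)$gc_raw[1], 0)
})

test_that("high-methylation windows gain coverage under a biased enzyme", {
  meth <- cbind(CG = c(0.9, 0.9, 0.1, 0.1), CHG = c(0.7, 0.7, 0.05, 0.05),
                CHH = c(0.3, 0.3, 0.02, 0.02))
  cfg <- tinyConfig(methylation = meth, enzyme = "pfu-like",
                    cycles = c(15L))
  g <- generateGenome(cfg$nRegions, cfg$regionLength, cfg$gcGradient,
                      cfg$controlLength, seed = 510)
  truth <- generateMethylome(g, meth)
  diffs <- vapply(1:20, function(s) {
    cfgS <- cfg
    cfgS$seed <- 3000L + s
    series <- runCycleSeries(cfgS, genome = g, truth = truth)
    sm <- series$perCycle[[1]]$summary
    hi <- start(sm) <= 4000
    mean(mcols(sm)$scaled_count[hi]) - mean(mcols(sm)$scaled_count[!hi])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("read-count totals are conserved across windowing", {
  cfg <- tinyConfig(cycles = c(4L))
  series <- runCycleSeries(cfg)
  pc <- series$perCycle[[1]]
  windows <- makeWindows(series$genome, cfg$windowSize)
  cnt <- countReadsInWindows(pc$placements, windows)
  expect_equal(sum(cnt), sum(pc$placements$placed))
})
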