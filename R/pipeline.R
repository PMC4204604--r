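#' Build and validate a simulation-and-analysis run configuration
#'
#' Scenario presets bundle the study conditions:
#' \describe{
#'   \item{`"demo"`}{small end-to-end run: 100 kb main contig, 3 cycle
#'     conditions, 20,000 reads.}
#'   \item{`"null-kapa"`}{flat-efficiency null (kapa-like, no GC bias):
#'     200 kb main contig, 200 windows of 1 kb, 50x read coverage.}
#'   \item{`"bias-pfu"`}{same genome under the strongly GC-biased
#'     pfu-like profile — the cycle-number enrichment experiment.}
#'   \item{`"at-depletion"`}{genomic (non-bisulfite) library under the
#'     pfu-like profile, cycles 4 vs 15 — the AT-rich depletion
#'     experiment.}
#' }
#' Any field can be overridden. All fields are validated here, before any
#' stage runs.
#'
#' @param scenario Preset name.
#' @param ... Field overrides: `nRegions`, `regionLength`, `gcGradient`,
#'   `controlLength`, `controlGC`, `methylation` (per-region CG/CHG/CHH
#'   matrix, or NULL for the default heterochromatin-to-gene gradient),
#'   `enzyme`, `cycles`, `depth`, `nonConversionRate`, `fragmentLength`,
#'   `nFragments`, `windowSize`, `fdr`, `minCoverage`, `scaling`,
#'   `libraryType` ("bisulfite" or "genomic"), `seed`, `outputDir`.
#' @return A validated config list of class `"RunConfig"`.
#' @examples
#' cfg <- scenarioConfig("demo", seed = 11)
#' @export
scenarioConfig <- function(scenario = c("demo", "null-kapa", "bias-pfu",
                                        "at-depletion"), ...) {
  scenario <- match.arg(scenario)
  base <- list(scenario = scenario,
               nRegions = 10L, regionLength = 10000L,
               gcGradient = c(0.34, 0.40),
               controlLength = 10000L, controlGC = 0.36,
               methylation = NULL,
               enzyme = "pfu-like",
               cycles = c(4L, 8L, 15L),
               depth = 20000L,
               nonConversionRate = 0.005,
               fragmentLength = 100L,
               nFragments = 10000L,
               windowSize = 1000L,
               fdr = 0.05, minCoverage = 1L,
               scaling = "first-tile",
               libraryType = "bisulfite",
               seed = 1L, outputDir = NULL)
  preset <- switch(scenario,
    "demo" = list(),
    "null-kapa" = list(nRegions = 20L, controlLength = 20000L,
                       enzyme = "kapa-like", depth = 110000L,
                       nFragments = 30000L),
    "bias-pfu" = list(nRegions = 20L, controlLength = 20000L,
                      enzyme = "pfu-like", depth = 110000L,
                      nFragments = 30000L),
    "at-depletion" = list(nRegions = 20L, controlLength = 20000L,
                          gcGradient = c(0.30, 0.515),
                          enzyme = "pfu-like", cycles = c(4L, 15L),
                          depth = 110000L, nFragments = 30000L,
                          libraryType = "genomic"))
  cfg <- utils::modifyList(base, preset)
  cfg <- utils::modifyList(cfg, list(...))
  validateConfig(cfg)
}

#' @rdname scenarioConfig
#' @param config A config list to validate.
#' @export
validateConfig <- function(config) {
  asCount(config$nRegions, "nRegions", min = 2)
  asCount(config$regionLength, "regionLength", min = 100)
  asCount(config$controlLength, "controlLength", min = 1)
  if (length(config$gcGradient) != 2L)
    stop("gcGradient must be a pair")
  for (g in config$gcGradient)
    asFraction(g, "gcGradient", 0, 1, open_lo = TRUE, open_hi = TRUE)
  if (!is.null(config$methylation)) {
    m <- as.matrix(as.data.frame(config$methylation))
    if (nrow(m) != config$nRegions)
      stop("methylation must have one row per region")
  }
  if (!is(config$enzyme, "EnzymeProfile") &&
      !(is.character(config$enzyme) && length(config$enzyme) == 1L))
    stop("enzyme must be a profile or preset name")
  if (!length(config$cycles)) stop("at least one cycle condition needed")
  for (cc in config$cycles) asCount(cc, "cycles", min = 0)
  if (anyDuplicated(config$cycles)) stop("duplicate cycle conditions")
  asCount(config$depth, "depth", min = 1)
  asFraction(config$nonConversionRate, "nonConversionRate", 0, 1,
             open_hi = TRUE)
  asCount(config$fragmentLength, "fragmentLength", min = 1)
  asCount(config$nFragments, "nFragments", min = 1)
  asCount(config$windowSize, "windowSize", min = 1)
  asFraction(config$fdr, "fdr", 0, 1, open_lo = TRUE, open_hi = TRUE)
  asCount(config$minCoverage, "minCoverage", min = 1)
  if (!config$scaling %in% c("first-tile", "total"))
    stop("scaling must be 'first-tile' or 'total'")
  if (!config$libraryType %in% c("bisulfite", "genomic"))
    stop("libraryType must be 'bisulfite' or 'genomic'")
  asCount(config$seed, "seed", min = 0)
  class(config) <- c("RunConfig", "list")
  config
}

# Heterochromatin-to-gene methylation gradient: region 1 is the AT-rich,
# highly methylated extreme; the last region the gene-like extreme.
defaultMethylation <- function(nRegions) {
  cbind(CG = seq(0.9, 0.1, length.out = nRegions),
        CHG = seq(0.7, 0.05, length.out = nRegions),
        CHH = seq(0.3, 0.02, length.out = nRegions))
}

#' Simulate and analyse one scenario across its PCR cycle conditions
#'
#' The engine behind the cycle-number experiments: generates (or reuses)
#' the genome and methylome, shears one fragment pool, bisulfite-converts
#' it (unless the scenario is a genomic library), and for each cycle
#' condition amplifies, samples, places and piles up a library, then
#' summarizes windows on the main contig. Placement is done once for the
#' pool: every read is a copy of a pool fragment, so its placement is the
#' fragment's.
#'
#' @param config A `"RunConfig"` from [scenarioConfig()].
#' @param genome,truth Optionally reuse a genome/methylome (e.g. across
#'   replicate library seeds); generated from the config seed otherwise.
#' @return A list with `config`, `genome`, `truth`, `pool`, `index`,
#'   `poolPlacements`, and `perCycle`: one entry per cycle condition with
#'   `cycles`, `placements`, `counts`, `summary`
#'   ([summarizeWindows()] on the main contig), `nonConversion`
#'   (control-contig estimate; bisulfite libraries only) and `totalReads`.
#' @export
runCycleSeries <- function(config, genome = NULL, truth = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(genome))
    genome <- generateGenome(config$nRegions, config$regionLength,
                             config$gcGradient, config$controlLength,
                             seed = config$seed,
                             controlGC = config$controlGC)
  meth <- if (is.null(config$methylation))
    defaultMethylation(config$nRegions) else config$methylation
  if (is.null(truth)) truth <- generateMethylome(genome, meth)
  enzyme <- if (is(config$enzyme, "EnzymeProfile")) config$enzyme else
    enzymeProfile(config$enzyme)

  pool <- simulateFragments(genome, config$nFragments,
                            config$fragmentLength, seed = config$seed + 1L)
  if (config$libraryType == "bisulfite")
    pool <- bisulfiteConvert(pool, truth, config$nonConversionRate,
                             seed = config$seed + 2L)
  index <- buildConvertedIndex(genome)
  sites <- cytosineSites(genome)
  poolPl <- placeReads(pool, index)

  mainContigs <- setdiff(names(genome@sequences), genome@controlContig)
  perCycle <- vector("list", length(config$cycles))
  names(perCycle) <- paste0("cycles_", config$cycles)
  for (i in seq_along(config$cycles)) {
    cyc <- config$cycles[i]
    lib <- amplifyAndSample(pool, enzyme, cyc, config$depth,
                            seed = config$seed + 10L + i)
    # reads are pool fragments: inherit the pool placements
    m <- match(lib@reads, pool@sequences)
    pl <- poolPl[m, , drop = FALSE]
    pl$read_id <- lib@origins$read_id
    rownames(pl) <- NULL
    counts <- pileupCytosines(pl, lib@reads, genome, sites)
    summary <- summarizeWindows(pl, counts, genome, truth,
                                config$windowSize,
                                scaling = config$scaling,
                                contigs = mainContigs)
    ncr <- if (config$libraryType == "bisulfite")
      estimateNonconversion(counts, genome@controlContig) else NULL
    perCycle[[i]] <- list(cycles = cyc, library = lib, placements = pl,
                          counts = counts, summary = summary,
                          nonConversion = ncr,
                          totalReads = length(lib@reads))
  }
  list(config = config, genome = genome, truth = truth, pool = pool,
       index = index, poolPlacements = poolPl, perCycle = perCycle)
}

#' Coverage-versus-methylation bias report for a cycle series
#'
#' For each cycle condition, fits the outlier-trimmed regression of
#' scaled window coverage on weighted methylation. The methylation axis
#' is taken from a designated reference condition (default: the fewest
#' cycles), fixing the x-coordinates so points can only move vertically
#' between conditions; and the pairwise Pearson correlation of scaled
#' window counts across conditions is attached.
#'
#' @param series Result of [runCycleSeries()].
#' @param referenceCycle Cycle count whose summary provides the
#'   methylation axis (default: the smallest).
#' @param alpha,maxFraction Outlier-trim parameters
#'   ([trimmedRegression()]).
#' @param xVar Predictor: `"weighted_mC"` (default) or one of the GC
#'   columns (for genomic libraries, which have no methylation axis, the
#'   default falls back to `"gc_raw"`).
#' @return data.frame with one row per cycle condition: `cycles`,
#'   `slope`, `slope_se`, `slope_t`, `r`, `r_squared`, `n_used`,
#'   `n_outliers`; the correlation matrix is in
#'   `attr(, "correlations")` and the fits in `attr(, "fits")`.
#' @export
biasReport <- function(series, referenceCycle = NULL, alpha = 0.05,
                       maxFraction = 0.05, xVar = NULL) {
  cycles <- vapply(series$perCycle, `[[`, numeric(1), "cycles")
  if (is.null(xVar))
    xVar <- if (series$config$libraryType == "genomic") "gc_raw" else
      "weighted_mC"
  if (is.null(referenceCycle)) referenceCycle <- min(cycles)
  ref <- series$perCycle[[which(cycles == referenceCycle)[1]]]
  x <- mcols(ref$summary)[[xVar]]
  fits <- lapply(series$perCycle, function(pc)
    trimmedRegression(x, mcols(pc$summary)$scaled_count,
                      alpha = alpha, maxFraction = maxFraction))
  scaled <- lapply(series$perCycle, function(pc)
    mcols(pc$summary)$scaled_count)
  names(scaled) <- sprintf("cycles_%d", cycles)
  out <- data.frame(
    cycles = cycles,
    slope = vapply(fits, function(f) f@slope, numeric(1)),
    slope_se = vapply(fits, function(f) f@slopeSE, numeric(1)),
    slope_t = vapply(fits, function(f) f@slopeT, numeric(1)),
    r = vapply(fits, function(f) f@r, numeric(1)),
    r_squared = vapply(fits, function(f) f@rSquared, numeric(1)),
    n_used = vapply(fits, function(f) f@nUsed, integer(1)),
    n_outliers = vapply(fits, function(f) length(f@outlierIndices),
                        integer(1)),
    row.names = NULL)
  attr(out, "correlations") <- cycleCorrelationMatrix(scaled)
  attr(out, "fits") <- fits
  out
}

#' Run the full simulation-and-analysis pipeline and write its artifacts
#'
#' End-to-end composition: genome and methylome generation, per-cycle
#' library simulation, converted-space placement, cytosine pileup,
#' methylation calling against the control-contig non-conversion null,
#' window summaries, enrichment against an unamplified genomic baseline,
#' log2 cycle-ratio profiles, and the bias report. All outputs are plain
#' text (FASTA/FASTQ/BED/bedGraph and '#'-headed TSV, 0-based half-open
#' coordinates) under `config$outputDir`, with the resolved configuration
#' and a run log; the pipeline is a pure function of the config, so
#' reruns produce byte-identical tables.
#'
#' @param config A `"RunConfig"` from [scenarioConfig()] with a non-NULL
#'   `outputDir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [runCycleSeries()] result with added elements
#'   `biasReport` and `outputDir`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  config <- validateConfig(config)
  if (is.null(config$outputDir)) stop("config$outputDir is required")
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outputDir, ...)
  say <- function(...) if (!quiet) message(...)
  logLines <- c(sprintf("wgbsbias %s | R %s.%s",
                        as.character(utils::packageVersion("wgbsbias")),
                        R.version$major, R.version$minor),
                sprintf("scenario=%s seed=%d", config$scenario,
                        config$seed))

  cfgOut <- config
  cfgOut$enzyme <- if (is(config$enzyme, "EnzymeProfile"))
    config$enzyme@name else config$enzyme
  yaml::write_yaml(unclass(cfgOut), out("config.yaml"))

  say("simulating scenario '", config$scenario, "'")
  series <- runCycleSeries(config)
  writeGenomeFasta(series$genome, out("genome.fa"))
  writeTruthTsv(series$truth, out("truth.tsv"))
  windows <- makeWindows(series$genome, config$windowSize)
  writeBedWindows(windows, out("windows.bed"))

  # unamplified genomic baseline through the same converted-space pipeline
  genPool <- simulateFragments(series$genome, config$nFragments,
                               config$fragmentLength,
                               seed = config$seed + 5L)
  genPool@sequences <- convertFull(genPool@sequences)
  genPl <- placeReads(genPool, series$index)
  mainContigs <- setdiff(names(series$genome@sequences),
                         series$genome@controlContig)
  mainWindows <- windows[as.character(seqnames(windows)) %in% mainContigs]
  genCounts <- countReadsInWindows(genPl, mainWindows)
  genScaled <- if (config$scaling == "first-tile")
    scaleByFirstTile(genCounts) else scaleByTotal(genCounts)

  for (pc in series$perCycle) {
    d <- out(sprintf("cycles_%02d", pc$cycles))
    dir.create(d, showWarnings = FALSE)
    say("  writing cycle condition ", pc$cycles)
    writeLibraryFastq(pc$library, file.path(d, "reads.fastq"))
    writeTsv(within(pc$library@origins, start <- start - 1L),
             file.path(d, "read_origins.tsv"))
    writePlacementsTsv(pc$placements, file.path(d, "placements.tsv"))
    writeCountsTsv(pc$counts, file.path(d, "cytosine_counts.tsv"))
    if (config$libraryType == "bisulfite") {
      calls <- callMethylation(pc$counts, pc$nonConversion,
                               fdr = config$fdr,
                               minCoverage = config$minCoverage,
                               controlContig = series$genome@controlContig)
      writeTsv(data.frame(contig = as.character(seqnames(calls)),
                          pos0 = start(calls) - 1L,
                          strand = as.character(strand(calls)),
                          context = as.character(mcols(calls)$context),
                          n_meth = mcols(calls)$n_meth,
                          n_total = mcols(calls)$n_total,
                          p_value = mcols(calls)$p_value,
                          q_value = mcols(calls)$q_value,
                          called = mcols(calls)$called),
               file.path(d, "methylation_calls.tsv"))
      covd <- mcols(calls)$n_total > 0
      writeBedGraph(granges(calls)[covd],
                    (mcols(calls)$n_meth / mcols(calls)$n_total)[covd],
                    file.path(d, "methylation_fraction.bedGraph"),
                    trackName = sprintf("mC_fraction_c%d", pc$cycles))
      logLines <- c(logLines,
                    sprintf("cycles=%d non_conversion=%.6g", pc$cycles,
                            pc$nonConversion$rate))
    }
    writeWindowSummaryTsv(pc$summary, file.path(d, "window_summary.tsv"))
    writeBedGraph(granges(pc$summary), mcols(pc$summary)$weighted_mC,
                  file.path(d, "weighted_mC.bedGraph"),
                  trackName = sprintf("weighted_mC_c%d", pc$cycles))
    enr <- enrichmentVsGenomic(mcols(pc$summary)$scaled_count, genScaled,
                               granges(pc$summary))
    writeWindowSummaryTsv(enr, file.path(d, "enrichment.tsv"))
    writeBedGraph(granges(enr), mcols(enr)$enrichment,
                  file.path(d, "enrichment.bedGraph"),
                  trackName = sprintf("enrichment_c%d", pc$cycles))
  }

  cycles <- vapply(series$perCycle, `[[`, numeric(1), "cycles")
  if (length(cycles) > 1L) {
    a <- which.min(cycles)
    for (b in seq_along(cycles)[-a]) {
      lr <- log2CycleRatio(mcols(series$perCycle[[a]]$summary)$scaled_count,
                           mcols(series$perCycle[[b]]$summary)$scaled_count,
                           granges(series$perCycle[[a]]$summary),
                           mcols(series$perCycle[[a]]$summary)$gc_raw)
      writeWindowSummaryTsv(lr, out(sprintf("log2_ratio_%d_vs_%d.tsv",
                                            cycles[b], cycles[a])))
    }
  }
  rep <- biasReport(series)
  writeTsv(rep, out("bias_report.tsv"))
  cors <- attr(rep, "correlations")
  writeTsv(data.frame(library = rownames(cors), as.data.frame(cors)),
           out("cycle_correlations.tsv"))
  writeLines(logLines, out("run.log"))
  series$biasReport <- rep
  series$outputDir <- config$outputDir
  say("done: ", config$outputDir)
  invisible(series)
}

#' Replicate a scenario across library seeds
#'
#' Runs [runCycleSeries()] once per seed against a single genome and
#' methylome (generated from the config seed), collecting per-seed bias
#' regressions, cross-cycle coverage correlations, and — when the
#' scenario has more than one cycle condition — the least-squares slope
#' of the per-window log2 coverage ratio (each condition versus the
#' fewest cycles) against raw window GC. This is the package's replicate
#' experiment: one genome, many independently sheared and amplified
#' libraries.
#'
#' @param config A `"RunConfig"` from [scenarioConfig()].
#' @param seeds Integer vector of library seeds.
#' @param quiet Suppress progress messages.
#' @return A list with `bias` (data.frame: seed, cycles, slope, slope_t,
#'   r_squared, n_used), `correlations` (per-seed list of matrices from
#'   [cycleCorrelationMatrix()]), `log2GcSlope` (data.frame: seed,
#'   cycles, slope, slope_t of log2 ratio vs GC), and `meanCorrelation`
#'   (element-wise mean of the per-seed correlation matrices).
#' @export
cycleSweep <- function(config, seeds, quiet = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  genome <- generateGenome(config$nRegions, config$regionLength,
                           config$gcGradient, config$controlLength,
                           seed = config$seed,
                           controlGC = config$controlGC)
  meth <- if (is.null(config$methylation))
    defaultMethylation(config$nRegions) else config$methylation
  truth <- generateMethylome(genome, meth)
  bias <- list(); cors <- list(); lg <- list()
  for (s in seeds) {
    if (!quiet) message("  seed ", s)
    cfg <- config
    cfg$seed <- as.integer(s)
    series <- runCycleSeries(cfg, genome = genome, truth = truth)
    rep <- biasReport(series)
    bias[[length(bias) + 1L]] <-
      cbind(seed = s, rep[, c("cycles", "slope", "slope_t", "r_squared",
                              "n_used")])
    cors[[as.character(s)]] <- attr(rep, "correlations")
    cyc <- rep$cycles
    if (length(cyc) > 1L) {
      a <- which.min(cyc)
      refSum <- series$perCycle[[a]]$summary
      for (b in seq_along(cyc)[-a]) {
        lr <- log2CycleRatio(mcols(refSum)$scaled_count,
                             mcols(series$perCycle[[b]]$summary)$scaled_count,
                             granges(refSum), mcols(refSum)$gc_raw)
        ok <- !is.na(mcols(lr)$log2_ratio)
        f <- trimmedRegression(mcols(lr)$gc[ok], mcols(lr)$log2_ratio[ok],
                               maxFraction = 0)
        lg[[length(lg) + 1L]] <- data.frame(seed = s, cycles = cyc[b],
                                            slope = f@slope,
                                            slope_t = f@slopeT)
      }
    }
  }
  meanCor <- Reduce(`+`, cors) / length(cors)
  list(bias = do.call(rbind, bias), correlations = cors,
       log2GcSlope = if (length(lg)) do.call(rbind, lg) else NULL,
       meanCorrelation = meanCor)
}
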