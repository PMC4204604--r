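#' Tile a genome into fixed-size windows
#'
#' Half-open tiling windows; the last partial window of each contig is
#' included with its true (shorter) length.
#'
#' @param genome A [BisGenome-class].
#' @param windowSize Window size in bp.
#' @param contigs Optional subset of contig names (genome order kept).
#' @return A [GenomicRanges::GRanges] of windows in genome order.
#' @export
makeWindows <- function(genome, windowSize, contigs = NULL) {
  stopifnot(is(genome, "BisGenome"))
  windowSize <- asCount(windowSize, "windowSize", min = 1)
  nms <- names(genome@sequences)
  if (!is.null(contigs)) {
    if (!all(contigs %in% nms)) stop("unknown contig in 'contigs'")
    nms <- nms[nms %in% contigs]
  }
  parts <- lapply(nms, function(ctg) {
    len <- width(genome@sequences)[match(ctg, names(genome@sequences))]
    starts <- seq.int(1L, len, by = windowSize)
    GRanges(ctg, IRanges(start = starts,
                         end = pmin(starts + windowSize - 1L, len)))
  })
  suppressWarnings(do.call(c, parts))
}

#' Normalized read coverage of a region
#'
#' Reads in the region divided by the library's total read count, scaled
#' by 1e5 — the region-level (DMR-level) coverage statistic. Invariant
#' under uniform duplication of the whole library.
#'
#' @param readsInRegion Read count(s) in the region(s).
#' @param totalReads Total reads sequenced from the library (>= 1).
#' @return `(readsInRegion / totalReads) * 1e5`, vectorized over regions.
#' @examples
#' regionNormalizedCoverage(20, 2e6)
#' @export
regionNormalizedCoverage <- function(readsInRegion, totalReads) {
  totalReads <- asCount(totalReads, "totalReads", min = 1)
  if (any(is.na(readsInRegion)) || any(readsInRegion < 0) ||
      any(readsInRegion > totalReads))
    stop("readsInRegion must be in [0, totalReads]")
  (readsInRegion / totalReads) * 1e5
}

#' Count reads per window by start coordinate
#'
#' Each uniquely placed read is assigned to the single window containing
#' its start coordinate (half-open windows, so a read starting exactly at
#' a boundary belongs to the right-hand window). Reads on contigs not
#' covered by `windows` are ignored.
#'
#' @param placements Placement table from [placeReads()].
#' @param windows Window [GenomicRanges::GRanges] (non-overlapping).
#' @return Integer read counts parallel to `windows`.
#' @export
countReadsInWindows <- function(placements, windows) {
  pl <- placements[placements$placed, , drop = FALSE]
  if (!nrow(pl)) return(integer(length(windows)))
  starts <- GRanges(pl$contig, IRanges(pl$start, width = 1L))
  hits <- findOverlaps(starts, windows, ignore.strand = TRUE)
  tabulate(subjectHits(hits), nbins = length(windows))
}

#' Scale window counts by the first tile
#'
#' Divides every window's count by the first window's count, placing
#' libraries of different depths on a common scale anchored at 1 in the
#' first tile. Fragile when the first window is empty; in that case an
#' error points to total-count scaling ([scaleByTotal()]).
#'
#' @param readCounts Numeric per-window counts; the first element is the
#'   first tile of the first contig in genome order.
#' @return Scaled counts; element 1 is exactly 1.
#' @examples
#' scaleByFirstTile(c(100, 50, 200))
#' @export
scaleByFirstTile <- function(readCounts) {
  if (length(readCounts) == 0L) stop("no windows to scale")
  if (is.na(readCounts[1]) || readCounts[1] <= 0)
    stop("first tile has zero reads; use scaleByTotal() ",
         "(scaling = \"total\") instead")
  readCounts / readCounts[1]
}

#' Scale window counts by the library total
#'
#' Alternative to [scaleByFirstTile()]: divides by the sum over windows.
#'
#' @param readCounts Numeric per-window counts with positive sum.
#' @return Counts summing to 1.
#' @export
scaleByTotal <- function(readCounts) {
  s <- sum(readCounts)
  if (is.na(s) || s <= 0) stop("window counts sum to zero")
  readCounts / s
}

#' Per-window enrichment of a bisulfite library over a genomic baseline
#'
#' Subtracts the scaled genomic-DNA window counts from the scaled
#' bisulfite window counts. The genomic library must have been processed
#' through the same converted-space pipeline with [convertFull()] applied
#' to its reads first, so that the baseline captures mappability rather
#' than conversion effects; identical libraries give an all-zero profile.
#'
#' @param bisulfiteScaled,genomicScaled Scaled per-window counts from the
#'   two libraries, parallel to `windows`.
#' @param windows The shared window [GenomicRanges::GRanges].
#' @return `windows` with metadata `bis_scaled`, `gen_scaled`,
#'   `enrichment`.
#' @export
enrichmentVsGenomic <- function(bisulfiteScaled, genomicScaled, windows) {
  if (length(bisulfiteScaled) != length(windows) ||
      length(genomicScaled) != length(windows))
    stop("window mismatch: scaled counts must be parallel to windows")
  mcols(windows)$bis_scaled <- bisulfiteScaled
  mcols(windows)$gen_scaled <- genomicScaled
  mcols(windows)$enrichment <- bisulfiteScaled - genomicScaled
  windows
}

#' Per-window log2 coverage ratio between two cycle conditions
#'
#' log2 of library B's scaled count over library A's, paired with each
#' window's GC fraction — the AT-depletion profile when B was amplified
#' for more cycles than A. Windows with a zero count in either library
#' are emitted as missing (NA) unless a pseudocount is supplied.
#'
#' @param scaledA,scaledB Scaled per-window counts (A = fewer cycles).
#' @param windows The shared window [GenomicRanges::GRanges].
#' @param gc Per-window GC fraction (e.g. `gc_raw` from
#'   [windowGcProfile()]).
#' @param pseudocount Added to both scaled counts before the ratio
#'   (default 0 = strict missing-window policy).
#' @return `windows` with metadata `log2_ratio` and `gc`.
#' @export
log2CycleRatio <- function(scaledA, scaledB, windows, gc, pseudocount = 0) {
  if (length(scaledA) != length(windows) ||
      length(scaledB) != length(windows) || length(gc) != length(windows))
    stop("window mismatch among inputs")
  a <- scaledA + pseudocount
  b <- scaledB + pseudocount
  lr <- ifelse(a > 0 & b > 0, log2(b / a), NA_real_)
  mcols(windows)$log2_ratio <- lr
  mcols(windows)$gc <- gc
  windows
}

#' Summarize a library per window: coverage, methylation and GC
#'
#' The per-window join behind the coverage-versus-methylation panels:
#' read count, scaled count, weighted methylation over all contexts
#' combined (from the observed basecall counts; NA where the window has
#' no covered cytosine), and the three GC fractions (raw, expected
#' post-conversion, fully converted).
#'
#' @param placements Placement table from [placeReads()].
#' @param counts Per-cytosine counts from [pileupCytosines()].
#' @param genome The [BisGenome-class].
#' @param truth Methylome truth (for the converted GC track).
#' @param windowSize Window size in bp.
#' @param scaling `"first-tile"` (default) or `"total"`.
#' @param contigs Optional contig subset (e.g. excluding the control
#'   contig from bias fits).
#' @return A [GenomicRanges::GRanges] of windows with metadata
#'   `read_count`, `scaled_count`, `weighted_mC`, `gc_raw`,
#'   `gc_converted`, `gc_full`.
#' @export
summarizeWindows <- function(placements, counts, genome, truth, windowSize,
                             scaling = c("first-tile", "total"),
                             contigs = NULL) {
  scaling <- match.arg(scaling)
  gcp <- windowGcProfile(genome, truth, windowSize)
  windows <- granges(gcp)
  keep <- rep(TRUE, length(windows))
  if (!is.null(contigs))
    keep <- as.character(seqnames(windows)) %in% contigs
  windows <- windows[keep]
  gcp <- gcp[keep]

  rc <- countReadsInWindows(placements, windows)
  sc <- if (scaling == "first-tile") scaleByFirstTile(rc) else
    scaleByTotal(rc)

  hits <- findOverlaps(counts, windows, ignore.strand = TRUE)
  nm <- nt <- numeric(length(windows))
  if (length(hits)) {
    aggM <- rowsum(as.numeric(mcols(counts)$n_meth[queryHits(hits)]),
                   subjectHits(hits))
    aggT <- rowsum(as.numeric(mcols(counts)$n_total[queryHits(hits)]),
                   subjectHits(hits))
    nm[as.integer(rownames(aggM))] <- aggM[, 1]
    nt[as.integer(rownames(aggT))] <- aggT[, 1]
  }
  mcols(windows)$read_count <- rc
  mcols(windows)$scaled_count <- sc
  mcols(windows)$weighted_mC <- ifelse(nt > 0, nm / nt, NA_real_)
  mcols(windows)$gc_raw <- mcols(gcp)$gc_raw
  mcols(windows)$gc_converted <- mcols(gcp)$gc_converted
  mcols(windows)$gc_full <- mcols(gcp)$gc_full
  windows
}
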