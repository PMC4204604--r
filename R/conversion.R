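#' GC content of DNA sequences
#'
#' @param sequence Character vector of nonempty sequences over
#'   \{A, C, G, T\}.
#' @return Numeric vector: (G + C) / length per sequence.
#' @examples
#' gcContent(c("GGCC", "ATAT", "ACGCT"))
#' @export
gcContent <- function(sequence) {
  checkAlphabet(sequence)
  if (any(nchar(sequence) == 0L)) stop("sequences must be nonempty")
  f <- Biostrings::letterFrequency(DNAStringSet(sequence), c("G", "C"))
  unname(rowSums(f) / nchar(sequence))
}

#' Full in-silico bisulfite conversion
#'
#' Replaces every C by T, the transformation applied to genomic reads to
#' build the mappability baseline and to queries before converted-space
#' placement. Idempotent and length-preserving.
#'
#' @param sequence Character vector over \{A, C, G, T\}.
#' @return Converted sequences.
#' @examples
#' convertFull("ACGT")
#' @export
convertFull <- function(sequence) {
  checkAlphabet(sequence)
  chartr("C", "T", sequence)
}

#' Methylation-aware in-silico conversion of one sequence
#'
#' Cytosines at the listed (methylated) positions are retained; all other
#' cytosines convert to T. With no methylated positions this equals
#' [convertFull()]; with all cytosines listed it is the identity.
#'
#' @param sequence A single sequence over \{A, C, G, T\}.
#' @param methylatedPositions 1-based positions within `sequence` that are
#'   methylated; each must hold a C.
#' @return The converted sequence.
#' @examples
#' convertMethylationAware("ACGCT", 2)
#' @export
convertMethylationAware <- function(sequence, methylatedPositions = integer()) {
  checkAlphabet(sequence)
  stopifnot(length(sequence) == 1L)
  pos <- as.integer(methylatedPositions)
  if (length(pos)) {
    if (any(pos < 1L | pos > nchar(sequence)))
      stop("methylated position outside the sequence")
    if (any(substring(sequence, pos, pos) != "C"))
      stop("consistency error: a listed methylated position is not a C")
  }
  out <- charToRaw(chartr("C", "T", sequence))
  out[pos] <- as.raw(67L)
  rawToChar(out)
}

#' Per-window GC content before, after, and under full conversion
#'
#' Computes, for tiling windows of the plus strand, the raw GC fraction,
#' the expected GC fraction after methylation-aware bisulfite conversion
#' (each plus-strand cytosine retained with its ground-truth methylation
#' probability), and the GC fraction under computed full conversion (all
#' C to T). `gc_delta = gc_raw - gc_full` is the maximal GC loss the
#' window can suffer. The expected (probability-weighted) retention is
#' used rather than one Bernoulli realization: the profile is a property
#' of the methylome, not of a particular library.
#'
#' Post-conversion GC is not strand-symmetric; the profile reports the
#' plus strand.
#'
#' @param genome A [BisGenome-class].
#' @param truth Methylome truth ([generateMethylome()]).
#' @param windowSize Window size in bp; the last partial window is kept
#'   with its true length as denominator.
#' @return A [GenomicRanges::GRanges] of windows with `gc_raw`,
#'   `gc_converted`, `gc_full`, `gc_delta`.
#' @export
windowGcProfile <- function(genome, truth, windowSize) {
  stopifnot(is(genome, "BisGenome"))
  windowSize <- asCount(windowSize, "windowSize", min = 1)
  windows <- makeWindows(genome, windowSize)
  truthP <- truth[strand(truth) == "+"]
  gcw <- numeric(length(windows))
  gw <- numeric(length(windows))
  for (ctg in names(genome@sequences)) {
    wi <- which(as.character(seqnames(windows)) == ctg)
    if (!length(wi)) next
    v <- Biostrings::Views(genome@sequences[[ctg]],
                           start = start(windows)[wi],
                           end = BiocGenerics::end(windows)[wi])
    f <- Biostrings::letterFrequency(v, c("G", "C"))
    gw[wi] <- f[, "G"]
    gcw[wi] <- rowSums(f)
  }
  len <- width(windows)
  # expected retained cytosines per window from the truth probabilities
  hits <- findOverlaps(truthP, windows, ignore.strand = TRUE)
  retained <- numeric(length(windows))
  if (length(hits)) {
    agg <- rowsum(mcols(truthP)$prob[queryHits(hits)], subjectHits(hits))
    retained[as.integer(rownames(agg))] <- agg[, 1]
  }
  mcols(windows)$gc_raw <- gcw / len
  mcols(windows)$gc_converted <- (gw + retained) / len
  mcols(windows)$gc_full <- gw / len
  mcols(windows)$gc_delta <- mcols(windows)$gc_raw - mcols(windows)$gc_full
  windows
}
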