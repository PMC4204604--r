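#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement PDict matchPDict
#' @importFrom BiocGenerics width start strand
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom GenomicRanges GRanges seqnames granges
#' @importFrom stats pbinom p.adjust lm pt cor coef runif rbinom
#'   setNames complete.cases
#' @importFrom utils read.table write.table
NULL

#' Reference genome for bisulfite simulation
#'
#' A multi-contig DNA reference with one contig designated as the fully
#' unmethylated control (the chloroplast stand-in used to estimate the
#' bisulfite non-conversion rate).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of uppercase contig
#'   sequences over the strict alphabet A, C, G, T.
#' @slot controlContig Name of the control contig; must be an element of
#'   `names(sequences)`.
#'
#' @seealso [generateGenome()], [cytosineSites()]
#' @export
setClass("BisGenome",
  representation(sequences = "DNAStringSet", controlContig = "character"))

setValidity("BisGenome", function(object) {
  msgs <- character()
  sq <- object@sequences
  if (length(sq) == 0L) msgs <- c(msgs, "genome has no contigs")
  if (is.null(names(sq)) || anyNA(names(sq)) || any(names(sq) == "") ||
      anyDuplicated(names(sq)))
    msgs <- c(msgs, "contigs must have unique non-empty names")
  if (any(width(sq) == 0L)) msgs <- c(msgs, "all contigs must be nonempty")
  freq <- Biostrings::alphabetFrequency(sq, collapse = TRUE)
  if (sum(freq) != sum(freq[c("A", "C", "G", "T")]))
    msgs <- c(msgs, "contig alphabet must be strictly {A,C,G,T}")
  if (length(object@controlContig) != 1L ||
      !(object@controlContig %in% names(sq)))
    msgs <- c(msgs, "controlContig must name exactly one contig")
  if (length(msgs)) msgs else TRUE
})

#' GC-dependent amplification efficiency profile of a polymerase
#'
#' Mechanistic stand-in for enzyme-specific PCR behaviour: the per-cycle
#' duplication efficiency of a fragment is a clamped linear function of its
#' (post-conversion) GC fraction g,
#' \deqn{e(g) = \mathrm{clamp}(e_0 + \gamma (g' - 0.5),\ 0,\ 1),\quad
#'   g' = \min(g, \mathrm{saturationGC}),}
#' so a fragment accrues copy weight \eqn{(1 + e(g))^{\mathrm{cycles}}}.
#'
#' @slot name Profile label.
#' @slot baseEfficiency Efficiency at GC 0.5, in \[0, 1\].
#' @slot gcCoefficient Slope per unit GC fraction (dimensionless).
#' @slot saturationGC GC fraction above which efficiency stops increasing;
#'   `NA_real_` for no saturation.
#'
#' @seealso [enzymeProfile()], [amplificationEfficiency()]
#' @export
setClass("EnzymeProfile",
  representation(name = "character", baseEfficiency = "numeric",
                 gcCoefficient = "numeric", saturationGC = "numeric"))

setValidity("EnzymeProfile", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msgs <- c(msgs, "name must be a single string")
  e0 <- object@baseEfficiency
  if (length(e0) != 1L || is.na(e0) || e0 < 0 || e0 > 1)
    msgs <- c(msgs, "baseEfficiency must be in [0, 1]")
  if (length(object@gcCoefficient) != 1L || is.na(object@gcCoefficient))
    msgs <- c(msgs, "gcCoefficient must be a single number")
  sg <- object@saturationGC
  if (length(sg) != 1L || (!is.na(sg) && (sg <= 0 || sg > 1)))
    msgs <- c(msgs, "saturationGC must be in (0, 1] or NA")
  if (length(msgs)) msgs else TRUE
})

#' Pool of genomic fragments with known origins
#'
#' Fragments sheared from a [BisGenome], each carrying its origin contig,
#' 0-based start and strand. Sequences are strand-specific (5'->3' on the
#' origin strand). After [bisulfiteConvert()] the `converted` flag is TRUE
#' and sequences hold the realized post-conversion fragments.
#'
#' @slot origins data.frame with columns `contig`, `start` (0-based),
#'   `strand` ("+"/"-"), `width`.
#' @slot sequences Character vector of fragment sequences, parallel to
#'   `origins`.
#' @slot converted Logical flag: have the fragments been bisulfite
#'   converted?
#' @slot nonConversionRate Rate used at conversion (NA before conversion).
#' @slot seed Seed of the generating call.
#' @seealso [simulateFragments()], [bisulfiteConvert()]
#' @export
setClass("FragmentPool",
  representation(origins = "data.frame", sequences = "character",
                 converted = "logical", nonConversionRate = "numeric",
                 seed = "integer"))

setValidity("FragmentPool", function(object) {
  msgs <- character()
  o <- object@origins
  need <- c("contig", "start", "strand", "width")
  if (!all(need %in% names(o)))
    msgs <- c(msgs, "origins must have contig/start/strand/width columns")
  else {
    if (nrow(o) != length(object@sequences))
      msgs <- c(msgs, "origins and sequences must be parallel")
    if (nrow(o) && !all(o$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    if (nrow(o) && any(o$start < 0))
      msgs <- c(msgs, "starts must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' A simulated sequencing library
#'
#' Reads drawn (with replacement, amplification-weighted) from a fragment
#' pool. Read sequences are whole fragment sequences; true origins are
#' retained as ground truth.
#'
#' @slot reads Character vector of read sequences.
#' @slot origins data.frame with `read_id`, `contig`, `start` (0-based),
#'   `strand` for every read.
#' @slot cycles PCR cycle count used for the copy weights.
#' @slot enzyme Name of the [EnzymeProfile-class] used.
#' @slot nonConversionRate Non-conversion rate of the underlying pool (NA
#'   for unconverted genomic libraries).
#' @slot seed Sampling seed.
#' @seealso [amplifyAndSample()]
#' @export
setClass("SimulatedLibrary",
  representation(reads = "character", origins = "data.frame",
                 cycles = "integer", enzyme = "character",
                 nonConversionRate = "numeric", seed = "integer"))

setValidity("SimulatedLibrary", function(object) {
  msgs <- character()
  if (nrow(object@origins) != length(object@reads))
    msgs <- c(msgs, "origins and reads must be parallel")
  if (length(object@cycles) != 1L || is.na(object@cycles) ||
      object@cycles < 0L)
    msgs <- c(msgs, "cycles must be a single integer >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Fully-converted exact-match placement index
#'
#' Holds, for every contig, the fully C-to-T converted plus-strand sequence
#' and the fully converted reverse-complement, for the three-letter-space
#' exact substring lookup used by bisulfite aligners.
#'
#' @slot plusConverted Named [Biostrings::DNAStringSet]: C->T converted
#'   plus strands.
#' @slot minusConverted Named [Biostrings::DNAStringSet]: C->T converted
#'   reverse complements.
#' @slot contigLengths Named integer vector of contig lengths.
#' @seealso [buildConvertedIndex()], [placeReads()]
#' @export
setClass("ConvertedIndex",
  representation(plusConverted = "DNAStringSet",
                 minusConverted = "DNAStringSet",
                 contigLengths = "integer"))

#' Result of an outlier-trimmed simple linear regression
#'
#' @slot slope,intercept OLS coefficients on the retained points.
#' @slot slopeSE,slopeT Standard error and t statistic of the slope.
#' @slot r Pearson correlation of the retained points.
#' @slot rSquared `r^2`.
#' @slot nInput,nUsed Points supplied / retained after trimming.
#' @slot outlierIndices Indices (into the input vectors) removed as
#'   Bonferroni outliers.
#' @seealso [trimmedRegression()], [bonferroniOutliers()]
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric",
                 slopeSE = "numeric", slopeT = "numeric",
                 r = "numeric", rSquared = "numeric",
                 nInput = "integer", nUsed = "integer",
                 outlierIndices = "integer"))

setMethod("show", "BisGenome", function(object) {
  cat("BisGenome with", length(object@sequences), "contig(s),",
      sum(width(object@sequences)), "bp total\n")
  cat("  contigs:", paste(names(object@sequences), collapse = ", "), "\n")
  cat("  control contig:", object@controlContig, "\n")
})

setMethod("show", "EnzymeProfile", function(object) {
  cat(sprintf(
    "EnzymeProfile '%s': e(g) = clamp(%.3g + %.3g*(g - 0.5), 0, 1)%s\n",
    object@name, object@baseEfficiency, object@gcCoefficient,
    if (is.na(object@saturationGC)) ""
    else sprintf(", saturating at GC %.3g", object@saturationGC)))
})

setMethod("show", "FragmentPool", function(object) {
  cat("FragmentPool of", length(object@sequences), "fragments",
      if (isTRUE(object@converted)) "(bisulfite converted)" else
        "(unconverted)", "\n")
})

setMethod("show", "SimulatedLibrary", function(object) {
  cat(sprintf(
    "SimulatedLibrary: %d reads, %d PCR cycle(s), enzyme '%s', seed %d\n",
    length(object@reads), object@cycles, object@enzyme, object@seed))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "RegressionResult: slope %.4g (SE %.3g, t %.3g), intercept %.4g\n",
    object@slope, object@slopeSE, object@slopeT, object@intercept))
  cat(sprintf("  r = %.4g, r^2 = %.4g; used %d of %d points (%d outliers)\n",
    object@r, object@rSquared, object@nUsed, object@nInput,
    length(object@outlierIndices)))
})

#' @describeIn BisGenome-class Number of contigs.
#' @param x,object A `BisGenome`.
#' @export
setMethod("length", "BisGenome", function(x) length(x@sequences))

#' Accessors for simulation classes
#'
#' `genomeSequences()` returns the contig [Biostrings::DNAStringSet] of a
#' [BisGenome-class]; `controlContig()` its control contig name;
#' `fragmentOrigins()` the origin table of a [FragmentPool-class] or
#' [SimulatedLibrary-class]; `readSequences()` the read or fragment
#' sequences.
#'
#' @param x A `BisGenome`, `FragmentPool` or `SimulatedLibrary`.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
genomeSequences <- function(x) {
  stopifnot(is(x, "BisGenome"))
  x@sequences
}

#' @rdname accessors
#' @export
controlContig <- function(x) {
  stopifnot(is(x, "BisGenome"))
  x@controlContig
}

#' @rdname accessors
#' @export
fragmentOrigins <- function(x) {
  if (is(x, "FragmentPool") || is(x, "SimulatedLibrary")) x@origins
  else stop("no origins for class ", class(x))
}

#' @rdname accessors
#' @export
readSequences <- function(x) {
  if (is(x, "FragmentPool")) x@sequences
  else if (is(x, "SimulatedLibrary")) x@reads
  else stop("no sequences for class ", class(x))
}
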