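#' Generate a synthetic reference genome with a GC gradient
#'
#' Builds a two-contig reference emulating a plant chromosome arm: one main
#' contig of `nRegions` concatenated blocks whose expected GC content
#' interpolates linearly between `gcGradient[1]` (heterochromatin-like,
#' AT-rich end) and `gcGradient[2]` (gene-like end), plus a designated
#' control contig that downstream steps treat as fully unmethylated (the
#' chloroplast stand-in used to estimate the bisulfite non-conversion
#' rate). Bases are drawn independently with P(G) = P(C) = gc/2 at each
#' region's target GC.
#'
#' @param nRegions Number of regions on the main contig (>= 2).
#' @param regionLength Length of each region in bp (>= 100).
#' @param gcGradient Numeric pair of GC fractions in (0, 1); region i gets
#'   target GC linearly interpolated between the two.
#' @param controlLength Length of the control contig in bp.
#' @param seed Integer seed; the genome is a pure function of the
#'   arguments.
#' @param controlGC Target GC of the control contig (default 0.36,
#'   chloroplast-like).
#' @param mainContig,controlName Contig names.
#' @return A [BisGenome-class]. Region boundaries and target GC values are
#'   retained in `genomeRegions()`.
#' @examples
#' g <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 7)
#' g
#' @export
generateGenome <- function(nRegions, regionLength, gcGradient,
                           controlLength, seed,
                           controlGC = 0.36,
                           mainContig = "chr_sim",
                           controlName = "ctrl_chloroplast") {
  nRegions <- asCount(nRegions, "nRegions", min = 2)
  regionLength <- asCount(regionLength, "regionLength", min = 100)
  controlLength <- asCount(controlLength, "controlLength", min = 1)
  if (length(gcGradient) != 2L)
    stop("gcGradient must be a pair of GC fractions")
  for (g in gcGradient)
    asFraction(g, "gcGradient", 0, 1, open_lo = TRUE, open_hi = TRUE)
  asFraction(controlGC, "controlGC", 0, 1, open_lo = TRUE, open_hi = TRUE)

  gcByRegion <- seq(gcGradient[1], gcGradient[2], length.out = nRegions)
  withSeed(seed, {
    sampleBlock <- function(len, gc) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }
    main <- paste(vapply(gcByRegion, function(gc)
      sampleBlock(regionLength, gc), character(1)), collapse = "")
    ctrl <- sampleBlock(controlLength, controlGC)
  })
  seqs <- DNAStringSet(setNames(c(main, ctrl), c(mainContig, controlName)))
  genome <- new("BisGenome", sequences = seqs, controlContig = controlName)
  regions <- GRanges(mainContig,
                     IRanges(start = (seq_len(nRegions) - 1L) *
                               regionLength + 1L,
                             width = regionLength))
  mcols(regions)$region_id <- seq_len(nRegions)
  mcols(regions)$target_gc <- gcByRegion
  attr(genome, "regions") <- regions
  genome
}

#' Region annotation of a generated genome
#'
#' @param genome A [BisGenome-class] created by [generateGenome()].
#' @return A [GenomicRanges::GRanges] of region blocks with `region_id`
#'   and `target_gc` metadata, or `NULL` for genomes built from files.
#' @export
genomeRegions <- function(genome) attr(genome, "regions")

#' Enumerate cytosine sites and their sequence context
#'
#' Lists every cytosine on both strands of every contig and assigns its
#' context: CG, CHG or CHH with H in \{A, C, T\}. A cytosine too close to
#' the contig end for its context to be resolved is classed CHH (the
#' missing downstream base is treated as H).
#'
#' @param genome A [BisGenome-class].
#' @return A [GenomicRanges::GRanges] of width-1 sites (1-based, as is
#'   standard for GRanges; file writers emit 0-based coordinates) with
#'   strand and a `context` factor.
#' @examples
#' g <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 7)
#' table(S4Vectors::mcols(cytosineSites(g))$context)
#' @export
cytosineSites <- function(genome) {
  stopifnot(is(genome, "BisGenome"))
  out <- lapply(names(genome@sequences), function(ctg) {
    s <- strsplit(as.character(genome@sequences[[ctg]]), "", fixed = TRUE)[[1]]
    n <- length(s)
    at <- function(i) ifelse(i >= 1L & i <= n, s[pmax(pmin(i, n), 1L)], "N")
    # plus strand: C at i, downstream bases i+1, i+2
    ip <- which(s == "C")
    ctxP <- ifelse(at(ip + 1L) == "G", "CG",
            ifelse(at(ip + 2L) == "G", "CHG", "CHH"))
    # minus strand: G at i on the plus strand is a C on the minus strand;
    # its downstream bases (5'->3' on minus) are i-1, i-2 on plus, and a
    # minus-strand G corresponds to a plus-strand C.
    im <- which(s == "G")
    ctxM <- ifelse(at(im - 1L) == "C", "CG",
            ifelse(at(im - 2L) == "C", "CHG", "CHH"))
    nSites <- length(ip) + length(im)
    GRanges(rep(ctg, nSites),
            IRanges(start = c(ip, im), width = 1L),
            strand = rep(c("+", "-"), c(length(ip), length(im))),
            context = factor(c(ctxP, ctxM), levels = c("CG", "CHG", "CHH")))
  })
  sites <- suppressWarnings(do.call(c, out))
  sort(sites, ignore.strand = TRUE)
}

#' Assign ground-truth methylation probabilities per region and context
#'
#' Every cytosine on both strands of each region of the main contig
#' receives the region's probability for its context (CG, CHG or CHH);
#' every cytosine of the control contig receives probability 0. The
#' assignment is deterministic given the genome; stochastic realization
#' happens later, per fragment, in [bisulfiteConvert()].
#'
#' @param genome A [BisGenome-class] from [generateGenome()].
#' @param methylationByRegion Numeric matrix or data.frame with one row
#'   per region and columns `CG`, `CHG`, `CHH` of probabilities in
#'   \[0, 1\].
#' @return The methylome truth: a [GenomicRanges::GRanges] of cytosine
#'   sites with `context` and `prob` metadata columns.
#' @examples
#' g <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 7)
#' m <- cbind(CG = c(0.9, 0.1), CHG = c(0.7, 0.05), CHH = c(0.3, 0.02))
#' truth <- generateMethylome(g, m)
#' @export
generateMethylome <- function(genome, methylationByRegion) {
  stopifnot(is(genome, "BisGenome"))
  regions <- genomeRegions(genome)
  if (is.null(regions))
    stop("genome carries no region annotation; generate it with ",
         "generateGenome()")
  m <- as.matrix(as.data.frame(methylationByRegion)[, c("CG", "CHG", "CHH")])
  if (nrow(m) != length(regions))
    stop("methylationByRegion must have one row per region (",
         length(regions), ")")
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop("methylation probabilities must be in [0, 1]")

  sites <- cytosineSites(genome)
  prob <- numeric(length(sites))
  hits <- findOverlaps(sites, regions, ignore.strand = TRUE)
  ctxIdx <- as.integer(mcols(sites)$context)  # CG=1, CHG=2, CHH=3
  prob[queryHits(hits)] <-
    m[cbind(subjectHits(hits), ctxIdx[queryHits(hits)])]
  prob[as.character(seqnames(sites)) == genome@controlContig] <- 0
  mcols(sites)$prob <- prob
  sites
}

#' Shear a genome into an origin-tagged fragment pool
#'
#' Fragment origins are uniform over all valid start positions and both
#' strands, across contigs in proportion to their number of valid starts.
#' Minus-strand fragment sequences are reverse complemented (5'->3' on the
#' origin strand).
#'
#' @param genome A [BisGenome-class].
#' @param nFragments Number of fragments to draw (0 gives an empty pool).
#' @param fragmentLength Fragment length in bp; must not exceed the
#'   shortest contig.
#' @param seed Integer seed.
#' @return A [FragmentPool-class] of unconverted fragments.
#' @export
simulateFragments <- function(genome, nFragments, fragmentLength, seed) {
  stopifnot(is(genome, "BisGenome"))
  nFragments <- asCount(nFragments, "nFragments", min = 0)
  fragmentLength <- asCount(fragmentLength, "fragmentLength", min = 1)
  lens <- setNames(width(genome@sequences), names(genome@sequences))
  if (fragmentLength > min(lens))
    stop("fragmentLength (", fragmentLength,
         ") exceeds the shortest contig (", min(lens), " bp)")
  validStarts <- lens - fragmentLength + 1L
  withSeed(seed, {
    ctg <- sample(names(lens), nFragments, replace = TRUE,
                  prob = validStarts)
    start1 <- floor(runif(nFragments) * validStarts[ctg]) + 1L
    strand <- sample(c("+", "-"), nFragments, replace = TRUE)
  })
  origins <- data.frame(contig = as.character(ctg),
                        start = as.integer(start1),
                        strand = strand,
                        width = rep(fragmentLength, nFragments),
                        stringsAsFactors = FALSE)
  seqs <- character(nFragments)
  for (c1 in unique(origins$contig)) {
    i <- which(origins$contig == c1)
    ex <- Biostrings::extractAt(genome@sequences[[c1]],
                                IRanges(origins$start[i],
                                        width = fragmentLength))
    seqs[i] <- as.character(ex)
  }
  neg <- origins$strand == "-"
  if (any(neg)) seqs[neg] <- revComp(seqs[neg])
  new("FragmentPool", origins = origins, sequences = seqs,
      converted = FALSE, nonConversionRate = NA_real_,
      seed = asCount(seed, "seed"))
}

#' Construct a fragment pool from explicit origins and sequences
#'
#' Mainly useful for worked examples and tests; simulation uses
#' [simulateFragments()].
#'
#' @param contig,start,strand Origin coordinates (start is 1-based).
#' @param sequences Fragment sequences on the origin strand.
#' @param converted Whether the sequences are already bisulfite converted.
#' @param seed Provenance seed to record.
#' @return A [FragmentPool-class].
#' @export
newFragmentPool <- function(contig, start, strand, sequences,
                            converted = FALSE, seed = 0L) {
  checkAlphabet(sequences, "fragment sequences")
  origins <- data.frame(contig = as.character(contig),
                        start = as.integer(start),
                        strand = as.character(strand),
                        width = nchar(sequences),
                        stringsAsFactors = FALSE)
  new("FragmentPool", origins = origins, sequences = sequences,
      converted = converted, nonConversionRate = NA_real_,
      seed = asCount(seed, "seed"))
}

#' Bisulfite-convert a fragment pool against a ground-truth methylome
#'
#' For every cytosine on every fragment's strand, the methylation state is
#' realized as a Bernoulli draw at the truth probability of that site.
#' Methylated cytosines are protected and retained as C; unmethylated
#' cytosines convert to T, except that each independently fails to convert
#' (and is retained as C) with probability `nonConversionRate`. All other
#' bases are untouched. Fragments overlapping the same site receive
#' independent realizations, as distinct molecules do.
#'
#' Every fragment cytosine must be covered by a truth record; a mismatch
#' between fragment sequence and truth is an internal consistency error.
#'
#' @param pool An unconverted [FragmentPool-class].
#' @param truth Methylome truth from [generateMethylome()].
#' @param nonConversionRate Failure-to-convert probability in \[0, 1).
#' @param seed Integer seed.
#' @return The pool with converted sequences and `converted = TRUE`.
#' @export
bisulfiteConvert <- function(pool, truth, nonConversionRate, seed) {
  stopifnot(is(pool, "FragmentPool"))
  if (isTRUE(pool@converted)) stop("pool is already converted")
  r <- asFraction(nonConversionRate, "nonConversionRate", 0, 1,
                  open_hi = TRUE)
  n <- length(pool@sequences)
  if (n == 0L) {
    pool@converted <- TRUE
    pool@nonConversionRate <- r
    return(pool)
  }
  o <- pool@origins
  fragGR <- GRanges(o$contig, IRanges(o$start, width = o$width),
                    strand = o$strand)
  hits <- findOverlaps(fragGR, truth)  # strand-aware: site on frag strand
  fi <- queryHits(hits)
  si <- subjectHits(hits)

  # consistency: every C on a fragment's strand must be a truth site
  nC <- vapply(gregexpr("C", pool@sequences, fixed = TRUE),
               function(x) sum(x > 0L), integer(1))
  if (sum(nC) != length(fi))
    stop("internal consistency error: ", sum(nC), " fragment cytosines ",
         "but ", length(fi), " truth records overlap the pool; every ",
         "fragment C must have a truth record")

  withSeed(seed, {
    p <- mcols(truth)$prob[si]
    methylated <- runif(length(si)) < p
    retainC <- methylated | (runif(length(si)) < r)
  })

  # offset of each site within its fragment's strand-specific sequence
  sitePos <- start(truth)[si]
  fStart <- o$start[fi]
  fEnd <- fStart + o$width[fi] - 1L
  off <- ifelse(o$strand[fi] == "+", sitePos - fStart + 1L,
                fEnd - sitePos + 1L)

  # fully convert, then restore retained cytosines in one pass
  conv <- chartr("C", "T", pool@sequences)
  keepF <- fi[retainC]
  keepOff <- off[retainC]
  if (length(keepF)) {
    ends <- cumsum(nchar(conv))
    starts <- ends - nchar(conv) + 1L
    big <- charToRaw(paste(conv, collapse = ""))
    big[starts[keepF] + keepOff - 1L] <- as.raw(67L)  # 'C'
    allstr <- rawToChar(big)
    conv <- substring(allstr, starts, ends)
  }
  pool@sequences <- conv
  pool@converted <- TRUE
  pool@nonConversionRate <- r
  pool
}
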