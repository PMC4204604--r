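#' Build a fully-converted exact-match placement index
#'
#' Bisulfite reads are placed in three-letter space: every query is fully
#' C-to-T converted and looked up as an exact substring of (i) each
#' contig's C-to-T converted plus strand and (ii) each contig's C-to-T
#' converted reverse complement (the minus strand read 5'->3'). This
#' mirrors the converted-space mapping convention of bisulfite aligners,
#' restricted to exact full-length matches since simulated reads are
#' error-free.
#'
#' @param genome A [BisGenome-class].
#' @return A [ConvertedIndex-class].
#' @export
buildConvertedIndex <- function(genome) {
  stopifnot(is(genome, "BisGenome"))
  plus <- chartr("C", "T", as.character(genome@sequences))
  minus <- chartr("C", "T", revComp(as.character(genome@sequences)))
  new("ConvertedIndex",
      plusConverted = DNAStringSet(setNames(plus, names(genome@sequences))),
      minusConverted = DNAStringSet(setNames(minus, names(genome@sequences))),
      contigLengths = setNames(width(genome@sequences),
                               names(genome@sequences)))
}

# All exact hits of fully-converted queries against one strand of the
# index. Returns data.frame(query, contig, start1, strand).
.matchOneStrand <- function(queries, subjects, strandChar, contigLengths) {
  res <- vector("list", length(subjects) * 4L)
  k <- 0L
  for (w in unique(nchar(queries))) {
    qi <- which(nchar(queries) == w)
    pd <- PDict(DNAStringSet(queries[qi]))
    for (ctg in names(subjects)) {
      if (w > contigLengths[[ctg]]) next
      m <- matchPDict(pd, subjects[[ctg]])
      st <- Biostrings::startIndex(m)  # list of start vectors per query
      nh <- lengths(st)
      if (sum(nh) == 0L) next
      k <- k + 1L
      s <- unlist(st, use.names = FALSE)
      q <- rep(qi, nh)
      if (strandChar == "-") {
        # subject is the reverse complement: map back to plus coordinates
        s <- contigLengths[[ctg]] - s - w + 2L
      }
      res[[k]] <- data.frame(query = q, contig = ctg, start1 = s,
                             strand = strandChar, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    data.frame(query = integer(), contig = character(),
               start1 = integer(), strand = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, res[seq_len(k)])
}

#' Place reads by exact match in converted space
#'
#' Each read is fully C-to-T converted and looked up in the index.
#' Exactly one hit across both strands of all contigs gives a unique
#' placement; zero or multiple hits discard the read (discards are data,
#' recorded with their reason, and excluded from all downstream counting).
#'
#' @param reads A [SimulatedLibrary-class], [FragmentPool-class], or
#'   character vector of read sequences.
#' @param index A [ConvertedIndex-class] from [buildConvertedIndex()].
#' @param readIds Optional read identifiers (defaults to the library's
#'   `read_id`s or `read_<i>`).
#' @return A data.frame with one row per read: `read_id`, `contig`,
#'   `start` (1-based; file writers emit 0-based), `strand`, `width`,
#'   `placed` (logical) and `reason` (`"unique"`, `"no_hit"` or
#'   `"multi_hit"`). Unplaced reads have NA coordinates.
#' @export
placeReads <- function(reads, index, readIds = NULL) {
  stopifnot(is(index, "ConvertedIndex"))
  if (is(reads, "SimulatedLibrary")) {
    if (is.null(readIds)) readIds <- reads@origins$read_id
    reads <- reads@reads
  } else if (is(reads, "FragmentPool")) {
    reads <- reads@sequences
  }
  if (is.null(readIds)) readIds <- sprintf("read_%d", seq_along(reads))
  if (length(reads) == 0L)
    return(data.frame(read_id = character(), contig = character(),
                      start = integer(), strand = character(),
                      width = integer(), placed = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  checkAlphabet(reads, "reads")
  uq <- unique(reads)
  conv <- convertFull(uq)
  hp <- .matchOneStrand(conv, index@plusConverted, "+", index@contigLengths)
  hm <- .matchOneStrand(conv, index@minusConverted, "-", index@contigLengths)
  hits <- rbind(hp, hm)
  nhits <- tabulate(hits$query, nbins = length(uq))
  uniqueHit <- hits[nhits[hits$query] == 1L, , drop = FALSE]

  ctg <- rep(NA_character_, length(uq))
  st <- rep(NA_integer_, length(uq))
  sd <- rep(NA_character_, length(uq))
  ctg[uniqueHit$query] <- uniqueHit$contig
  st[uniqueHit$query] <- uniqueHit$start1
  sd[uniqueHit$query] <- uniqueHit$strand
  reason <- ifelse(nhits == 0L, "no_hit",
                   ifelse(nhits == 1L, "unique", "multi_hit"))

  m <- match(reads, uq)
  data.frame(read_id = readIds, contig = ctg[m], start = st[m],
             strand = sd[m], width = nchar(reads),
             placed = nhits[m] == 1L, reason = reason[m],
             stringsAsFactors = FALSE)
}

#' Pile up per-cytosine basecalls from placed reads
#'
#' For every reference cytosine covered on its strand by a uniquely placed
#' read, the read base at that position is counted: C increments both
#' `n_meth` and `n_total` (an unconverted, i.e. methylated-looking,
#' basecall); T increments `n_total` only; any other base is ignored at
#' that position.
#'
#' @param placements Placement table from [placeReads()]; only rows with
#'   `placed == TRUE` are used.
#' @param reads The read sequences the placements refer to (same order as
#'   the placement table), a character vector or
#'   [SimulatedLibrary-class]/[FragmentPool-class].
#' @param genome The [BisGenome-class] the reads were placed on.
#' @param sites Optional precomputed [cytosineSites()] of `genome`.
#' @return A [GenomicRanges::GRanges] of all reference cytosine sites with
#'   `context`, `n_meth` and `n_total` metadata (zero counts where
#'   uncovered).
#' @export
pileupCytosines <- function(placements, reads, genome, sites = NULL) {
  stopifnot(is(genome, "BisGenome"))
  if (is(reads, "SimulatedLibrary")) reads <- reads@reads
  else if (is(reads, "FragmentPool")) reads <- reads@sequences
  if (length(reads) != nrow(placements))
    stop("reads and placements must be parallel")
  if (is.null(sites)) sites <- cytosineSites(genome)
  nm <- numeric(length(sites))
  nt <- numeric(length(sites))

  keep <- which(placements$placed)
  if (length(keep)) {
    pl <- placements[keep, , drop = FALSE]
    rd <- reads[keep]
    lens <- setNames(width(genome@sequences), names(genome@sequences))
    if (any(pl$start < 1L) ||
        any(pl$start + pl$width - 1L > lens[pl$contig]))
      stop("consistency error: placement out of contig bounds")
    # identical read sequences place identically; aggregate multiplicities
    key <- paste0(rd, "\r", pl$contig, "\r", pl$start, "\r", pl$strand)
    first <- !duplicated(key)
    wgt <- as.numeric(table(factor(key, levels = key[first])))
    pl <- pl[first, , drop = FALSE]
    rd <- rd[first]

    frags <- GRanges(pl$contig, IRanges(pl$start, width = pl$width),
                     strand = pl$strand)
    hits <- findOverlaps(frags, sites)  # strand-matched
    fi <- queryHits(hits)
    si <- subjectHits(hits)
    if (length(fi)) {
      fStart <- pl$start[fi]
      fEnd <- fStart + pl$width[fi] - 1L
      pos <- start(sites)[si]
      off <- ifelse(pl$strand[fi] == "+", pos - fStart + 1L,
                    fEnd - pos + 1L)
      base <- substring(rd[fi], off, off)
      isC <- base == "C"
      isT <- base == "T"
      use <- isC | isT
      if (any(use)) {
        aggT <- rowsum(wgt[fi][use], si[use])
        nt[as.integer(rownames(aggT))] <- aggT[, 1]
        if (any(isC)) {
          aggM <- rowsum(wgt[fi][isC], si[isC])
          nm[as.integer(rownames(aggM))] <- aggM[, 1]
        }
      }
    }
  }
  mcols(sites)$n_meth <- as.integer(round(nm))
  mcols(sites)$n_total <- as.integer(round(nt))
  sites
}
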