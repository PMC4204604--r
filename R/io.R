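# Text format layer. All emitted coordinates are 0-based half-open;
# in-memory GRanges are 1-based as usual, and the readers/writers do the
# shift. Tables are tab-separated with a single '#'-prefixed header line.

#' Write and read tab-separated tables with a '#' header
#'
#' @param df A data.frame.
#' @param path File path.
#' @return `readTsv` returns the data.frame; `writeTsv` the path,
#'   invisibly.
#' @export
writeTsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("malformed table ", path, ": line 1 must be a '#' header")
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- read.table(path, sep = "\t", skip = 1L, col.names = cols,
                   stringsAsFactors = FALSE, colClasses = NA,
                   comment.char = "")
  df
}

#' Genome FASTA I/O
#'
#' @param genome A [BisGenome-class].
#' @param path FASTA path.
#' @param controlContig Control contig name, required when reading.
#' @return `readGenomeFasta` returns a [BisGenome-class].
#' @export
writeGenomeFasta <- function(genome, path) {
  stopifnot(is(genome, "BisGenome"))
  writeXStringSet(genome@sequences, path)
  invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path, controlContig) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new("BisGenome", sequences = seqs, controlContig = controlContig)
}

#' Library FASTQ I/O
#'
#' Reads are written with the constant dummy quality 'I'. On reading,
#' records whose sequence strays outside A, C, G, T, N are rejected with
#' their file line number.
#'
#' @param library A [SimulatedLibrary-class] (or character reads with
#'   `readIds`).
#' @param path FASTQ path.
#' @param readIds Optional ids when `library` is a character vector.
#' @return `readLibraryFastq` returns a data.frame with `read_id` and
#'   `sequence`.
#' @export
writeLibraryFastq <- function(library, path, readIds = NULL) {
  if (is(library, "SimulatedLibrary")) {
    reads <- library@reads
    ids <- library@origins$read_id
  } else {
    reads <- library
    ids <- if (is.null(readIds)) sprintf("read_%d", seq_along(reads))
           else readIds
  }
  x <- DNAStringSet(setNames(reads, ids))
  q <- Biostrings::BStringSet(strrep("I", width(x)))
  writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname writeLibraryFastq
#' @export
readLibraryFastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  seqs <- as.character(x)
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad))
    stop("malformed FASTQ ", path, ": record ", bad[1], " (line ",
         4L * (bad[1] - 1L) + 2L, ") has characters outside {A,C,G,T,N}")
  data.frame(read_id = sub("\\s.*$", "", names(x)), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Methylome truth TSV I/O
#'
#' Columns: contig, pos0 (0-based), strand, context, probability.
#'
#' @param truth Truth GRanges from [generateMethylome()].
#' @param path File path.
#' @return `readTruthTsv` returns the truth GRanges.
#' @export
writeTruthTsv <- function(truth, path) {
  writeTsv(data.frame(contig = as.character(seqnames(truth)),
                      pos0 = start(truth) - 1L,
                      strand = as.character(strand(truth)),
                      context = as.character(mcols(truth)$context),
                      probability = mcols(truth)$prob), path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
  df <- readTsv(path)
  GRanges(df$contig, IRanges(df$pos0 + 1L, width = 1L),
          strand = df$strand,
          context = factor(df$context, levels = c("CG", "CHG", "CHH")),
          prob = df$probability)
}

#' Per-cytosine count TSV I/O (CX-report-like)
#'
#' Columns: contig, pos0 (0-based), strand, context, n_meth, n_total.
#'
#' @param counts Counts GRanges from [pileupCytosines()].
#' @param path File path.
#' @return `readCountsTsv` returns the counts GRanges.
#' @export
writeCountsTsv <- function(counts, path) {
  writeTsv(data.frame(contig = as.character(seqnames(counts)),
                      pos0 = start(counts) - 1L,
                      strand = as.character(strand(counts)),
                      context = as.character(mcols(counts)$context),
                      n_meth = mcols(counts)$n_meth,
                      n_total = mcols(counts)$n_total), path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  df <- readTsv(path)
  GRanges(df$contig, IRanges(df$pos0 + 1L, width = 1L),
          strand = df$strand,
          context = factor(df$context, levels = c("CG", "CHG", "CHH")),
          n_meth = df$n_meth, n_total = df$n_total)
}

#' Placement table TSV I/O
#'
#' Columns: read_id, contig, start0, strand, width, placed, reason.
#'
#' @param placements Placement data.frame from [placeReads()].
#' @param path File path.
#' @return `readPlacementsTsv` returns the placement data.frame (1-based
#'   `start`).
#' @export
writePlacementsTsv <- function(placements, path) {
  df <- placements
  df$start0 <- df$start - 1L
  writeTsv(df[, c("read_id", "contig", "start0", "strand", "width",
                  "placed", "reason")], path)
}

#' @rdname writePlacementsTsv
#' @export
readPlacementsTsv <- function(path) {
  df <- readTsv(path)
  df$start <- df$start0 + 1L
  df$start0 <- NULL
  df$contig[df$contig == "NA"] <- NA_character_
  df$strand[df$strand == "NA"] <- NA_character_
  df[, c("read_id", "contig", "start", "strand", "width", "placed",
         "reason")]
}

#' BED window I/O (0-based half-open)
#'
#' @param windows A window [GenomicRanges::GRanges].
#' @param path File path.
#' @return `readBedWindows` returns a GRanges.
#' @export
writeBedWindows <- function(windows, path) {
  df <- data.frame(as.character(seqnames(windows)),
                   start(windows) - 1L,
                   BiocGenerics::end(windows))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedWindows
#' @export
readBedWindows <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 3L) stop("malformed BED ", path, ": need 3 columns")
  GRanges(df[[1]], IRanges(start = df[[2]] + 1L, end = df[[3]]))
}

#' Write a bedGraph track of per-window values
#'
#' Full-precision values; windows with missing values are skipped.
#'
#' @param windows Window [GenomicRanges::GRanges].
#' @param values Numeric values parallel to `windows`.
#' @param path File path.
#' @param trackName Track name written in the header line.
#' @export
writeBedGraph <- function(windows, values, path, trackName = "track") {
  if (length(values) != length(windows)) stop("values/windows mismatch")
  keep <- !is.na(values)
  lines <- c(sprintf("track type=bedGraph name=\"%s\"", trackName),
             sprintf("%s\t%d\t%d\t%.17g",
                     as.character(seqnames(windows))[keep],
                     start(windows)[keep] - 1L,
                     BiocGenerics::end(windows)[keep],
                     values[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a WindowSummary table
#'
#' @param summary Window summary GRanges from [summarizeWindows()].
#' @param path File path.
#' @return `readWindowSummaryTsv` returns the GRanges.
#' @export
writeWindowSummaryTsv <- function(summary, path) {
  df <- data.frame(contig = as.character(seqnames(summary)),
                   start0 = start(summary) - 1L,
                   end = BiocGenerics::end(summary),
                   as.data.frame(mcols(summary)))
  writeTsv(df, path)
}

#' @rdname writeWindowSummaryTsv
#' @export
readWindowSummaryTsv <- function(path) {
  df <- readTsv(path)
  gr <- GRanges(df$contig, IRanges(start = df$start0 + 1L, end = df$end))
  mcols(gr) <- df[, setdiff(names(df), c("contig", "start0", "end")),
                  drop = FALSE]
  gr
}
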