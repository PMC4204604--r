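suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Genome built from literal contig strings, with optional region blocks
# covering the main (first) contig so generateMethylome() can be used.
literalGenome <- function(contigs, control = names(contigs)[length(contigs)],
                          regionLength = NULL) {
  g <- new("BisGenome", sequences = DNAStringSet(contigs),
           controlContig = control)
  main <- names(contigs)[1]
  len <- nchar(contigs[[main]])
  if (is.null(regionLength)) regionLength <- len
  starts <- seq.int(1L, len, by = regionLength)
  regions <- GRanges(main, IRanges(start = starts,
                                   end = pmin(starts + regionLength - 1L,
                                              len)))
  mcols(regions)$region_id <- seq_along(regions)
  mcols(regions)$target_gc <- NA_real_
  attr(g, "regions") <- regions
  g
}

# Truth GRanges over explicit sites.
literalTruth <- function(contig, pos, strand, context, prob) {
  n <- length(pos)
  GRanges(rep_len(contig, n), IRanges(pos, width = 1L),
          strand = rep_len(strand, n),
          context = factor(context, levels = c("CG", "CHG", "CHH")),
          prob = prob)
}

# Counts GRanges from bare vectors (sites on a dummy contig by default).
literalCounts <- function(nMeth, nTotal, contig = "chr_sim",
                          context = "CG", pos = NULL) {
  n <- length(nMeth)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  GRanges(rep_len(contig, n), IRanges(pos, width = 1L),
          strand = rep_len("+", n),
          context = factor(rep_len(context, n),
                           levels = c("CG", "CHG", "CHH")),
          n_meth = as.integer(nMeth), n_total = as.integer(nTotal))
}

# Small bisulfite scenario used by several Monte-Carlo checks.
tinyConfig <- function(...) {
  args <- list(nRegions = 4L, regionLength = 2000L, controlLength = 1000L,
               nFragments = 2000L, depth = 6000L, fragmentLength = 80L,
               windowSize = 500L, cycles = c(4L, 8L, 15L))
  args <- utils::modifyList(args, list(...))
  do.call(scenarioConfig, c(list("demo"), args))
}

# Brute-force oracles -------------------------------------------------

# Binomial upper tail by explicit summation of the mass function.
bruteBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# BH step-up from the definition: sort, find largest k with
# p_(k) <= (k/m) a; q_(i) = min_{j >= i} (m/j) p_(j), capped at 1.
bruteBH <- function(p, a) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- (seq_len(m) / m) * a
  k <- suppressWarnings(max(which(ps <= thresh)))
  reject_sorted <- seq_len(m) <= ifelse(is.finite(k), k, 0)
  q_sorted <- rev(cummin(rev(pmin(ps * m / seq_len(m), 1))))
  q <- numeric(m); rej <- logical(m)
  q[o] <- q_sorted
  rej[o] <- reject_sorted
  list(q = q, reject = rej)
}

# Two-pass Pearson formula.
brutePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
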