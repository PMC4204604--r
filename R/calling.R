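#' Estimate the bisulfite non-conversion rate from the control contig
#'
#' The control contig is unmethylated by construction (the chloroplast
#' stand-in), so every methylated-looking basecall there is a conversion
#' failure. The rate is the pooled ratio of methylated basecalls to total
#' basecalls over all control-contig sites and strands, and is used as
#' the null hypothesis rate of the binomial methylation test.
#'
#' @param counts Per-cytosine counts ([pileupCytosines()]), either
#'   restricted to the control contig already or full-genome together
#'   with `controlContig`.
#' @param controlContig Name of the control contig to restrict to
#'   (optional when `counts` is already restricted).
#' @return A list of class `"NonConversionRate"` with `rate`, `nMeth`,
#'   `nTotal`.
#' @export
estimateNonconversion <- function(counts, controlContig = NULL) {
  if (!is.null(controlContig))
    counts <- counts[as.character(seqnames(counts)) == controlContig]
  nTotal <- sum(mcols(counts)$n_total)
  if (nTotal == 0)
    stop("zero basecalls on the control contig: the binomial null ",
         "cannot be formed")
  nMeth <- sum(mcols(counts)$n_meth)
  structure(list(rate = nMeth / nTotal, nMeth = nMeth, nTotal = nTotal),
            class = "NonConversionRate")
}

#' @export
print.NonConversionRate <- function(x, ...) {
  cat(sprintf("Non-conversion rate: %.5g (%d / %d control basecalls)\n",
              x$rate, x$nMeth, x$nTotal))
  invisible(x)
}

#' One-sided binomial tail p-value for methylated basecalls
#'
#' Exact upper-tail probability P(X >= n_meth) for
#' X ~ Binomial(n_total, rate): non-conversion can only inflate
#' methylated basecalls, so the test is one-sided. No normal
#' approximation is used.
#'
#' @param nMeth,nTotal Methylated and total basecall counts (vectorized);
#'   0 <= nMeth <= nTotal, nTotal >= 1.
#' @param rate Null rate in \[0, 1) — the non-conversion rate.
#' @return P-values in \[0, 1\].
#' @examples
#' binomialPValue(3, 10, 0.01)
#' @export
binomialPValue <- function(nMeth, nTotal, rate) {
  rate <- asFraction(rate, "rate", 0, 1, open_hi = TRUE)
  if (length(nMeth) != length(nTotal))
    stop("nMeth and nTotal must be parallel")
  bad <- is.na(nMeth) | is.na(nTotal) | nMeth < 0 | nTotal < 1 |
    nMeth > nTotal | nMeth != round(nMeth) | nTotal != round(nTotal)
  if (any(bad)) stop("invalid counts: need 0 <= nMeth <= nTotal, nTotal >= 1")
  pbinom(nMeth - 1, nTotal, rate, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment with rejection flags
#'
#' Standard step-up procedure: with m p-values sorted ascending, reject
#' the largest k with p_(k) <= (k/m) * fdr and all smaller; the adjusted
#' q-value of p_(i) is min over j >= i of (m/j) p_(j), capped at 1. Ties
#' share a q-value and the original order is restored.
#'
#' @param pValues Numeric p-values in \[0, 1\].
#' @param fdr Target false discovery rate in (0, 1).
#' @return data.frame with `q_value` and `reject`, parallel to the input;
#'   empty input gives an empty result.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04, 0.5), 0.05)
#' @export
bhAdjust <- function(pValues, fdr = 0.05) {
  fdr <- asFraction(fdr, "fdr", 0, 1, open_lo = TRUE, open_hi = TRUE)
  if (length(pValues) == 0L)
    return(data.frame(q_value = numeric(), reject = logical()))
  if (any(is.na(pValues)) || any(pValues < 0) || any(pValues > 1))
    stop("p-values must be in [0, 1]")
  q <- p.adjust(pValues, method = "BH")
  data.frame(q_value = q, reject = q <= fdr)
}

#' Call methylated cytosines by binomial test with BH correction
#'
#' Sites with coverage at least `minCoverage` are tested one-sided
#' against the non-conversion rate null ([binomialPValue()]) and
#' corrected jointly by Benjamini-Hochberg at the configured FDR
#' ([bhAdjust()]). Sites below the coverage floor carry no p-value and
#' `called = FALSE`. Control-contig sites, if present and named, are
#' excluded from testing. `byContext = TRUE` stratifies the BH batch per
#' context instead of one joint batch (the default).
#'
#' @param counts Per-cytosine counts ([pileupCytosines()]).
#' @param rate A `"NonConversionRate"` (from [estimateNonconversion()])
#'   or a bare numeric rate.
#' @param fdr False discovery rate cutoff (default 0.05).
#' @param minCoverage Minimum `n_total` for a site to be tested
#'   (default 1).
#' @param controlContig Optional control contig name to exclude.
#' @param byContext Stratify the BH batch by CG/CHG/CHH context.
#' @return `counts` with added metadata `p_value`, `q_value`, `called`.
#' @export
callMethylation <- function(counts, rate, fdr = 0.05, minCoverage = 1,
                            controlContig = NULL, byContext = FALSE) {
  if (inherits(rate, "NonConversionRate")) rate <- rate$rate
  rate <- asFraction(rate, "rate", 0, 1, open_hi = TRUE)
  fdr <- asFraction(fdr, "fdr", 0, 1, open_lo = TRUE, open_hi = TRUE)
  minCoverage <- asCount(minCoverage, "minCoverage", min = 1)
  nTot <- mcols(counts)$n_total
  tested <- nTot >= minCoverage
  if (!is.null(controlContig))
    tested <- tested & as.character(seqnames(counts)) != controlContig
  p <- rep(NA_real_, length(counts))
  q <- rep(NA_real_, length(counts))
  called <- rep(FALSE, length(counts))
  if (any(tested)) {
    p[tested] <- binomialPValue(mcols(counts)$n_meth[tested],
                                nTot[tested], rate)
    if (byContext) {
      for (cx in levels(mcols(counts)$context)) {
        i <- which(tested & mcols(counts)$context == cx)
        if (!length(i)) next
        adj <- bhAdjust(p[i], fdr)
        q[i] <- adj$q_value
        called[i] <- adj$reject
      }
    } else {
      adj <- bhAdjust(p[tested], fdr)
      q[tested] <- adj$q_value
      called[tested] <- adj$reject
    }
  }
  mcols(counts)$p_value <- p
  mcols(counts)$q_value <- q
  mcols(counts)$called <- called
  counts
}

#' Weighted methylation level of a set of sites
#'
#' The coverage-weighted level: the sum of methylated basecalls over the
#' sum of all basecalls across the sites — not the mean of per-site
#' fractions, so a deeply covered unmethylated site outweighs a shallow
#' methylated one.
#'
#' @param counts Per-cytosine counts (a GRanges with `n_meth`/`n_total`
#'   metadata, or a data.frame with those columns).
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`).
#' @return A fraction in \[0, 1\], or `NA` when the sites carry no
#'   basecalls (undefined, not 0).
#' @examples
#' weightedMethylation(data.frame(n_meth = c(10, 0), n_total = c(10, 90)))
#' @export
weightedMethylation <- function(counts, context = NULL) {
  df <- if (is(counts, "GRanges")) as.data.frame(mcols(counts)) else counts
  if (!is.null(context)) df <- df[df$context %in% context, , drop = FALSE]
  tot <- sum(df$n_total)
  if (tot == 0) return(NA_real_)
  sum(df$n_meth) / tot
}
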