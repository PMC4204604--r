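#' Construct an enzyme amplification-efficiency profile
#'
#' Three presets capture the qualitatively distinct behaviours of
#' uracil-tolerant polymerases on bisulfite-converted template:
#' \describe{
#'   \item{`"pfu-like"`}{strong GC-dependent bias, `gcCoefficient` 0.8.}
#'   \item{`"kapa-like"`}{flat efficiency, `gcCoefficient` 0 — the
#'     unbiased null.}
#'   \item{`"epimark-like"`}{moderate bias (`gcCoefficient` 0.4) that
#'     saturates above GC 0.6.}
#' }
#' All presets use `baseEfficiency` 0.5 at GC 0.5. The presets are
#' modelling choices calibrated to be qualitatively distinguishable at
#' desk scale, not measured enzyme constants.
#'
#' @param name A preset name, or any label when the numeric parameters
#'   are given explicitly.
#' @param baseEfficiency,gcCoefficient,saturationGC Override the preset
#'   parameters; see [EnzymeProfile-class].
#' @return An [EnzymeProfile-class].
#' @examples
#' enzymeProfile("pfu-like")
#' enzymeProfile("custom", baseEfficiency = 0.6, gcCoefficient = 0.2)
#' @export
enzymeProfile <- function(name, baseEfficiency = NULL, gcCoefficient = NULL,
                          saturationGC = NULL) {
  presets <- list(
    "pfu-like" = list(e0 = 0.5, gamma = 0.8, sat = NA_real_),
    "kapa-like" = list(e0 = 0.5, gamma = 0.0, sat = NA_real_),
    "epimark-like" = list(e0 = 0.5, gamma = 0.4, sat = 0.6))
  p <- presets[[name]]
  if (is.null(p)) {
    if (is.null(baseEfficiency) || is.null(gcCoefficient))
      stop("unknown preset '", name, "'; give baseEfficiency and ",
           "gcCoefficient explicitly (presets: ",
           paste(names(presets), collapse = ", "), ")")
    p <- list(e0 = baseEfficiency, gamma = gcCoefficient,
              sat = if (is.null(saturationGC)) NA_real_ else saturationGC)
  } else {
    if (!is.null(baseEfficiency)) p$e0 <- baseEfficiency
    if (!is.null(gcCoefficient)) p$gamma <- gcCoefficient
    if (!is.null(saturationGC)) p$sat <- saturationGC
  }
  new("EnzymeProfile", name = name, baseEfficiency = as.numeric(p$e0),
      gcCoefficient = as.numeric(p$gamma),
      saturationGC = as.numeric(p$sat))
}

#' Per-cycle amplification efficiency at a given GC fraction
#'
#' \eqn{e(g) = \mathrm{clamp}(e_0 + \gamma(\min(g, s) - 0.5), 0, 1)} with
#' saturation point s (ignored when NA).
#'
#' @param profile An [EnzymeProfile-class].
#' @param gc GC fraction(s) in \[0, 1\].
#' @return Efficiencies in \[0, 1\], vectorized over `gc`.
#' @export
amplificationEfficiency <- function(profile, gc) {
  stopifnot(is(profile, "EnzymeProfile"))
  if (any(is.na(gc)) || any(gc < 0) || any(gc > 1))
    stop("gc must be in [0, 1]")
  g <- if (is.na(profile@saturationGC)) gc else pmin(gc, profile@saturationGC)
  pmin(pmax(profile@baseEfficiency +
              profile@gcCoefficient * (g - 0.5), 0), 1)
}

#' PCR-amplify a fragment pool and sample a read library
#'
#' Models PCR as deterministic exponential copy weights: a fragment with
#' post-conversion GC fraction g accrues weight \eqn{(1 + e(g))^C} over C
#' cycles, where e is the enzyme's efficiency function. Reads are then
#' drawn with replacement with probability proportional to the weights
#' (the multinomial sampling reintroduces library-level variance). Reads
#' are the full fragment sequences; no sub-read sampling or sequencing
#' error is applied.
#'
#' With 0 cycles, or a GC-independent efficiency, sampling is uniform.
#'
#' @param pool A [FragmentPool-class] (converted for bisulfite libraries;
#'   an unconverted pool models a genomic DNA library).
#' @param enzyme An [EnzymeProfile-class].
#' @param cycles PCR cycle count (>= 0).
#' @param depth Number of reads to draw (>= 1).
#' @param seed Integer seed.
#' @return A [SimulatedLibrary-class].
#' @export
amplifyAndSample <- function(pool, enzyme, cycles, depth, seed) {
  stopifnot(is(pool, "FragmentPool"), is(enzyme, "EnzymeProfile"))
  cycles <- asCount(cycles, "cycles", min = 0)
  depth <- asCount(depth, "depth", min = 1)
  if (length(pool@sequences) == 0L) stop("empty fragment pool")
  g <- gcContent(pool@sequences)
  w <- (1 + amplificationEfficiency(enzyme, g))^cycles
  withSeed(seed, {
    idx <- sample.int(length(w), depth, replace = TRUE, prob = w)
  })
  o <- pool@origins[idx, , drop = FALSE]
  origins <- data.frame(read_id = sprintf("read_%07d", seq_len(depth)),
                        contig = o$contig, start = o$start,
                        strand = o$strand, stringsAsFactors = FALSE)
  new("SimulatedLibrary", reads = pool@sequences[idx], origins = origins,
      cycles = cycles, enzyme = enzyme@name,
      nonConversionRate = pool@nonConversionRate,
      seed = asCount(seed, "seed"))
}
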