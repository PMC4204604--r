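# Internal helpers shared across modules.

# Run `expr` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- asCount(seed, "seed", min = 0)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

asCount <- function(x, what, min = 0) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x) ||
      x < min)
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}

asFraction <- function(x, what, lo = 0, hi = 1, open_lo = FALSE,
                       open_hi = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok)
    stop(what, " must be in ", if (open_lo) "(" else "[", lo, ", ", hi,
         if (open_hi) ")" else "]", call. = FALSE)
  as.numeric(x)
}

checkAlphabet <- function(sequence, what = "sequence") {
  if (length(sequence) == 0L)
    stop(what, " must be provided", call. = FALSE)
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(sequence)
}

# Reverse-complement plain character vectors.
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
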