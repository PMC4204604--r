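#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3. Pairs with missing
#'   values are dropped. With zero variance in either vector the
#'   coefficient is undefined and returned as NA.
#' @return The correlation coefficient in \[-1, 1\], or NA.
#' @examples
#' pearsonR(c(0, 1, 2, 3), c(1, 0, 3, 2))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# One pass of the outlier screen on the active subset: Bonferroni-adjusted
# two-sided p of the externally studentized residuals (df = n - 3 for a
# simple regression). An (essentially) exact fit has no outliers; an
# infinite studentized residual (the deleted fit is exact) is maximally
# outlying.
.studentizedScreen <- function(x, y) {
  fit <- lm(y ~ x)
  n <- length(x)
  res <- stats::residuals(fit)
  if (sqrt(mean(res^2)) <= 1e-10 * (stats::sd(y) + 1e-300))
    return(data.frame(t = rep(0, n), p_bonf = rep(1, n)))
  infl <- stats::lm.influence(fit)
  tol <- 1e-10 * (stats::sd(y) + 1e-300)
  denom <- infl$sigma * sqrt(pmax(1 - infl$hat, 0))
  # deleted-fit sigma of 0 with a real residual: infinitely outlying
  t <- ifelse(denom > tol, res / denom,
              ifelse(abs(res) > tol, sign(res) * Inf, 0))
  p <- 2 * pt(-abs(t), df = n - 3)
  p[is.infinite(t)] <- 0
  data.frame(t = t, p_bonf = pmin(n * p, 1))
}

#' Identify regression outliers by Bonferroni-adjusted studentized residuals
#'
#' Fits ordinary least squares of y on x, computes externally studentized
#' residuals, and flags points whose Bonferroni-adjusted two-sided t
#' p-value (n times the raw p, with n - 3 degrees of freedom) falls below
#' `alpha`. By default removal is iterative: the single most extreme
#' flagged point is removed and the model refit, until nothing is flagged
#' or the removal cap of `maxFraction` of the input points is reached.
#' `oneShot = TRUE` instead flags from a single fit (most extreme first,
#' up to the cap).
#'
#' @param x,y Numeric vectors, length >= 5.
#' @param alpha Significance level of the Bonferroni outlier test.
#' @param maxFraction Cap on the fraction of points removable
#'   (`ceiling(maxFraction * n)` points); 0 disables trimming.
#' @param oneShot Flag from a single fit instead of iterating.
#' @return Integer indices (into `x`) of the flagged outliers.
#' @export
bonferroniOutliers <- function(x, y, alpha = 0.05, maxFraction = 0.05,
                               oneShot = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5L) stop("need at least 5 points for the outlier test")
  alpha <- asFraction(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  asFraction(maxFraction, "maxFraction", 0, 1)
  cap <- ceiling(maxFraction * length(x))
  if (cap == 0L) return(integer())
  active <- which(complete.cases(x, y))
  removed <- integer()
  if (oneShot) {
    scr <- .studentizedScreen(x[active], y[active])
    flagged <- which(scr$p_bonf < alpha)
    flagged <- flagged[order(-abs(scr$t[flagged]))]
    return(sort(active[utils::head(flagged, cap)]))
  }
  while (length(removed) < cap && length(active) >= 5L) {
    scr <- .studentizedScreen(x[active], y[active])
    if (min(scr$p_bonf) >= alpha) break
    worst <- which.max(abs(scr$t))
    removed <- c(removed, active[worst])
    active <- active[-worst]
  }
  sort(removed)
}

#' Outlier-trimmed simple linear regression
#'
#' Removes Bonferroni outliers ([bonferroniOutliers()]) capped at
#' `maxFraction` of the points, then fits ordinary least squares and the
#' Pearson correlation on the retained points. With `maxFraction = 0`
#' this is plain OLS on all points.
#'
#' @inheritParams bonferroniOutliers
#' @return A [RegressionResult-class].
#' @examples
#' fit <- trimmedRegression(0:9, 2 * (0:9) + 1)
#' fit
#' @export
trimmedRegression <- function(x, y, alpha = 0.05, maxFraction = 0.05,
                              oneShot = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  out <- if (maxFraction > 0 && length(x) >= 5L)
    bonferroniOutliers(x, y, alpha, maxFraction, oneShot) else integer()
  keep <- setdiff(which(complete.cases(x, y)), out)
  if (length(keep) < 3L) stop("fewer than 3 points retained")
  xr <- x[keep]; yr <- y[keep]
  fit <- lm(yr ~ xr)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)[2])
  se <- if (nrow(sm) >= 2) unname(sm[2, 2]) else NA_real_
  r <- if (stats::sd(xr) == 0 || stats::sd(yr) == 0) NA_real_ else
    cor(xr, yr)
  new("RegressionResult",
      slope = slope, intercept = unname(coef(fit)[1]),
      slopeSE = se,
      slopeT = if (is.na(se) || se == 0) NA_real_ else slope / se,
      r = r, rSquared = if (is.na(r)) NA_real_ else r^2,
      nInput = length(x), nUsed = length(keep),
      outlierIndices = as.integer(out))
}

#' Pairwise Pearson correlation of per-window coverage across libraries
#'
#' Compares scaled window counts between cycle conditions (or any set of
#' libraries sharing a window set); each pair is correlated over its
#' shared non-missing windows.
#'
#' @param libraries Named list of numeric per-window vectors, all the
#'   same length.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
cycleCorrelationMatrix <- function(libraries) {
  if (!length(libraries)) stop("no libraries supplied")
  n <- lengths(libraries)
  if (length(unique(n)) != 1L)
    stop("window mismatch: libraries differ in window count")
  m <- length(libraries)
  nm <- names(libraries)
  if (is.null(nm)) nm <- paste0("lib", seq_len(m))
  out <- matrix(NA_real_, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m)) {
    out[i, i] <- 1
    for (j in seq_len(m)[-seq_len(i)]) {
      out[i, j] <- out[j, i] <- pearsonR(libraries[[i]], libraries[[j]])
    }
  }
  out
}
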