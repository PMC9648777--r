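#' Interpolate age-banded rates to single-year ages
#'
#' Grouped epidemiological rates (mortality, disease hazards, disability
#' rates) are routinely published by age band but consumed by a single-year
#' cohort model. This reproduces the interpolation/smoothing role that
#' grouped-data tools play in life-table modelling: a shape-preserving
#' monotone (Fritsch--Carlson) piecewise-cubic through the band midpoints,
#' evaluated at every single-year age.
#'
#' Between the outermost band midpoints the interpolant cannot overshoot the
#' neighbouring band values (monotone cubic property). Beyond the outermost
#' midpoints the curve is extended linearly with the boundary tangent and
#' floored at zero, so that rates which are linear in the band midpoints are
#' recovered exactly over the whole age range.
#'
#' @param bands data.frame with columns `age_lo`, `age_hi` (inclusive integer
#'   bounds of contiguous bands) and `rate` (nonnegative).
#' @param ages integer vector of target single-year ages; defaults to the full
#'   range covered by the bands.
#' @return data.frame with columns `age` and `rate`.
#' @examples
#' b <- data.frame(age_lo = c(20, 60), age_hi = c(59, 100), rate = c(0.01, 0.03))
#' head(interpolate_to_single_year(b))
#' @export
interpolate_to_single_year <- function(bands, ages = NULL) {
  stopifnot(is.data.frame(bands),
            all(c("age_lo", "age_hi", "rate") %in% names(bands)))
  bands <- bands[order(bands$age_lo), , drop = FALSE]
  if (any(bands$rate < 0)) {
    stop("interpolate_to_single_year: negative band rates", call. = FALSE)
  }
  if (any(bands$age_hi < bands$age_lo)) {
    stop("interpolate_to_single_year: band with age_hi < age_lo", call. = FALSE)
  }
  if (nrow(bands) > 1) {
    gaps <- bands$age_lo[-1] - bands$age_hi[-nrow(bands)]
    if (any(gaps != 1)) {
      stop("interpolate_to_single_year: bands must be contiguous (gap/overlap found)",
           call. = FALSE)
    }
  }
  if (is.null(ages)) ages <- seq(min(bands$age_lo), max(bands$age_hi))
  mid <- (bands$age_lo + bands$age_hi) / 2
  if (nrow(bands) == 1) {
    return(data.frame(age = ages, rate = rep(bands$rate, length(ages))))
  }
  if (nrow(bands) == 2) {
    # two knots: the monotone cubic degenerates to the straight line
    slope <- diff(bands$rate) / diff(mid)
    out <- bands$rate[1] + slope * (ages - mid[1])
  } else {
    fit <- function(targets, at) {
      f <- stats::splinefun(mid, targets, method = "monoH.FC")
      out <- f(at)
      # linear tangent extension outside the outermost midpoints
      lo <- at < mid[1]
      hi <- at > mid[length(mid)]
      if (any(lo)) out[lo] <- f(mid[1]) + f(mid[1], deriv = 1) * (at[lo] - mid[1])
      if (any(hi)) {
        mk <- mid[length(mid)]
        out[hi] <- f(mk) + f(mk, deriv = 1) * (at[hi] - mk)
      }
      pmax(out, 0)
    }
    # knot targets are nudged multiplicatively (and clamped to the input
    # range) so band means of the curve reproduce the band inputs; linear
    # and constant inputs are fixed points of the correction
    full_ages <- seq(min(bands$age_lo), max(bands$age_hi))
    targets <- bands$rate
    for (it in 1:4) {
      bm <- band_means(data.frame(age = full_ages,
                                  rate = fit(targets, full_ages)), bands)
      adj <- ifelse(bm > 0, bands$rate / bm, 1)
      targets <- pmin(pmax(targets * adj, min(bands$rate)), max(bands$rate))
    }
    out <- fit(targets, ages)
  }
  data.frame(age = ages, rate = pmax(out, 0))
}

#' Band means of a single-year rate table
#'
#' Audit helper: averages a single-year rate over each input band, to check
#' that interpolation preserves the banded inputs.
#'
#' @param single data.frame with `age`, `rate`.
#' @param bands data.frame with `age_lo`, `age_hi`.
#' @return numeric vector, one mean per band.
#' @export
band_means <- function(single, bands) {
  vapply(seq_len(nrow(bands)), function(i) {
    sel <- single$age >= bands$age_lo[i] & single$age <= bands$age_hi[i]
    mean(single$rate[sel])
  }, numeric(1))
}
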