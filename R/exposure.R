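#' Continuous exposure distributions
#'
#' A stratum's risk-factor exposure (BMI in kg/m2, or SSB intake in
#' servings/day) is summarised by a two-parameter continuous distribution.
#' The lognormal family (the default, matching common burden-of-disease
#' practice for BMI) is parameterised by its arithmetic mean and standard
#' deviation via moment matching, so interventions and secular trends can be
#' expressed as shifts of the arithmetic mean with the standard deviation
#' held fixed.
#'
#' @param mean arithmetic mean of the exposure (> 0 for lognormal).
#' @param sd arithmetic standard deviation (> 0).
#' @param family `"lognormal"` or `"normal"`.
#' @return object of class `exposure_dist`.
#' @export
exposure_distribution <- function(mean, sd, family = c("lognormal", "normal")) {
  family <- match.arg(family)
  if (sd <= 0) stop("exposure_distribution: sd must be > 0", call. = FALSE)
  if (family == "lognormal" && mean <= 0) {
    stop("exposure_distribution: lognormal mean must be > 0", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, family = family),
            class = "exposure_dist")
}

.lnorm_pars <- function(mean, sd) {
  s2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' @rdname exposure_distribution
#' @param x quantiles at which to evaluate the density.
#' @param dist an `exposure_dist`.
#' @export
d_exposure <- function(x, dist) {
  if (dist$family == "normal") return(stats::dnorm(x, dist$mean, dist$sd))
  p <- .lnorm_pars(dist$mean, dist$sd)
  stats::dlnorm(x, p$meanlog, p$sdlog)
}

#' @rdname exposure_distribution
#' @param q probabilities for the quantile / distribution functions.
#' @export
q_exposure <- function(q, dist) {
  if (dist$family == "normal") return(stats::qnorm(q, dist$mean, dist$sd))
  p <- .lnorm_pars(dist$mean, dist$sd)
  stats::qlnorm(q, p$meanlog, p$sdlog)
}

#' @rdname exposure_distribution
#' @export
p_exposure <- function(x, dist) {
  if (dist$family == "normal") return(stats::pnorm(x, dist$mean, dist$sd))
  p <- .lnorm_pars(dist$mean, dist$sd)
  stats::plnorm(x, p$meanlog, p$sdlog)
}

#' Shift an exposure distribution's mean
#'
#' Location shift of the arithmetic mean with the standard deviation held
#' fixed (the intervention and the secular trend both act on the mean only).
#'
#' @param dist an `exposure_dist`.
#' @param delta shift to add to the mean (same units as the exposure).
#' @return a new `exposure_dist`.
#' @export
shift_exposure <- function(dist, delta) {
  exposure_distribution(dist$mean + delta, dist$sd, dist$family)
}

#' Apply the secular trend to an exposure distribution
#'
#' Shifts the mean by `trend_slope * (year - base_year)`. The identical shift
#' is applied to comparator and intervention arms, so the tax-attributable
#' difference in means is unaffected by the trend. A missing/NA slope is
#' treated as zero with a warning.
#'
#' @param dist an `exposure_dist`.
#' @param year calendar year to project to.
#' @param base_year reference year of the distribution.
#' @param trend_slope mean change per calendar year (e.g. kg/m2 per year).
#' @return a new `exposure_dist`.
#' @export
apply_trend <- function(dist, year, base_year, trend_slope) {
  if (is.null(trend_slope) || is.na(trend_slope)) {
    warning("apply_trend: missing trend slope treated as 0")
    trend_slope <- 0
  }
  shift_exposure(dist, trend_slope * (year - base_year))
}
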