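#' Relative-risk function for a continuous exposure
#'
#' Log-linear relative risk above a theoretical minimum-risk exposure level
#' (TMREL): \eqn{RR(x) = rr^{(x - tmrel)_+ / per}}, flat at 1 below the
#' TMREL. For BMI, `rr` is the risk ratio per 5 kg/m2 (`per = 5`,
#' `tmrel = 22.5` by default); for a direct consumption pathway, `rr` is the
#' risk ratio per serving/day (`per = 1`, `tmrel = 0`).
#'
#' @param rr risk ratio per `per` exposure units, >= 1.
#' @param tmrel exposure level below which RR = 1.
#' @param per exposure increment over which `rr` applies.
#' @return object of class `risk_function`.
#' @export
risk_function <- function(rr, tmrel = 22.5, per = 5) {
  if (rr < 1) stop("risk_function: rr must be >= 1", call. = FALSE)
  if (per <= 0) stop("risk_function: per must be > 0", call. = FALSE)
  structure(list(rr = rr, tmrel = tmrel, per = per), class = "risk_function")
}

#' @rdname risk_function
#' @param rf a `risk_function`.
#' @param x exposure values.
#' @export
rr_eval <- function(rf, x) {
  exp(log(rf$rr) * pmax(x - rf$tmrel, 0) / rf$per)
}

#' Potential impact fraction of an exposure shift
#'
#' The proportional change in disease risk caused by moving the exposure
#' distribution from \eqn{P} to \eqn{P^*}:
#' \deqn{PIF = \frac{\int_l^h RR(x)P(x)dx - \int_l^h RR(x)P^*(x)dx}
#'                  {\int_l^h RR(x)P(x)dx}.}
#' The integrals are evaluated by adaptive quadrature. Default bounds are
#' the 0.1th and 99.9th percentiles of the comparator distribution.
#'
#' @param rr a [risk_function()].
#' @param p comparator [exposure_distribution()].
#' @param p_star post-intervention [exposure_distribution()] (same stratum).
#' @param bounds optional `c(l, h)` integration bounds, `l < h`.
#' @return scalar PIF, `<= 1`; 0 when the distributions are identical.
#' @export
compute_pif <- function(rr, p, p_star, bounds = NULL) {
  if (is.null(bounds)) bounds <- q_exposure(c(0.001, 0.999), p)
  if (bounds[1] >= bounds[2]) stop("compute_pif: need l < h", call. = FALSE)
  if (identical(unclass(p), unclass(p_star))) return(0)
  ig <- function(dist) {
    stats::integrate(function(x) rr_eval(rr, x) * d_exposure(x, dist),
                     bounds[1], bounds[2],
                     rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 400L)$value
  }
  num <- ig(p)
  if (num <= 0) stop("compute_pif: nonpositive denominator", call. = FALSE)
  (num - ig(p_star)) / num
}

# Vectorised fixed-grid PIF for the production pipeline.
#
# Simpson quadrature on one shared exposure grid for a whole block of strata
# and diseases at once: `rrs` is a vector of risk ratios (one per disease,
# same tmrel/per), `mean`/`sd`/`delta` are parallel vectors over strata.
# Returns a (diseases x strata) matrix of PIFs. Identical comparator and
# shifted parameters (delta == 0) give exactly zero.
.pif_grid <- function(rrs, tmrel, per, mean, sd, delta,
                      family = "lognormal", n_nodes = 241L, lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    qf <- function(q, m, s) {
      if (family == "normal") stats::qnorm(q, m, s)
      else {
        s2 <- log1p((s / m)^2)
        stats::qlnorm(q, log(m) - s2 / 2, sqrt(s2))
      }
    }
    lo <- min(qf(2e-4, mean, sd), qf(2e-4, mean + delta, sd))
    hi <- max(qf(1 - 2e-4, mean, sd), qf(1 - 2e-4, mean + delta, sd))
  }
  simpson <- function(a, b, k) {
    if (k %% 2L == 0L) k <- k + 1L
    xx <- seq(a, b, length.out = k)
    hh <- xx[2] - xx[1]
    ww <- rep(c(2, 4), length.out = k); ww[1] <- ww[k] <- 1
    list(x = xx, w = ww * hh / 3)
  }
  # split the panel at the TMREL kink of the risk function so the composite
  # rule only ever integrates smooth pieces
  if (tmrel > lo && tmrel < hi) {
    k1 <- max(11L, as.integer(round(n_nodes * (tmrel - lo) / (hi - lo))))
    s1 <- simpson(lo, tmrel, k1)
    s2 <- simpson(tmrel, hi, max(11L, n_nodes - k1))
    x <- c(s1$x, s2$x); w <- c(s1$w, s2$w)
  } else {
    s <- simpson(lo, hi, n_nodes)
    x <- s$x; w <- s$w
  }
  n_nodes <- length(x)

  ns <- length(mean)
  X <- matrix(x, n_nodes, ns)
  dens <- function(m) {
    # (n_nodes x n_strata) density matrix, one vectorised density call
    if (family == "normal") {
      stats::dnorm(X, matrix(m, n_nodes, ns, byrow = TRUE),
                   matrix(sd, n_nodes, ns, byrow = TRUE))
    } else {
      s2 <- log1p((sd / m)^2)
      stats::dlnorm(X, matrix(log(m) - s2 / 2, n_nodes, ns, byrow = TRUE),
                    matrix(sqrt(s2), n_nodes, ns, byrow = TRUE))
    }
  }
  P <- dens(mean)
  Ps <- if (all(delta == 0)) P else dens(mean + delta)
  RRm <- exp(outer(log(rrs) / per, pmax(x - tmrel, 0)))  # diseases x nodes
  num <- RRm %*% (w * P)
  num_s <- if (all(delta == 0)) num else RRm %*% (w * Ps)
  1 - num_s / num
}
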