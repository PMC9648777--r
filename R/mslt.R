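#' Build a proportional multi-state life table for one cohort
#'
#' Merges modelled-disease mortality and disability back onto the residual
#' ("minus") all-other-cause rates: total mortality
#' \eqn{m(x) = m^-(x) + \sum_d m_d(x)} and total disability
#' \eqn{w(x) = w^-(x) + \sum_d w_d(x)}, then the classic columns
#' \eqn{q = 1 - e^{-m}} (constant hazard within the year; the alternative
#' actuarial conversion \eqn{m/(1 + m/2)} is available), survivors
#' \eqn{l_{x+1} = l_x (1 - q_x)}, person-years \eqn{L_x = (l_x + l_{x+1})/2}
#' with an exponential tail \eqn{L = l/m} at the terminal age, health-adjusted
#' person-years \eqn{Lw_x = L_x (1 - w_x)}, and life expectancy / DALE by
#' backward cumulation.
#'
#' @param ages attained ages of the cohort (increasing by 1).
#' @param l0 cohort size at entry (persons).
#' @param m_minus mortality hazard excluding modelled diseases, per age.
#' @param w_minus pYLD rate excluding modelled diseases, per age.
#' @param m_dis summed modelled-disease mortality hazard per age (this arm).
#' @param w_dis summed modelled-disease pYLD per age (this arm).
#' @param qx_convention `"exponential"` (default) or `"actuarial"`.
#' @return data.frame with columns `x, m, q, l, L, w, Lw, e, dale`.
#' @export
build_life_table <- function(ages, l0, m_minus, w_minus,
                             m_dis = 0, w_dis = 0,
                             qx_convention = c("exponential", "actuarial")) {
  qx_convention <- match.arg(qx_convention)
  n <- length(ages)
  m_dis <- rep_len(m_dis, n); w_dis <- rep_len(w_dis, n)
  if (any(m_minus < -1e-12)) {
    bad <- ages[which(m_minus < -1e-12)[1]]
    stop("build_life_table: negative residual mortality at age ", bad, call. = FALSE)
  }
  if (any(w_minus < -1e-12)) {
    bad <- ages[which(w_minus < -1e-12)[1]]
    stop("build_life_table: negative residual pYLD at age ", bad, call. = FALSE)
  }
  m <- m_minus + m_dis
  w <- pmin(w_minus + w_dis, 1)
  q <- if (qx_convention == "exponential") -expm1(-m) else m / (1 + m / 2)
  l <- numeric(n + 1)
  l[1] <- l0
  for (k in seq_len(n)) l[k + 1] <- l[k] * (1 - q[k])
  L <- (l[-(n + 1)] + l[-1]) / 2
  # terminal age: exponential tail holds all remaining person-years
  L[n] <- if (m[n] > 0) l[n] / m[n] else l[n]
  Lw <- L * (1 - w)
  e <- rev(cumsum(rev(L)))
  dale <- rev(cumsum(rev(Lw)))
  pos <- l[seq_len(n)] > 0
  e <- ifelse(pos, e / l[seq_len(n)], 0)
  dale <- ifelse(pos, dale / l[seq_len(n)], 0)
  data.frame(x = ages, m = m, q = q, l = l[seq_len(n)], L = L,
             w = w, Lw = Lw, e = e, dale = dale)
}

#' DALYs averted between two life-table arms
#'
#' The arm difference in health-adjusted person-years: per year,
#' `sum over strata of (Lw_intervention - Lw_comparator)`. Nonnegative when
#' the intervention weakly reduces every hazard and disability rate.
#'
#' @param comparator,intervention life tables from [build_life_table()]
#'   (same cohort and ages), or lists of them (one per stratum).
#' @return numeric vector of DALYs averted by year of follow-up.
#' @export
dalys_averted <- function(comparator, intervention) {
  if (is.data.frame(comparator)) comparator <- list(comparator)
  if (is.data.frame(intervention)) intervention <- list(intervention)
  if (length(comparator) != length(intervention)) {
    stop("dalys_averted: mismatched strata", call. = FALSE)
  }
  out <- NULL
  for (k in seq_along(comparator)) {
    a <- comparator[[k]]; b <- intervention[[k]]
    if (!identical(a$x, b$x)) stop("dalys_averted: mismatched ages", call. = FALSE)
    d <- b$Lw - a$Lw
    if (is.null(out)) out <- d else out <- out + d
  }
  out
}

#' QALYs from survivorship and BMI-category prevalences
#'
#' Per year, `L * (p_normal u_n + p_overweight u_ow + p_obese u_ob)` summed
#' over strata; the gain between arms includes both the utility-weight effect
#' of the obesity-prevalence shift and the survival (L) difference.
#'
#' @param L person-years alive per year (vector or matrix, strata in columns).
#' @param prev 3-column matrix/array of category prevalences per year
#'   (`p_normal`, `p_overweight`, `p_obese`).
#' @param utilities length-3 utility weights `(u_normal, u_overweight,
#'   u_obese)` or a matrix matching `prev`'s rows.
#' @return QALYs per year.
#' @export
qalys_from_prevalence <- function(L, prev, utilities) {
  prev <- rbind(prev)
  if (is.null(dim(utilities))) {
    utilities <- matrix(utilities, nrow(prev), 3, byrow = TRUE)
  }
  ubar <- rowSums(prev * utilities)
  L * ubar
}

#' QALYs gained between two arms
#'
#' @param qaly_comparator,qaly_intervention QALY streams by year (from
#'   [qalys_from_prevalence()], already summed over strata).
#' @return QALYs gained per year (intervention minus comparator).
#' @export
qalys_gained <- function(qaly_comparator, qaly_intervention) {
  if (length(qaly_comparator) != length(qaly_intervention)) {
    stop("qalys_gained: mismatched streams", call. = FALSE)
  }
  qaly_intervention - qaly_comparator
}
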