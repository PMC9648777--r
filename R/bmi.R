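#' Steady-state BMI change from a sustained energy-intake change
#'
#' Energy-balance relation: a sustained change of `rho` kcal/day in energy
#' intake moves steady-state body weight by 1 kg, so
#' \eqn{\Delta BMI = (\Delta TEI / \rho) / height^2}. The full steady-state
#' effect is applied from the first cycle and held for life, mirroring the
#' one-time sustained consumption change.
#'
#' @param delta_tei change in total energy intake, kcal/person/day
#'   (negative under a tax).
#' @param height_m height in metres (> 0).
#' @param rho kcal/day of sustained intake change per kg of steady-state
#'   weight change (default 22.5, about 94 kJ).
#' @return change in BMI, kg/m2.
#' @examples
#' energy_to_bmi(-22.5, 1.70)  # about -0.346
#' @export
energy_to_bmi <- function(delta_tei, height_m, rho = 22.5) {
  if (any(rho <= 0)) stop("energy_to_bmi: rho must be > 0", call. = FALSE)
  if (any(height_m <= 0)) stop("energy_to_bmi: height must be > 0", call. = FALSE)
  (delta_tei / rho) / height_m^2
}

#' BMI category prevalences of a stratum distribution
#'
#' Probabilities of normal weight (BMI <= 25), overweight (25 < BMI <= 30)
#' and obesity (BMI > 30) under the stratum's exposure distribution.
#'
#' @param dist an [exposure_distribution()] of BMI.
#' @return named numeric vector `(p_normal, p_overweight, p_obese)`,
#'   summing to 1.
#' @export
category_prevalence <- function(dist) {
  f25 <- p_exposure(25, dist)
  f30 <- p_exposure(30, dist)
  c(p_normal = f25, p_overweight = f30 - f25, p_obese = 1 - f30)
}

#' Overweight/obesity cases prevented by an intervention
#'
#' Per stratum, the drop in combined overweight + obesity prevalence times
#' the stratum population, floored at zero (a stratum where combined
#' prevalence rises contributes nothing), summed over strata.
#'
#' @param pre matrix or vector of pre-intervention category prevalences
#'   (columns/names `p_normal`, `p_overweight`, `p_obese`), one row per
#'   stratum.
#' @param post matching post-intervention prevalences.
#' @param population stratum population counts.
#' @return total cases prevented (persons).
#' @export
cases_prevented <- function(pre, post, population) {
  pre <- rbind(pre); post <- rbind(post)
  over_pre <- pre[, "p_overweight"] + pre[, "p_obese"]
  over_post <- post[, "p_overweight"] + post[, "p_obese"]
  sum(population * pmax(0, over_pre - over_post))
}
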