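#' Boltzmann-Arrhenius rate
#'
#' Evaluates the monotone reaction-kinetics temperature response
#' `value_at_ref * exp(arrhenius * (1/t_ref - 1/t))`. Used for mortality rates
#' and the monotonic competition response.
#'
#' @param p an [arrhenius_params()] object.
#' @param t temperature(s) in Kelvin; must be positive.
#' @return rate(s) per day, same length as `t`.
#' @export
#' @examples
#' arrhenius_rate(arrhenius_params(0.0926, 12355.6, 297), 297) # = 0.0926 at t_ref
arrhenius_rate <- function(p, t) {
  stopifnot(inherits(p, "arrhenius_params"))
  check_kelvin(t)
  p$value_at_ref * exp(p$arrhenius * (1 / p$t_ref - 1 / t))
}

#' Gaussian rate
#'
#' Evaluates the symmetric unimodal temperature response
#' `peak * exp(-(t - t_opt)^2 / (2 * breadth^2))`. Used for the birth rate and
#' the unimodal competition response.
#'
#' @param p a [gaussian_params()] object.
#' @param t temperature(s) in Kelvin; must be positive.
#' @return rate(s) per day.
#' @export
gaussian_rate <- function(p, t) {
  stopifnot(inherits(p, "gaussian_params"))
  check_kelvin(t)
  p$peak * exp(-(t - p$t_opt)^2 / (2 * p$breadth^2))
}

#' Sharpe-Schoolfield maturation rate
#'
#' Evaluates the thermodynamic rate-process model of the maturation rate:
#' an Arrhenius numerator scaled by `t/t_ref`, divided by
#' `1 + exp(a_low*(1/t_half_low - 1/t)) + exp(a_high*(1/t_half_high - 1/t))`.
#' Inactivation terms whose parameters are absent are dropped; when both are
#' absent the `t/t_ref` prefactor is dropped too and the response reduces to a
#' bare exponential (see [maturation_family()]).
#'
#' @param p a [schoolfield_params()] object.
#' @param t temperature(s) in Kelvin; must be positive.
#' @return maturation rate(s) per day.
#' @export
maturation_rate <- function(p, t) {
  stopifnot(inherits(p, "schoolfield_params"))
  check_kelvin(t)
  num <- p$value_at_ref * exp(p$arrhenius * (1 / p$t_ref - 1 / t))
  fam <- maturation_family(p)
  if (fam == "exponential") return(num)
  den <- 1 + exp(p$a_high * (1 / p$t_half_high - 1 / t))
  if (fam == "full") den <- den + exp(p$a_low * (1 / p$t_half_low - 1 / t))
  (t / p$t_ref) * num / den
}

#' Per-capita competition strength
#'
#' Dispatches the temperature response of self-limitation to the Arrhenius
#' (monotonic) or Gaussian (unimodal) evaluator according to the populated
#' parameter block.
#'
#' @param c a [competition_spec()] object.
#' @param t temperature(s) in Kelvin.
#' @return per-individual competition coefficient(s).
#' @export
competition_strength <- function(c, t) {
  stopifnot(inherits(c, "competition_spec"))
  if (c$shape == "monotonic") arrhenius_rate(c$params, t) else gaussian_rate(c$params, t)
}

#' Juvenile stage duration at constant temperature
#'
#' The developmental delay `tau(T) = 1 / m_J(T)`: the time to develop through
#' the juvenile stage at constant temperature.
#'
#' @param p a [schoolfield_params()] object.
#' @param t temperature(s) in Kelvin.
#' @return stage duration(s) in days.
#' @export
stage_duration <- function(p, t) {
  m <- maturation_rate(p, t)
  if (any(m <= 0))
    abort("maturation rate is zero: stage duration is infinite",
          class = "thermalniche_domain_error")
  1 / m
}

#' Through-stage survivorship at constant temperature
#'
#' The probability `exp(-d_J(T) / m_J(T))` that a juvenile survives the whole
#' developmental period at constant temperature.
#'
#' @param traits a [species_traits()] object.
#' @param t temperature(s) in Kelvin.
#' @return survivorship in (0, 1].
#' @export
through_stage_survivorship <- function(traits, t) {
  stopifnot(inherits(traits, "species_traits"))
  exp(-arrhenius_rate(traits$juvenile_mortality, t) /
        maturation_rate(traits$maturation, t))
}

#' Tabulate a species' thermal reaction norms
#'
#' Evaluates all four life-history rates of a species on a temperature grid.
#'
#' @param traits a [species_traits()] object.
#' @param t temperatures in Kelvin.
#' @return a tibble with columns `temperature_k`, `trait`, `rate`.
#' @export
#' @examples
#' rate_curves(tn_species("harlequin"), seq(288, 308, by = 0.5))
rate_curves <- function(traits, t) {
  stopifnot(inherits(traits, "species_traits"))
  tibble(
    temperature_k = rep(t, 4),
    trait = rep(c("birth", "maturation", "juvenile_mortality", "adult_mortality"),
                each = length(t)),
    rate = c(gaussian_rate(traits$birth, t),
             maturation_rate(traits$maturation, t),
             arrhenius_rate(traits$juvenile_mortality, t),
             arrhenius_rate(traits$adult_mortality, t))
  )
}

check_kelvin <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0))
    abort("temperature must be positive (Kelvin)", class = "thermalniche_domain_error")
  invisible(t)
}

trait_rate <- function(traits, trait, t) {
  switch(trait,
    birth = gaussian_rate(traits$birth, t),
    maturation = maturation_rate(traits$maturation, t),
    juvenile_mortality = arrhenius_rate(traits$juvenile_mortality, t),
    adult_mortality = arrhenius_rate(traits$adult_mortality, t),
    abort(sprintf("unknown trait '%s'", trait)))
}
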