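#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup
#' @importFrom stats coef integrate optimize pt qt rnorm sd setNames uniroot vcov lm
NULL

# Celsius offset used throughout. The shipped trait parameters were estimated
# under the convention that 273 K is the freezing point (the low inactivation
# temperature T_L/2 = 273 K is described as freezing), so reported Celsius
# values use the same offset; see the methods vignette.
.kelvin_offset <- 273

#' Convert between Celsius and Kelvin
#'
#' The package works in Kelvin internally; Celsius appears only at the I/O
#' boundary. The default offset is 273 K, the convention under which the
#' shipped trait parameters were estimated (see the methods vignette).
#'
#' @param x temperature(s) to convert.
#' @param offset freezing point in Kelvin (default 273).
#' @return numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(x, offset = .kelvin_offset) x + offset

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x, offset = .kelvin_offset) x - offset

stop_bad_param <- function(field, msg) {
  abort(sprintf("invalid parameter `%s`: %s", field, msg), class = "thermalniche_param_error")
}

#' Boltzmann-Arrhenius parameter set
#'
#' Parameters of the monotone Boltzmann-Arrhenius temperature response
#' `value_at_ref * exp(arrhenius * (1/t_ref - 1/t))`, used for juvenile and
#' adult mortality rates and for the monotonic competition response.
#'
#' @param value_at_ref rate (per day) at the reference temperature.
#' @param arrhenius Arrhenius constant (Kelvin): activation enthalpy over the
#'   gas constant; larger values mean steeper increase with warming.
#' @param t_ref reference temperature (Kelvin), within the range of full
#'   enzyme activity (typically 293-303 K).
#' @return an object of class `arrhenius_params`.
#' @export
#' @examples
#' arrhenius_params(0.0926, 12355.6, 297)
arrhenius_params <- function(value_at_ref, arrhenius, t_ref = 297) {
  if (!is.numeric(value_at_ref) || value_at_ref <= 0)
    stop_bad_param("value_at_ref", "must be > 0")
  if (!is.finite(arrhenius)) stop_bad_param("arrhenius", "must be finite")
  if (t_ref <= 273) stop_bad_param("t_ref", "must exceed 273 K")
  structure(list(value_at_ref = value_at_ref, arrhenius = arrhenius, t_ref = t_ref),
            class = c("arrhenius_params", "tn_params"))
}

#' Gaussian (symmetric unimodal) parameter set
#'
#' Parameters of the Gaussian temperature response
#' `peak * exp(-(t - t_opt)^2 / (2 * breadth^2))`, used for the birth rate and
#' the unimodal competition response.
#'
#' @param peak rate (per day) at the thermal optimum.
#' @param t_opt optimum temperature (Kelvin).
#' @param breadth response breadth (Kelvin); the SD of the Gaussian.
#' @return an object of class `gaussian_params`.
#' @export
#' @examples
#' gaussian_params(0.8921, 298.3, 3.085)
gaussian_params <- function(peak, t_opt, breadth) {
  if (!is.numeric(peak) || peak <= 0) stop_bad_param("peak", "must be > 0")
  if (!is.numeric(breadth) || breadth <= 0) stop_bad_param("breadth", "must be > 0")
  structure(list(peak = peak, t_opt = t_opt, breadth = breadth),
            class = c("gaussian_params", "tn_params"))
}

#' Sharpe-Schoolfield maturation parameter set
#'
#' Parameters of the thermodynamic rate-process (Sharpe-Schoolfield) model of
#' the maturation rate, with optional low- and high-temperature enzyme
#' inactivation terms. Leaving the low-temperature fields `NULL` selects the
#' reduced form with only the high-temperature decline; leaving both sides
#' `NULL` selects the bare exponential (Boltzmann-Arrhenius) form, which also
#' drops the `t/t_ref` prefactor.
#'
#' @param value_at_ref maturation rate (per day) at `t_ref`.
#' @param arrhenius Arrhenius constant (Kelvin).
#' @param t_ref reference temperature (Kelvin).
#' @param a_low,t_half_low enthalpy term (Kelvin) and half-activity temperature
#'   (Kelvin) of low-temperature inactivation, or `NULL`.
#' @param a_high,t_half_high enthalpy term and half-activity temperature of
#'   high-temperature inactivation, or `NULL`.
#' @return an object of class `schoolfield_params`.
#' @export
#' @examples
#' # full model (both inactivation terms)
#' schoolfield_params(0.0138, 13480, 297,
#'   a_low = -1e5, t_half_low = 273, a_high = 48150, t_half_high = 303.8)
#' # bare exponential
#' schoolfield_params(0.015, 11500, 297)
schoolfield_params <- function(value_at_ref, arrhenius, t_ref = 297,
                               a_low = NULL, t_half_low = NULL,
                               a_high = NULL, t_half_high = NULL) {
  if (!is.numeric(value_at_ref) || value_at_ref <= 0)
    stop_bad_param("value_at_ref", "must be > 0")
  if (!is.finite(arrhenius)) stop_bad_param("arrhenius", "must be finite")
  if (is.null(a_low) != is.null(t_half_low))
    stop_bad_param("t_half_low", "a_low and t_half_low must be given together")
  if (is.null(a_high) != is.null(t_half_high))
    stop_bad_param("t_half_high", "a_high and t_half_high must be given together")
  if (!is.null(t_half_low)) {
    if (t_half_low < 273) stop_bad_param("t_half_low", "must be >= 273 K (freezing)")
    if (!is.null(t_half_high) && t_half_low >= t_half_high)
      stop_bad_param("t_half_low", "must be below t_half_high")
  }
  structure(list(value_at_ref = value_at_ref, arrhenius = arrhenius, t_ref = t_ref,
                 a_low = a_low, t_half_low = t_half_low,
                 a_high = a_high, t_half_high = t_half_high),
            class = c("schoolfield_params", "tn_params"))
}

#' Which Sharpe-Schoolfield variant a parameter set selects
#'
#' @param p a [schoolfield_params()] object.
#' @return `"full"` (both inactivation terms), `"high_only"` (high-temperature
#'   decline only), or `"exponential"`.
#' @export
maturation_family <- function(p) {
  stopifnot(inherits(p, "schoolfield_params"))
  if (!is.null(p$a_low)) "full"
  else if (!is.null(p$a_high)) "high_only"
  else "exponential"
}

#' Species life-history trait set
#'
#' Bundles the four fitted thermal reaction norms of one species: Gaussian
#' birth rate, Sharpe-Schoolfield maturation rate, and Boltzmann-Arrhenius
#' juvenile and adult mortality rates.
#'
#' @param name species label.
#' @param birth a [gaussian_params()] object.
#' @param maturation a [schoolfield_params()] object.
#' @param juvenile_mortality,adult_mortality [arrhenius_params()] objects.
#' @return an object of class `species_traits`.
#' @seealso [tn_species()] for the shipped parameter sets.
#' @export
species_traits <- function(name, birth, maturation, juvenile_mortality, adult_mortality) {
  if (!inherits(birth, "gaussian_params")) stop_bad_param("birth", "must be gaussian_params")
  if (!inherits(maturation, "schoolfield_params"))
    stop_bad_param("maturation", "must be schoolfield_params")
  if (!inherits(juvenile_mortality, "arrhenius_params"))
    stop_bad_param("juvenile_mortality", "must be arrhenius_params")
  if (!inherits(adult_mortality, "arrhenius_params"))
    stop_bad_param("adult_mortality", "must be arrhenius_params")
  structure(list(name = as.character(name), birth = birth, maturation = maturation,
                 juvenile_mortality = juvenile_mortality, adult_mortality = adult_mortality),
            class = "species_traits")
}

#' @export
print.species_traits <- function(x, ...) {
  cat("<species_traits> ", x$name, "\n", sep = "")
  cat("  birth:      Gaussian  peak ", format(x$birth$peak), "/d at ",
      format(x$birth$t_opt), " K (breadth ", format(x$birth$breadth), " K)\n", sep = "")
  cat("  maturation: Sharpe-Schoolfield [", maturation_family(x$maturation), "]  ",
      format(x$maturation$value_at_ref), "/d at ", format(x$maturation$t_ref), " K\n", sep = "")
  cat("  mortality:  juvenile ", format(x$juvenile_mortality$value_at_ref),
      "/d, adult ", format(x$adult_mortality$value_at_ref), "/d at T_R\n", sep = "")
  invisible(x)
}

#' @export
print.tn_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flds <- x[!vapply(x, is.null, logical(1))]
  cat(paste0("  ", names(flds), " = ", vapply(flds, format, character(1)), collapse = "\n"), "\n")
  invisible(x)
}

#' Intraspecific competition (self-limitation) specification
#'
#' Declares which life-history trait density dependence acts on and how the
#' per-capita competition coefficient responds to temperature: monotonically
#' increasing (Boltzmann-Arrhenius) or unimodal (Gaussian, strongest at the
#' reproductive optimum).
#'
#' @param acts_on one of `"fecundity"`, `"adult_mortality"`,
#'   `"juvenile_mortality"`.
#' @param shape `"monotonic"` or `"unimodal"`.
#' @param params an [arrhenius_params()] object when `shape = "monotonic"`, a
#'   [gaussian_params()] object when `shape = "unimodal"`; values are
#'   per-individual competition coefficients.
#' @return an object of class `competition_spec`.
#' @export
#' @examples
#' competition_spec("adult_mortality", "monotonic", arrhenius_params(0.1, 16824, 297))
competition_spec <- function(acts_on = c("fecundity", "adult_mortality", "juvenile_mortality"),
                             shape = c("monotonic", "unimodal"), params) {
  acts_on <- match.arg(acts_on)
  shape <- match.arg(shape)
  want <- if (shape == "monotonic") "arrhenius_params" else "gaussian_params"
  if (!inherits(params, want))
    abort(sprintf("competition shape '%s' requires %s, got %s",
                  shape, want, class(params)[1]),
          class = "thermalniche_config_error")
  structure(list(acts_on = acts_on, shape = shape, params = params),
            class = "competition_spec")
}

#' @export
print.competition_spec <- function(x, ...) {
  cat("<competition_spec> ", x$shape, " response acting on ", x$acts_on, "\n", sep = "")
  print(x$params)
  invisible(x)
}
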