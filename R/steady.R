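#' Default competition configuration for a species
#'
#' Builds the standard self-limitation configuration used for the two-species
#' comparisons: when density dependence acts on fecundity, a unimodal
#' (Gaussian) response centred on the species' reproductive optimum with the
#' birth-rate breadth; when it acts on adult mortality, a monotonic
#' (Arrhenius) response with the species' adult-mortality Arrhenius constant.
#' Baseline strength is 0.1 per individual in both cases.
#'
#' @param traits a [species_traits()] object.
#' @param acts_on `"fecundity"` or `"adult_mortality"`.
#' @param strength baseline per-capita competition coefficient.
#' @return a [competition_spec()] object.
#' @export
default_competition <- function(traits, acts_on = c("fecundity", "adult_mortality"),
                                strength = 0.1) {
  acts_on <- match.arg(acts_on)
  if (acts_on == "fecundity") {
    competition_spec("fecundity", "unimodal",
                     gaussian_params(strength, traits$birth$t_opt, traits$birth$breadth))
  } else {
    competition_spec("adult_mortality", "monotonic",
                     arrhenius_params(strength, traits$adult_mortality$arrhenius,
                                      traits$adult_mortality$t_ref))
  }
}

eq_rates <- function(model, t) {
  traits <- model$traits
  tau <- stage_duration(traits$maturation, t)
  list(tau = tau,
       s_j = exp(-arrhenius_rate(traits$juvenile_mortality, t) * tau),
       b = gaussian_rate(traits$birth, t),
       d_a = arrhenius_rate(traits$adult_mortality, t),
       d_j = arrhenius_rate(traits$juvenile_mortality, t),
       q = competition_strength(model$competition, t))
}

#' Closed-form equilibrium of the density-dependent model
#'
#' Steady state of the density-dependent model in a constant thermal
#' environment. With `tau = 1/m_J(T)` and `S_J = exp(-d_J * tau)`, the net
#' reproductive number is `R0 = b * S_J / d_A` and the adult equilibrium is
#' `ln(R0) / q_b(T)` under density-dependent fecundity or `(R0 - 1) / q_d(T)`
#' under density-dependent adult mortality; the population is nonviable when
#' `R0 <= 1`. The juvenile equilibrium follows from the juvenile balance,
#' `J* = B(A*) * A* * (1 - S_J) / d_J`.
#'
#' @param model a [model_spec()] with constant forcing and a competition
#'   specification acting on fecundity or adult mortality.
#' @param t temperature (Kelvin); defaults to the forcing mean.
#' @return an object of class `equilibrium_result`: list with `adults_star`,
#'   `juveniles_star`, `viable`, `dd_trait`, `t`.
#' @export
#' @examples
#' har <- tn_species("harlequin")
#' m <- model_spec(har, default_competition(har, "adult_mortality"),
#'                 temperature_forcing("constant", 296.7))
#' equilibrium(m)
equilibrium <- function(model, t = attr(model$forcing, "mean")) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(model$competition))
    abort("equilibrium requires a density-dependent model", class = "thermalniche_config_error")
  if (attr(model$forcing, "amplitude") != 0)
    abort("no equilibrium exists under time-varying forcing", class = "thermalniche_config_error")
  dd <- model$competition$acts_on
  if (dd == "juvenile_mortality")
    abort("juvenile-stage density dependence equilibria are not implemented",
          class = "thermalniche_not_implemented")
  r <- eq_rates(model, t)
  r0 <- r$b * r$s_j / r$d_a
  if (r0 <= 1) {
    return(structure(list(adults_star = 0, juveniles_star = 0, viable = FALSE,
                          dd_trait = dd, t = t), class = "equilibrium_result"))
  }
  a_star <- if (dd == "fecundity") log(r0) / r$q else (r0 - 1) / r$q
  b_eff <- if (dd == "fecundity") r$b * exp(-r$q * a_star) else r$b
  j_star <- b_eff * a_star * (1 - r$s_j) / r$d_j
  structure(list(adults_star = a_star, juveniles_star = j_star, viable = TRUE,
                 dd_trait = dd, t = t), class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> DD on %s at %.2f K: %s\n", x$dd_trait, x$t,
              if (x$viable) sprintf("A* = %.3f, J* = %.3f", x$adults_star, x$juveniles_star)
              else "nonviable (R0 <= 1)"))
  invisible(x)
}

#' Density-dependent climate envelope
#'
#' Evaluates the closed-form adult equilibrium on a temperature grid and
#' refines the abundance maximum by bounded maximization (1e-3 K).
#'
#' @param model a density-dependent [model_spec()] (forcing mean is ignored;
#'   temperature is swept).
#' @param temperatures grid of temperatures (Kelvin).
#' @return a tibble (`temperature_k`, `adults_star`, `viable`) with
#'   attributes `t_opt_add` and `a_max` (the refined argmax and maximum).
#' @export
dd_envelope <- function(model, temperatures) {
  a_of <- function(tt) equilibrium(model, tt)$adults_star
  a_star <- vapply(temperatures, a_of, numeric(1))
  out <- tibble(temperature_k = temperatures, adults_star = a_star,
                viable = a_star > 0)
  i <- which.max(a_star)
  lo <- temperatures[max(1, i - 1)]; hi <- temperatures[min(length(temperatures), i + 1)]
  opt <- optimize(a_of, lower = lo, upper = hi, maximum = TRUE, tol = 1e-3)
  attr(out, "t_opt_add") <- opt$maximum
  attr(out, "a_max") <- opt$objective
  out
}

# Linearization coefficients of the adult equation about A*: the scalar
# delayed characteristic equation is  lambda = -a + c * exp(-lambda * tau).
# S_J and tau are constants at fixed temperature and J does not enter the
# adult equation, so the adult dynamics close on themselves.
char_coefs <- function(model, t, eq) {
  r <- eq_rates(model, t)
  if (eq$dd_trait == "fecundity") {
    list(a = r$d_a, c = r$d_a * (1 - r$q * eq$adults_star), tau = r$tau)
  } else {
    list(a = r$d_a * (1 + 2 * r$q * eq$adults_star), c = r$b * r$s_j, tau = r$tau)
  }
}

#' Dominant eigenvalue and recovery time of the delayed linearization
#'
#' Linearizes the adult equation of the density-dependent model about its
#' equilibrium, giving the scalar delayed characteristic equation
#' `lambda = -a + c * exp(-lambda * tau)`; under density-dependent fecundity
#' `a = d_A`, `c = d_A * (1 - q_b * A*)`, and under density-dependent adult
#' mortality `a = d_A * (1 + 2 * q_d * A*)`, `c = b * S_J`. Roots are found
#' on the Lambert-W branches of `lambda = -a + W_k(c * tau * e^(a*tau)) / tau`
#' (solved in log space) and the maximal-real-part root is returned, together
#' with the recovery time `-Re(lambda) / |lambda|^2` when stable.
#'
#' @param model a density-dependent [model_spec()].
#' @param eq an [equilibrium()] result; computed if missing.
#' @param t temperature (Kelvin); defaults to the forcing mean.
#' @return an object of class `stability_result`: list with
#'   `dominant_eigenvalue` (complex, per day), `stable`, `recovery_time_d`
#'   (`NA` when unstable), `residual` of the characteristic equation, and the
#'   coefficients `a`, `c`, `tau`.
#' @export
dominant_eigenvalue <- function(model, eq = NULL, t = attr(model$forcing, "mean")) {
  if (is.null(eq)) eq <- equilibrium(model, t)
  if (!eq$viable)
    abort("no viable equilibrium to linearize about", class = "thermalniche_domain_error")
  co <- char_coefs(model, t, eq)
  roots <- char_roots(co$a, co$c, co$tau)
  lam <- roots[1]
  resid <- char_residual(lam, co)
  stable <- Re(lam) < 0
  structure(list(dominant_eigenvalue = lam, stable = stable,
                 recovery_time_d = if (stable) -Re(lam) / Mod(lam)^2 else NA_real_,
                 residual = resid, a = co$a, c = co$c, tau = co$tau, t = t),
            class = "stability_result")
}

# |lambda + a - c e^{-lambda tau}|, evaluated stably: when the direct
# exponential would overflow, use the equivalent scaled residual
# |(lambda + a) e^{lambda tau} - c| / e^{Re(lambda) tau}.
char_residual <- function(lam, co) {
  x <- -lam * co$tau
  if (Re(x) < 700) return(Mod(lam + co$a - co$c * exp(x)))
  Mod((lam + co$a) * exp(lam * co$tau) - co$c) * exp(-Re(lam) * co$tau)
}

#' @export
print.stability_result <- function(x, ...) {
  lam <- x$dominant_eigenvalue
  cat(sprintf("<stability_result> lambda = %.6g %+.6gi /day (%s)\n",
              Re(lam), Im(lam), if (x$stable) "stable" else "unstable"))
  if (x$stable) cat(sprintf("  recovery time %.3f days\n", x$recovery_time_d))
  invisible(x)
}

#' Recovery time across temperature
#'
#' Evaluates the perturbation recovery time over a temperature grid
#' (restricted to viable, stable equilibria) and refines the minimum by
#' bounded minimization (1e-3 K).
#'
#' @param model a density-dependent [model_spec()].
#' @param temperatures grid of temperatures (Kelvin).
#' @return a tibble (`temperature_k`, `recovery_time_d`, `stable`) with
#'   attributes `t_opt_recovery` and `t_recovery_min`.
#' @export
recovery_curve <- function(model, temperatures) {
  trec_of <- function(tt) {
    eq <- equilibrium(model, tt)
    if (!eq$viable) return(c(NA_real_, NA))
    st <- dominant_eigenvalue(model, eq, tt)
    c(if (st$stable) st$recovery_time_d else NA_real_, st$stable)
  }
  vals <- vapply(temperatures, trec_of, numeric(2))
  out <- tibble(temperature_k = temperatures, recovery_time_d = vals[1, ],
                stable = as.logical(vals[2, ]))
  ok <- which(is.finite(out$recovery_time_d))
  if (length(ok)) {
    i <- ok[which.min(out$recovery_time_d[ok])]
    lo <- temperatures[max(1, i - 1)]; hi <- temperatures[min(length(temperatures), i + 1)]
    opt <- optimize(function(tt) {
      v <- trec_of(tt)[1]; if (is.na(v)) Inf else v
    }, lower = lo, upper = hi, tol = 1e-3)
    attr(out, "t_opt_recovery") <- opt$minimum
    attr(out, "t_recovery_min") <- opt$objective
  }
  out
}
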