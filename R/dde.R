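#' Temperature forcing
#'
#' Temperature as a function of time (days): constant, or sinusoidal
#' `T(t) = mean + amplitude * sin(2 * pi * t / period)` for seasonal or
#' diurnal variation.
#'
#' @param kind `"constant"` or `"sinusoidal"`.
#' @param mean mean temperature (Kelvin).
#' @param amplitude half-range of the oscillation (Kelvin); 0 for constant.
#' @param period period in days (365 for seasonal, 1 for diurnal).
#' @return an object of class `temperature_forcing`; callable as a function
#'   of time.
#' @export
#' @examples
#' f <- temperature_forcing("sinusoidal", mean = 300, amplitude = 3, period = 365)
#' f(c(0, 91.25))
temperature_forcing <- function(kind = c("constant", "sinusoidal"), mean,
                                amplitude = 0, period = 365) {
  kind <- match.arg(kind)
  check_kelvin(mean)
  if (amplitude < 0) abort("amplitude must be >= 0", class = "thermalniche_config_error")
  if (kind == "sinusoidal" && period <= 0)
    abort("period must be > 0", class = "thermalniche_config_error")
  fn <- if (kind == "constant" || amplitude == 0) {
    function(t) rep_len(mean, length(t))
  } else {
    function(t) mean + amplitude * sin(2 * pi * t / period)
  }
  structure(fn, kind = kind, mean = mean, amplitude = amplitude, period = period,
            class = c("temperature_forcing", "function"))
}

#' @export
print.temperature_forcing <- function(x, ...) {
  cat("<temperature_forcing> ", attr(x, "kind"),
      sprintf(": mean %.2f K, amplitude %.2f K, period %g d\n",
              attr(x, "mean"), attr(x, "amplitude"), attr(x, "period")), sep = "")
  invisible(x)
}

#' Population model specification
#'
#' Bundles a species' traits, an optional intraspecific-competition
#' specification (absent means density-independent dynamics), and a
#' temperature forcing.
#'
#' @param traits a [species_traits()] object.
#' @param competition a [competition_spec()] object, or `NULL` for the
#'   density-independent model.
#' @param forcing a [temperature_forcing()] object.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(traits, competition = NULL, forcing) {
  stopifnot(inherits(traits, "species_traits"), inherits(forcing, "temperature_forcing"))
  if (!is.null(competition) && !inherits(competition, "competition_spec"))
    abort("competition must be a competition_spec or NULL",
          class = "thermalniche_config_error")
  structure(list(traits = traits, competition = competition, forcing = forcing),
            class = "model_spec")
}

# Fixed-step classical RK4 by the method of steps: the full solution is kept
# at the step nodes together with its derivative, and delayed state is read
# off by cubic Hermite interpolation on the enclosing interval. Explicit
# stepping is valid because the developmental delay always spans many steps
# (enforced below), so stage evaluations never need history from the current
# step.
sim_rk4 <- function(rhs, y0, times, step, initial_juveniles, initial_adults) {
  n <- length(times)
  Y <- matrix(NA_real_, n, 4)
  D <- matrix(NA_real_, n, 4)
  Y[1, ] <- y0
  if (y0[4] < 2 * step)
    abort("step exceeds half the developmental delay; choose a smaller step",
          class = "thermalniche_numeric_error")
  hist0 <- c(initial_juveniles, initial_adults, y0[3], y0[4])
  lag_state <- function(tl, i) {
    if (tl <= 0) return(hist0[i])
    j <- floor(tl / step) + 1
    # the enclosing interval needs both endpoint derivatives; tl lands at a
    # node boundary when tau is an exact step multiple, in which case the
    # previous interval (with th = 1) is equivalent and fully known
    if (j + 1 > n || is.na(D[j + 1, 1])) j <- j - 1
    th <- (tl - times[j]) / step
    y_a <- Y[j, i]; y_b <- Y[j + 1, i]; d_a <- D[j, i]; d_b <- D[j + 1, i]
    h00 <- (1 + 2 * th) * (1 - th)^2; h10 <- th * (1 - th)^2
    h01 <- th^2 * (3 - 2 * th); h11 <- th^2 * (th - 1)
    h00 * y_a + h10 * step * d_a + h01 * y_b + h11 * step * d_b
  }
  for (k in seq_len(n - 1)) {
    t_k <- times[k]; y <- Y[k, ]
    k1 <- rhs(t_k, y, lag_state)
    D[k, ] <- k1
    k2 <- rhs(t_k + step / 2, y + step / 2 * k1, lag_state)
    k3 <- rhs(t_k + step / 2, y + step / 2 * k2, lag_state)
    k4 <- rhs(t_k + step, y + step * k3, lag_state)
    Y[k + 1, ] <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (Y[k + 1, 4] < 2 * step)
      abort("delay fell below twice the step; choose a smaller step",
            class = "thermalniche_numeric_error")
  }
  D[n, ] <- rhs(times[n], Y[n, ], lag_state)
  cbind(time = times, Y)
}

# Consistent initial developmental delay: tau0 solves the maturation-index
# identity  integral of m_J(T(x)) over (t0 - tau0, t0) = 1, which the delay
# DDE then conserves exactly. Reduces to 1/m_J(T(0)) under constant forcing.
initial_delay <- function(traits, forcing, t0 = 0) {
  m <- function(x) maturation_rate(traits$maturation, forcing(x))
  if (attr(forcing, "kind") == "constant" || attr(forcing, "amplitude") == 0)
    return(1 / m(t0))
  idx <- function(tau) integrate(Vectorize(m), t0 - tau, t0,
                                 abs.tol = 1e-10, subdivisions = 500L)$value - 1
  tau_c <- 1 / m(t0)
  lo <- tau_c; hi <- tau_c
  while (idx(lo) > 0) lo <- lo / 2
  while (idx(hi) < 0) hi <- hi * 2
  uniroot(idx, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Simulate the stage-structured delay-differential population model
#'
#' Integrates the coupled juvenile/adult DDE system together with the
#' auxiliary dynamics of the developmental delay `tau(t)` and through-stage
#' survivorship `S_J(t)`. The maturation inflow at time `t` is the birth
#' cohort of time `t - tau(t)`, corrected by the maturation-rate ratio
#' `m_J[T(t)] / m_J[T(t - tau(t))]` and discounted by `S_J(t)`. With a
#' [competition_spec()] present, the affected rate becomes density-dependent:
#' birth `b * exp(-q * A)` or mortality `d_X * (1 + q * X)`.
#'
#' Delayed state (`A`, and `J` when juvenile mortality is density-dependent)
#' is looked up from the integrator's dense interpolated history
#' ([deSolve::dede()]); times before the start fall back on the constant
#' pre-history `A = initial_adults`, `J = initial_juveniles`. The initial
#' delay solves the maturation-index identity (so it equals `1/m_J(T(0))`
#' under constant forcing), and initial survivorship is the corresponding
#' integrated survival.
#'
#' @param model a [model_spec()] object.
#' @param initial_adults,initial_juveniles initial abundances.
#' @param horizon length of the run in days.
#' @param step output (and, for fixed-step methods, integration) step in days.
#' @param method integration method: `"lsoda"` (adaptive; default) or
#'   `"rk4"` (fixed step, useful for step-convergence studies).
#' @param rtol,atol solver tolerances for adaptive methods.
#' @return a tibble of class `trajectory` with columns `time_d`, `juveniles`,
#'   `adults`, `survivorship`, `delay_d`, `temperature_k`.
#' @export
#' @examples
#' m <- model_spec(tn_species("generic"),
#'                 forcing = temperature_forcing("constant", 300))
#' tr <- simulate_population(m, horizon = 200)
simulate_population <- function(model, initial_adults = 1, initial_juveniles = 0,
                                horizon = 365 * 5, step = 0.05,
                                method = c("lsoda", "rk4"),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "model_spec"))
  method <- match.arg(method)
  traits <- model$traits; forcing <- model$forcing; comp <- model$competition
  acts_on <- if (is.null(comp)) "none" else comp$acts_on
  q_of <- if (is.null(comp)) function(tt) 0 else function(tt) competition_strength(comp, tt)

  b_of <- function(tt) gaussian_rate(traits$birth, tt)
  m_of <- function(tt) maturation_rate(traits$maturation, tt)
  dj_of <- function(tt) arrhenius_rate(traits$juvenile_mortality, tt)
  da_of <- function(tt) arrhenius_rate(traits$adult_mortality, tt)

  tau0 <- initial_delay(traits, forcing)
  # survivorship over the initial cohort's development window (-tau0, 0)
  s0 <- exp(-integrate(function(x) dj_of(forcing(x)), -tau0, 0,
                       abs.tol = 1e-10, subdivisions = 500L)$value)
  y0 <- c(J = initial_juveniles, A = initial_adults, S = s0, tau = tau0)

  # rhs shared by both integration paths; `lag_state(tl, i)` returns state
  # component i at a past time (constant pre-history before t = 0)
  rhs <- function(t, y, lag_state) {
    Tt <- forcing(t)
    tl <- t - y[4]
    Tl <- forcing(tl)
    A_lag <- lag_state(tl, 2)
    m_t <- m_of(Tt); m_l <- m_of(Tl)
    b_t <- b_of(Tt); b_l <- b_of(Tl)
    dj_t <- dj_of(Tt); dj_l <- dj_of(Tl)
    da_t <- da_of(Tt)
    B_t <- b_t; B_l <- b_l
    DJ_t <- dj_t; DJ_l <- dj_l
    DA_t <- da_t
    if (acts_on == "fecundity") {
      B_t <- b_t * exp(-q_of(Tt) * y[2])
      B_l <- b_l * exp(-q_of(Tl) * A_lag)
    } else if (acts_on == "adult_mortality") {
      DA_t <- da_t * (1 + q_of(Tt) * y[2])
    } else if (acts_on == "juvenile_mortality") {
      J_lag <- lag_state(tl, 1)
      DJ_t <- dj_t * (1 + q_of(Tt) * y[1])
      DJ_l <- dj_l * (1 + q_of(Tl) * J_lag)
    }
    MJ <- B_l * A_lag * (m_t / m_l) * y[3]
    c(B_t * y[2] - MJ - DJ_t * y[1],
      MJ - DA_t * y[2],
      y[3] * (m_t * DJ_l / m_l - DJ_t),
      1 - m_t / m_l)
  }

  times <- seq(0, horizon, by = step)
  sol <- if (method == "lsoda") {
    lag_desolve <- function(tl, i) {
      if (tl <= 0) c(initial_juveniles, initial_adults)[i] else deSolve::lagvalue(tl, i)
    }
    deSolve::dede(y = y0, times = times,
                  func = function(t, y, parms) list(rhs(t, y, lag_desolve)),
                  parms = NULL, rtol = rtol, atol = atol)
  } else {
    sim_rk4(rhs, y0, times, step, initial_juveniles, initial_adults)
  }
  out <- as_tibble(as.data.frame(sol))
  names(out) <- c("time_d", "juveniles", "adults", "survivorship", "delay_d")
  out$temperature_k <- forcing(out$time_d)
  floor_tol <- -1e-9 * pmax(1, max(abs(out$adults)), max(abs(out$juveniles)))
  if (min(out$juveniles, out$adults) < floor_tol)
    abort("negative-state excursion beyond integrator tolerance; reduce step or tolerances",
          class = "thermalniche_numeric_error")
  class(out) <- c("trajectory", class(out))
  out
}

#' Density-independent climate envelope
#'
#' Runs the density-independent model to a fixed horizon (default 5 years,
#' long enough to reach a stable stage distribution) across a set of constant
#' temperatures and records the final log adult abundance. Under
#' density-independent growth its argmax coincides with the thermal optimum
#' of the intrinsic growth rate.
#'
#' @param traits a [species_traits()] object.
#' @param temperatures constant temperatures (Kelvin).
#' @param years run length in years.
#' @param initial_adults,initial_juveniles initial abundances.
#' @param ... passed to [simulate_population()].
#' @return a tibble with columns `temperature_k`, `log_adults` and attribute
#'   `t_argmax` (Kelvin, at grid resolution).
#' @export
di_envelope <- function(traits, temperatures, years = 5,
                        initial_adults = 1, initial_juveniles = 0, ...) {
  stopifnot(inherits(traits, "species_traits"))
  log_a <- vapply(temperatures, function(tt) {
    m <- model_spec(traits, forcing = temperature_forcing("constant", tt))
    tr <- simulate_population(m, initial_adults, initial_juveniles,
                              horizon = 365 * years, ...)
    log(tr$adults[nrow(tr)])
  }, numeric(1))
  out <- tibble(temperature_k = temperatures, log_adults = log_a)
  attr(out, "t_argmax") <- temperatures[which.max(log_a)]
  out
}

#' Maturation-index consistency check
#'
#' The delay dynamics conserve the maturation index: the integral of
#' `m_J[T(x)]` over each individual's developmental window
#' `(t - tau(t), t)` equals 1 at maturation. This evaluates that integral by
#' quadrature over the (exogenous) temperature history at sampled trajectory
#' times and reports the worst absolute deviation from 1 — a direct numerical
#' audit of the delay integration.
#'
#' @param trajectory a trajectory from [simulate_population()].
#' @param model the [model_spec()] that produced it.
#' @param n_check number of (evenly spaced) trajectory times to audit.
#' @return maximum `|integral - 1|` across the audited times.
#' @export
maturation_index_check <- function(trajectory, model, n_check = 50) {
  stopifnot(inherits(model, "model_spec"))
  m <- function(x) maturation_rate(model$traits$maturation, model$forcing(x))
  idx <- round(seq(1, nrow(trajectory), length.out = n_check))
  dev <- vapply(idx, function(i) {
    t_i <- trajectory$time_d[i]; tau_i <- trajectory$delay_d[i]
    abs(integrate(Vectorize(m), t_i - tau_i, t_i,
                  abs.tol = 1e-10, subdivisions = 1000L)$value - 1)
  }, numeric(1))
  max(dev)
}

#' Plot a simulated trajectory
#'
#' @param object a `trajectory` tibble from [simulate_population()].
#' @param ... unused.
#' @return a ggplot of juvenile and adult abundances over time (log scale).
#' @export
autoplot.trajectory <- function(object, ...) {
  dat <- tidyr::pivot_longer(object[, c("time_d", "juveniles", "adults")],
                             -"time_d", names_to = "stage", values_to = "abundance")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_d, .data$abundance,
                                    colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (days)", y = "Abundance", colour = NULL) +
    ggplot2::theme_minimal()
}
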