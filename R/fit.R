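# Model functions, free-parameter sets, bounds and start grids per family.
# Bounds encode biological realism: positive rates and breadths, half-activity
# temperatures above freezing (273 K) and ordered.
fit_families <- function(t_ref) {
  list(
    gaussian = list(
      pars = c("peak", "t_opt", "breadth"),
      fn = function(t, p) p[["peak"]] * exp(-(t - p[["t_opt"]])^2 / (2 * p[["breadth"]]^2)),
      lower = c(peak = 1e-8, t_opt = 250, breadth = 1e-3),
      upper = c(peak = Inf, t_opt = 350, breadth = 50),
      starts = function(tt, y) {
        grid <- seq(min(tt) - 5, max(tt) + 5, length.out = 7)
        lapply(grid, function(g) c(peak = max(y), t_opt = g,
                                   breadth = max(diff(range(tt)) / 4, 1)))
      }),
    arrhenius = list(
      pars = c("value_at_ref", "arrhenius"),
      fn = function(t, p) p[["value_at_ref"]] * exp(p[["arrhenius"]] * (1 / t_ref - 1 / t)),
      lower = c(value_at_ref = 1e-10, arrhenius = -1e6),
      upper = c(value_at_ref = Inf, arrhenius = 1e6),
      starts = function(tt, y) {
        sl <- if (length(tt) > 1 && all(y > 0))
          coef(lm(log(y) ~ I(1 / t_ref - 1 / tt)))[2] else 5000
        list(c(value_at_ref = max(mean(y), 1e-6), arrhenius = unname(sl)))
      }),
    exponential = list(
      pars = c("value_at_ref", "arrhenius"),
      fn = function(t, p) p[["value_at_ref"]] * exp(p[["arrhenius"]] * (1 / t_ref - 1 / t)),
      lower = c(value_at_ref = 1e-10, arrhenius = -1e6),
      upper = c(value_at_ref = Inf, arrhenius = 1e6),
      starts = function(tt, y) {
        sl <- if (length(tt) > 1 && all(y > 0))
          coef(lm(log(y) ~ I(1 / t_ref - 1 / tt)))[2] else 5000
        list(c(value_at_ref = max(mean(y), 1e-6), arrhenius = unname(sl)))
      }),
    schoolfield_high = list(
      pars = c("value_at_ref", "arrhenius", "a_high", "t_half_high"),
      fn = function(t, p) {
        (t / t_ref) * p[["value_at_ref"]] * exp(p[["arrhenius"]] * (1 / t_ref - 1 / t)) /
          (1 + exp(p[["a_high"]] * (1 / p[["t_half_high"]] - 1 / t)))
      },
      lower = c(value_at_ref = 1e-10, arrhenius = 0, a_high = 1000, t_half_high = 274),
      upper = c(value_at_ref = Inf, arrhenius = 1e6, a_high = 5e5, t_half_high = 350),
      starts = function(tt, y) {
        grid <- seq(max(tt) - 3, max(tt) + 12, length.out = 6)
        lapply(grid, function(g) c(value_at_ref = max(mean(y), 1e-6), arrhenius = 1e4,
                                   a_high = 5e4, t_half_high = g))
      }),
    schoolfield_full = list(
      pars = c("value_at_ref", "arrhenius", "a_low", "t_half_low", "a_high", "t_half_high"),
      fn = function(t, p) {
        (t / t_ref) * p[["value_at_ref"]] * exp(p[["arrhenius"]] * (1 / t_ref - 1 / t)) /
          (1 + exp(p[["a_low"]] * (1 / p[["t_half_low"]] - 1 / t)) +
             exp(p[["a_high"]] * (1 / p[["t_half_high"]] - 1 / t)))
      },
      lower = c(value_at_ref = 1e-10, arrhenius = 0, a_low = -5e5, t_half_low = 273,
                a_high = 1000, t_half_high = 274),
      upper = c(value_at_ref = Inf, arrhenius = 1e6, a_low = 0, t_half_low = 310,
                a_high = 5e5, t_half_high = 350),
      starts = function(tt, y) {
        grid <- seq(max(tt) - 3, max(tt) + 12, length.out = 6)
        lapply(grid, function(g) c(value_at_ref = max(mean(y), 1e-6), arrhenius = 1e4,
                                   a_low = -1e5, t_half_low = 273,
                                   a_high = 5e4, t_half_high = g))
      })
  )
}

#' Fit a thermal response function to per-temperature trait means
#'
#' Least-squares nonlinear regression of one response family against mean
#' trait values, one row per experimental temperature. Fitting is
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with a multi-start grid over
#' the location parameter (thermal optimum or high half-activity temperature)
#' to escape the local minima of skewed response surfaces; ties are broken by
#' lowest residual sum of squares, then lowest parameter norm. Asymptotic
#' standard errors come from the residual-variance-scaled inverse of the
#' Gauss-Newton normal matrix; t statistics and two-sided p-values use a t
#' reference distribution with the residual degrees of freedom. Parameters
#' named in `fixed` (conventionally the reference-temperature trait value,
#' which is observed rather than estimated) are pinned and reported without
#' standard errors.
#'
#' @param obs a data frame with columns `temperature_k` and `mean_value`
#'   (optionally `se`, `n`), one row per temperature; at least 3 distinct
#'   temperatures.
#' @param family one of `"gaussian"`, `"arrhenius"`, `"exponential"`,
#'   `"schoolfield_high"`, `"schoolfield_full"`.
#' @param fixed named numeric vector of parameters to pin.
#' @param weights `"se"` (default) weights each temperature by the inverse
#'   squared standard error of its mean when an all-positive `se` column is
#'   present (the natural weighting when fitting means of unequal precision);
#'   `"none"` forces ordinary (unweighted) least squares.
#' @param t_ref reference temperature (Kelvin) for the Arrhenius-type
#'   families.
#' @return an object of class `tn_fit`; see [tidy.tn_fit()] and
#'   [glance.tn_fit()].
#' @export
#' @examples
#' obs <- generate_trait_data(tn_species("harlequin"), n_per_temp = 1,
#'                            noise_sd_frac = 0, seed = 1)
#' fit_response(dplyr::filter(obs, trait == "birth"), "gaussian")
fit_response <- function(obs, family = c("gaussian", "arrhenius", "exponential",
                                         "schoolfield_high", "schoolfield_full"),
                         fixed = NULL, weights = c("se", "none"), t_ref = 297) {
  family <- match.arg(family)
  weights <- match.arg(weights)
  obs <- as_tibble(obs)
  if (!all(c("temperature_k", "mean_value") %in% names(obs)))
    abort("obs needs columns temperature_k and mean_value", class = "thermalniche_config_error")
  obs <- arrange(obs, .data$temperature_k)
  tt <- obs$temperature_k; y <- obs$mean_value
  if (length(unique(tt)) < 3) abort("need >= 3 distinct temperatures",
                                    class = "thermalniche_config_error")
  fam <- fit_families(t_ref)[[family]]
  free <- setdiff(fam$pars, names(fixed))
  dof <- length(tt) - length(free)
  if (dof < 1) abort("not enough temperatures for the free parameters (dof < 1)",
                     class = "thermalniche_config_error")

  w <- rep(1, length(y))
  if (weights == "se" && "se" %in% names(obs) &&
      all(is.finite(obs$se)) && all(obs$se > 0)) {
    w <- 1 / obs$se^2
    w <- w / mean(w)
  }
  sw <- sqrt(w)

  full_par <- function(p_free) {
    p <- c(p_free, fixed)
    p[fam$pars]
  }
  resid_fn <- function(p_free) sw * (y - fam$fn(tt, full_par(p_free)))

  fits <- list()
  for (st in fam$starts(tt, y)) {
    st <- st[free]
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = fam$lower[free], upper = fam$upper[free],
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f)) fits <- c(fits, list(f))
  }
  if (!length(fits)) {
    return(structure(list(family = family, converged = FALSE,
                          diagnostics = "no start converged",
                          estimates = NULL, fixed = fixed, data = obs),
                     class = "tn_fit"))
  }
  ssr <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best_ssr <- min(ssr)
  cand <- fits[ssr <= best_ssr * (1 + 1e-8) + 1e-300]
  norms <- vapply(cand, function(f) sqrt(sum(unlist(f$par)^2)), numeric(1))
  fit <- cand[[which.min(norms)]]
  est <- unlist(fit$par)

  # asymptotic covariance: sigma^2 * (J'WJ)^-1; nls.lm's hessian is J'WJ for
  # the weighted residuals. Rank deficiency is judged on the scale-free
  # correlation form so that wildly different parameter units do not
  # masquerade as singularity.
  jtj <- fit$hessian
  d <- sqrt(pmax(diag(jtj), 0))
  if (any(d == 0)) {
    abort(sprintf("singular normal matrix: parameter `%s` is not identifiable from these data",
                  free[which(d == 0)[1]]), class = "thermalniche_rank_error")
  }
  corr <- jtj / tcrossprod(d)
  sv_c <- svd(corr)
  if (min(sv_c$d) < max(sv_c$d) * 1e-10) {
    worst <- free[which.max(abs(sv_c$v[, length(sv_c$d)]))]
    abort(sprintf("singular normal matrix: parameter `%s` is not identifiable from these data",
                  worst), class = "thermalniche_rank_error")
  }
  sigma2 <- sum(fit$fvec^2) / dof
  vc <- sigma2 * solve(jtj)
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- free
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = dof)
  rel <- se / pmax(abs(est), 1e-300)
  if (any(is.finite(rel) & rel > 1))
    warn(sprintf("weakly identified parameter(s): %s (SE exceeds the estimate); the data do not constrain this family",
                 paste(free[rel > 1], collapse = ", ")))
  structure(list(family = family, estimates = est, standard_errors = se,
                 t_values = tval, p_values = pval, dof = dof,
                 converged = fit$info %in% 1:4, fixed = fixed,
                 ssr = sum(fit$fvec^2), sigma = sqrt(sigma2),
                 t_ref = t_ref, data = obs, fn = fam$fn, pars = fam$pars),
            class = "tn_fit")
}

#' @export
print.tn_fit <- function(x, ...) {
  cat("<tn_fit> family:", x$family, if (!x$converged) "(NOT converged)", "\n")
  if (!is.null(x$estimates)) print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a thermal response fit
#'
#' @param x a `tn_fit` object.
#' @param ... unused.
#' @return a tibble with one row per parameter: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `df`, `fixed`.
#' @export
tidy.tn_fit <- function(x, ...) {
  if (is.null(x$estimates)) return(tibble())
  free <- tibble(term = names(x$estimates), estimate = unname(x$estimates),
                 std_error = unname(x$standard_errors),
                 statistic = unname(x$t_values), p_value = unname(x$p_values),
                 df = x$dof, fixed = FALSE)
  if (length(x$fixed)) {
    free <- bind_rows(free, tibble(term = names(x$fixed), estimate = unname(x$fixed),
                                   std_error = NA_real_, statistic = NA_real_,
                                   p_value = NA_real_, df = NA_integer_, fixed = TRUE))
  }
  free
}

#' Fit summary
#'
#' @param x a `tn_fit` object.
#' @param ... unused.
#' @return a one-row tibble: `family`, `ssr`, `sigma`, `df_residual`,
#'   `n_points`, `converged`.
#' @export
glance.tn_fit <- function(x, ...) {
  tibble(family = x$family, ssr = x$ssr %||% NA_real_, sigma = x$sigma %||% NA_real_,
         df_residual = x$dof %||% NA_integer_, n_points = nrow(x$data),
         converged = x$converged)
}

#' @export
predict.tn_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature_k else newdata$temperature_k
  p <- c(object$estimates, object$fixed)[object$pars]
  object$fn(tt, p)
}

#' Plot a thermal response fit
#'
#' @param object a `tn_fit` object.
#' @param ... unused.
#' @return a ggplot of the observed means (with SE bars when present) and the
#'   fitted curve.
#' @export
autoplot.tn_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(temperature_k = seq(min(dat$temperature_k) - 2,
                                     max(dat$temperature_k) + 2, length.out = 200))
  grid$fit <- predict(object, grid)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$temperature_k, .data$mean_value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::labs(x = "Temperature (K)", y = "Rate (/day)",
                  title = paste("Thermal response fit:", object$family)) +
    ggplot2::theme_minimal()
  if ("se" %in% names(dat) && any(dat$se > 0, na.rm = TRUE))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_value - .data$se,
                   ymax = .data$mean_value + .data$se), width = 0.2)
  p
}
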