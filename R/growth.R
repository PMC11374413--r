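#' Intrinsic growth rate at constant temperature
#'
#' Closed form for the long-term exponential growth rate of the
#' density-independent stage-structured model at constant temperature:
#' \deqn{r(T) = -d_A(T) + \frac{1}{\tau(T)}
#'   W\!\left(b(T)\,\tau(T)\, e^{\tau(T)(d_A(T) - d_J(T))}\right),}
#' with \eqn{\tau(T) = 1/m_J(T)} the developmental delay and W the principal
#' branch of the Lambert W function. The W argument is evaluated in log space
#' so the formula is usable arbitrarily deep into the cold/hot tails where
#' \eqn{\tau} becomes enormous.
#'
#' @param traits a [species_traits()] object.
#' @param t temperature(s) in Kelvin.
#' @return intrinsic growth rate(s), per day.
#' @export
#' @examples
#' intrinsic_growth_rate(tn_species("harlequin"), celsius_to_kelvin(26.7))
intrinsic_growth_rate <- function(traits, t) {
  stopifnot(inherits(traits, "species_traits"))
  check_kelvin(t)
  vapply(t, function(tt) {
    m <- maturation_rate(traits$maturation, tt)
    if (m <= 0) abort("maturation rate is zero: growth rate undefined",
                      class = "thermalniche_domain_error")
    tau <- 1 / m
    d_a <- arrhenius_rate(traits$adult_mortality, tt)
    d_j <- arrhenius_rate(traits$juvenile_mortality, tt)
    b <- gaussian_rate(traits$birth, tt)
    log_arg <- log(b * tau) + tau * (d_a - d_j)
    -d_a + m * lambert_w0(log_x = log_arg)
  }, numeric(1))
}

#' Fundamental thermal niche metrics
#'
#' Locates the thermal optimum of the intrinsic growth rate by bounded
#' maximization, and the lower and upper thermal limits `t_min`, `t_max`
#' (roots of `r(T) = 0`) by bracketed root finding on either side of the
#' optimum. Also returns the sampled `r(T)` curve.
#'
#' @param traits a [species_traits()] object.
#' @param search_range temperatures (Kelvin) bracketing the search; default
#'   (274, 323) spans biologically plausible niches while avoiding the deep
#'   cold-side singularities of the maturation response.
#' @param curve_by sampling resolution of the returned curve (Kelvin).
#' @return an object of class `niche_metrics`: a list with `t_opt_r`,
#'   `r_max`, `t_min`, `t_max` (Kelvin), `viable`, the species name, and the
#'   `r_curve` tibble (`temperature_k`, `r`). For a nonviable species
#'   (`r <= 0` everywhere) `viable` is `FALSE` and the limits are `NA`.
#' @export
#' @examples
#' niche_metrics(tn_species("bagrada"))
niche_metrics <- function(traits, search_range = c(274, 323), curve_by = 0.05) {
  stopifnot(inherits(traits, "species_traits"), length(search_range) == 2)
  lo <- search_range[1]; hi <- search_range[2]
  opt <- optimize(function(tt) intrinsic_growth_rate(traits, tt),
                  lower = lo, upper = hi, maximum = TRUE, tol = 1e-4)
  t_opt <- opt$maximum; r_max <- opt$objective
  grid <- seq(lo, hi, by = curve_by)
  r_grid <- intrinsic_growth_rate(traits, grid)
  curve <- tibble(temperature_k = grid, r = r_grid)
  if (r_max <= 0) {
    return(structure(list(species = traits$name, viable = FALSE,
                          t_opt_r = NA_real_, r_max = r_max,
                          t_min = NA_real_, t_max = NA_real_, r_curve = curve),
                     class = "niche_metrics"))
  }
  root_near <- function(side_grid, side_r, default_bracket) {
    # bracket from sampled sign changes; take the one nearest the optimum
    sgn <- sign(side_r)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flips) > 1)
      warn("multiple r(T) = 0 sign changes; using the bracket nearest the optimum")
    if (!length(flips)) return(NA_real_)
    i <- if (default_bracket == "lower") flips[length(flips)] else flips[1]
    uniroot(function(tt) intrinsic_growth_rate(traits, tt),
            lower = side_grid[i], upper = side_grid[i + 1], tol = 1e-6)$root
  }
  below <- grid <= t_opt
  t_min <- root_near(grid[below], r_grid[below], "lower")
  t_max <- root_near(grid[!below], r_grid[!below], "upper")
  structure(list(species = traits$name, viable = TRUE,
                 t_opt_r = t_opt, r_max = r_max,
                 t_min = t_min, t_max = t_max, r_curve = curve),
            class = "niche_metrics")
}

#' @export
print.niche_metrics <- function(x, ...) {
  cat("<niche_metrics> ", x$species, "\n", sep = "")
  if (!x$viable) { cat("  nonviable: r(T) <= 0 over the search range\n"); return(invisible(x)) }
  cat(sprintf("  t_opt_r  %7.2f K (%.1f degC)\n", x$t_opt_r, kelvin_to_celsius(x$t_opt_r)))
  cat(sprintf("  r_max    %7.4f /day\n", x$r_max))
  cat(sprintf("  t_min    %7.2f K (%.1f degC)\n", x$t_min, kelvin_to_celsius(x$t_min)))
  cat(sprintf("  t_max    %7.2f K (%.1f degC)\n", x$t_max, kelvin_to_celsius(x$t_max)))
  invisible(x)
}

#' @export
tidy.niche_metrics <- function(x, ...) {
  tibble(species = x$species, viable = x$viable,
         t_opt_r_k = x$t_opt_r, r_max = x$r_max,
         t_min_k = x$t_min, t_max_k = x$t_max,
         t_opt_r_c = kelvin_to_celsius(x$t_opt_r),
         t_min_c = kelvin_to_celsius(x$t_min),
         t_max_c = kelvin_to_celsius(x$t_max))
}

#' Interspecific thermal niche overlap
#'
#' Finds the overlap of two species' fundamental niches. The overlap interval
#' runs from the cool species-limit that bounds it below (the warmer of the
#' two `t_min`) to the warmer species' `t_max` that bounds it above (the
#' cooler of the two `t_max`). The niche intersection temperature
#' `t_intersect` is located by bisection of `r_a(T) - r_b(T)` to
#' `|delta r| <= 1e-6`. The shared niche area is the integral of the lower
#' envelope of the two growth-rate curves over the overlap interval —
#' equivalently the sum of the integral of the curve that is lower below
#' `t_intersect` and of the other curve above it — and each species' overlap
#' fraction divides that shared area by the integral of its own `r(T)` over
#' its full niche.
#'
#' @param a,b [species_traits()] objects.
#' @param search_range passed to [niche_metrics()].
#' @return an object of class `overlap_result`: list with `t_intersect`,
#'   `overlap_interval` (Kelvin), the component integrals, and `fraction_a`,
#'   `fraction_b` in `[0, 1]`. Disjoint niches give an empty interval and zero
#'   fractions.
#' @export
#' @examples
#' niche_overlap(tn_species("bagrada"), tn_species("harlequin"))
niche_overlap <- function(a, b, search_range = c(274, 323)) {
  na <- niche_metrics(a, search_range); nb <- niche_metrics(b, search_range)
  if (!na$viable || !nb$viable)
    abort("both species must be viable for an overlap computation",
          class = "thermalniche_domain_error")
  r_a <- function(tt) intrinsic_growth_rate(a, tt)
  r_b <- function(tt) intrinsic_growth_rate(b, tt)
  lo <- max(na$t_min, nb$t_min); hi <- min(na$t_max, nb$t_max)
  int_a_total <- integrate(Vectorize(r_a), na$t_min, na$t_max, abs.tol = 1e-8)$value
  int_b_total <- integrate(Vectorize(r_b), nb$t_min, nb$t_max, abs.tol = 1e-8)$value
  if (lo >= hi) {
    return(structure(list(species_a = a$name, species_b = b$name,
                          t_intersect = NA_real_, overlap_interval = c(NA_real_, NA_real_),
                          shared_area = 0,
                          integral_a_total = int_a_total, integral_b_total = int_b_total,
                          fraction_a = 0, fraction_b = 0),
                     class = "overlap_result"))
  }
  diff_fun <- function(tt) r_a(tt) - r_b(tt)
  t_int <- if (sign(diff_fun(lo)) == sign(diff_fun(hi))) NA_real_ else
    uniroot(diff_fun, lower = lo, upper = hi, tol = 1e-9,
            f.lower = diff_fun(lo), f.upper = diff_fun(hi))$root
  lower_env <- function(tt) pmin(r_a(tt), r_b(tt))
  shared <- if (is.na(t_int)) {
    integrate(Vectorize(lower_env), lo, hi, abs.tol = 1e-8)$value
  } else {
    # split at the intersection: below it one curve is the lower envelope,
    # above it the other
    left_is_a <- diff_fun((lo + t_int) / 2) < 0
    f_left <- if (left_is_a) r_a else r_b
    f_right <- if (left_is_a) r_b else r_a
    integrate(Vectorize(f_left), lo, t_int, abs.tol = 1e-8)$value +
      integrate(Vectorize(f_right), t_int, hi, abs.tol = 1e-8)$value
  }
  structure(list(species_a = a$name, species_b = b$name,
                 t_intersect = t_int, overlap_interval = c(lo, hi),
                 shared_area = shared,
                 integral_a_total = int_a_total, integral_b_total = int_b_total,
                 fraction_a = shared / int_a_total, fraction_b = shared / int_b_total),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", x$species_a, " vs ", x$species_b, "\n", sep = "")
  if (!is.finite(x$overlap_interval[1])) {
    cat("  niches are disjoint\n"); return(invisible(x))
  }
  cat(sprintf("  overlap interval  %.1f - %.1f degC\n",
              kelvin_to_celsius(x$overlap_interval[1]),
              kelvin_to_celsius(x$overlap_interval[2])))
  if (is.finite(x$t_intersect))
    cat(sprintf("  niche intersection at %.1f degC\n", kelvin_to_celsius(x$t_intersect)))
  cat(sprintf("  shared area %.4f /day*K;  %.1f%% of %s niche, %.1f%% of %s niche\n",
              x$shared_area, 100 * x$fraction_a, x$species_a,
              100 * x$fraction_b, x$species_b))
  invisible(x)
}

#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(species_a = x$species_a, species_b = x$species_b,
         t_intersect_c = kelvin_to_celsius(x$t_intersect),
         overlap_lo_c = kelvin_to_celsius(x$overlap_interval[1]),
         overlap_hi_c = kelvin_to_celsius(x$overlap_interval[2]),
         shared_area = x$shared_area,
         fraction_a = x$fraction_a, fraction_b = x$fraction_b)
}

#' Plot a thermal niche
#'
#' @param object a `niche_metrics` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.niche_metrics <- function(object, ...) {
  dat <- mutate(object$r_curve, temperature_c = kelvin_to_celsius(.data$temperature_k))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$temperature_c, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)", y = "Intrinsic growth rate r(T) (/day)",
                  title = object$species) +
    ggplot2::theme_minimal()
  if (object$viable)
    p <- p + ggplot2::geom_vline(
      xintercept = kelvin_to_celsius(c(object$t_min, object$t_opt_r, object$t_max)),
      linetype = 3, colour = "steelblue")
  p
}
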