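test_that("closed-form equilibria match long DD simulations", {
  cases <- list(
    list(sp = har, dd = "adult_mortality", t_c = 23.7),
    list(sp = har, dd = "fecundity", t_c = 21),
    list(sp = bag, dd = "adult_mortality", t_c = 31),
    list(sp = bag, dd = "fecundity", t_c = 29))
  for (cs in cases) {
    m <- dd_model(cs$sp, cs$dd, celsius_to_kelvin(cs$t_c))
    eq <- equilibrium(m)
    expect_true(eq$viable)
    tr <- simulate_population(m, initial_adults = 0.5 * eq$adults_star,
                              initial_juveniles = 0.5 * eq$juveniles_star,
                              horizon = 365 * 8, step = 0.5)
    expect_equal(tr$adults[nrow(tr)], eq$adults_star, tolerance = 1e-3)
    expect_equal(tr$juveniles[nrow(tr)], eq$juveniles_star, tolerance = 1e-3)
  }
})

test_that("the equilibrium vanishes continuously at the replacement boundary", {
  # below t_min the net reproductive number is < 1: nonviable, A* = 0
  m <- dd_model(har, "fecundity", celsius_to_kelvin(17))
  eq <- equilibrium(m)
  expect_false(eq$viable)
  expect_identical(eq$adults_star, 0)
  # just inside the niche the equilibrium is positive and shrinks toward the
  # boundary from within
  a_near <- equilibrium(dd_model(har, "fecundity", oracle$har_tmin_k + 0.02))$adults_star
  a_far <- equilibrium(dd_model(har, "fecundity", oracle$har_tmin_k + 0.5))$adults_star
  expect_gt(a_near, 0)
  expect_lt(a_near, a_far)
  # an exactly balanced species (b * S_J = d_A) has A* = 0 under both forms
  t_k <- 300
  s_j <- through_stage_survivorship(har, t_k)
  d_a <- arrhenius_rate(har$adult_mortality, t_k)
  scale <- d_a / (gaussian_rate(har$birth, t_k) * s_j)
  bal <- species_traits("balanced",
    gaussian_params(har$birth$peak * scale, har$birth$t_opt, har$birth$breadth),
    har$maturation, har$juvenile_mortality, har$adult_mortality)
  for (dd in c("fecundity", "adult_mortality")) {
    eqb <- equilibrium(model_spec(bal, default_competition(bal, dd),
                                  temperature_forcing("constant", t_k)))
    expect_identical(eqb$adults_star, 0)
  }
})

test_that("juvenile-stage density dependence is explicitly not implemented", {
  m <- model_spec(har, competition_spec("juvenile_mortality", "monotonic",
                                        arrhenius_params(0.1, 5743, 297)),
                  temperature_forcing("constant", 296))
  expect_error(equilibrium(m), class = "thermalniche_not_implemented")
})

test_that("every returned characteristic root satisfies its equation to near machine precision", {
  for (cs in list(list(sp = har, dd = "adult_mortality", t_c = 23.7),
                  list(sp = har, dd = "fecundity", t_c = 27),
                  list(sp = bag, dd = "fecundity", t_c = 33),
                  list(sp = bag, dd = "adult_mortality", t_c = 35))) {
    m <- dd_model(cs$sp, cs$dd, celsius_to_kelvin(cs$t_c))
    st <- dominant_eigenvalue(m)
    expect_lt(st$residual, 1e-10 * (abs(st$a) + abs(st$c)))
  }
})

test_that("the Lambert-branch root search agrees with argument-principle counting", {
  for (cs in list(list(sp = har, dd = "fecundity", t_c = 27),
                  list(sp = har, dd = "adult_mortality", t_c = 25))) {
    m <- dd_model(cs$sp, cs$dd, celsius_to_kelvin(cs$t_c))
    st <- dominant_eigenvalue(m)
    roots <- thermalniche:::char_roots(st$a, st$c, st$tau)
    re_lo <- -5 * st$a; re_hi <- st$a; im_hi <- 4 * pi / st$tau
    counted <- thermalniche:::count_char_roots(st$a, st$c, st$tau,
                                               re_lo, re_hi, 1e-9, im_hi)
    found <- sum(Re(roots) > re_lo & Re(roots) < re_hi &
                   Im(roots) > 1e-9 & Im(roots) < im_hi)
    expect_equal(found, counted)
  }
})

test_that("a vanishing delayed term collapses the eigenvalue to -a exactly", {
  roots <- thermalniche:::char_roots(0.05, 0, 30)
  expect_identical(roots, complex(real = -0.05, imaginary = 0))
})

test_that("perturbation decay and ring-down match the dominant eigenvalue", {
  # real eigenvalue: monotone decay rate
  m <- dd_model(har, "adult_mortality", celsius_to_kelvin(25))
  eq <- equilibrium(m); st <- dominant_eigenvalue(m)
  expect_true(abs(Im(st$dominant_eigenvalue)) < 1e-12)
  tr <- simulate_population(m, initial_adults = 1.1 * eq$adults_star,
                            initial_juveniles = eq$juveniles_star,
                            horizon = 1500, step = 0.5)
  dev <- abs(tr$adults - eq$adults_star)
  i <- tr$time_d > 300 & dev > 1e-8 * eq$adults_star
  rate <- -coef(lm(log(dev[i]) ~ tr$time_d[i]))[[2]]
  expect_equal(rate, -Re(st$dominant_eigenvalue), tolerance = 0.05)

  # complex pair: decay envelope and oscillation period
  m2 <- dd_model(har, "fecundity", celsius_to_kelvin(27))
  eq2 <- equilibrium(m2); st2 <- dominant_eigenvalue(m2)
  lam <- st2$dominant_eigenvalue
  expect_gt(abs(Im(lam)), 0)
  tr2 <- simulate_population(m2, initial_adults = 1.1 * eq2$adults_star,
                             initial_juveniles = eq2$juveniles_star,
                             horizon = 1200, step = 0.25)
  dev2 <- tr2$adults - eq2$adults_star
  i2 <- tr2$time_d > 200
  # period from zero crossings of the deviation
  s <- sign(dev2[i2]); tt <- tr2$time_d[i2]
  crossings <- tt[which(s[-1] * s[-length(s)] < 0)]
  period <- 2 * mean(diff(crossings))
  expect_equal(period, 2 * pi / abs(Im(lam)), tolerance = 0.05)
  # envelope decay from the local maxima of |deviation|
  mag <- abs(dev2[i2])
  pk_idx <- which(diff(sign(diff(mag))) == -2) + 1
  env_fit <- lm(log(mag[pk_idx]) ~ tt[pk_idx])
  expect_equal(-coef(env_fit)[[2]], -Re(lam), tolerance = 0.05)
})

test_that("the DD envelope peaks below the growth optimum for both species and forms", {
  for (sp in list(bag, har)) {
    nm <- niche_metrics(sp)
    grid <- seq(nm$t_min + 0.01, nm$t_max - 0.01, by = 0.2)
    for (dd in c("fecundity", "adult_mortality")) {
      m <- dd_model(sp, dd, 300)
      env <- dd_envelope(m, grid)
      expect_lt(attr(env, "t_opt_add"), nm$t_opt_r)
    }
  }
})

test_that("recovery-time argmin location is invariant under a common rate rescaling", {
  # doubling every rate halves all time scales: lambda doubles, recovery
  # halves, and the argmin temperature stays put
  scale_traits <- function(sp, f) species_traits(
    paste0(sp$name, "_x", f),
    gaussian_params(sp$birth$peak * f, sp$birth$t_opt, sp$birth$breadth),
    schoolfield_params(sp$maturation$value_at_ref * f, sp$maturation$arrhenius,
                       sp$maturation$t_ref, sp$maturation$a_low,
                       sp$maturation$t_half_low, sp$maturation$a_high,
                       sp$maturation$t_half_high),
    arrhenius_params(sp$juvenile_mortality$value_at_ref * f,
                     sp$juvenile_mortality$arrhenius, sp$juvenile_mortality$t_ref),
    arrhenius_params(sp$adult_mortality$value_at_ref * f,
                     sp$adult_mortality$arrhenius, sp$adult_mortality$t_ref))
  grid <- seq(oracle$har_tmin_k + 0.2, oracle$har_tmax_k - 0.2, by = 0.1)
  m1 <- dd_model(har, "adult_mortality", 300)
  m2 <- model_spec(scale_traits(har, 2),
                   default_competition(scale_traits(har, 2), "adult_mortality"),
                   temperature_forcing("constant", 300))
  r1 <- recovery_curve(m1, grid)
  r2 <- recovery_curve(m2, grid)
  expect_equal(attr(r1, "t_opt_recovery"), attr(r2, "t_opt_recovery"),
               tolerance = 1e-5)
  ok <- is.finite(r1$recovery_time_d) & is.finite(r2$recovery_time_d)
  expect_equal(r1$recovery_time_d[ok], 2 * r2$recovery_time_d[ok], tolerance = 1e-9)
})

test_that("equilibrium computations refuse time-varying forcing", {
  m <- model_spec(har, default_competition(har, "fecundity"),
                  temperature_forcing("sinusoidal", 296, 3, 365))
  expect_error(equilibrium(m), class = "thermalniche_config_error")
})
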