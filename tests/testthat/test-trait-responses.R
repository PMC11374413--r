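test_that("Arrhenius response returns the reference value at t_ref and matches direct evaluation", {
  expect_identical(arrhenius_rate(bag$adult_mortality, 297), 0.0926)
  expect_equal(arrhenius_rate(har$adult_mortality, 299.85), oracle$har_da_299.85,
               tolerance = 1e-12)
  expect_equal(arrhenius_rate(har$juvenile_mortality, 292.85), oracle$har_dj_292.85,
               tolerance = 1e-12)
})

test_that("Arrhenius response is strictly increasing for positive Arrhenius constants", {
  grid <- seq(280, 320, by = 0.01)
  for (p in list(bag$adult_mortality, har$juvenile_mortality,
                 arrhenius_params(0.1, 16824, 297))) {
    expect_true(all(diff(arrhenius_rate(p, grid)) > 0))
  }
})

test_that("Gaussian response peaks at the optimum and is symmetric", {
  expect_identical(gaussian_rate(har$birth, 298.3), 0.8921)
  expect_equal(gaussian_rate(har$birth, 292.85), oracle$har_b_292.85, tolerance = 1e-12)
  grid <- seq(285, 315, by = 0.01)
  vals <- gaussian_rate(har$birth, grid)
  expect_true(all(vals <= gaussian_rate(har$birth, har$birth$t_opt)))
  delta <- seq(0.1, 8, by = 0.37)
  expect_equal(gaussian_rate(bag$birth, bag$birth$t_opt + delta),
               gaussian_rate(bag$birth, bag$birth$t_opt - delta))
})

test_that("maturation rate matches direct evaluation of the full thermodynamic model", {
  expect_equal(maturation_rate(har$maturation, 299.85), oracle$har_m_299.85,
               tolerance = 1e-12)
  expect_equal(maturation_rate(har$maturation, 296.85), oracle$har_m_296.85,
               tolerance = 1e-12)
})

test_that("the exponential maturation form equals the Arrhenius numerator at t_ref", {
  p <- schoolfield_params(0.015, 11500, 297)
  expect_identical(maturation_family(p), "exponential")
  expect_identical(maturation_rate(p, 297), 0.015)
})

test_that("reduced maturation forms are limits of the full model", {
  # negligible low-temperature inactivation -> the high-only (m_alt) form
  full <- schoolfield_params(0.0168, 10671, 297, a_low = -1e7, t_half_low = 273,
                             a_high = 90000, t_half_high = 312)
  alt <- schoolfield_params(0.0168, 10671, 297, a_high = 90000, t_half_high = 312)
  grid <- seq(290, 315, by = 0.25)
  low_term <- exp(-1e7 * (1 / 273 - 1 / grid))
  expect_true(all(low_term < 1e-12))
  expect_equal(maturation_rate(full, grid), maturation_rate(alt, grid),
               tolerance = 1e-10)
  # both inactivation terms negligible and the t/t_ref prefactor removed
  # -> the bare exponential form
  both <- schoolfield_params(0.015, 11500, 297, a_low = -1e7, t_half_low = 273,
                             a_high = 1e6, t_half_high = 340)
  expo <- schoolfield_params(0.015, 11500, 297)
  expect_equal(maturation_rate(both, grid) * (297 / grid),
               maturation_rate(expo, grid), tolerance = 1e-10)
})

test_that("competition strength dispatches on the populated block", {
  mono <- competition_spec("adult_mortality", "monotonic",
                           arrhenius_params(0.1, 16824, 297))
  uni <- competition_spec("fecundity", "unimodal",
                          gaussian_params(0.1, 298.3, 3.085))
  expect_identical(competition_strength(mono, 297), 0.1)
  expect_equal(competition_strength(mono, 292.85), oracle$q_mono_292.85, tolerance = 1e-12)
  expect_equal(competition_strength(uni, 292.85), oracle$q_uni_292.85, tolerance = 1e-12)
  expect_error(competition_spec("fecundity", "unimodal", arrhenius_params(0.1, 1e4)),
               class = "thermalniche_config_error")
})

test_that("stage duration is the reciprocal maturation rate", {
  expect_equal(stage_duration(har$maturation, 299.85), oracle$har_tau_299.85,
               tolerance = 1e-12)
  expect_equal(stage_duration(har$maturation, 292.85), oracle$har_tau_292.85,
               tolerance = 1e-12)
  p <- schoolfield_params(0.02, 0, 297)  # flat exponential: rate 0.02 everywhere
  expect_equal(stage_duration(p, 300), 50)
})

test_that("through-stage survivorship lies in (0, 1] across the niche", {
  # range spans every species' niche with margin; far outside it the
  # exponent d_J/m_J exceeds ~745 and survivorship underflows double
  # precision to an exact 0 (still non-negative)
  grid <- seq(280, 312, by = 0.25)
  for (sp in list(bag, har, gen)) {
    s <- through_stage_survivorship(sp, grid)
    expect_true(all(s > 0 & s <= 1))
  }
})

test_that("non-positive temperatures are rejected", {
  expect_error(arrhenius_rate(bag$adult_mortality, -1), class = "thermalniche_domain_error")
  expect_error(gaussian_rate(har$birth, 0), class = "thermalniche_domain_error")
})

test_that("parameter containers enforce their invariants", {
  expect_error(gaussian_params(0.5, 300, -1), class = "thermalniche_param_error")
  expect_error(arrhenius_params(-0.1, 1e4), class = "thermalniche_param_error")
  expect_error(schoolfield_params(0.01, 1e4, a_low = -1e5, t_half_low = 272,
                                  a_high = 1e4, t_half_high = 310),
               class = "thermalniche_param_error")
  expect_error(schoolfield_params(0.01, 1e4, a_low = -1e5, t_half_low = 305,
                                  a_high = 1e4, t_half_high = 303),
               class = "thermalniche_param_error")
})
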