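fit_cases <- list(
  list(trait = "birth", family = "gaussian", fixed = NULL,
       truth = c(peak = 0.8921, t_opt = 298.3, breadth = 3.085)),
  list(trait = "adult_mortality", family = "arrhenius",
       fixed = c(value_at_ref = 0.0029), truth = c(arrhenius = 16824)),
  list(trait = "juvenile_mortality", family = "arrhenius", fixed = NULL,
       truth = c(value_at_ref = 0.0343, arrhenius = 5743)),
  list(trait = "maturation", family = "schoolfield_full",
       fixed = c(value_at_ref = 0.0138, a_low = -1e5, t_half_low = 273),
       truth = c(arrhenius = 13480, a_high = 48150, t_half_high = 303.8))
)

test_that("noiseless synthetic data give back the generating parameters", {
  obs <- generate_trait_data(har, n_per_temp = 1, noise_sd_frac = 0, seed = 1)
  for (cs in fit_cases) {
    ft <- fit_response(dplyr::filter(obs, trait == cs$trait), cs$family,
                       fixed = cs$fixed)
    expect_true(ft$converged)
    expect_equal(ft$estimates[names(cs$truth)], cs$truth, tolerance = 1e-6)
  }
  # exponential family, generic-species maturation
  obs_g <- generate_trait_data(gen, n_per_temp = 1, noise_sd_frac = 0, seed = 1)
  fe <- fit_response(dplyr::filter(obs_g, trait == "maturation"), "exponential")
  expect_equal(fe$estimates, c(value_at_ref = 0.015, arrhenius = 11500),
               tolerance = 1e-6)
})

test_that("the generator is deterministic under a seed and exact at zero noise", {
  a <- generate_trait_data(har, n_per_temp = 7, noise_sd_frac = 0.05, seed = 99)
  b <- generate_trait_data(har, n_per_temp = 7, noise_sd_frac = 0.05, seed = 99)
  expect_identical(a, b)
  z <- generate_trait_data(har, n_per_temp = 5, noise_sd_frac = 0, seed = 1)
  birth <- dplyr::filter(z, trait == "birth")
  expect_equal(birth$mean_value, gaussian_rate(har$birth, birth$temperature_k))
  expect_true(all(z$se == 0))
})

test_that("replicate standard errors follow the central limit theorem", {
  z <- generate_trait_data(har, n_per_temp = 10000, noise_sd_frac = 0.10, seed = 5)
  birth <- dplyr::filter(z, trait == "birth", temperature_k > 291)  # away from truncation
  theo <- gaussian_rate(har$birth, birth$temperature_k) * 0.10 / sqrt(10000)
  expect_true(all(abs(birth$se / theo - 1) < 0.05))
})

test_that("estimates are unbiased under measurement noise (small Monte-Carlo)", {
  n_rep <- 40
  ests <- t(sapply(seq_len(n_rep), function(i) {
    obs <- generate_trait_data(har, n_per_temp = 20, noise_sd_frac = 0.05,
                               seed = 1000 + i)
    ft <- fit_response(dplyr::filter(obs, trait == "birth"), "gaussian")
    ft$estimates
  }))
  truth <- c(peak = 0.8921, t_opt = 298.3, breadth = 3.085)
  for (p in names(truth)) {
    mc_se <- sd(ests[, p]) / sqrt(n_rep)
    expect_lt(abs(mean(ests[, p]) - truth[[p]]), 3 * mc_se)
  }
})

test_that("reported asymptotic SEs track the replicate spread of estimates", {
  n_rep <- 40
  res <- lapply(seq_len(n_rep), function(i) {
    obs <- generate_trait_data(har, n_per_temp = 20, noise_sd_frac = 0.05,
                               seed = 2000 + i)
    ft <- fit_response(dplyr::filter(obs, trait == "birth"), "gaussian")
    list(est = ft$estimates, se = ft$standard_errors)
  })
  est <- t(sapply(res, `[[`, "est"))
  se <- t(sapply(res, `[[`, "se"))
  for (p in colnames(est)) {
    expect_lt(abs(mean(se[, p]) / sd(est[, p]) - 1), 0.25)
  }
})

test_that("one-sided temperature coverage yields a wide-SE warning, not silent confidence", {
  # ordinary least squares cannot pin a Gaussian optimum from the cold flank
  # alone: the flagged fit must not be silently confident. (Inverse-variance
  # weighting under proportional noise effectively fits the log curve, which
  # IS one-sided-identifiable, so the degenerate path is the unweighted one.)
  temps_cold <- celsius_to_kelvin(c(7, 10, 13, 16, 19, 22))  # all below the optimum
  obs <- generate_trait_data(bag, temperatures = temps_cold, n_per_temp = 15,
                             noise_sd_frac = 0.05, seed = 3)
  expect_warning(fit_response(dplyr::filter(obs, trait == "birth"), "gaussian",
                              weights = "none"),
                 "weakly identified")
})

test_that("insufficient degrees of freedom are refused", {
  obs <- generate_trait_data(har, temperatures = celsius_to_kelvin(c(20, 25, 30)),
                             n_per_temp = 1, noise_sd_frac = 0, seed = 1)
  expect_error(fit_response(dplyr::filter(obs, trait == "maturation"),
                            "schoolfield_full"),
               class = "thermalniche_config_error")
})

test_that("tidy and glance report the fit in standard form", {
  obs <- generate_trait_data(har, n_per_temp = 10, noise_sd_frac = 0.05, seed = 11)
  ft <- fit_response(dplyr::filter(obs, trait == "birth"), "gaussian")
  td <- tidy(ft)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value",
                     "df", "fixed"))
  expect_equal(td$statistic, td$estimate / td$std_error)
  expect_equal(td$p_value, 2 * pt(-abs(td$statistic), df = td$df))
  gl <- glance(ft)
  expect_identical(gl$df_residual, nrow(ft$data) - 3L)
  expect_true(gl$converged)
})

test_that("per-individual CSV input aggregates to the fitting contract", {
  csv <- tempfile(fileext = ".csv")
  set.seed(4)
  long <- data.frame(
    temperature_c = rep(c(20, 24, 28, 32), each = 5), trait = "birth",
    value = rep(gaussian_rate(har$birth, celsius_to_kelvin(c(20, 24, 28, 32))),
                each = 5) * (1 + rnorm(20, 0, 0.05)))
  write.csv(long, csv, row.names = FALSE)
  obs <- read_trait_csv(csv)
  expect_named(obs, c("trait", "temperature_k", "mean_value", "se", "n"))
  expect_identical(nrow(obs), 4L)
  expect_true(all(obs$n == 5))
  expect_equal(obs$mean_value[1],
               mean(long$value[long$temperature_c == 20]))
})
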