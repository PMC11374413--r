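#' Experimental temperature sets
#'
#' The constant-temperature treatments of the two rearing experiments behind
#' the shipped parameter sets: 24-36 degC (six treatments) for the bagrada
#' bug and 15-35 degC (eight treatments) for the harlequin bug.
#'
#' @param species `"bagrada"` or `"harlequin"`.
#' @return temperatures in Kelvin.
#' @export
experimental_temperatures <- function(species = c("harlequin", "bagrada")) {
  species <- match.arg(species)
  celsius_to_kelvin(switch(species,
    bagrada = c(24, 27, 30, 33, 35, 36),
    harlequin = c(15, 18, 21, 24, 27, 29, 33, 35)))
}

#' Generate synthetic trait observations
#'
#' Emulates replicate constant-temperature trait measurements around a known
#' set of thermal reaction norms: at each temperature, `n_per_temp` replicate
#' values are drawn as `truth(T) * (1 + Normal(0, noise_sd_frac))`, truncated
#' at zero, and summarised into a mean, standard error and count — the form
#' in which such experiments are analysed. Useful for parameter-recovery
#' testing of [fit_response()]. Identical seeds give identical tables; the
#' caller's RNG state is left untouched.
#'
#' @param truth a [species_traits()] object supplying the generating curves.
#' @param temperatures treatment temperatures (Kelvin); defaults to the
#'   eight-treatment experimental set.
#' @param n_per_temp replicates (individuals) per temperature.
#' @param noise_sd_frac coefficient of variation of the multiplicative
#'   Gaussian measurement noise (0 = noiseless).
#' @param seed integer seed.
#' @return a tibble with columns `trait`, `temperature_k`, `mean_value`,
#'   `se`, `n`.
#' @export
#' @examples
#' generate_trait_data(tn_species("harlequin"), n_per_temp = 10,
#'                     noise_sd_frac = 0.05, seed = 42)
generate_trait_data <- function(truth,
                                temperatures = experimental_temperatures("harlequin"),
                                n_per_temp = 10, noise_sd_frac = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "species_traits"), n_per_temp >= 1, noise_sd_frac >= 0)
  traits <- c("birth", "maturation", "juvenile_mortality", "adult_mortality")
  withr::with_seed(as.integer(seed), {
    rows <- lapply(traits, function(tr) {
      mu <- trait_rate(truth, tr, temperatures)
      reps <- lapply(seq_along(temperatures), function(i) {
        v <- pmax(0, mu[i] * (1 + rnorm(n_per_temp, 0, noise_sd_frac)))
        tibble(trait = tr, temperature_k = temperatures[i],
               mean_value = mean(v),
               se = if (n_per_temp > 1) sd(v) / sqrt(n_per_temp) else 0,
               n = n_per_temp)
      })
      bind_rows(reps)
    })
    bind_rows(rows)
  })
}

#' Read a trait-observation CSV
#'
#' Accepts either long per-individual records (columns `temperature_c`,
#' `trait`, `value`) which are aggregated to per-temperature means, or
#' pre-aggregated records (columns `temperature_c`, `trait`, `mean`, `se`,
#' `n`). Temperatures are converted to Kelvin.
#'
#' @param path CSV file path.
#' @return a tibble with columns `trait`, `temperature_k`, `mean_value`,
#'   `se`, `n`.
#' @export
read_trait_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path))
  if (all(c("temperature_c", "trait", "value") %in% names(x))) {
    x |>
      group_by(.data$trait, .data$temperature_c) |>
      summarise(mean_value = mean(.data$value),
                se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
                n = dplyr::n(), .groups = "drop") |>
      mutate(temperature_k = celsius_to_kelvin(.data$temperature_c)) |>
      select("trait", "temperature_k", "mean_value", "se", "n")
  } else if (all(c("temperature_c", "trait", "mean", "se", "n") %in% names(x))) {
    x |>
      mutate(temperature_k = celsius_to_kelvin(.data$temperature_c),
             mean_value = .data$mean) |>
      select("trait", "temperature_k", "mean_value", "se", "n")
  } else {
    abort("CSV must have columns (temperature_c, trait, value) or (temperature_c, trait, mean, se, n)",
          class = "thermalniche_config_error")
  }
}
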