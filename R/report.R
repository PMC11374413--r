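#' Two-species thermal niche comparison
#'
#' Orchestrates the full comparison pipeline for two species: fundamental
#' niche metrics from the intrinsic growth rate, density-dependent climate
#' envelopes under both standard self-limitation configurations
#' ([default_competition()]: unimodal on fecundity, monotonic on adult
#' mortality), recovery-time curves, and the interspecific niche overlap.
#'
#' @param a,b [species_traits()] objects.
#' @param q_strength baseline competition strength (per individual).
#' @param grid_by temperature grid resolution (Kelvin) for the
#'   envelope/recovery sweeps.
#' @param search_range Kelvin range searched for the niche.
#' @return an object of class `comparison_report`; see
#'   [tidy.comparison_report()] and [write_report()].
#' @export
#' @examples
#' \donttest{
#' rep <- run_compare(tn_species("bagrada"), tn_species("harlequin"))
#' tidy(rep)
#' }
run_compare <- function(a, b, q_strength = 0.1, grid_by = 0.1,
                        search_range = c(274, 323)) {
  species <- list(a, b)
  per_species <- lapply(species, function(sp) {
    nm <- niche_metrics(sp, search_range)
    if (!nm$viable)
      abort(sprintf("stage niche_metrics failed: %s nonviable over the search range", sp$name),
            class = "thermalniche_numeric_error")
    grid <- seq(nm$t_min + 1e-3, nm$t_max - 1e-3, by = grid_by)
    dd <- lapply(c(fecundity = "fecundity", adult_mortality = "adult_mortality"),
                 function(trait) {
      m <- model_spec(sp, default_competition(sp, trait, q_strength),
                      temperature_forcing("constant", 300))
      env <- dd_envelope(m, grid)
      rec <- recovery_curve(m, grid)
      list(envelope = env, recovery = rec,
           t_opt_add = attr(env, "t_opt_add"), a_max = attr(env, "a_max"),
           t_opt_recovery = attr(rec, "t_opt_recovery"),
           t_recovery_min = attr(rec, "t_recovery_min"))
    })
    list(niche = nm, dd = dd)
  })
  names(per_species) <- c(a$name, b$name)
  structure(list(species = per_species, overlap = niche_overlap(a, b, search_range),
                 q_strength = q_strength, grid_by = grid_by),
            class = "comparison_report")
}

#' Tidy a comparison report into a summary table
#'
#' One row per species with the niche, density-dependent envelope and
#' recovery metrics, temperatures in degC (reported to the package's Celsius
#' convention; see [kelvin_to_celsius()]).
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.comparison_report <- function(x, ...) {
  bind_rows(lapply(names(x$species), function(nm) {
    s <- x$species[[nm]]
    tibble(species = nm,
           t_opt_r_c = kelvin_to_celsius(s$niche$t_opt_r),
           r_max = s$niche$r_max,
           t_min_c = kelvin_to_celsius(s$niche$t_min),
           t_max_c = kelvin_to_celsius(s$niche$t_max),
           t_opt_add_fec_c = kelvin_to_celsius(s$dd$fecundity$t_opt_add),
           a_max_fec = s$dd$fecundity$a_max,
           t_opt_recovery_fec_c = kelvin_to_celsius(s$dd$fecundity$t_opt_recovery),
           t_opt_add_mort_c = kelvin_to_celsius(s$dd$adult_mortality$t_opt_add),
           a_max_mort = s$dd$adult_mortality$a_max,
           t_opt_recovery_mort_c = kelvin_to_celsius(s$dd$adult_mortality$t_opt_recovery))
  }))
}

#' @export
print.comparison_report <- function(x, ...) {
  tab <- tidy(x)
  ov <- x$overlap
  cat("<comparison_report>\n\n")
  rows <- list(
    c("Intrinsic growth rate r(T)", "", ""),
    c("  Topt_r (degC)", fmt1(tab$t_opt_r_c)),
    c("  r(Topt) (/day)", fmt3(tab$r_max)),
    c("  Tmin (degC)", fmt1(tab$t_min_c)),
    c("  Tmax (degC)", fmt1(tab$t_max_c)),
    c("Density-dependent fecundity", "", ""),
    c("  Topt_ADD (degC)", fmt1(tab$t_opt_add_fec_c)),
    c("  ADD(Topt) (adults)", fmt1(tab$a_max_fec)),
    c("  Topt_trecovery (degC)", fmt1(tab$t_opt_recovery_fec_c)),
    c("Density-dependent mortality", "", ""),
    c("  Topt_ADD (degC)", fmt1(tab$t_opt_add_mort_c)),
    c("  ADD(Topt) (adults)", fmt1(tab$a_max_mort)),
    c("  Topt_trecovery (degC)", fmt1(tab$t_opt_recovery_mort_c)))
  hdr <- sprintf("%-26s %10s %10s", "Metric", tab$species[1], tab$species[2])
  cat(hdr, "\n", strrep("-", nchar(hdr)), "\n", sep = "")
  for (r in rows) cat(sprintf("%-26s %10s %10s", r[1], r[2], if (length(r) > 2) r[3] else ""), "\n")
  cat(sprintf("\nNiche overlap: %.1f-%.1f degC; %.0f%% of %s niche, %.0f%% of %s niche\n",
              kelvin_to_celsius(ov$overlap_interval[1]),
              kelvin_to_celsius(ov$overlap_interval[2]),
              100 * ov$fraction_a, ov$species_a, 100 * ov$fraction_b, ov$species_b))
  invisible(x)
}

fmt1 <- function(x) sprintf("%.1f", x)
fmt3 <- function(x) sprintf("%.3f", x)

#' Write a comparison report to disk
#'
#' Writes the tidy summary as CSV and, optionally, the printed table as plain
#' text. The CSV carries a provenance header comment (package version).
#'
#' @param report a `comparison_report`.
#' @param csv_path output CSV path.
#' @param txt_path optional plain-text table path.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(report, csv_path, txt_path = NULL) {
  tab <- tidy(report)
  con <- file(csv_path, "w")
  writeLines(sprintf("# thermalniche %s comparison report; temperatures degC, rates /day",
                     as.character(utils::packageVersion("thermalniche"))), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  if (!is.null(txt_path)) {
    sink(txt_path); print(report); sink()
  }
  invisible(csv_path)
}
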