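#' Specification of a synthetic benthos survey
#'
#' Describes the true state of a simulated mudflat: per-species numerical
#' density, shell-length distribution (lognormal), flesh and shell
#' length-mass allometries with lognormal measurement noise, and the
#' accessibility fraction (probability an individual lies in the top 0-4 cm
#' sediment layer). The defaults mirror a thin-shelled toxic lucinid and a
#' thick-shelled non-toxic venerid whose mean available-item masses match
#' [prey_template()].
#'
#' @param species_params tibble with columns `species`, `d_m2` (true total
#'   density, items m^-2), `len_meanlog`, `len_sdlog` (lognormal shell
#'   length, mm), `flesh_alpha`, `flesh_beta`, `shell_alpha`, `shell_beta`
#'   (power-law mass-at-length, mg at mm), `mass_sigma` (lognormal noise SD
#'   on the log scale), `accessibility` (probability of the top stratum).
#' @param n_cores number of sediment cores in the survey.
#' @param p_measured fraction of items weighed; the rest get `NA` masses
#'   (filled later by [fill_masses()]).
#' @return A list with class `survey_spec`.
#' @export
survey_spec <- function(species_params = default_species_params(),
                        n_cores = 50, p_measured = 1) {
  check_cols(species_params,
             c("species", "d_m2", "len_meanlog", "len_sdlog",
               "flesh_alpha", "flesh_beta", "shell_alpha", "shell_beta",
               "mass_sigma", "accessibility"),
             "species parameters")
  if (any(species_params$d_m2 < 0)) abort("densities must be >= 0")
  if (any(species_params$mass_sigma < 0)) abort("mass_sigma must be >= 0")
  if (any(species_params$accessibility < 0 | species_params$accessibility > 1)) {
    abort("accessibility must be in [0, 1]")
  }
  if (n_cores < 1) abort("n_cores must be >= 1")
  if (p_measured < 0 || p_measured > 1) abort("p_measured must be in [0, 1]")
  structure(list(species_params = as_tibble(species_params),
                 n_cores = n_cores, p_measured = p_measured),
            class = "survey_spec")
}

#' @rdname survey_spec
#' @export
default_species_params <- function() {
  tibble(
    species = c("loripes", "dosinia"),
    d_m2 = c(500, 150),
    len_meanlog = log(c(8, 9)), len_sdlog = c(0.25, 0.30),
    flesh_alpha = c(3 / 8^3, 5 / 9^3), flesh_beta = c(3, 3),
    shell_alpha = c(20 / 8^3, 85 / 9^3), shell_beta = c(3, 3),
    mass_sigma = c(0.15, 0.15),
    accessibility = c(0.70, 0.73)
  )
}

#' Generate a synthetic benthos survey
#'
#' Simulates one survey under a [survey_spec()]: per core and species, item
#' counts are Poisson at `density * core_area`; shell lengths are lognormal;
#' flesh and shell masses follow the power-law allometries with
#' multiplicative lognormal noise; each item lands in the top 0-4 cm stratum
#' with the species' accessibility probability; a fraction `1 - p_measured`
#' of items get missing masses. Fully reproducible given `seed`.
#'
#' @param spec a [survey_spec()].
#' @param seed integer seed (RNG state is restored afterwards).
#' @param year year label attached to all records.
#' @param core_diameter_cm sediment-core diameter (cm), default 15.
#' @return A benthos-record tibble: `year`, `station`, `species`, `stratum`,
#'   `length_mm`, `afdm_mg`, `dm_mg`.
#' @examples
#' survey <- gen_benthos_survey(survey_spec(), seed = 1)
#' @export
gen_benthos_survey <- function(spec, seed, year = 1L, core_diameter_cm = 15) {
  stopifnot(inherits(spec, "survey_spec"))
  core_area_m2 <- pi * (core_diameter_cm / 2)^2 * 1e-4
  with_local_seed(seed, {
    rows <- purrr::pmap(spec$species_params, function(species, d_m2,
                                                      len_meanlog, len_sdlog,
                                                      flesh_alpha, flesh_beta,
                                                      shell_alpha, shell_beta,
                                                      mass_sigma, accessibility) {
      counts <- rpois(spec$n_cores, d_m2 * core_area_m2)
      n <- sum(counts)
      if (n == 0) return(NULL)
      len <- rlnorm(n, len_meanlog, len_sdlog)
      afdm <- flesh_alpha * len^flesh_beta * exp(rnorm(n, 0, mass_sigma))
      dm <- shell_alpha * len^shell_beta * exp(rnorm(n, 0, mass_sigma))
      unmeasured <- runif(n) > spec$p_measured
      afdm[unmeasured] <- NA_real_
      dm[unmeasured] <- NA_real_
      tibble(
        year = year,
        station = rep(seq_len(spec$n_cores), counts),
        species = species,
        stratum = ifelse(runif(n) < accessibility, "top_0_4cm", "bottom_4_16cm"),
        length_mm = len, afdm_mg = afdm, dm_mg = dm
      )
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out)) arrange(out, .data$species, .data$station) else
      tibble(year = integer(), station = integer(), species = character(),
             stratum = character(), length_mm = numeric(),
             afdm_mg = numeric(), dm_mg = numeric())
  })
}

#' Generate correlated annual prey biomasses
#'
#' Seeded bivariate lognormal series of toxic and bulky prey flesh biomass
#' (g AFDM m^-2) with a target correlation on the log scale. The default
#' correlation of -0.76 emulates the observed tendency of the two prey
#' stocks to alternate between years.
#'
#' @param n_years number of years.
#' @param seed integer seed.
#' @param rho log-scale correlation in `[-1, 1]`.
#' @param meanlog,sdlog length-2 vectors of lognormal parameters for
#'   (toxic, bulky) biomass. Defaults put the toxic prey usually above the
#'   0.25 g m^-2 toxin threshold and the bulky prey mostly below the
#'   digestive-onset range.
#' @return A tibble `year`, `b_tox_g_m2`, `b_bulk_g_m2`.
#' @export
gen_annual_system <- function(n_years, seed, rho = -0.76,
                              meanlog = log(c(0.5, 0.3)),
                              sdlog = c(0.6, 0.8)) {
  if (abs(rho) > 1) abort("|rho| must be <= 1")
  if (n_years < 1) abort("n_years must be >= 1")
  with_local_seed(seed, {
    z1 <- rnorm(n_years)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_years)
    tibble(
      year = seq_len(n_years),
      b_tox_g_m2 = exp(meanlog[1] + sdlog[1] * z1),
      b_bulk_g_m2 = exp(meanlog[2] + sdlog[2] * z2)
    )
  })
}
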