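#' Which constraints bind at the optimal diet?
#'
#' Solves the two-constraint diet model and reports the constraint regime:
#' `"neither"`, `"toxin"`, `"digestive"` or `"both"`. A constraint counts as
#' binding when its intake rate at the optimum lies within an absolute
#' tolerance (1e-6 mg s^-1) of its limit.
#'
#' @param prey a [prey_table()] with densities set.
#' @param forager a [forager_spec()].
#' @return A length-1 character regime label.
#' @export
classify_regime <- function(prey, forager) {
  solve_tdrm(prey, forager)$regime
}

#' Regime map over a biomass-density grid
#'
#' Classifies the constraint regime of a two-species system (toxic
#' thin-shelled vs. non-toxic bulky prey) at every combination of available
#' flesh biomass densities, reproducing the regime shading of a
#' density–density state plot.
#'
#' @param templates a two-row [prey_table()] (e.g. [prey_template()]); the
#'   first row is taken as the toxic species, the second as the bulky one
#'   (order only affects which axis is which).
#' @param forager a [forager_spec()].
#' @param b_tox,b_bulk numeric vectors of flesh biomass densities
#'   (g AFDM m^-2) for the toxic and bulky species.
#' @return A tibble with one row per grid point: `b_tox`, `b_bulk`,
#'   `regime`, plus the optimal `Y` and `model_used`.
#' @export
regime_map <- function(templates, forager,
                       b_tox = seq(0, 1, by = 0.1),
                       b_bulk = seq(0, 1, by = 0.1)) {
  templates <- validate_prey(templates)
  if (nrow(templates) != 2) abort("regime_map expects a two-row prey template table")
  grid <- tidyr::expand_grid(b_tox = b_tox, b_bulk = b_bulk)
  res <- purrr::pmap(grid, function(b_tox, b_bulk) {
    sol <- solve_tdrm(set_biomass(templates, c(b_tox, b_bulk)), forager)
    tibble(regime = sol$regime, Y = sol$rates$Y, model_used = sol$model_used)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Toxic-prey biomass density at which the toxin constraint is first met
#'
#' In the negligible-handling limit, full acceptance of the toxic prey gives
#' a toxin intake rate of `a * D * s = a * B` (with toxin expressed in
#' flesh-equivalent units so that `D * s` is the flesh biomass `B` per cm^2).
#' The toxin ceiling `q` is therefore reached at a flesh biomass of `q / a`,
#' converted to field units (1 mg cm^-2 = 10 g m^-2).
#'
#' With the red-knot defaults (q = 0.1 mg s^-1, a = 4 cm^2 s^-1) this is
#' 0.25 g AFDM m^-2: above such densities diet composition no longer depends
#' on the toxic prey's abundance.
#'
#' @param forager a [forager_spec()] (only `q_mg_s` is used).
#' @param a_cm2_s searching efficiency (cm^2 s^-1).
#' @return Biomass density in g AFDM m^-2.
#' @examples
#' threshold_toxin_biomass(forager_spec(), a_cm2_s = 4)  # 0.25
#' @export
threshold_toxin_biomass <- function(forager, a_cm2_s = 4) {
  if (a_cm2_s <= 0) abort("searching efficiency must be > 0")
  (forager$q_mg_s / a_cm2_s) * 10
}

#' Bulky-prey biomass density at which the digestive constraint is first met
#'
#' Numerically locates the smallest bulky-prey flesh biomass at which the
#' digestive constraint starts to bind in the two-constraint optimum, with
#' the toxic prey held at a fixed biomass (default: above the toxin
#' threshold, so the toxin constraint is already binding). Above this
#' density, diet composition becomes independent of the bulky prey's
#' density.
#'
#' @param templates two-row prey table: toxic species first, bulky second.
#' @param forager a [forager_spec()].
#' @param b_tox toxic-prey flesh biomass (g AFDM m^-2) held fixed.
#' @param upper search upper bound for the bulky biomass (g AFDM m^-2).
#' @param tol bisection tolerance on the biomass (g m^-2).
#' @return Biomass density in g AFDM m^-2 (NA if the constraint never binds
#'   below `upper`).
#' @export
threshold_bulk_biomass <- function(templates, forager, b_tox = 0.5,
                                   upper = 5, tol = 1e-4) {
  templates <- validate_prey(templates)
  if (nrow(templates) != 2) abort("expected a two-row prey template table")
  binds <- function(b) {
    sol <- solve_tdrm(set_biomass(templates, c(b_tox, b)), forager)
    "digestive" %in% sol$binding
  }
  if (!binds(upper)) return(NA_real_)
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (binds(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
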