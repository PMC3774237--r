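#' Functional response of the two-constraint forager
#'
#' Optimal long-term energy intake rate as a function of the bulky
#' (non-toxic) prey's available biomass density, at one or more fixed toxic
#' prey biomasses, both with the toxic prey present and with it removed from
#' the system. The with-toxic curve is never below the without-toxic curve
#' (extra prey cannot reduce the optimal rate), rises with bulky-prey
#' density, and plateaus once the digestive constraint binds.
#'
#' @param templates two-row prey table (toxic species first, bulky second),
#'   e.g. [prey_template()].
#' @param forager a [forager_spec()].
#' @param b_bulk numeric grid of bulky-prey flesh biomass (g AFDM m^-2).
#' @param b_tox numeric vector of toxic-prey flesh biomass levels
#'   (g AFDM m^-2).
#' @return A tibble: `b_bulk`, `b_tox`, `Y_with`, `Y_without` (mg s^-1),
#'   `regime` (at the with-toxic optimum).
#' @examples
#' fr <- functional_response_curve(prey_template(), forager_spec(),
#'                                 b_bulk = seq(0, 1, by = 0.25), b_tox = 0.5)
#' @export
functional_response_curve <- function(templates, forager,
                                      b_bulk = seq(0, 1.5, by = 0.05),
                                      b_tox = c(0.1, 0.5)) {
  templates <- validate_prey(templates)
  if (nrow(templates) != 2) abort("expected a two-row prey template table")
  if (!length(b_bulk)) abort("empty bulky-prey biomass grid")
  grid <- tidyr::expand_grid(b_tox = b_tox, b_bulk = b_bulk)
  res <- purrr::pmap(grid, function(b_tox, b_bulk) {
    both <- solve_tdrm(set_biomass(templates, c(b_tox, b_bulk)), forager)
    alone <- solve_tdrm(set_biomass(templates, c(0, b_bulk)), forager)
    tibble(Y_with = both$rates$Y, Y_without = alone$rates$Y,
           regime = both$regime)
  })
  dplyr::bind_cols(grid[, c("b_bulk", "b_tox")], dplyr::bind_rows(res))
}

#' Relative contribution of the toxic prey to the optimal diet
#'
#' Fraction of the optimal energy intake contributed by the toxic prey,
#' `Y_tox / (Y_tox + Y_bulk)`, over a grid of bulky-prey biomass densities.
#' Below the digestive plateau the fraction falls as bulky prey become more
#' available; above the toxin threshold it is invariant to further increases
#' in toxic-prey biomass (the toxic intake is pinned at the ceiling `q`).
#' At zero total intake the fraction is undefined and returned as `NA`.
#'
#' @inheritParams functional_response_curve
#' @return A tibble: `b_bulk`, `b_tox`, `frac_tox`, `Y_tox`, `Y_bulk`,
#'   `regime`.
#' @export
diet_fraction_curve <- function(templates, forager,
                                b_bulk = seq(0, 1.5, by = 0.05),
                                b_tox = c(0.1, 0.5)) {
  templates <- validate_prey(templates)
  if (nrow(templates) != 2) abort("expected a two-row prey template table")
  if (!length(b_bulk)) abort("empty bulky-prey biomass grid")
  grid <- tidyr::expand_grid(b_tox = b_tox, b_bulk = b_bulk)
  res <- purrr::pmap(grid, function(b_tox, b_bulk) {
    sol <- solve_tdrm(set_biomass(templates, c(b_tox, b_bulk)), forager)
    comp <- intake_components(sol$prey, sol$policy$p)
    y_tox <- comp$Y_i[1]; y_bulk <- comp$Y_i[2]
    tot <- y_tox + y_bulk
    tibble(frac_tox = if (tot > 0) y_tox / tot else NA_real_,
           Y_tox = y_tox, Y_bulk = y_bulk, regime = sol$regime)
  })
  dplyr::bind_cols(grid[, c("b_bulk", "b_tox")], dplyr::bind_rows(res))
}
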