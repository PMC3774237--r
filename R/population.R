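#' Two-stage matrix population projection
#'
#' Projects juvenile and adult counts forward one year at a time with the
#' stage-structured matrix
#' \deqn{M_t = \begin{pmatrix} 0 & f \\ \Phi_{juv} & \Phi_{ad} \end{pmatrix},}
#' i.e. adults alive at `t` produce `f` juveniles each, juveniles that
#' survive mature into adults after one year, and surviving adults remain
#' adults. With constant rates the realized growth factor converges to the
#' dominant eigenvalue
#' \eqn{\lambda = (\Phi_{ad} + \sqrt{\Phi_{ad}^2 + 4 f \Phi_{juv}})/2}.
#'
#' @param rates tibble with one row per projected year: `phi_juv`, `phi_ad`
#'   in `[0, 1]` and fecundity `f >= 0` (young per adult per year).
#' @param initial length-2 numeric `c(n_juv, n_ad)` at the start year.
#' @param start_year calendar year of the initial state.
#' @return A tibble `year`, `n_juv`, `n_ad`, `n_total` with
#'   `nrow(rates) + 1` rows (initial state included).
#' @examples
#' rates <- tibble::tibble(phi_juv = 0.8, phi_ad = 0.85, f = 0.14)[rep(1, 8), ]
#' project_population(rates, initial = c(3000, 19859), start_year = 2002)
#' @export
project_population <- function(rates, initial, start_year = 1L) {
  check_cols(rates, c("phi_juv", "phi_ad", "f"), "vital rates")
  if (nrow(rates) < 1) abort("need at least one year of vital rates")
  if (anyNA(rates[c("phi_juv", "phi_ad", "f")])) abort("vital rates contain NA")
  if (any(rates$phi_juv < 0 | rates$phi_juv > 1) ||
      any(rates$phi_ad < 0 | rates$phi_ad > 1)) {
    abort("survival probabilities must lie in [0, 1]")
  }
  if (any(rates$f < 0)) abort("fecundity must be >= 0")
  if (length(initial) != 2 || any(initial < 0)) {
    abort("initial state must be c(n_juv, n_ad) with non-negative counts")
  }
  state <- as.numeric(initial)
  out <- matrix(NA_real_, nrow = nrow(rates) + 1, ncol = 2)
  out[1, ] <- state
  for (t in seq_len(nrow(rates))) {
    M <- rbind(c(0, rates$f[t]),
               c(rates$phi_juv[t], rates$phi_ad[t]))
    state <- as.numeric(M %*% state)
    out[t + 1, ] <- state
  }
  tibble(year = start_year + 0:nrow(rates),
         n_juv = out[, 1], n_ad = out[, 2],
         n_total = out[, 1] + out[, 2])
}

#' Asymptotic growth factor of the two-stage model
#'
#' Dominant eigenvalue of the projection matrix, in closed form.
#'
#' @param phi_juv,phi_ad annual survival probabilities.
#' @param f adult fecundity (yr^-1).
#' @return The growth factor lambda.
#' @export
growth_factor <- function(phi_juv, phi_ad, f = 0.14) {
  (phi_ad + sqrt(phi_ad^2 + 4 * f * phi_juv)) / 2
}

#' Survival as a logit-linear function of intake rate
#'
#' Maps a predicted long-term energy intake rate `Y` to an annual apparent
#' survival probability through a logit-linear link
#' `Phi = plogis(b0 + b1 * Y)`. The link stands in for a fitted
#' capture-resighting covariate model; its coefficients are user-supplied or
#' estimated with [fit_survival_link()].
#'
#' @param link a list or `survival_link` with elements `b0`, `b1`.
#' @param y intake rate(s), mg flesh s^-1.
#' @return Survival probabilities in (0, 1).
#' @export
survival_from_intake <- function(link, y) {
  stopifnot(is.finite(link$b0), is.finite(link$b1), all(is.finite(y)))
  plogis(link$b0 + link$b1 * y)
}

#' Fit a logit-linear intake-to-survival link
#'
#' Least squares of `qlogis(phi)` on `y`. This is a deliberately simple
#' stand-in for capture-recapture machinery: it reproduces the structure
#' "survival correlates positively with predicted intake rate" from a small
#' table of (intake, survival) pairs.
#'
#' @param data tibble with columns `y` (intake rate, mg s^-1) and `phi`
#'   (annual survival in (0, 1)).
#' @return A `survival_link` list with `b0`, `b1` and the underlying `lm`.
#' @export
fit_survival_link <- function(data) {
  check_cols(data, c("y", "phi"), "survival table")
  if (nrow(data) < 2) abort("need at least 2 (y, phi) pairs")
  if (any(data$phi <= 0 | data$phi >= 1)) abort("phi must lie strictly in (0, 1)")
  fit <- lm(qlogis(phi) ~ y, data = data)
  structure(list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]), fit = fit),
            class = "survival_link")
}

#' @export
print.survival_link <- function(x, ...) {
  cat("<survival_link> logit(phi) =", signif(x$b0, 4), "+", signif(x$b1, 4), "* Y\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.survival_link <- function(x, ...) {
  tibble(term = c("b0", "b1"), estimate = c(x$b0, x$b1))
}

#' Project the population under prey-removal scenarios
#'
#' For each year: build the prey table from annual parameters (optionally
#' removing the toxic or the bulky species), compute the optimal intake rate
#' with [solve_tdrm()], convert it to adult survival through the link
#' (juvenile survival offset on the logit scale), and advance the population
#' one step. The three scenarios bracket how much the predator depends on
#' each prey: removing the bulky non-toxic prey caps intake near the toxin
#' ceiling and gives the steepest decline; keeping both gives the
#' shallowest.
#'
#' @param annual_params tibble from [annual_prey_params()] (columns `year`,
#'   `species`, `d_m2`, `e_mg`, `k_mg`, `s_mg`); years are projected in
#'   order.
#' @param forager a [forager_spec()].
#' @param link a `survival_link` (or list with `b0`, `b1`).
#' @param initial length-2 `c(n_juv, n_ad)` in the first year.
#' @param scenario `"both"`, `"no_toxic"` (toxic species removed) or
#'   `"no_bulky"` (all non-toxic species removed).
#' @param f adult fecundity (default 0.14 yr^-1).
#' @param juv_logit_offset additive offset on the logit of adult survival
#'   giving juvenile survival (default 0, i.e. equal).
#' @param h_s,a_cm2_s handling time and searching efficiency assumed for all
#'   species (per-item masses vary annually, these do not).
#' @return A trajectory tibble `year`, `n_juv`, `n_ad`, `n_total`, `Y`,
#'   `phi_ad`, `scenario` (first row: initial state, `NA` rates).
#' @export
scenario_project <- function(annual_params, forager, link, initial,
                             scenario = c("both", "no_toxic", "no_bulky"),
                             f = 0.14, juv_logit_offset = 0,
                             h_s = 1, a_cm2_s = 4) {
  scenario <- match.arg(scenario)
  check_cols(annual_params, c("year", "species", "d_m2", "e_mg", "k_mg", "s_mg"),
             "annual prey parameters")
  years <- sort(unique(annual_params$year))
  yearly <- purrr::map_dbl(years, function(yr) {
    tab <- filter(annual_params, .data$year == yr, .data$d_m2 > 0,
                  !is.na(.data$e_mg))
    tab <- switch(scenario,
      both = tab,
      no_toxic = filter(tab, .data$s_mg == 0),
      no_bulky = filter(tab, .data$s_mg > 0)
    )
    if (nrow(tab) == 0) return(0)
    prey <- prey_table(tab$species, e_mg = tab$e_mg, k_mg = tab$k_mg,
                       s_mg = tab$s_mg, h_s = h_s, a_cm2_s = a_cm2_s,
                       d_m2 = tab$d_m2)
    solve_tdrm(prey, forager)$rates$Y
  })
  phi_ad <- survival_from_intake(link, yearly)
  phi_juv <- plogis(qlogis(phi_ad) + juv_logit_offset)
  rates <- tibble(phi_juv = phi_juv, phi_ad = phi_ad, f = f)
  traj <- project_population(rates, initial, start_year = years[1])
  traj$Y <- c(NA_real_, yearly)
  traj$phi_ad <- c(NA_real_, phi_ad)
  traj$scenario <- scenario
  traj
}

#' Percent change between two counts
#'
#' `100 * (n_end - n_start) / n_start`. Round to integer percent for
#' display.
#'
#' @param n_start,n_end counts; `n_start` must be positive.
#' @return Percent change (not rounded).
#' @examples
#' percent_change(22859, 12465)  # about -45
#' @export
percent_change <- function(n_start, n_end) {
  if (any(n_start <= 0)) abort("n_start must be > 0")
  100 * (n_end - n_start) / n_start
}
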