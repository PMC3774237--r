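#' Long-term intake rates under a diet policy
#'
#' The multi-species Holling disc equation. Given acceptance probabilities
#' `p` (one per prey type), the long-term energy intake rate is
#'
#' \deqn{Y = \frac{\sum_i p_i a_i D_i e_i}{1 + \sum_i p_i a_i D_i h_i},}
#'
#' and the ballast intake rate `X` and toxin intake rate `Z` are the same
#' expression with the shell mass \eqn{k_i} and toxin content \eqn{s_i} in
#' place of \eqn{e_i}. All three share one denominator: time is split between
#' searching and handling regardless of which currency is being tallied.
#'
#' @param prey a [prey_table()].
#' @param p acceptance probabilities in `[0, 1]`, one per prey row.
#' @return A one-row tibble with columns `Y`, `X`, `Z` (mg s^-1).
#' @examples
#' prey <- prey_table("clam", e_mg = 1, k_mg = 2, s_mg = 0, d_m2 = 10)
#' intake_rates(prey, p = 1)
#' @export
intake_rates <- function(prey, p) {
  prey <- validate_prey(prey)
  p <- check_policy(p, nrow(prey))
  enc <- p * prey$a_cm2_s * prey$d_cm2     # accepted encounter rate, items s^-1
  den <- 1 + sum(enc * prey$h_s)
  tibble(Y = sum(enc * prey$e_mg) / den,
         X = sum(enc * prey$k_mg) / den,
         Z = sum(enc * prey$s_mg) / den)
}

#' Per-prey energy intake components
#'
#' Splits the total energy intake rate `Y` into the contribution of each prey
#' type (same shared denominator as [intake_rates()]).
#'
#' @inheritParams intake_rates
#' @return A tibble with one row per prey: `name`, `Y_i`.
#' @export
intake_components <- function(prey, p) {
  prey <- validate_prey(prey)
  p <- check_policy(p, nrow(prey))
  enc <- p * prey$a_cm2_s * prey$d_cm2
  den <- 1 + sum(enc * prey$h_s)
  tibble(name = prey$name, Y_i = enc * prey$e_mg / den)
}

check_policy <- function(p, n) {
  p <- as.numeric(p)
  if (length(p) != n) {
    abort(paste0("policy has length ", length(p), " but prey table has ", n, " rows"))
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("acceptance probabilities must lie in [0, 1]")
  }
  p
}
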