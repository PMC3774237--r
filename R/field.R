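#' Default accessibility / ingestibility rules
#'
#' Availability of a benthic prey item to a probing shorebird has two parts:
#' it must be *accessible* (lying in the top 0–4 cm sediment layer the bill
#' can reach) and *ingestible* (shell length below the gape limit). The
#' default rules encode a lucinid/venerid pair: all size classes of
#' `"loripes"` are ingestible, `"dosinia"` only strictly below 13.2 mm.
#'
#' @return A tibble with columns `species`, `max_length_mm` (exclusive upper
#'   bound; `Inf` = all sizes ingestible).
#' @export
ingestibility_rules <- function() {
  tibble(species = c("loripes", "dosinia"), max_length_mm = c(Inf, 13.2))
}

#' Filter benthos records to items available to the forager
#'
#' Keeps only top-stratum (0–4 cm) records, and applies the species-specific
#' ingestibility rule: records of a species with `max_length_mm = Inf` are
#' all kept; otherwise only `length_mm` strictly below the bound. Species
#' absent from `rules` are kept in full, with a warning asking for an
#' explicit rule (other systems have other gape limits).
#'
#' @param records tibble with at least `species`, `stratum`
#'   (`"top_0_4cm"` / `"bottom_4_16cm"`), `length_mm`.
#' @param rules tibble like [ingestibility_rules()].
#' @return The filtered records (same columns).
#' @export
filter_available <- function(records, rules = ingestibility_rules()) {
  check_cols(records, c("species", "stratum", "length_mm"), "benthos records")
  strata <- c("top_0_4cm", "bottom_4_16cm")
  bad <- !records$stratum %in% strata
  if (any(bad)) {
    abort(paste0("unknown stratum in rows ", paste(head(which(bad), 5), collapse = ", "),
                 "; expected one of: ", paste(strata, collapse = ", ")))
  }
  if (any(records$length_mm <= 0, na.rm = TRUE)) abort("shell lengths must be > 0")
  unknown <- setdiff(unique(records$species), rules$species)
  if (length(unknown)) {
    warn(paste0("no ingestibility rule for species: ",
                paste(unknown, collapse = ", "), "; keeping all size classes"))
    rules <- bind_rows(rules, tibble(species = unknown, max_length_mm = Inf))
  }
  out <- left_join(records, rules, by = "species")
  out <- filter(out, .data$stratum == "top_0_4cm",
                .data$length_mm < .data$max_length_mm)
  select(out, -"max_length_mm")
}

#' Numerical density from sediment-core counts
#'
#' Converts an item count over a number of sediment cores to items per m^2.
#' The default core diameter of 15 cm gives a core area of
#' `pi * 7.5^2` cm^2 ≈ 0.01767 m^2.
#'
#' @param count item count (vectorized).
#' @param n_cores number of cores the count came from.
#' @param core_diameter_cm core diameter (cm).
#' @return Density in items m^-2.
#' @examples
#' core_density(1, 1)   # about 56.59 items per m^2
#' @export
core_density <- function(count, n_cores, core_diameter_cm = 15) {
  if (any(n_cores < 1)) abort("n_cores must be >= 1")
  if (any(count < 0)) abort("counts must be >= 0")
  area_m2 <- pi * (core_diameter_cm / 2)^2 * 1e-4
  count / (n_cores * area_m2)
}

#' Fit a length–mass allometry
#'
#' Least-squares power law `mass = alpha * length^beta`, fitted on the
#' log–log scale. Used to predict the flesh or shell mass of items that were
#' measured for length but not weighed.
#'
#' @param lengths,masses positive numeric vectors (incomplete pairs are
#'   dropped); at least 3 complete pairs are required.
#' @return An object of class `allometry` with `alpha`, `beta`, `sigma`
#'   (residual SD of log mass), `n`, and the underlying `lm` fit.
#' @export
fit_allometry <- function(lengths, masses) {
  keep <- complete.cases(lengths, masses)
  lengths <- lengths[keep]; masses <- masses[keep]
  if (length(lengths) < 3) {
    abort("allometry fit needs at least 3 complete length-mass pairs")
  }
  if (any(lengths <= 0) || any(masses <= 0)) {
    abort("allometry fit needs strictly positive lengths and masses")
  }
  fit <- lm(log(masses) ~ log(lengths))
  # suppressWarnings: exact power-law data trip lm's perfect-fit warning
  s <- suppressWarnings(summary(fit))
  structure(
    list(alpha = unname(exp(coef(fit)[1])), beta = unname(coef(fit)[2]),
         sigma = s$sigma, n = length(lengths), fit = fit),
    class = "allometry"
  )
}

#' @export
predict.allometry <- function(object, lengths, ...) {
  object$alpha * lengths^object$beta
}

#' @export
print.allometry <- function(x, ...) {
  cat("<allometry> mass =", signif(x$alpha, 4), "* length^", signif(x$beta, 4),
      " (n =", x$n, ")\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.allometry <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("alpha", "beta"),
         estimate = c(x$alpha, x$beta),
         std.error = c(x$alpha * s[1, 2], s[2, 2]))
}

#' @exportS3Method generics::glance
glance.allometry <- function(x, ...) {
  tibble(n = x$n, sigma = x$sigma,
         r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' Fill missing item masses from per-species allometries
#'
#' Fits a length–mass power law per species and mass column (flesh
#' `afdm_mg`, shell `dm_mg`) from the weighed items, and predicts masses for
#' records where they are missing. Observed masses are never overwritten.
#' A species with missing masses but fewer than 3 weighed items is an error.
#'
#' @param records tibble with `species`, `length_mm`, `afdm_mg`, `dm_mg`.
#' @return `records` with `afdm_mg` and `dm_mg` completed.
#' @export
fill_masses <- function(records) {
  check_cols(records, c("species", "length_mm", "afdm_mg", "dm_mg"), "benthos records")
  fill_col <- function(df, col) {
    miss <- is.na(df[[col]])
    if (!any(miss)) return(df)
    fit <- fit_allometry(df$length_mm[!miss], df[[col]][!miss])
    df[[col]][miss] <- predict(fit, df$length_mm[miss])
    df
  }
  records |>
    group_by(.data$species) |>
    dplyr::group_modify(function(df, key) fill_col(fill_col(df, "afdm_mg"), "dm_mg")) |>
    ungroup()
}

#' Correct stratified habitat densities for cover and availability
#'
#' Combines densities sampled separately in vegetated (seagrass) and bare
#' habitat into a landscape density using the vegetated cover fraction, then
#' multiplies by the species' availability fraction (the proportion of
#' individuals both accessible and ingestible):
#' `(cover * d_seagrass + (1 - cover) * d_bare) * availability`.
#'
#' @param d_seagrass,d_bare densities in the two habitats (any shared unit).
#' @param cover vegetated cover fraction in `[0, 1]` (default 0.80).
#' @param availability availability fraction in `[0, 1]`.
#' @return Available density, same unit as the inputs.
#' @examples
#' stratified_correction(200, 0, cover = 0.8, availability = 0.70)  # 112
#' @export
stratified_correction <- function(d_seagrass, d_bare, cover = 0.80,
                                  availability = 1) {
  if (any(d_seagrass < 0) || any(d_bare < 0)) abort("densities must be >= 0")
  if (any(cover < 0 | cover > 1)) abort("cover must be in [0, 1]")
  if (any(availability < 0 | availability > 1)) abort("availability must be in [0, 1]")
  (cover * d_seagrass + (1 - cover) * d_bare) * availability
}

#' Annual per-species model parameters from benthos surveys
#'
#' The survey-to-model bridge: filters records to available items, fills
#' missing masses allometrically, and per year and species computes the
#' available numerical density `d_m2` (via [core_density()]) and the
#' per-item mean flesh (`e_mg`) and shell (`k_mg`) masses, pooled over
#' stations. Toxin content `s_mg` is set equal to `e_mg` for the species
#' named in `toxic_species` and 0 otherwise (the toxin ceiling is expressed
#' as a toxic-flesh intake rate). Year-species combinations with no
#' available items get `d_m2 = 0` and `NA` masses.
#'
#' @param records tibble with `year`, `station`, `species`, `stratum`,
#'   `length_mm`, `afdm_mg`, `dm_mg`.
#' @param cores_per_year tibble `year`, `n_cores` (cores taken that year).
#' @param rules ingestibility rules, see [filter_available()].
#' @param toxic_species character vector of species whose flesh counts as
#'   toxin.
#' @return A tibble: `year`, `species`, `d_m2`, `e_mg`, `k_mg`, `s_mg`.
#' @export
annual_prey_params <- function(records, cores_per_year,
                               rules = ingestibility_rules(),
                               toxic_species = "loripes") {
  check_cols(records, c("year", "species", "stratum", "length_mm",
                        "afdm_mg", "dm_mg"), "benthos records")
  check_cols(cores_per_year, c("year", "n_cores"), "cores_per_year")
  avail <- filter_available(records, rules)
  species_all <- unique(records$species)
  if (nrow(avail)) avail <- fill_masses(avail)
  counts <- avail |>
    group_by(.data$year, .data$species) |>
    summarise(n_items = dplyr::n(),
              e_mg = mean(.data$afdm_mg), k_mg = mean(.data$dm_mg),
              .groups = "drop")
  out <- tidyr::expand_grid(year = cores_per_year$year, species = species_all) |>
    left_join(counts, by = c("year", "species")) |>
    left_join(cores_per_year, by = "year") |>
    mutate(n_items = dplyr::coalesce(.data$n_items, 0L),
           d_m2 = core_density(.data$n_items, .data$n_cores),
           s_mg = ifelse(.data$species %in% toxic_species & !is.na(.data$e_mg),
                         .data$e_mg, 0)) |>
    select("year", "species", "d_m2", "e_mg", "k_mg", "s_mg")
  out
}

#' Total ingested shell mass from sieve-retained fragments
#'
#' Shell fragments recovered from droppings undersample ingested shell: a
#' fixed fraction passes the sieve. With the default 35% loss, ingested
#' shell mass is `retained / 0.65`.
#'
#' @param retained_dm_mg retained shell dry mass (mg), vectorized.
#' @param retention fraction of shell retained on the sieve (default 0.65).
#' @return Ingested shell dry mass (mg).
#' @examples
#' shell_mass_ingested(6.5)  # 10
#' @export
shell_mass_ingested <- function(retained_dm_mg, retention = 0.65) {
  if (any(retained_dm_mg < 0)) abort("retained shell mass must be >= 0")
  if (any(retention <= 0 | retention > 1)) abort("retention must be in (0, 1]")
  retained_dm_mg / retention
}

#' Reconstruct per-sample diet composition in flesh terms
#'
#' Dropping analysis yields per-species ingested shell mass; because
#' flesh-to-shell ratios are size dependent, a species' *flesh* contribution
#' is its ingested shell mass times a supplied flesh/shell ratio
#' (typically from the allometry predictors at the reconstructed ingested
#' sizes), normalized across species within each sample.
#'
#' @param samples tibble with `sample`, `year`, `species`, `retained_dm_mg`.
#' @param ratios tibble with `species`, `flesh_shell_ratio`.
#' @param retention sieve retention fraction, see [shell_mass_ingested()].
#' @return A tibble `sample`, `year`, `species`, `flesh_mg`, `fraction`
#'   (fractions sum to 1 within a sample; `NA` for all-zero samples).
#' @export
diet_fractions <- function(samples, ratios, retention = 0.65) {
  check_cols(samples, c("sample", "year", "species", "retained_dm_mg"), "diet samples")
  check_cols(ratios, c("species", "flesh_shell_ratio"), "ratios")
  missing_sp <- setdiff(unique(samples$species), ratios$species)
  if (length(missing_sp)) {
    abort(paste0("no flesh/shell ratio for species: ", paste(missing_sp, collapse = ", ")))
  }
  samples |>
    left_join(ratios, by = "species") |>
    mutate(flesh_mg = shell_mass_ingested(.data$retained_dm_mg, retention) *
             .data$flesh_shell_ratio) |>
    group_by(.data$sample, .data$year) |>
    mutate(fraction = if (sum(.data$flesh_mg) > 0) {
      .data$flesh_mg / sum(.data$flesh_mg)
    } else NA_real_) |>
    ungroup() |>
    select("sample", "year", "species", "flesh_mg", "fraction")
}

#' Annual mean of compositional fractions on the logit scale
#'
#' Diet fractions are compositional; annual averages are taken as the
#' inverse-logit of the mean logit. Fractions at the 0/1 boundary are nudged
#' inward by `eps` before transforming (the logit is undefined there).
#'
#' @param fractions numeric vector of fractions in `[0, 1]`.
#' @param eps boundary nudge (default 0.01).
#' @return The back-transformed annual mean (scalar); `NA` for empty input.
#' @examples
#' annual_logit_mean(c(0.2, 0.8))  # 0.5 by symmetry of logits
#' @export
annual_logit_mean <- function(fractions, eps = 0.01) {
  fractions <- fractions[!is.na(fractions)]
  if (!length(fractions)) return(NA_real_)
  if (any(fractions < 0 | fractions > 1)) abort("fractions must lie in [0, 1]")
  f <- pmin(pmax(fractions, eps), 1 - eps)
  plogis(mean(qlogis(f)))
}

#' Paired comparison of observed vs. predicted annual diet fractions
#'
#' Paired t test on the logit scale of annual diet fractions, with the sign
#' convention observed − predicted. Zero-variance differences are flagged as
#' degenerate: the t statistic is 0 when the vectors are identical and
#' signed infinity for a constant non-zero offset.
#'
#' @param observed,predicted numeric vectors of paired annual fractions in
#'   (0, 1) (boundary values nudged by `eps` as in [annual_logit_mean()]).
#' @param eps boundary nudge.
#' @return A one-row tibble: `estimate` (mean logit difference),
#'   `statistic`, `df`, `p.value`, `degenerate`.
#' @export
compare_diets <- function(observed, predicted, eps = 0.01) {
  if (length(observed) != length(predicted)) abort("paired vectors differ in length")
  n <- length(observed)
  if (n < 2) abort("need at least 2 paired years")
  sq <- function(x) qlogis(pmin(pmax(x, eps), 1 - eps))
  d <- sq(observed) - sq(predicted)
  m <- mean(d); s <- sd(d)
  if (s <= 1e-10 * max(1, abs(m))) {  # numerically constant differences
    stat <- if (m == 0) 0 else sign(m) * Inf
    return(tibble(estimate = m, statistic = stat, df = n - 1,
                  p.value = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  stat <- m / (s / sqrt(n))
  tibble(estimate = m, statistic = stat, df = n - 1,
         p.value = 2 * pt(-abs(stat), n - 1), degenerate = FALSE)
}

check_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort(paste0(what, " missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}
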