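#' Build a prey-type table
#'
#' A prey table holds one row per prey type with the per-item quantities the
#' diet models need, in canonical internal units (mg, cm, s):
#'
#' * `e_mg` — flesh energy content per item (mg ash-free dry mass of flesh),
#' * `k_mg` — indigestible ballast (shell dry mass) per item (mg),
#' * `s_mg` — toxin content per item, expressed in flesh-equivalent mg so that
#'   the toxin ceiling is an intake rate of toxic flesh (set `s_mg = e_mg` for
#'   a toxic species, 0 for a non-toxic one),
#' * `h_s` — handling time per item (s),
#' * `a_cm2_s` — searching efficiency (cm^2 s^-1),
#' * `d_cm2` — numerical density (items cm^-2; 1 item m^-2 = 1e-4 cm^-2).
#'
#' @param name character vector of prey-type names.
#' @param e_mg,k_mg,s_mg,h_s,a_cm2_s numeric vectors, recycled to length
#'   `length(name)`.
#' @param d_cm2 numerical density in items cm^-2. Give either this or
#'   `d_m2`.
#' @param d_m2 numerical density in items m^-2 (converted internally).
#' @return A tibble with class `tdrm_prey`.
#' @examples
#' prey_table(c("loripes", "dosinia"),
#'            e_mg = c(3, 5), k_mg = c(20, 85), s_mg = c(3, 0),
#'            d_m2 = c(500, 100))
#' @export
prey_table <- function(name, e_mg, k_mg, s_mg = 0, h_s = 1, a_cm2_s = 4,
                       d_cm2 = NULL, d_m2 = NULL) {
  if (is.null(d_cm2) && is.null(d_m2)) {
    abort("supply prey density as `d_cm2` or `d_m2`")
  }
  if (is.null(d_cm2)) d_cm2 <- d_m2 * 1e-4
  prey <- tibble(
    name = as.character(name),
    e_mg = as.numeric(e_mg), k_mg = as.numeric(k_mg),
    s_mg = as.numeric(s_mg),
    h_s = as.numeric(h_s), a_cm2_s = as.numeric(a_cm2_s),
    d_cm2 = as.numeric(d_cm2)
  )
  validate_prey(prey)
}

#' Validate a prey table
#'
#' Checks the type invariants (non-negative contents and densities, strictly
#' positive handling times and searching efficiencies). A toxin content
#' exceeding the flesh content is flagged with a warning, not an error, since
#' toxin is only *conventionally* expressed in flesh-equivalent units.
#'
#' @param prey a data frame with the `prey_table()` columns.
#' @return The validated table, with class `tdrm_prey`.
#' @export
validate_prey <- function(prey) {
  needed <- c("name", "e_mg", "k_mg", "s_mg", "h_s", "a_cm2_s", "d_cm2")
  missing_cols <- setdiff(needed, names(prey))
  if (length(missing_cols)) {
    abort(paste0("prey table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(prey) == 0) abort("prey table has no rows")
  bad <- function(test, what) {
    if (any(test, na.rm = TRUE) || anyNA(test)) {
      abort(paste0("prey table rows ", paste(which(test | is.na(test)), collapse = ", "),
                   ": ", what))
    }
  }
  bad(prey$e_mg < 0, "e_mg must be >= 0")
  bad(prey$k_mg < 0, "k_mg must be >= 0")
  bad(prey$s_mg < 0, "s_mg must be >= 0")
  bad(prey$h_s <= 0, "h_s must be > 0")
  bad(prey$a_cm2_s <= 0, "a_cm2_s must be > 0")
  bad(prey$d_cm2 < 0, "d_cm2 must be >= 0")
  if (any(prey$s_mg > prey$e_mg + 1e-12)) {
    warn("some prey have s_mg > e_mg; toxin content exceeds flesh-equivalent mass")
  }
  prey <- as_tibble(prey)
  class(prey) <- unique(c("tdrm_prey", class(prey)))
  prey
}

#' Forager constraint specification
#'
#' @param c_mg_s digestive constraint: maximum sustainable ballast (shell dry
#'   mass) processing rate, mg s^-1. Default 5 (a 10 g gizzard).
#' @param q_mg_s toxin constraint: maximum tolerable intake rate of toxic
#'   flesh, mg s^-1. Default 0.1.
#' @param y_req_mg_s subsistence energy intake rate, mg flesh s^-1.
#'   Default 0.2.
#' @param gizzard_g optional gizzard mass (g), informational only.
#' @return A list with class `forager_spec`.
#' @examples
#' forager_spec()                    # red-knot-like defaults
#' forager_spec(c_mg_s = 10, q_mg_s = 0.5)
#' @export
forager_spec <- function(c_mg_s = 5, q_mg_s = 0.1, y_req_mg_s = 0.2,
                         gizzard_g = NULL) {
  stopifnot(is.numeric(c_mg_s), is.numeric(q_mg_s), is.numeric(y_req_mg_s))
  if (c_mg_s <= 0) abort("digestive constraint c_mg_s must be > 0")
  if (q_mg_s <= 0) abort("toxin constraint q_mg_s must be > 0")
  if (y_req_mg_s < 0) abort("subsistence rate y_req_mg_s must be >= 0")
  structure(
    list(c_mg_s = c_mg_s, q_mg_s = q_mg_s, y_req_mg_s = y_req_mg_s,
         gizzard_g = gizzard_g),
    class = "forager_spec"
  )
}

#' @export
print.forager_spec <- function(x, ...) {
  cat("<forager_spec>\n")
  cat("  digestive constraint c =", x$c_mg_s, "mg shell DM / s\n")
  cat("  toxin constraint     q =", x$q_mg_s, "mg toxic flesh / s\n")
  cat("  subsistence rate         ", x$y_req_mg_s, "mg flesh / s\n")
  invisible(x)
}

#' Preset prey templates
#'
#' Two-species templates mirroring the thin-shelled toxic lucinid vs.
#' thick-shelled non-toxic venerid contrast: `"loripes_like"` is easily
#' digested (high e/k) but fully toxic (s = e); `"dosinia_like"` is bulky
#' (low e/k) and non-toxic (s = 0). Handling time 1 s and searching
#' efficiency 4 cm^2 s^-1 for both. Densities are left at 0; set them from
#' field estimates or via [set_biomass()].
#'
#' @param which character vector of template names.
#' @return A `tdrm_prey` tibble with `d_cm2 = 0`.
#' @examples
#' prey_template()
#' prey_template("loripes_like")
#' @export
prey_template <- function(which = c("loripes_like", "dosinia_like")) {
  all <- tibble(
    template = c("loripes_like", "dosinia_like"),
    name = c("loripes", "dosinia"),
    e_mg = c(3, 5),
    k_mg = c(20, 85),
    s_mg = c(3, 0),
    h_s = c(1, 1),
    a_cm2_s = c(4, 4),
    d_cm2 = c(0, 0)
  )
  which <- match.arg(which, all$template, several.ok = TRUE)
  out <- all[match(which, all$template), ]
  validate_prey(select(out, -"template"))
}

#' Set prey densities from flesh biomass densities
#'
#' Converts available flesh biomass (g ash-free dry mass m^-2, the unit field
#' surveys report) to numerical density via the per-item flesh content:
#' 1 g m^-2 = 0.1 mg cm^-2, and D = biomass / e.
#'
#' @param prey a `tdrm_prey` table.
#' @param biomass_g_m2 numeric vector of flesh biomass densities, one per row.
#' @return The prey table with `d_cm2` replaced.
#' @export
set_biomass <- function(prey, biomass_g_m2) {
  prey <- validate_prey(prey)
  stopifnot(length(biomass_g_m2) == nrow(prey))
  if (any(biomass_g_m2 < 0)) abort("biomass must be >= 0")
  prey$d_cm2 <- ifelse(prey$e_mg > 0, biomass_g_m2 * 0.1 / prey$e_mg, 0)
  validate_prey(prey)
}

#' Flesh biomass density of each prey row
#'
#' @param prey a `tdrm_prey` table.
#' @return numeric vector of g AFDM m^-2 (inverse of [set_biomass()]).
#' @export
prey_biomass <- function(prey) {
  prey <- validate_prey(prey)
  prey$d_cm2 * prey$e_mg * 10
}
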