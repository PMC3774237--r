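#' Read a prey-type table from CSV
#'
#' Expected header: `name,e_mg,k_mg,s_mg,h_s,a_cm2_s,density_per_m2`.
#' Densities are converted to the canonical items cm^-2 on read
#' (1 item m^-2 = 1e-4 cm^-2). Validation failures name the offending rows.
#'
#' @param path path to a CSV file.
#' @return A `tdrm_prey` tibble.
#' @export
read_prey_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("name", "e_mg", "k_mg", "s_mg", "h_s", "a_cm2_s", "density_per_m2")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0("prey CSV ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- setdiff(needed, "name")
  for (cc in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(vals) & !is.na(df[[cc]]) | is.na(df[[cc]]))
    if (length(bad)) {
      abort(paste0("prey CSV ", path, ": non-numeric or missing `", cc,
                   "` in row(s) ", paste(bad, collapse = ", ")))
    }
    df[[cc]] <- vals
  }
  prey_table(df$name, e_mg = df$e_mg, k_mg = df$k_mg, s_mg = df$s_mg,
             h_s = df$h_s, a_cm2_s = df$a_cm2_s, d_m2 = df$density_per_m2)
}

#' Write a prey-type table to CSV
#'
#' Inverse of [read_prey_table()] (densities written back as items m^-2);
#' write-then-read is the identity.
#'
#' @param prey a `tdrm_prey` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prey_table <- function(prey, path) {
  prey <- validate_prey(prey)
  out <- tibble(name = prey$name, e_mg = prey$e_mg, k_mg = prey$k_mg,
                s_mg = prey$s_mg, h_s = prey$h_s, a_cm2_s = prey$a_cm2_s,
                density_per_m2 = prey$d_cm2 * 1e4)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a forager spec from JSON
#'
#' Expected fields: `c_mg_s`, `q_mg_s`, `y_req_mg_s` (and optionally
#' `gizzard_g`).
#'
#' @param path path to a JSON file.
#' @return A [forager_spec()].
#' @export
read_forager_spec <- function(path) {
  js <- jsonlite::fromJSON(path)
  needed <- c("c_mg_s", "q_mg_s", "y_req_mg_s")
  missing_fields <- setdiff(needed, names(js))
  if (length(missing_fields)) {
    abort(paste0("forager JSON ", path, " is missing field(s): ",
                 paste(missing_fields, collapse = ", ")))
  }
  forager_spec(c_mg_s = js$c_mg_s, q_mg_s = js$q_mg_s,
               y_req_mg_s = js$y_req_mg_s,
               gizzard_g = js$gizzard_g)
}

#' Write a forager spec to JSON
#'
#' @param forager a [forager_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forager_spec <- function(forager, path) {
  stopifnot(inherits(forager, "forager_spec"))
  jsonlite::write_json(forager[!vapply(forager, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
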