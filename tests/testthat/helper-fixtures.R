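# Shared fixtures for the diet-model tests.

# A forager with constraints far beyond anything achievable: the CM optimum
# is always feasible.
vacuous_forager <- function() forager_spec(c_mg_s = 1e9, q_mg_s = 1e9)

knot_forager <- function() forager_spec()  # c = 5, q = 0.1, y_req = 0.2

# Two-prey system mirroring the study contrast, with densities set from
# flesh biomass in g AFDM m^-2.
study_prey <- function(b_tox = 0.5, b_bulk = 0.3) {
  set_biomass(prey_template(), c(b_tox, b_bulk))
}

# Tiny benthos-record table with known per-item means.
toy_records <- function() {
  tibble::tibble(
    year = 1L,
    station = c(1L, 1L, 2L, 2L, 2L),
    species = c("loripes", "loripes", "loripes", "dosinia", "dosinia"),
    stratum = "top_0_4cm",
    length_mm = c(7, 8, 9, 10, 12),
    afdm_mg = c(2, 3, 4, 4, 6),
    dm_mg = c(15, 20, 25, 70, 100)
  )
}
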