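test_that("surveys are reproducible and empty at zero density", {
  sp <- survey_spec(n_cores = 10)
  expect_identical(gen_benthos_survey(sp, seed = 5),
                   gen_benthos_survey(sp, seed = 5))
  sp0 <- survey_spec(dplyr::mutate(default_species_params(), d_m2 = 0),
                     n_cores = 10)
  expect_equal(nrow(gen_benthos_survey(sp0, seed = 1)), 0)
})

test_that("per-core counts match the Poisson sampling intensity", {
  # 1000 items / m^2 in a 15-cm core: mean 1000 * 0.0176715 = 17.67 per core
  pars <- dplyr::mutate(default_species_params()[1, ], d_m2 = 1000,
                        accessibility = 1)
  sp <- survey_spec(pars, n_cores = 500)
  survey <- gen_benthos_survey(sp, seed = 11)
  mean_count <- nrow(survey) / 500
  expected <- 1000 * pi * 0.075^2
  se <- sqrt(expected / 500)
  expect_lt(abs(mean_count - expected), 3 * se)
})

test_that("generated records satisfy the consuming modules' invariants", {
  survey <- gen_benthos_survey(survey_spec(n_cores = 30), seed = 3)
  expect_true(all(survey$length_mm > 0))
  expect_true(all(survey$afdm_mg > 0, na.rm = TRUE))
  expect_true(all(survey$stratum %in% c("top_0_4cm", "bottom_4_16cm")))
  # flows through the field pipeline without error
  params <- annual_prey_params(survey,
                               tibble::tibble(year = 1L, n_cores = 30))
  expect_true(all(params$d_m2 >= 0))
  expect_true(all(params$s_mg[params$species == "loripes"] ==
                    params$e_mg[params$species == "loripes"], na.rm = TRUE))
})

test_that("unmeasured items appear as missing masses and can be filled", {
  sp <- survey_spec(n_cores = 40, p_measured = 0.4)
  survey <- gen_benthos_survey(sp, seed = 8)
  expect_gt(sum(is.na(survey$afdm_mg)), 0)
  filled <- fill_masses(survey)
  expect_false(anyNA(filled$afdm_mg))
  expect_false(anyNA(filled$dm_mg))
})

test_that("the survey-to-parameter pipeline recovers the true density", {
  # single large survey: estimated available density within 3 SE of truth
  pars <- default_species_params()
  sp <- survey_spec(pars, n_cores = 400)
  survey <- gen_benthos_survey(sp, seed = 21)
  est <- annual_prey_params(survey, tibble::tibble(year = 1L, n_cores = 400))
  area <- 400 * pi * 0.075^2
  for (i in seq_len(nrow(pars))) {
    ingestible <- plnorm(13.2, pars$len_meanlog[i], pars$len_sdlog[i])
    if (pars$species[i] == "loripes") ingestible <- 1
    truth <- pars$d_m2[i] * pars$accessibility[i] * ingestible
    got <- est$d_m2[est$species == pars$species[i]]
    se <- sqrt(truth / area)     # Poisson counting error on the density scale
    expect_lt(abs(got - truth), 3 * se)
  }
})

test_that("annual biomass systems hit the requested log correlation", {
  a <- gen_annual_system(8, seed = 2)
  expect_identical(a, gen_annual_system(8, seed = 2))
  expect_equal(nrow(a), 8)

  big0 <- gen_annual_system(10000, seed = 3, rho = 0)
  expect_lt(abs(cor(log(big0$b_tox_g_m2), log(big0$b_bulk_g_m2))), 0.05)
  bigneg <- gen_annual_system(10000, seed = 4, rho = -0.76)
  expect_lt(abs(cor(log(bigneg$b_tox_g_m2), log(bigneg$b_bulk_g_m2)) + 0.76), 0.05)
})
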