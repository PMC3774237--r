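test_that("availability filter applies stratum and size rules", {
  rec <- tibble::tibble(
    year = 1L, station = 1L,
    species = c("dosinia", "dosinia", "dosinia", "loripes", "loripes"),
    stratum = c("top_0_4cm", "top_0_4cm", "top_0_4cm", "top_0_4cm", "bottom_4_16cm"),
    length_mm = c(13.2, 13.1, 5, 20, 6),
    afdm_mg = 1, dm_mg = 1
  )
  out <- filter_available(rec)
  # 13.2 mm is out (strict), 13.1 in; all loripes sizes in, bottom stratum out
  expect_equal(nrow(out), 3)
  expect_false(any(out$species == "dosinia" & out$length_mm >= 13.2))
  expect_true(any(out$species == "loripes" & out$length_mm == 20))

  expect_equal(nrow(filter_available(rec[0, ])), 0)
  expect_warning(filter_available(dplyr::mutate(rec, species = "mystery")),
                 "mystery")
})

test_that("core counts convert to areal densities", {
  expect_equal(core_density(0, 5), 0)
  # one item in one 15-cm core: 1 / 0.0176715 m^2
  expect_equal(core_density(1, 1), 1 / (pi * 0.075^2), tolerance = 1e-12)
  expect_equal(core_density(1, 1), 56.59, tolerance = 1e-4)
  expect_equal(core_density(10, 10), core_density(1, 1))
  expect_error(core_density(1, 0), "n_cores")
})

test_that("allometry fits recover power laws and only fill missing masses", {
  len <- c(4, 6, 8, 10, 12)
  mass <- 0.02 * len^2.8
  fit <- fit_allometry(len, mass)
  expect_equal(fit$alpha, 0.02, tolerance = 1e-10)
  expect_equal(fit$beta, 2.8, tolerance = 1e-10)
  expect_equal(predict(fit, 7), 0.02 * 7^2.8, tolerance = 1e-9)
  expect_error(fit_allometry(c(4, 6), c(1, 2)), "at least 3")

  rec <- tibble::tibble(
    species = "x", length_mm = c(4, 6, 8, 10, 12, 7),
    afdm_mg = c(mass[1:5], NA), dm_mg = c(10 * mass[1:5], NA)
  )
  filled <- fill_masses(rec)
  expect_equal(filled$afdm_mg[1:5], mass[1:5])          # observed untouched
  expect_equal(filled$afdm_mg[6], 0.02 * 7^2.8, tolerance = 1e-9)
  expect_equal(filled$dm_mg[6], 0.2 * 7^2.8, tolerance = 1e-9)
})

test_that("noisy allometry recovers the exponent within 2 standard errors", {
  inst <- withr::with_seed(7, {
    len <- runif(200, 4, 14)
    mass <- 0.015 * len^2.9 * exp(rnorm(200, 0, 0.2))
    list(len = len, mass = mass)
  })
  fit <- fit_allometry(inst$len, inst$mass)
  se_beta <- generics::tidy(fit)$std.error[2]
  expect_lt(abs(fit$beta - 2.9), 2 * se_beta)
})

test_that("stratified correction mixes habitats and applies availability", {
  expect_equal(stratified_correction(100, 100, 0.8, 0.73), 73)
  expect_equal(stratified_correction(150, 40, 1, 1), 150)
  expect_equal(stratified_correction(200, 0, 0.8, 0.70), 112)
})

test_that("annual parameters pool filtered, mass-filled records per year", {
  params <- annual_prey_params(toy_records(),
                               cores_per_year = tibble::tibble(year = 1L, n_cores = 2))
  lor <- params[params$species == "loripes", ]
  dos <- params[params$species == "dosinia", ]
  expect_equal(lor$e_mg, 3)                     # mean of 2, 3, 4
  expect_equal(lor$k_mg, 20)
  expect_equal(lor$s_mg, 3)                     # toxic: s = e
  expect_equal(dos$s_mg, 0)
  expect_equal(lor$d_m2, core_density(3, 2))
  expect_equal(dos$d_m2, core_density(2, 2))

  # a second year with no available items gets zero density, NA masses
  rec2 <- dplyr::bind_rows(toy_records(),
                           dplyr::mutate(toy_records(), year = 2L,
                                         stratum = "bottom_4_16cm"))
  p2 <- annual_prey_params(rec2, tibble::tibble(year = c(1L, 2L), n_cores = 2))
  expect_equal(nrow(p2), 4)
  y2 <- p2[p2$year == 2L, ]
  expect_true(all(y2$d_m2 == 0))
  expect_true(all(is.na(y2$e_mg)))
})

test_that("sieve correction rescales retained shell mass", {
  expect_equal(shell_mass_ingested(0), 0)
  expect_equal(shell_mass_ingested(6.5), 10)
  expect_equal(shell_mass_ingested(0.65), 1)
})

test_that("diet fractions weight shell mass by flesh/shell ratios", {
  ratios <- tibble::tibble(species = c("a", "b"), flesh_shell_ratio = c(0.3, 0.1))
  samples <- tibble::tibble(
    sample = c(1, 1, 2, 3, 3),
    year = 1L,
    species = c("a", "b", "a", "a", "b"),
    retained_dm_mg = c(10, 10, 5, 0, 0)
  )
  out <- diet_fractions(samples, ratios)
  s1 <- out[out$sample == 1, ]
  expect_equal(s1$fraction, c(0.75, 0.25))      # 10*0.3 vs 10*0.1
  expect_equal(sum(s1$fraction), 1)
  expect_equal(out$fraction[out$sample == 2], 1)  # single species
  expect_true(all(is.na(out$fraction[out$sample == 3])))  # all-zero sample
  expect_error(diet_fractions(dplyr::mutate(samples, species = "zz"), ratios),
               "zz")
})

test_that("annual logit means behave like logit-scale averages", {
  expect_equal(annual_logit_mean(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(annual_logit_mean(rep(0.37, 4)), 0.37)
  expect_equal(annual_logit_mean(c(0.2, 0.8)), 0.5)   # symmetric logits
  # boundary fractions are nudged, not fatal
  expect_true(annual_logit_mean(c(0, 1, 0.5)) > 0.49)
  expect_true(is.na(annual_logit_mean(numeric(0))))
})

test_that("paired diet comparison matches t.test and flags degenerate cases", {
  obs <- c(0.55, 0.62, 0.48, 0.71, 0.60)
  pred <- c(0.60, 0.58, 0.52, 0.80, 0.57)
  res <- compare_diets(obs, pred)
  ref <- t.test(qlogis(obs) - qlogis(pred))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
  expect_equal(res$df, 4)
  expect_false(res$degenerate)

  same <- compare_diets(obs, obs)
  expect_equal(same$statistic, 0)
  expect_true(same$degenerate)

  off <- compare_diets(plogis(qlogis(obs) + 0.5), obs)
  expect_true(is.infinite(off$statistic) && off$statistic > 0)
  expect_true(off$degenerate)

  expect_error(compare_diets(0.5, 0.6), "at least 2")
})
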