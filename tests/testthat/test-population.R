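test_that("projection conserves individuals when survival is 1 and fecundity 0", {
  rates <- tibble::tibble(phi_juv = 1, phi_ad = 1, f = 0)[rep(1, 5), ]
  traj <- project_population(rates, initial = c(100, 400), start_year = 2000)
  expect_equal(traj$n_total, rep(500, 6))
  expect_equal(traj$n_juv[2], 0)            # juveniles matured
  expect_equal(traj$year, 2000:2005)
})

test_that("zero survival drives extinction within two steps", {
  rates <- tibble::tibble(phi_juv = 0, phi_ad = 0, f = 0.14)[rep(1, 3), ]
  traj <- project_population(rates, initial = c(50, 100))
  expect_equal(traj$n_total[3], 0)
})

test_that("constant-rate growth matches the closed-form dominant eigenvalue", {
  phi_juv <- 0.8; phi_ad <- 0.85; f <- 0.14
  lam <- growth_factor(phi_juv, phi_ad, f)
  # independent check: eigen() on the projection matrix
  M <- rbind(c(0, f), c(phi_juv, phi_ad))
  expect_equal(lam, max(eigen(M)$values), tolerance = 1e-12)
  # realized growth converges to lambda
  rates <- tibble::tibble(phi_juv = phi_juv, phi_ad = phi_ad, f = f)[rep(1, 80), ]
  traj <- project_population(rates, initial = c(1000, 5000))
  realized <- traj$n_total[81] / traj$n_total[80]
  expect_equal(realized, lam, tolerance = 1e-10)
})

test_that("projection is linear in the initial state", {
  rates <- tibble::tibble(phi_juv = c(0.7, 0.9), phi_ad = c(0.8, 0.85),
                          f = 0.14)
  t1 <- project_population(rates, initial = c(100, 300))
  t3 <- project_population(rates, initial = 3 * c(100, 300))
  expect_equal(t3$n_total, 3 * t1$n_total)
})

test_that("projection refuses missing or invalid rates", {
  expect_error(project_population(tibble::tibble(phi_juv = 0.5, phi_ad = NA, f = 0.1),
                                  c(1, 1)), "NA")
  expect_error(project_population(tibble::tibble(phi_juv = 1.2, phi_ad = 0.5, f = 0.1),
                                  c(1, 1)), "survival")
  expect_error(project_population(tibble::tibble(phi_juv = 0.5, phi_ad = 0.5, f = 0.1),
                                  c(1, -1)), "initial")
})

test_that("the intake-survival link is monotone and recoverable", {
  expect_equal(survival_from_intake(list(b0 = 0, b1 = 0), 0.3), 0.5)
  expect_equal(survival_from_intake(list(b0 = 1.2, b1 = 0), c(0, 1)),
               rep(plogis(1.2), 2))
  phis <- survival_from_intake(list(b0 = -1, b1 = 10), c(0.1, 0.2, 0.3))
  expect_true(all(diff(phis) > 0))

  # exact logit-linear data are recovered by the least-squares helper
  y <- c(0.10, 0.15, 0.22, 0.30)
  link0 <- list(b0 = -0.5, b1 = 8)
  tab <- tibble::tibble(y = y, phi = survival_from_intake(link0, y))
  fit <- fit_survival_link(tab)
  expect_equal(fit$b0, -0.5, tolerance = 1e-10)
  expect_equal(fit$b1, 8, tolerance = 1e-10)
})

test_that("prey-removal scenarios order trajectories as expected", {
  params <- tidyr::expand_grid(year = 2002:2009,
                               species = c("loripes", "dosinia")) |>
    dplyr::mutate(
      e_mg = ifelse(species == "loripes", 3, 5),
      k_mg = ifelse(species == "loripes", 20, 85),
      s_mg = ifelse(species == "loripes", 3, 0),
      d_m2 = ifelse(species == "loripes", 0.5, 0.35) * 100 / e_mg * 10
    )
  f <- knot_forager()
  link <- list(b0 = -1.5, b1 = 15)
  run <- function(sc) scenario_project(params, f, link, initial = c(3000, 19859),
                                       scenario = sc)
  both <- run("both"); no_tox <- run("no_toxic"); no_bulk <- run("no_bulky")
  n <- nrow(both)
  # removing either prey can only depress intake, hence the trajectory
  expect_true(all(no_tox$n_total <= both$n_total + 1e-9))
  expect_true(all(no_bulk$n_total <= both$n_total + 1e-9))
  expect_true(all(no_tox$Y[-1] <= both$Y[-1] + 1e-12))

  # removing an absent species changes nothing
  params0 <- dplyr::mutate(params, d_m2 = ifelse(species == "loripes", 0, d_m2))
  expect_equal(scenario_project(params0, f, link, c(3000, 19859), "both")$n_total,
               scenario_project(params0, f, link, c(3000, 19859), "no_toxic")$n_total)
})

test_that("percent change matches the printed example arithmetic", {
  expect_equal(round(percent_change(22859, 12465)), -45)
  expect_equal(percent_change(500, 500), 0)
  expect_equal(round(percent_change(100, 21)), -79)
  expect_error(percent_change(0, 10), "n_start")
})
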