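test_that("the decision cascade reduces to DRM and CM when constraints are vacuous", {
  for (s in 1:50) {
    inst <- random_instance(s)
    # both vacuous -> exact CM policy
    both <- solve_tdrm(inst$prey, vacuous_forager())
    expect_identical(both$policy$p, solve_cm(inst$prey)$policy$p)
    expect_identical(both$model_used, "CM")
    # toxin vacuous -> exact single-constraint (digestive) policy
    f <- forager_spec(c_mg_s = inst$forager$c_mg_s, q_mg_s = 1e9)
    red <- solve_tdrm(inst$prey, f)
    drm <- solve_drm(inst$prey, "digestive", limit = f$c_mg_s)
    expect_identical(red$policy$p, drm$policy$p)
  }
})

test_that("both-binding interior solution matches the linearized 2x2 system", {
  prey <- study_prey(b_tox = 1.0, b_bulk = 1.0)
  f <- knot_forager()
  sol <- solve_tdrm(prey, f)
  expect_identical(sol$model_used, "TDRM")
  expect_true(all(sol$policy$p > 0 & sol$policy$p < 1))  # partial on both

  # independent hand solve of the two constraint equalities
  A_enc <- prey$a_cm2_s * prey$d_cm2
  A <- A_enc[1] * (prey$k_mg[1] - f$c_mg_s * prey$h_s[1])
  B <- A_enc[2] * (prey$k_mg[2] - f$c_mg_s * prey$h_s[2])
  C <- A_enc[1] * (prey$s_mg[1] - f$q_mg_s * prey$h_s[1])
  E <- A_enc[2] * (prey$s_mg[2] - f$q_mg_s * prey$h_s[2])
  p1 <- (f$c_mg_s * E - f$q_mg_s * B) / (A * E - B * C)
  p2 <- (f$q_mg_s * A - f$c_mg_s * C) / (A * E - B * C)
  expect_equal(sol$policy$p, c(p1, p2), tolerance = 1e-10)

  # substituting back into the disc equation hits both ceilings exactly
  r <- intake_rates(prey, sol$policy$p)
  expect_equal(r$X, f$c_mg_s, tolerance = 1e-9)
  expect_equal(r$Z, f$q_mg_s, tolerance = 1e-9)
  expect_identical(sol$regime, "both")
})

test_that("solutions are feasible, bind where partial, and match the oracle", {
  for (s in 1:60) {
    inst <- random_instance(s)
    sol <- solve_tdrm(inst$prey, inst$forager)
    # feasibility within absolute tolerance
    expect_lte(sol$rates$X, inst$forager$c_mg_s + 1e-9)
    expect_lte(sol$rates$Z, inst$forager$q_mg_s + 1e-9)
    # binding equality whenever the regime names a constraint
    if ("digestive" %in% sol$binding) {
      expect_equal(sol$rates$X, inst$forager$c_mg_s, tolerance = 1e-6)
    }
    if ("toxin" %in% sol$binding) {
      expect_equal(sol$rates$Z, inst$forager$q_mg_s, tolerance = 1e-6)
    }
    # an interior acceptance probability requires some binding constraint
    # (otherwise the CM corner solution would have been returned)
    if (any(sol$policy$p > 1e-9 & sol$policy$p < 1 - 1e-9)) {
      expect_gt(length(sol$binding), 0)
    }
    orc <- brute_force_policy(inst$prey, inst$forager, resolution = 501)
    expect_equal(sol$rates$Y, orc$rates$Y,
                 tolerance = 2e-4 * max(1, orc$rates$Y))
  }
})

test_that("optimal intake never falls when any prey density rises", {
  for (s in 1:25) {
    inst <- random_instance(s)
    y0 <- solve_tdrm(inst$prey, inst$forager)$rates$Y
    for (i in 1:2) {
      richer <- inst$prey
      richer$d_cm2[i] <- richer$d_cm2[i] * 2 + 0.01
      y1 <- solve_tdrm(richer, inst$forager)$rates$Y
      expect_gte(y1, y0 - 1e-12)
    }
  }
})

test_that("degenerate equal-constraint systems fall back gracefully", {
  # both constraints proportional (s = k, q = c): determinant is ~0
  prey <- prey_table(c("a", "b"), e_mg = c(3, 5), k_mg = c(2, 4),
                     s_mg = c(2, 4), h_s = 1, a_cm2_s = 4,
                     d_cm2 = c(0.5, 0.5))
  forager <- forager_spec(c_mg_s = 1, q_mg_s = 1)
  sol <- solve_tdrm(prey, forager)
  expect_lte(sol$rates$X, 1 + 1e-9)
  expect_lte(sol$rates$Z, 1 + 1e-9)
  orc <- brute_force_policy(prey, forager, resolution = 501)
  expect_equal(sol$rates$Y, orc$rates$Y, tolerance = 1e-4)
})

test_that("tidy and glance expose the policy and rates", {
  sol <- solve_tdrm(study_prey(1, 0.4), knot_forager())
  td <- generics::tidy(sol)
  expect_named(td, c("name", "p", "Y_i"))
  expect_equal(sum(td$Y_i), sol$rates$Y)
  gl <- generics::glance(sol)
  expect_true(gl$toxin_binding)
  expect_identical(gl$regime, sol$regime)
})
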