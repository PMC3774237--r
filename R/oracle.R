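#' Brute-force grid oracle for the constrained diet problem
#'
#' Exhaustively evaluates the intake rates on a regular grid of acceptance
#' probabilities, discards policies violating the digestive or toxin
#' constraint, and returns the energy-rate maximizer. Independent of the
#' analytic solvers, it serves as ground truth for them: the grid maximum can
#' undershoot the true optimum by at most one grid cell's worth of rate
#' change (the objective is Lipschitz on the unit cube).
#'
#' For one or two prey the scan also evaluates, in every grid column, the
#' exact acceptance probability at which each constraint reaches equality
#' (clipped to `[0, 1]`): a mesh restricted to interior grid points
#' systematically undershoots when the optimum sits on a constraint
#' boundary, since every feasible grid point can be up to one cell inside
#' it. The boundary-augmented scan is still exhaustive search — it never
#' ranks prey or solves the two-constraint system.
#'
#' Supports up to three prey types; the grid explodes combinatorially beyond
#' that (the default resolution is intended for two; the three-prey scan is
#' pure grid).
#'
#' @param prey a [prey_table()] with at most 3 rows.
#' @param forager a [forager_spec()].
#' @param resolution grid points per acceptance-probability axis
#'   (default 1001, i.e. policy granularity 1e-3).
#' @return A `diet_solution` with `model_used = "grid"`.
#' @examples
#' prey <- set_biomass(prey_template(), c(0.6, 0.3))
#' brute_force_policy(prey, forager_spec(), resolution = 201)
#' @export
brute_force_policy <- function(prey, forager, resolution = 1001) {
  prey <- validate_prey(prey)
  stopifnot(inherits(forager, "forager_spec"), resolution >= 2)
  n <- nrow(prey)
  if (n > 3) abort("grid oracle supports at most 3 prey types")
  pg <- seq(0, 1, length.out = resolution)
  A <- prey$a_cm2_s * prey$d_cm2
  c_lim <- forager$c_mg_s; q_lim <- forager$q_mg_s

  # boundary candidates: p solving sum p_i g_i = b for one coordinate, the
  # others fixed at grid values (g is the denominator-multiplied constraint)
  gX <- A * (prey$k_mg - c_lim * prey$h_s)
  gZ <- A * (prey$s_mg - q_lim * prey$h_s)

  if (n == 1) {
    pcand <- pg
    bX <- if (abs(gX) > 0) c_lim / gX else NA_real_
    bZ <- if (abs(gZ) > 0) q_lim / gZ else NA_real_
    pcand <- c(pcand, bX[bX >= 0 & bX <= 1 & is.finite(bX)],
               bZ[bZ >= 0 & bZ <= 1 & is.finite(bZ)])
    enc <- pcand * A
    den <- 1 + enc * prey$h_s
    numY <- enc * prey$e_mg; numX <- enc * prey$k_mg; numZ <- enc * prey$s_mg
    feas <- numX <= c_lim * den + tdrm_tol$feas & numZ <= q_lim * den + tdrm_tol$feas
    Y <- ifelse(feas, numY / den, -Inf)
    pick <- pick_grid(Y, numZ / den, numX / den, list(pcand))
    p <- pcand[pick]
  } else if (n == 2) {
    # One scan pass: vectorized over the pg1 x pg2 grid (feasibility checked
    # on the linearized, denominator-multiplied form to avoid divisions),
    # plus constraint-boundary candidates -- for each grid column the exact
    # other-axis probability at which X = c or Z = q. A mesh alone can sit
    # up to one cell inside a binding boundary and undershoot there.
    scan2 <- function(pg1, pg2) {
      e1 <- pg1 * A[1] * prey$e_mg[1]; e2 <- pg2 * A[2] * prey$e_mg[2]
      k1 <- pg1 * A[1] * prey$k_mg[1]; k2 <- pg2 * A[2] * prey$k_mg[2]
      s1 <- pg1 * A[1] * prey$s_mg[1]; s2 <- pg2 * A[2] * prey$s_mg[2]
      h1 <- pg1 * A[1] * prey$h_s[1];  h2 <- pg2 * A[2] * prey$h_s[2]
      den <- 1 + outer(h1, h2, "+")
      feas <- outer(k1, k2, "+") <= c_lim * den + tdrm_tol$feas &
              outer(s1, s2, "+") <= q_lim * den + tdrm_tol$feas
      Y <- outer(e1, e2, "+") / den
      Y[!feas] <- -Inf
      ymax <- max(Y)
      best <- NULL
      if (is.finite(ymax)) {
        tied <- which(Y >= ymax - tdrm_tol$tie * max(1, abs(ymax)))
        ij <- arrayInd(tied, dim(Y))
        Zt <- (s1[ij[, 1]] + s2[ij[, 2]]) / den[tied]
        Xt <- (k1[ij[, 1]] + k2[ij[, 2]]) / den[tied]
        ord <- order(Zt, Xt, pg1[ij[, 1]], pg2[ij[, 2]])[1]
        best <- list(p = c(pg1[ij[ord, 1]], pg2[ij[ord, 2]]), y = ymax)
      }
      boundary <- list()
      for (con in list(list(g = gX, b = c_lim), list(g = gZ, b = q_lim))) {
        if (abs(con$g[2]) > 0) {
          p2b <- (con$b - pg1 * con$g[1]) / con$g[2]
          ok <- is.finite(p2b) & p2b >= 0 & p2b <= 1
          if (any(ok)) boundary <- c(boundary, list(cbind(pg1[ok], p2b[ok])))
        }
        if (abs(con$g[1]) > 0) {
          p1b <- (con$b - pg2 * con$g[2]) / con$g[1]
          ok <- is.finite(p1b) & p1b >= 0 & p1b <= 1
          if (any(ok)) boundary <- c(boundary, list(cbind(p1b[ok], pg2[ok])))
        }
      }
      if (length(boundary)) {
        bp <- do.call(rbind, boundary)
        encb <- t(t(bp) * A)
        denb <- as.numeric(1 + encb %*% prey$h_s)
        Yb <- as.numeric(encb %*% prey$e_mg) / denb
        Xb <- as.numeric(encb %*% prey$k_mg) / denb
        Zb <- as.numeric(encb %*% prey$s_mg) / denb
        okb <- Xb <= c_lim + tdrm_tol$feas & Zb <= q_lim + tdrm_tol$feas
        if (any(okb)) {
          kb <- which(okb)[which.max(Yb[okb])]
          if (is.null(best) || Yb[kb] > best$y) {
            best <- list(p = bp[kb, ], y = Yb[kb])
          }
        }
      }
      best
    }
    coarse <- scan2(pg, pg)
    # second pass: rescan the one-cell neighbourhood of the first-pass best
    # at the same resolution (effective granularity ~ cell width squared)
    step <- 1 / (resolution - 1)
    fine_res <- min(resolution, 201)
    win <- function(p0) {
      seq(max(0, p0 - step), min(1, p0 + step), length.out = fine_res)
    }
    fine <- scan2(win(coarse$p[1]), win(coarse$p[2]))
    p <- if (!is.null(fine) && fine$y > coarse$y) fine$p else coarse$p
  } else {
    best <- NULL
    for (p3 in pg) {
      e1 <- pg * A[1] * prey$e_mg[1]; e2 <- pg * A[2] * prey$e_mg[2]
      base_h <- 1 + p3 * A[3] * prey$h_s[3]
      den <- base_h + outer(pg * A[1] * prey$h_s[1], pg * A[2] * prey$h_s[2], "+")
      numX <- p3 * A[3] * prey$k_mg[3] +
        outer(pg * A[1] * prey$k_mg[1], pg * A[2] * prey$k_mg[2], "+")
      numZ <- p3 * A[3] * prey$s_mg[3] +
        outer(pg * A[1] * prey$s_mg[1], pg * A[2] * prey$s_mg[2], "+")
      Y <- (p3 * A[3] * prey$e_mg[3] + outer(e1, e2, "+")) / den
      Y[numX > c_lim * den + tdrm_tol$feas | numZ > q_lim * den + tdrm_tol$feas] <- -Inf
      k <- which.max(Y)
      if (is.null(best) || Y[k] > best$y) {
        ij <- arrayInd(k, dim(Y))
        best <- list(y = Y[k], p = c(pg[ij[1]], pg[ij[2]], p3))
      }
    }
    p <- best$p
  }
  rates <- intake_rates(prey, p)
  new_diet_solution(tibble(name = prey$name, p = p), rates, "grid", prey, forager)
}

pick_grid <- function(Y, Z, X, pcols) {
  ymax <- max(Y)
  tied <- which(Y >= ymax - tdrm_tol$tie * max(1, abs(ymax)))
  ord <- do.call(order, c(list(Z[tied], X[tied]),
                          lapply(pcols, function(pc) pc[tied])))
  tied[ord[1]]
}

#' Reproducible random two-prey instances
#'
#' Draws a random prey pair plus forager spec mirroring the structure of the
#' toxic/bulky bivalve system: type 1 is toxic (s = e) and thin-shelled
#' (higher e/k), type 2 is non-toxic (s = 0) and thick-shelled (lower e/k).
#' All draws are uniform over configurable ranges; the RNG state is saved
#' and restored, so the draw depends only on `seed`.
#'
#' @param seed integer seed.
#' @param ranges named list overriding any of the default ranges:
#'   `e_tox`, `ek_tox` (flesh-to-shell ratio of the toxic type), `e_bulk`,
#'   `ek_bulk_frac` (bulky ratio as a fraction of the toxic one, keeping the
#'   ranking strict), `h`, `a`, `d_tox`, `d_bulk` (items cm^-2), `c`, `q`.
#' @return A list with elements `prey` (a `tdrm_prey` tibble) and `forager`.
#' @export
random_instance <- function(seed, ranges = list()) {
  r <- modifyList(list(
    e_tox = c(1, 5), ek_tox = c(0.08, 0.3),
    e_bulk = c(1, 8), ek_bulk_frac = c(0.1, 0.8),
    h = c(0.5, 2), a = c(2, 6),
    d_tox = c(0, 0.4), d_bulk = c(0, 0.15),
    c = c(1, 8), q = c(0.02, 0.3)
  ), ranges)
  stopifnot(all(vapply(r, function(x) all(x >= 0), logical(1))))
  with_local_seed(seed, {
    u <- function(rg) runif(1, rg[1], rg[2])
    e1 <- u(r$e_tox); ratio1 <- u(r$ek_tox)
    e2 <- u(r$e_bulk); ratio2 <- ratio1 * u(r$ek_bulk_frac)
    prey <- prey_table(
      name = c("toxic_thin", "bulky_clean"),
      e_mg = c(e1, e2),
      k_mg = c(e1 / ratio1, e2 / ratio2),
      s_mg = c(e1, 0),
      h_s = c(u(r$h), u(r$h)),
      a_cm2_s = c(u(r$a), u(r$a)),
      d_cm2 = c(u(r$d_tox), u(r$d_bulk))
    )
    list(prey = prey, forager = forager_spec(c_mg_s = u(r$c), q_mg_s = u(r$q)))
  })
}

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
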