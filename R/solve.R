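#' @title Diet solutions
#' @description Fitted-object container returned by [solve_cm()],
#'   [solve_drm()], [solve_tdrm()] and [brute_force_policy()]. Use [tidy()]
#'   for the per-prey acceptance probabilities and [glance()] for the rate
#'   triple, binding constraints and regime.
#' @param policy tibble with `name`, `p`.
#' @param rates one-row tibble `Y`, `X`, `Z`.
#' @param model_used one of `"CM"`, `"DRM"`, `"TDRM"`, `"grid"`.
#' @param prey,forager the inputs the solution was computed from
#'   (`forager` may be `NULL` when no constraints were supplied).
#' @keywords internal
new_diet_solution <- function(policy, rates, model_used, prey, forager = NULL) {
  binding <- character(0)
  regime <- NA_character_
  if (!is.null(forager)) {
    binding <- c(
      if (abs(rates$X - forager$c_mg_s) <= tdrm_tol$bind) "digestive",
      if (abs(rates$Z - forager$q_mg_s) <= tdrm_tol$bind) "toxin"
    )
    regime <- regime_label(binding)
  }
  structure(
    list(policy = policy, rates = rates, binding = binding, regime = regime,
         model_used = model_used, prey = prey, forager = forager),
    class = "diet_solution"
  )
}

regime_label <- function(binding) {
  if (length(binding) == 2) "both"
  else if (length(binding) == 0) "neither"
  else binding
}

#' @export
print.diet_solution <- function(x, digits = 4, ...) {
  cat("<diet_solution> model:", x$model_used, "\n")
  df <- x$policy
  df$p <- signif(df$p, digits)
  print(as.data.frame(df), row.names = FALSE)
  with(x$rates, cat("  Y =", signif(Y, digits), " X =", signif(X, digits),
                    " Z =", signif(Z, digits), "mg/s\n"))
  if (!is.na(x$regime)) {
    cat("  regime:", x$regime,
        if (length(x$binding)) paste0("(binding: ", paste(x$binding, collapse = ", "), ")"),
        "\n")
  }
  invisible(x)
}

#' @rdname new_diet_solution
#' @param x a `diet_solution`.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per prey type (`name`, `p`,
#'   per-prey energy contribution `Y_i`); `glance()`: a one-row tibble with
#'   the rate triple, model used, regime and binding flags.
#' @exportS3Method generics::tidy
tidy.diet_solution <- function(x, ...) {
  dplyr::left_join(x$policy, intake_components(x$prey, x$policy$p), by = "name")
}

#' @rdname new_diet_solution
#' @exportS3Method generics::glance
glance.diet_solution <- function(x, ...) {
  tibble(
    model_used = x$model_used,
    Y = x$rates$Y, X = x$rates$X, Z = x$rates$Z,
    regime = x$regime,
    digestive_binding = "digestive" %in% x$binding,
    toxin_binding = "toxin" %in% x$binding
  )
}

# ---- constraint linearization -----------------------------------------------
# X <= c  <=>  sum_i p_i a_i D_i (k_i - c h_i) <= c   (multiply out the shared
# denominator; identical structure for Z <= q with s_i and q). Each constraint
# is stored as its linear coefficient vector g and bound b.
linear_constraint <- function(prey, content, limit) {
  A <- prey$a_cm2_s * prey$d_cm2
  list(g = A * (content - limit * prey$h_s), b = limit)
}

# All candidate vertex policies of the feasible region: 0/1 corners, each
# constraint-equality solved for one free coordinate with the others at 0/1,
# and (for two constraints) the 2x2 interior solution for each coordinate
# pair. The objective Y is fractional-linear in p, so its constrained maximum
# is attained at one of these points.
candidate_policies <- function(n, constraints) {
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  colnames(corners) <- NULL
  cand <- list(corners)

  other_corners <- function(k) {
    if (k == 0) matrix(numeric(0), nrow = 1, ncol = 0)
    else as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  }

  for (con in constraints) {
    for (i in seq_len(n)) {
      if (abs(con$g[i]) < 1e-300) next
      oc <- other_corners(n - 1)
      for (r in seq_len(nrow(oc))) {
        p <- numeric(n)
        p[-i] <- oc[r, ]
        pi_val <- (con$b - sum(p[-i] * con$g[-i])) / con$g[i]
        if (is.finite(pi_val) && pi_val >= 0 && pi_val <= 1) {
          p[i] <- pi_val
          cand <- c(cand, list(matrix(p, nrow = 1)))
        }
      }
    }
  }

  if (length(constraints) == 2 && n >= 2) {
    c1 <- constraints[[1]]; c2 <- constraints[[2]]
    pairs <- utils::combn(n, 2)
    for (m in seq_len(ncol(pairs))) {
      ij <- pairs[, m]
      oc <- other_corners(n - 2)
      for (r in seq_len(nrow(oc))) {
        p <- numeric(n)
        p[-ij] <- oc[r, ]
        # A p_i + B p_j = c - r1 ; C p_i + E p_j = q - r2
        A <- c1$g[ij[1]]; B <- c1$g[ij[2]]
        C <- c2$g[ij[1]]; E <- c2$g[ij[2]]
        det <- A * E - B * C
        if (abs(det) < 1e-12 * max(abs(A * E), abs(B * C), 1e-300)) next
        b1 <- c1$b - sum(p[-ij] * c1$g[-ij])
        b2 <- c2$b - sum(p[-ij] * c2$g[-ij])
        pi_val <- (b1 * E - b2 * B) / det
        pj_val <- (b2 * A - b1 * C) / det
        if (is.finite(pi_val) && is.finite(pj_val) &&
            pi_val >= 0 && pi_val <= 1 && pj_val >= 0 && pj_val <= 1) {
          p[ij] <- c(pi_val, pj_val)
          cand <- c(cand, list(matrix(p, nrow = 1)))
        }
      }
    }
  }

  unique(do.call(rbind, cand))
}

# Evaluate candidates, drop infeasible ones, return the Y-maximizing policy.
# Ties (within relative tol_tie on Y) break toward lower Z, then lower X,
# then lexicographically smaller p.
best_vertex_policy <- function(prey, constraints, limits) {
  n <- nrow(prey)
  cand <- candidate_policies(n, constraints)
  rates <- t(apply(cand, 1, function(p) unlist(intake_rates(prey, p))))
  feas <- rep(TRUE, nrow(cand))
  if (!is.null(limits$c)) feas <- feas & rates[, "X"] <= limits$c + tdrm_tol$feas
  if (!is.null(limits$q)) feas <- feas & rates[, "Z"] <= limits$q + tdrm_tol$feas
  cand <- cand[feas, , drop = FALSE]
  rates <- rates[feas, , drop = FALSE]
  ymax <- max(rates[, "Y"])
  tied <- which(rates[, "Y"] >= ymax - tdrm_tol$tie * max(1, abs(ymax)))
  ord <- do.call(order, c(list(rates[tied, "Z"], rates[tied, "X"]),
                          lapply(seq_len(n), function(j) cand[tied, j])))
  pick <- tied[ord[1]]
  list(p = cand[pick, ], rates = as_tibble(as.list(rates[pick, ])))
}

# ---- the three models -------------------------------------------------------

#' Contingency model (classical prey model)
#'
#' Ranks prey by profitability e/h and accepts a type in full whenever its
#' profitability strictly exceeds the long-term rate achievable on the set of
#' higher-ranked accepted types; otherwise rejects it. No partial
#' preferences; digestive and toxin constraints are ignored. Prey with equal
#' profitability are treated as a single merged type (accepted or rejected
#' together).
#'
#' @param prey a [prey_table()].
#' @param forager optional [forager_spec()]; used only to annotate which
#'   constraints the CM solution would violate or bind, never to change it.
#' @return A `diet_solution` with `model_used = "CM"`.
#' @examples
#' prey <- prey_template()
#' solve_cm(set_biomass(prey, c(0.5, 0.3)))
#' @export
solve_cm <- function(prey, forager = NULL) {
  prey <- validate_prey(prey)
  prof <- prey$e_mg / prey$h_s
  # tie groups on profitability (relative tolerance)
  grp_key <- signif(prof, 12)
  levels_desc <- sort(unique(grp_key), decreasing = TRUE)
  p <- numeric(nrow(prey))
  for (g in levels_desc) {
    current <- intake_rates(prey, p)$Y
    if (g > current) p[grp_key == g] <- 1 else break
  }
  rates <- intake_rates(prey, p)
  new_diet_solution(tibble(name = prey$name, p = p), rates, "CM", prey, forager)
}

#' Digestive rate model (single-constraint diet solver)
#'
#' Maximizes the long-term energy intake rate subject to one linear-fractional
#' constraint: either the ballast (shell-mass) processing rate `X <= limit`
#' or the toxin intake rate `Z <= limit`. If the unconstrained contingency
#' model already satisfies the constraint it is returned unchanged
#' (`model_used = "CM"`). Otherwise the constrained optimum — which ranks
#' prey by digestive quality e/k (or e/s for toxin) and admits a partial
#' preference for the marginal type — is found by vertex enumeration over the
#' feasible region of the fractional-linear program.
#'
#' @param prey a [prey_table()].
#' @param which `"digestive"` (alias `"ballast"`) or `"toxin"`.
#' @param limit the constraint (mg s^-1); defaults to the relevant entry of
#'   `forager`.
#' @param forager optional [forager_spec()] used for the default limit and
#'   for annotating binding constraints.
#' @return A `diet_solution`.
#' @export
solve_drm <- function(prey, which = c("digestive", "ballast", "toxin"),
                      limit = NULL, forager = NULL) {
  prey <- validate_prey(prey)
  which <- match.arg(which)
  if (which == "ballast") which <- "digestive"
  if (is.null(limit)) {
    if (is.null(forager)) abort("supply `limit` or a `forager` spec")
    limit <- if (which == "digestive") forager$c_mg_s else forager$q_mg_s
  }
  if (limit <= 0) abort("constraint limit must be > 0")

  cm <- solve_cm(prey, forager)
  cm_rate <- if (which == "digestive") cm$rates$X else cm$rates$Z
  if (cm_rate <= limit + tdrm_tol$feas) {
    return(cm)
  }
  content <- if (which == "digestive") prey$k_mg else prey$s_mg
  con <- linear_constraint(prey, content, limit)
  limits <- if (which == "digestive") list(c = limit, q = NULL) else list(c = NULL, q = limit)
  best <- best_vertex_policy(prey, list(con), limits)
  new_diet_solution(tibble(name = prey$name, p = best$p), best$rates, "DRM",
                    prey, forager)
}

#' Toxin-digestive rate model (two-constraint diet solver)
#'
#' Maximizes the long-term energy intake rate subject to both a digestive
#' constraint (ballast processing rate `X <= c`) and a toxin constraint
#' (toxic-flesh intake rate `Z <= q`). The decision cascade is:
#'
#' 1. solve the contingency model; if it violates neither constraint, return
#'    it (`model_used = "CM"`);
#' 2. otherwise impose the violated constraint alone (digestive rate model);
#'    if the other constraint now holds, return that (`model_used = "DRM"`);
#' 3. otherwise solve with both constraints active (`model_used = "TDRM"`),
#'    where the interior solution sets both constraints to equality —
#'    for two prey the linear system
#'    \eqn{\sum_i p_i a_i D_i (k_i - c h_i) = c},
#'    \eqn{\sum_i p_i a_i D_i (s_i - q h_i) = q} —
#'    and vertex enumeration guards the cases where that interior point
#'    leaves the unit square or the system is degenerate.
#'
#' The two-constraint optimum generally shows partial preference for *both*
#' prey types.
#'
#' @param prey a [prey_table()].
#' @param forager a [forager_spec()] supplying `c` and `q`.
#' @return A `diet_solution` satisfying `X <= c` and `Z <= q` (within 1e-9)
#'   whose regime labels the binding constraint set.
#' @examples
#' prey <- set_biomass(prey_template(), c(1.0, 0.4))
#' sol <- solve_tdrm(prey, forager_spec())
#' tidy(sol)
#' glance(sol)
#' @export
solve_tdrm <- function(prey, forager) {
  prey <- validate_prey(prey)
  stopifnot(inherits(forager, "forager_spec"))
  c_lim <- forager$c_mg_s; q_lim <- forager$q_mg_s

  cm <- solve_cm(prey, forager)
  x_bad <- cm$rates$X > c_lim + tdrm_tol$feas
  z_bad <- cm$rates$Z > q_lim + tdrm_tol$feas
  if (!x_bad && !z_bad) return(cm)

  first <- if (x_bad) "digestive" else "toxin"
  drm <- solve_drm(prey, first, forager = forager)
  other_ok <- if (first == "digestive") drm$rates$Z <= q_lim + tdrm_tol$feas
              else drm$rates$X <= c_lim + tdrm_tol$feas
  if (other_ok) return(drm)

  cons <- list(linear_constraint(prey, prey$k_mg, c_lim),
               linear_constraint(prey, prey$s_mg, q_lim))
  best <- best_vertex_policy(prey, cons, list(c = c_lim, q = q_lim))
  new_diet_solution(tibble(name = prey$name, p = best$p), best$rates, "TDRM",
                    prey, forager)
}

#' Vertices of the feasible intake-rate region
#'
#' The feasible set of (X, Y, Z) rate triples over all policies is the image
#' of the unit cube under a fractional-linear map — the "kite" of the
#' graphical solution. This returns the rates at all candidate vertex
#' policies (0/1 corners, single-coordinate constraint-equality solutions
#' with the other coordinates at 0 or 1, and the two-constraint interior
#' point), filtered to those satisfying the forager's constraints. Used by
#' the fallback solver and convenient for plotting the kite.
#'
#' @param prey a [prey_table()].
#' @param forager optional [forager_spec()]; when `NULL`, only the 0/1
#'   corners are returned (no constraints to intersect).
#' @return A tibble with columns `p1..pn` (policy, prey-row order), `Y`,
#'   `X`, `Z`.
#' @export
feasible_vertices <- function(prey, forager = NULL) {
  prey <- validate_prey(prey)
  n <- nrow(prey)
  cons <- list()
  limits <- list(c = NULL, q = NULL)
  if (!is.null(forager)) {
    cons <- list(linear_constraint(prey, prey$k_mg, forager$c_mg_s),
                 linear_constraint(prey, prey$s_mg, forager$q_mg_s))
    limits <- list(c = forager$c_mg_s, q = forager$q_mg_s)
  }
  cand <- candidate_policies(n, cons)
  rates <- t(apply(cand, 1, function(p) unlist(intake_rates(prey, p))))
  feas <- rep(TRUE, nrow(cand))
  if (!is.null(limits$c)) feas <- feas & rates[, "X"] <= limits$c + tdrm_tol$feas
  if (!is.null(limits$q)) feas <- feas & rates[, "Z"] <= limits$q + tdrm_tol$feas
  out <- as_tibble(cbind(cand[feas, , drop = FALSE], rates[feas, , drop = FALSE]),
                   .name_repair = "minimal")
  names(out) <- c(paste0("p", seq_len(n)), "Y", "X", "Z")
  out
}
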