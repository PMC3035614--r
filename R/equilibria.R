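#' Enumerate interior coexistence equilibria
#'
#' Finds every equilibrium at which juveniles, adults and all resources are
#' strictly positive. For the three core scenarios the candidates are the
#' positive real roots of the [reduced_cubic()]; each root is mapped through
#' the adult isocline and [resource_equilibrium()] to a full state, checked
#' for positivity and for a vanishing right-hand side, and classified by
#' Jacobian eigenvalues. When subsidy resources are present (additional
#' scenario) the reduced equation is no longer cubic and the isoclines are
#' intersected numerically instead.
#'
#' @inheritParams rhs
#' @param residual_tol Acceptance tolerance on the scaled right-hand-side
#'   residual at a reported equilibrium.
#' @return A tibble, one row per interior equilibrium, sorted by `C_J`:
#'   columns `C_J`, `C_A` (per-class abundances), `stability`
#'   (`"stable"`, `"unstable"`, `"non-hyperbolic"`), `lambda_max` (largest
#'   real part of the Jacobian spectrum), `residual`, and a list-column
#'   `state` holding the full named state vector. Zero rows is a valid
#'   outcome. For non-integer habitat numbers (analytic branch of the
#'   multiple-habitat scenario) no state vector exists, so `stability` is
#'   `NA` and the residual is checked on the isocline relations instead.
#' @export
#' @examples
#' coexistence_equilibria(default_params("additional"))
coexistence_equilibria <- function(params, residual_tol = 1e-8) {
  stopifnot(inherits(params, "niche_params"))
  roots <- if (params$scenario == "additional" &&
               (any(p_subsidy(params, "J")) || any(p_subsidy(params, "A")))) {
    intersect_zngi_numeric(params)
  } else {
    cubic_roots(reduced_cubic(params))
  }
  recs <- purrr::pmap(roots, function(C_J, merged) {
    build_equilibrium(params, C_J, merged, residual_tol)
  })
  recs <- purrr::compact(recs)
  if (length(recs) == 0) {
    return(tibble::tibble(C_J = numeric(), C_A = numeric(),
                          stability = character(), lambda_max = numeric(),
                          residual = numeric(), state = list()))
  }
  dplyr::arrange(dplyr::bind_rows(recs), .data$C_J)
}

# Map one candidate C_J* to a verified interior equilibrium record, or NULL.
build_equilibrium <- function(params, C_J, merged, residual_tol) {
  if (!is.finite(C_J) || C_J <= 0) return(NULL)
  C_A <- zngi_adult(params, C_J)
  if (!is.finite(C_A) || C_A <= 0) return(NULL)
  R <- resource_equilibrium(params, C_J, C_A)
  if (any(R[active_resources(params)] <= 0)) return(NULL)
  integer_n <- params$scenario != "multiple" ||
    (params$n_J == round(params$n_J) && params$n_A == round(params$n_A))
  if (integer_n) {
    state <- equilibrium_state(params, C_J, C_A, R)
    scale <- max(1, state)
    residual <- max(abs(rhs_raw(params, state))) / scale
    if (residual > residual_tol) return(NULL)
    cls <- classify_stability(params, state)
    tibble::tibble(
      C_J = C_J, C_A = C_A,
      stability = if (merged) "non-hyperbolic" else cls$label,
      lambda_max = cls$lambda_max, residual = residual, state = list(state)
    )
  } else {
    residual <- abs(zngi_juvenile(params, C_A) - C_J) / max(1, C_J)
    if (residual > sqrt(residual_tol)) return(NULL)
    tibble::tibble(C_J = C_J, C_A = C_A,
                   stability = NA_character_, lambda_max = NA_real_,
                   residual = residual, state = list(NULL))
  }
}

equilibrium_state <- function(params, C_J, C_A, R) {
  cons <- switch(params$scenario,
    multiple = c(rep(C_J, as.integer(params$n_J)),
                 rep(C_A, as.integer(params$n_A))),
    c(C_J, C_A)
  )
  stats::setNames(c(R, cons), state_names(params))
}

# Numeric isocline intersection for parameter sets whose reduced equation is
# not polynomial (subsidy resources): locate sign changes of
# phi(u) = zngi_juvenile(zngi_adult(u)) - u on a dense grid, refine by
# bisection.
intersect_zngi_numeric <- function(params, n_grid = 4000) {
  u_max <- feasible_C_max(params)
  u <- seq(u_max / n_grid, u_max * (1 - 1e-9), length.out = n_grid)
  v <- zngi_adult(params, u)
  phi <- rep(NA_real_, length(u))
  ok <- is.finite(v) & v >= 0
  phi[ok] <- zngi_juvenile(params, v[ok]) - u[ok]
  roots <- numeric(0)
  for (i in seq_len(length(u) - 1)) {
    if (!is.finite(phi[i]) || !is.finite(phi[i + 1])) next
    if (phi[i] == 0) roots <- c(roots, u[i])
    if (phi[i] * phi[i + 1] < 0) {
      f <- function(x) zngi_juvenile(params, max(zngi_adult(params, x), 0)) - x
      roots <- c(roots, stats::uniroot(f, c(u[i], u[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  tibble::tibble(C_J = roots, merged = FALSE)
}

#' Local stability of a state
#'
#' Classifies a (near-)equilibrium state by the eigenvalues of the Jacobian
#' of the right-hand side, computed by central finite differences.
#'
#' @inheritParams rhs
#' @param state Named state vector (an equilibrium for the label to be
#'   meaningful).
#' @param tol States whose leading eigenvalue real part is within `tol` of
#'   zero are labelled `"non-hyperbolic"`.
#' @return List with `label` (`"stable"`, `"unstable"`, `"non-hyperbolic"`),
#'   `lambda_max` (largest real part) and `eigenvalues` (complex vector).
#' @export
#' @examples
#' p <- default_params("sharing")
#' classify_stability(p, state_template(p))
classify_stability <- function(params, state, tol = 1e-6) {
  J <- pracma::jacobian(function(s) rhs_raw(params, s), unname(state))
  ev <- eigen(J, only.values = TRUE)$values
  lambda_max <- max(Re(ev))
  label <- if (abs(lambda_max) < tol) "non-hyperbolic"
  else if (lambda_max < 0) "stable" else "unstable"
  list(label = label, lambda_max = lambda_max, eigenvalues = ev)
}

#' Alternative-stable-state condition
#'
#' Diagnoses whether a parameter set admits alternative stable states: the
#' reduced cubic must have three distinct real roots (positive discriminant
#' \eqn{\Delta = 18\Lambda_1\Lambda_2\Lambda_3\Lambda_4 - 4\Lambda_2^3\Lambda_4
#' + \Lambda_2^2\Lambda_3^2 - 4\Lambda_1\Lambda_3^3 -
#' 27\Lambda_1^2\Lambda_4^2}) and every root must map to a fully positive
#' equilibrium (juveniles, adults and all resources). Under that condition
#' the system has three coexistence equilibria, of which the middle one is
#' unstable and the outer two attract.
#'
#' @inheritParams rhs
#' @param boundary_tol Discriminants with \eqn{|\Delta|} below
#'   `boundary_tol * max(|\Lambda|)^4` are flagged as boundary cases, where
#'   the boolean answer is numerically unreliable.
#' @param require_resources If `TRUE` (default) a root only counts when all
#'   resource abundances are positive as well (strict interior coexistence).
#'   With `FALSE` only juvenile and adult positivity is required; roots whose
#'   mapped resource abundance is negative correspond to states in which the
#'   over-exploited resource is dynamically extinct. The relaxed condition is
#'   the one under which strong interstage resource sharing recovers
#'   alternative states (both stages having effectively exchanged their major
#'   resources, at the cost of excluding each minor resource).
#' @return An object of class `ass_diagnostics`: list with `ass_exists`,
#'   `boundary`, `discriminant`, `lambda` (cubic coefficients; `NA` for
#'   subsidy parameter sets, where the equation is non-polynomial and the
#'   equilibria are counted numerically), `n_interior`, and `roots`, a tibble
#'   of all real roots with per-root positivity flags (`C_J_pos`, `C_A_pos`,
#'   `R_pos`). Use [generics::tidy()] / [generics::glance()] for tabular
#'   views.
#' @export
#' @examples
#' ass_condition(default_params("additional"))
ass_condition <- function(params, boundary_tol = 1e-12,
                          require_resources = TRUE) {
  stopifnot(inherits(params, "niche_params"))
  subsidised <- params$scenario == "additional" &&
    (any(p_subsidy(params, "J")) || any(p_subsidy(params, "A")))
  if (subsidised) {
    roots <- intersect_zngi_numeric(params)
    lambda <- stats::setNames(rep(NA_real_, 4), paste0("lambda", 1:4))
    disc <- NA_real_
    boundary <- FALSE
    n_real <- nrow(roots)
  } else {
    cubic <- reduced_cubic(params)
    lambda <- cubic$lambda
    disc <- cubic_discriminant(lambda)
    boundary <- cubic$degree == 3 &&
      abs(disc) < boundary_tol * max(abs(lambda))^4
    roots <- cubic_roots(cubic)
    n_real <- nrow(roots)
  }
  flags <- purrr::pmap(roots, function(C_J, merged) {
    C_A <- if (C_J > 0) zngi_adult(params, C_J) else NA_real_
    R <- if (is.finite(C_A) && C_A > 0 && C_J > 0) {
      resource_equilibrium(params, C_J, C_A)[active_resources(params)]
    } else NA_real_
    tibble::tibble(C_J = C_J, C_A = C_A, merged = merged,
                   C_J_pos = C_J > 0,
                   C_A_pos = is.finite(C_A) && C_A > 0,
                   R_pos = all(is.finite(R)) && all(R > 0))
  })
  roots <- if (length(flags)) dplyr::bind_rows(flags) else
    tibble::tibble(C_J = numeric(), C_A = numeric(), merged = logical(),
                   C_J_pos = logical(), C_A_pos = logical(), R_pos = logical())
  admissible <- roots$C_J_pos & roots$C_A_pos & !roots$merged
  if (require_resources) admissible <- admissible & roots$R_pos
  n_interior <- sum(admissible)
  three_distinct <- if (subsidised) n_real == 3 else
    (is.finite(disc) && disc > 0 && !any(roots$merged))
  structure(
    list(ass_exists = three_distinct && n_interior == 3,
         boundary = boundary, discriminant = disc, lambda = lambda,
         lambda1_sign = sign(lambda[["lambda1"]]),
         n_interior = n_interior, roots = roots,
         scenario = params$scenario),
    class = "ass_diagnostics"
  )
}

cubic_discriminant <- function(lambda) {
  L1 <- lambda[[1]]; L2 <- lambda[[2]]; L3 <- lambda[[3]]; L4 <- lambda[[4]]
  18 * L1 * L2 * L3 * L4 - 4 * L2^3 * L4 + L2^2 * L3^2 -
    4 * L1 * L3^3 - 27 * L1^2 * L4^2
}

#' @export
print.ass_diagnostics <- function(x, ...) {
  cat(sprintf("<ASS diagnostics, scenario '%s'>\n", x$scenario))
  cat(sprintf("  ass_exists: %s%s\n", x$ass_exists,
              if (x$boundary) " (boundary: discriminant near zero)" else ""))
  cat(sprintf("  discriminant: %s\n", format(x$discriminant)))
  cat(sprintf("  interior equilibria: %d\n", x$n_interior))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ass_condition
#' @param x An `ass_diagnostics` object.
#' @param ... Unused.
#' @method tidy ass_diagnostics
#' @export
tidy.ass_diagnostics <- function(x, ...) {
  x$roots
}

#' @rdname ass_condition
#' @method glance ass_diagnostics
#' @export
glance.ass_diagnostics <- function(x, ...) {
  tibble::tibble(ass_exists = x$ass_exists, boundary = x$boundary,
                 discriminant = x$discriminant, n_interior = x$n_interior,
                 scenario = x$scenario)
}
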