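#' Zero-net-growth isoclines
#'
#' The coexistence equilibria of each scenario are found by eliminating the
#' resources (via [resource_equilibrium()]) and intersecting two isoclines in
#' the plane of juvenile and adult abundance:
#'
#' * `zngi_adult()` solves the adult balance `dC_A/dt = 0` for `C_A` given
#'   `C_J`: maturation inflow equals adult mortality.
#' * `zngi_juvenile()` solves the total-population balance
#'   `d(C_J + C_A)/dt = 0` for `C_J` given `C_A`: reproduction equals total
#'   mortality.
#'
#' For the additional-resource and multiple-habitat scenarios both isoclines
#' are upward-convex quadratics through the origin; for the interstage-sharing
#' scenario they are rational functions (upward-convex quadratic numerator
#' over a linearly increasing denominator). In the multiple-habitat scenario
#' the abundances are per habitat class and the isoclines carry the habitat
#' ratio `n_J/n_A`, which is how changes in stage-specific habitat number
#' shift the resource balance between stages.
#'
#' @inheritParams rhs
#' @param C_J,C_A Consumer abundance (vectorised).
#' @return Abundance on the isocline (same length as the input). Values can
#'   be negative where no feasible balance exists; callers filter.
#' @export
#' @examples
#' p <- default_params("additional")
#' zngi_adult(p, C_J = 5)
zngi_adult <- function(params, C_J) {
  stopifnot(all(C_J >= 0))
  UseMethod("zngi_adult")
}

#' @export
zngi_adult.additional_params <- function(params, C_J) {
  vapply(C_J, function(u) {
    R <- resource_equilibrium(params, u, 0)[seq_len(params$n_J)]
    sum(params$b_J * params$a_J * R) * u / params$d_A
  }, numeric(1))
}

#' @export
zngi_adult.habitats_params <- function(params, C_J) {
  rho <- params$n_J / params$n_A
  R_J <- params$K_J * (1 - params$a_J * C_J / params$r_J)
  rho * params$b_J * params$a_J * R_J * C_J / params$d_A
}

#' @export
zngi_adult.sharing_params <- function(params, C_J) {
  co <- sharing_coefficients(params)
  den <- params$d_A + co$Q * C_J
  if (any(den <= 0)) {
    stop("adult isocline undefined: denominator non-positive", call. = FALSE)
  }
  C_J * (co$p0 + co$p1 * C_J) / den
}

#' @rdname zngi_adult
#' @export
zngi_juvenile <- function(params, C_A) {
  stopifnot(all(C_A >= 0))
  UseMethod("zngi_juvenile")
}

#' @export
zngi_juvenile.additional_params <- function(params, C_A) {
  vapply(C_A, function(v) {
    nJ <- params$n_J
    R <- resource_equilibrium(params, 0, v)[nJ + seq_len(params$n_A)]
    v * (sum(params$b_A * params$a_A * R) - params$d_A) / params$d_J
  }, numeric(1))
}

#' @export
zngi_juvenile.habitats_params <- function(params, C_A) {
  rho <- params$n_J / params$n_A
  R_A <- params$K_A * (1 - params$a_A * C_A / params$r_A)
  C_A * (params$b_A * params$a_A * R_A - params$d_A) / (rho * params$d_J)
}

#' @export
zngi_juvenile.sharing_params <- function(params, C_A) {
  co <- sharing_coefficients(params)
  den <- params$d_J + co$S * C_A
  if (any(den <= 0)) {
    stop("juvenile isocline undefined: denominator non-positive", call. = FALSE)
  }
  C_A * (co$q0 - params$d_A + co$q1 * C_A) / den
}

# Aggregated interaction coefficients of the sharing scenario at resource
# equilibrium. Juvenile intake sum: L_A(C_J) - Q C_A with
# L_A = p0 + p1 C_J; adult intake sum: q0 + q1 C_A - S C_J.
sharing_coefficients <- function(params) {
  with(params, list(
    p0 = b_JJ * a_JJ * K_J + b_JA * a_JA * K_A,
    p1 = -(b_JJ * a_JJ^2 * K_J / r_J + b_JA * a_JA^2 * K_A / r_A),
    Q = b_JJ * a_JJ * K_J * a_AJ / r_J + b_JA * a_JA * K_A * a_AA / r_A,
    q0 = b_AA * a_AA * K_A + b_AJ * a_AJ * K_J,
    q1 = -(b_AA * a_AA^2 * K_A / r_A + b_AJ * a_AJ^2 * K_J / r_J),
    S = b_AA * a_AA * K_A * a_JA / r_A + b_AJ * a_AJ * K_J * a_JJ / r_J
  ))
}

#' Sample both isoclines for plotting
#'
#' @inheritParams rhs
#' @param C_max Upper end of the abundance range sampled on each axis;
#'   defaults to the consumer abundance that exhausts the most sensitive
#'   logistic resource.
#' @param n Number of grid points per curve.
#' @return A tibble with columns `curve` (`"ZNGI_A"` / `"ZNGI_J"`), `C_J` and
#'   `C_A`, restricted to the non-negative branch.
#' @seealso [plot_zngi()]
#' @export
zngi_curves <- function(params, C_max = NULL, n = 201) {
  if (is.null(C_max)) C_max <- feasible_C_max(params)
  u <- seq(0, C_max, length.out = n)
  adult <- tibble::tibble(curve = "ZNGI_A", C_J = u,
                          C_A = zngi_adult(params, u))
  juv <- tibble::tibble(curve = "ZNGI_J", C_J = zngi_juvenile(params, u),
                        C_A = u)
  dplyr::filter(dplyr::bind_rows(adult, juv), .data$C_A >= 0, .data$C_J >= 0)
}

# Largest consumer abundance compatible with positive logistic resources on
# the corresponding axis (used as a scan bound, not a hard constraint).
feasible_C_max <- function(params) {
  switch(params$scenario,
    additional = {
      logistic <- !p_subsidy(params, "J")
      if (any(logistic)) max(params$r_J[logistic] / params$a_J[logistic])
      else 10 * max(donor_eq(params$I_J, params$l_J), 1)
    },
    multiple = params$r_J / params$a_J,
    sharing = params$r_J / params$a_JJ
  )
}
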