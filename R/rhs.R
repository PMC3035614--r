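#' Model right-hand sides
#'
#' Time derivative of the state vector for each scenario. Resources grow
#' logistically (or follow donor control `I - l R` when flagged as subsidies)
#' and are consumed through linear (mass-action) trophic interactions;
#' maturation (juvenile -> adult) is proportional to juvenile food intake and
#' reproduction (adult -> juvenile) to adult food intake, with stage-specific
#' background mortality.
#'
#' Scenario `additional` (resources `R_J1..`, `R_A1..`, stages `C_J`, `C_A`):
#' \deqn{dR_{J,i}/dt = r_{J,i} R_{J,i}(1 - R_{J,i}/K_{J,i}) - a_{J,i} R_{J,i} C_J}
#' \deqn{dC_J/dt = \sum_i b_{A,i} a_{A,i} R_{A,i} C_A -
#'   \sum_i b_{J,i} a_{J,i} R_{J,i} C_J - d_J C_J}
#' \deqn{dC_A/dt = \sum_i b_{J,i} a_{J,i} R_{J,i} C_J - d_A C_A}
#' and analogously for the adult-side resources.
#'
#' Scenario `multiple` adds one consumer class per habitat; each recruitment
#' flow is pooled over source habitats and split evenly (factor `1/n`) across
#' destination habitats, reflecting random colonisation.
#'
#' Scenario `sharing` has one resource per stage but both stages consume both
#' resources with rates `a_JJ`, `a_JA`, `a_AJ`, `a_AA`.
#'
#' @param params A [scenario_params] object.
#' @param state Named or unnamed non-negative state vector in canonical order
#'   (resources, then juvenile classes, then adult classes).
#' @return Named numeric derivative vector, same length as `state`.
#' @export
#' @examples
#' p <- default_params("additional")
#' rhs(p, state_template(p, C_J = 1, C_A = 1))
rhs <- function(params, state) {
  if (length(state) != state_dim(params)) {
    stop("state length does not match the scenario dimensions", call. = FALSE)
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state must be non-negative and finite", call. = FALSE)
  }
  stats::setNames(rhs_raw(params, state), state_names(params))
}

# Unchecked core used by both rhs() and the integrator (which may hand in
# slightly negative values within solver tolerance; terms are mass-action so
# the formulas remain meaningful).
rhs_raw <- function(params, state) {
  UseMethod("rhs_raw")
}

#' @export
rhs_raw.additional_params <- function(params, state) {
  nJ <- params$n_J; nA <- params$n_A
  R_J <- state[seq_len(nJ)]
  R_A <- state[nJ + seq_len(nA)]
  C_J <- state[nJ + nA + 1]
  C_A <- state[nJ + nA + 2]
  growth_J <- ifelse(p_subsidy(params, "J"),
                     params$I_J - params$l_J * R_J,
                     params$r_J * R_J * (1 - R_J / params$K_J))
  growth_A <- ifelse(p_subsidy(params, "A"),
                     params$I_A - params$l_A * R_A,
                     params$r_A * R_A * (1 - R_A / params$K_A))
  dR_J <- growth_J - params$a_J * R_J * C_J
  dR_A <- growth_A - params$a_A * R_A * C_A
  maturation <- sum(params$b_J * params$a_J * R_J) * C_J
  reproduction <- sum(params$b_A * params$a_A * R_A) * C_A
  dC_J <- reproduction - maturation - params$d_J * C_J
  dC_A <- maturation - params$d_A * C_A
  c(dR_J, dR_A, dC_J, dC_A)
}

#' @export
rhs_raw.habitats_params <- function(params, state) {
  nJ <- as.integer(params$n_J); nA <- as.integer(params$n_A)
  K_J <- habitat_K(params, "J"); K_A <- habitat_K(params, "A")
  R_J <- state[seq_len(nJ)]
  R_A <- state[nJ + seq_len(nA)]
  C_J <- state[nJ + nA + seq_len(nJ)]
  C_A <- state[nJ + nA + nJ + seq_len(nA)]
  dR_J <- params$r_J * R_J * (1 - R_J / K_J) - params$a_J * R_J * C_J
  dR_A <- params$r_A * R_A * (1 - R_A / K_A) - params$a_A * R_A * C_A
  maturation_i <- params$b_J * params$a_J * R_J * C_J   # per juvenile habitat
  reproduction_i <- params$b_A * params$a_A * R_A * C_A # per adult habitat
  dC_J <- sum(reproduction_i) / nJ - maturation_i - params$d_J * C_J
  dC_A <- sum(maturation_i) / nA - params$d_A * C_A
  c(dR_J, dR_A, dC_J, dC_A)
}

#' @export
rhs_raw.sharing_params <- function(params, state) {
  R_J <- state[1]; R_A <- state[2]; C_J <- state[3]; C_A <- state[4]
  dR_J <- params$r_J * R_J * (1 - R_J / params$K_J) -
    params$a_JJ * R_J * C_J - params$a_AJ * R_J * C_A
  dR_A <- params$r_A * R_A * (1 - R_A / params$K_A) -
    params$a_AA * R_A * C_A - params$a_JA * R_A * C_J
  juvenile_intake <- params$b_JJ * params$a_JJ * R_J +
    params$b_JA * params$a_JA * R_A
  adult_intake <- params$b_AA * params$a_AA * R_A +
    params$b_AJ * params$a_AJ * R_J
  dC_J <- adult_intake * C_A - juvenile_intake * C_J - params$d_J * C_J
  dC_A <- juvenile_intake * C_J - params$d_A * C_A
  c(dR_J, dR_A, dC_J, dC_A)
}

#' Resource equilibria for given consumer abundances
#'
#' Closed-form steady-state resource abundances given juvenile and adult
#' abundances. For a logistic resource consumed only by its own stage,
#' \eqn{R^* = K (1 - a C / r)}; for the interstage-sharing scenario the
#' joint-consumption form \eqn{R_J^* = K_J(1 - (a_{JJ} C_J + a_{AJ} C_A)/r_J)}
#' (and symmetrically for the adult resource) is used, since both stages
#' deplete each resource. Subsidy resources rest at \eqn{I / (l + a C)}.
#' Values may be negative for over-exploitative consumer abundances; callers
#' decide feasibility.
#'
#' @inheritParams rhs
#' @param C_J,C_A Per-class consumer abundances (scalars; in the
#'   multiple-habitat scenario every habitat of a stage carries the same
#'   abundance, the symmetric case used by the analytic branch).
#' @return Named vector of resource abundances, juvenile-side first.
#' @export
#' @examples
#' resource_equilibrium(default_params("additional"), C_J = 5, C_A = 0)
resource_equilibrium <- function(params, C_J, C_A) {
  stopifnot(C_J >= 0, C_A >= 0)
  res <- switch(params$scenario,
    additional = {
      rj <- ifelse(p_subsidy(params, "J"),
                   params$I_J / (params$l_J + params$a_J * C_J),
                   params$K_J * (1 - params$a_J * C_J / params$r_J))
      ra <- ifelse(p_subsidy(params, "A"),
                   params$I_A / (params$l_A + params$a_A * C_A),
                   params$K_A * (1 - params$a_A * C_A / params$r_A))
      # a dormant subsidy channel (I = 0) is empty even when l + aC = 0
      rj[p_subsidy(params, "J") & params$I_J == 0] <- 0
      ra[p_subsidy(params, "A") & params$I_A == 0] <- 0
      c(rj, ra)
    },
    multiple = c(
      habitat_K(params, "J") * (1 - params$a_J * C_J / params$r_J),
      habitat_K(params, "A") * (1 - params$a_A * C_A / params$r_A)
    ),
    sharing = c(
      params$K_J * (1 - (params$a_JJ * C_J + params$a_AJ * C_A) / params$r_J),
      params$K_A * (1 - (params$a_AA * C_A + params$a_JA * C_J) / params$r_A)
    )
  )
  n_res <- length(res)
  stats::setNames(res, state_names(params)[seq_len(n_res)])
}
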