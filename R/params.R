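#' Scenario parameter sets
#'
#' Constructors for the three model scenarios of stage-structured
#' consumer-resource dynamics coupled by an ontogenetic niche shift:
#'
#' * `additional_resources()` — juveniles and adults each exploit a set of
#'   `n_J` / `n_A` independent resources in their own habitat. Individual
#'   resources may optionally be allochthonous subsidies with donor-controlled
#'   (input-loss) dynamics instead of logistic growth.
#' * `multiple_habitats()` — juveniles and adults each colonise `n_J` / `n_A`
#'   habitats, one logistic resource per habitat, with identical rates in all
#'   habitats of a stage; recruits are split evenly across destination
#'   habitats (random colonisation). Per-habitat carrying-capacity overrides
#'   introduce environmental heterogeneity.
#' * `interstage_sharing()` — a single juvenile and a single adult resource,
#'   but both stages may consume both resources, at stage-by-resource rates
#'   `a_JJ`, `a_JA`, `a_AJ`, `a_AA` (first index: consumer stage, second:
#'   resource).
#'
#' All rates use the same conventions: `r` intrinsic resource growth (1/time),
#' `K` carrying capacity (abundance), `a` per-capita consumption
#' (1/(abundance x time)), `b` conversion efficiency (dimensionless, in (0,1]),
#' `d` stage death rate (1/time). Maturation and reproduction are proportional
#' to juvenile and adult food intake respectively.
#'
#' @param n_J,n_A Number of juvenile / adult resources (or habitats).
#'   Positive integers for simulation; `multiple_habitats()` also accepts
#'   non-integer values for the analytic (ZNGI / cubic) branch.
#' @param r_J,r_A Intrinsic growth rate(s). Scalar or length `n_J` / `n_A`
#'   vectors for `additional_resources()`.
#' @param K_J,K_A Carrying capacities, recycled like `r_J` / `r_A`.
#' @param a_J,a_A Consumption rates.
#' @param b_J,b_A Conversion efficiencies.
#' @param d_J,d_A Stage-specific death rates.
#' @param subsidy_J,subsidy_A Logical vectors flagging resources that are
#'   allochthonous subsidies (donor control `dR/dt = I - l R - a R C`).
#' @param I_J,I_A Subsidy input rates (abundance/time); used only where the
#'   subsidy flag is set.
#' @param l_J,l_A Subsidy loss rates (1/time).
#' @param K_J_override,K_A_override Optional per-habitat carrying capacities
#'   for `multiple_habitats()` (length must equal the integer habitat count);
#'   `NULL` keeps the homogeneous value.
#' @param a_JJ,a_JA,a_AJ,a_AA Stage-by-resource consumption rates for
#'   `interstage_sharing()`; own-resource rates must be positive, cross rates
#'   may be zero.
#' @param b_JJ,b_JA,b_AJ,b_AA Matching conversion efficiencies.
#'
#' @return An object of class `niche_params` (subclass `additional_params`,
#'   `habitats_params` or `sharing_params`): a validated list of the fields
#'   above plus a `scenario` tag.
#' @seealso [default_params()] for the reference parameterisations,
#'   [set_param()] to modify single entries, [rhs()] for the dynamics.
#' @examples
#' p <- additional_resources(n_J = 2, n_A = 2, K_J = c(10, 20), K_A = 10)
#' p
#' rhs(p, state_template(p))
#' @name scenario_params
NULL

#' @rdname scenario_params
#' @export
additional_resources <- function(n_J = 2, n_A = 2,
                                 r_J = 1, r_A = 1,
                                 K_J = 10, K_A = 10,
                                 a_J = 0.1, a_A = 0.1,
                                 b_J = 0.5, b_A = 0.5,
                                 d_J = 0.1, d_A = 0.1,
                                 subsidy_J = FALSE, subsidy_A = FALSE,
                                 I_J = 0, I_A = 0,
                                 l_J = 0, l_A = 0) {
  n_J <- check_count(n_J, "n_J")
  n_A <- check_count(n_A, "n_A")
  p <- list(
    scenario = "additional", n_J = n_J, n_A = n_A,
    r_J = rep_len(r_J, n_J), r_A = rep_len(r_A, n_A),
    K_J = rep_len(K_J, n_J), K_A = rep_len(K_A, n_A),
    a_J = rep_len(a_J, n_J), a_A = rep_len(a_A, n_A),
    b_J = rep_len(b_J, n_J), b_A = rep_len(b_A, n_A),
    d_J = d_J, d_A = d_A,
    subsidy_J = rep_len(as.logical(subsidy_J), n_J),
    subsidy_A = rep_len(as.logical(subsidy_A), n_A),
    I_J = rep_len(I_J, n_J), I_A = rep_len(I_A, n_A),
    l_J = rep_len(l_J, n_J), l_A = rep_len(l_A, n_A)
  )
  validate_params(structure(p, class = c("additional_params", "niche_params")))
}

#' @rdname scenario_params
#' @export
multiple_habitats <- function(n_J = 2, n_A = 2,
                              r_J = 1, r_A = 1,
                              K_J = 10, K_A = 10,
                              a_J = 0.1, a_A = 0.1,
                              b_J = 0.5, b_A = 0.5,
                              d_J = 0.1, d_A = 0.1,
                              K_J_override = NULL, K_A_override = NULL) {
  stopifnot(length(n_J) == 1, length(n_A) == 1, n_J > 0, n_A > 0)
  p <- list(
    scenario = "multiple", n_J = n_J, n_A = n_A,
    r_J = r_J, r_A = r_A, K_J = K_J, K_A = K_A,
    a_J = a_J, a_A = a_A, b_J = b_J, b_A = b_A,
    d_J = d_J, d_A = d_A,
    K_J_override = K_J_override, K_A_override = K_A_override
  )
  validate_params(structure(p, class = c("habitats_params", "niche_params")))
}

#' @rdname scenario_params
#' @export
interstage_sharing <- function(r_J = 1, r_A = 1,
                               K_J = 15, K_A = 15,
                               a_JJ = 0.1, a_JA = 0.01,
                               a_AJ = 0.01, a_AA = 0.1,
                               b_JJ = 0.5, b_JA = 0.5,
                               b_AJ = 0.5, b_AA = 0.5,
                               d_J = 0.1, d_A = 0.1) {
  p <- list(
    scenario = "sharing",
    r_J = r_J, r_A = r_A, K_J = K_J, K_A = K_A,
    a_JJ = a_JJ, a_JA = a_JA, a_AJ = a_AJ, a_AA = a_AA,
    b_JJ = b_JJ, b_JA = b_JA, b_AJ = b_AJ, b_AA = b_AA,
    d_J = d_J, d_A = d_A
  )
  validate_params(structure(p, class = c("sharing_params", "niche_params")))
}

check_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  as.integer(x)
}

check_positive <- function(p, fields) {
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be strictly positive and finite", f), call. = FALSE)
    }
  }
}

validate_params <- function(p) {
  UseMethod("validate_params")
}

#' @export
validate_params.additional_params <- function(p) {
  check_positive(p, c("r_J", "r_A", "K_J", "K_A", "a_J", "a_A",
                      "b_J", "b_A", "d_J", "d_A"))
  if (any(p$b_J > 1) || any(p$b_A > 1)) {
    stop("conversion efficiencies must lie in (0, 1]", call. = FALSE)
  }
  if (any(p$subsidy_J) || any(p$subsidy_A)) {
    if (any(p$I_J[p$subsidy_J] < 0) || any(p$I_A[p$subsidy_A] < 0) ||
        any(p$l_J[p$subsidy_J] < 0) || any(p$l_A[p$subsidy_A] < 0)) {
      stop("subsidy input and loss rates must be non-negative", call. = FALSE)
    }
  }
  p
}

#' @export
validate_params.habitats_params <- function(p) {
  check_positive(p, c("n_J", "n_A", "r_J", "r_A", "K_J", "K_A",
                      "a_J", "a_A", "b_J", "b_A", "d_J", "d_A"))
  if (p$b_J > 1 || p$b_A > 1) {
    stop("conversion efficiencies must lie in (0, 1]", call. = FALSE)
  }
  for (side in c("J", "A")) {
    ov <- p[[paste0("K_", side, "_override")]]
    if (!is.null(ov)) {
      n <- p[[paste0("n_", side)]]
      if (n != round(n)) {
        stop("carrying-capacity overrides require an integer habitat count",
             call. = FALSE)
      }
      if (length(ov) != n || any(ov <= 0)) {
        stop(sprintf("K_%s_override must have length n_%s with positive entries",
                     side, side), call. = FALSE)
      }
    }
  }
  p
}

#' @export
validate_params.sharing_params <- function(p) {
  check_positive(p, c("r_J", "r_A", "K_J", "K_A", "a_JJ", "a_AA",
                      "b_JJ", "b_JA", "b_AJ", "b_AA", "d_J", "d_A"))
  if (p$a_JA < 0 || p$a_AJ < 0) {
    stop("cross-consumption rates must be non-negative", call. = FALSE)
  }
  if (any(c(p$b_JJ, p$b_JA, p$b_AJ, p$b_AA) > 1)) {
    stop("conversion efficiencies must lie in (0, 1]", call. = FALSE)
  }
  p
}

#' Reference parameterisations
#'
#' Returns the parameter set underlying the reference bifurcation analysis of
#' each scenario: shared rates `r = 1`, `a = 0.1`, `b = 0.5`, `d = 0.1`, with
#' two resources of carrying capacity 10 per stage for the additional-resource
#' scenario, `K = 10` and two habitats per stage for the multiple-habitat
#' scenario, and `K = 15` with weak cross-consumption (`a_JA = a_AJ = 0.01`)
#' for the interstage-sharing scenario. The baseline carrying capacity of the
#' first (focal) resource in the additional-resource scenario is 10, matching
#' the multiple-habitat setting.
#'
#' @param scenario One of `"additional"`, `"multiple"`, `"sharing"`.
#' @param panel Which panel of the reference figure the set corresponds to
#'   (`"left"`, `"center"`, `"right"`); all panels share the same base values,
#'   the argument is validated for interface stability.
#' @return A [scenario_params] object.
#' @export
#' @examples
#' default_params("sharing")
default_params <- function(scenario = c("additional", "multiple", "sharing"),
                           panel = c("right", "left", "center")) {
  scenario <- match.arg(scenario)
  panel <- match.arg(panel)
  switch(scenario,
    additional = additional_resources(n_J = 2, n_A = 2, K_J = 10, K_A = 10),
    multiple = multiple_habitats(n_J = 2, n_A = 2, K_J = 10, K_A = 10),
    sharing = interstage_sharing(K_J = 15, K_A = 15, a_JA = 0.01, a_AJ = 0.01)
  )
}

#' Modify a single parameter by path
#'
#' Parameter paths name a scalar field (`"d_J"`, `"n_A"`, `"a_JA"`) or an
#' element of a per-resource vector with bracket indexing (`"K_J[2]"`,
#' `"I_A[1]"`). Used by the scan machinery to sweep axes.
#'
#' @param params A [scenario_params] object.
#' @param path Character parameter path.
#' @param value Replacement value.
#' @return The modified, re-validated parameter object.
#' @export
#' @examples
#' set_param(default_params("additional"), "K_J[2]", 25)
set_param <- function(params, path, value) {
  stopifnot(inherits(params, "niche_params"))
  m <- regmatches(path, regexec("^([A-Za-z_]+)(\\[([0-9]+)\\])?$", path))[[1]]
  if (length(m) == 0 || !m[2] %in% names(params)) {
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  field <- m[2]
  if (nzchar(m[4])) {
    i <- as.integer(m[4])
    if (i > length(params[[field]])) {
      stop(sprintf("index %d out of range for '%s'", i, field), call. = FALSE)
    }
    params[[field]][i] <- value
  } else {
    if (length(params[[field]]) > 1) {
      params[[field]][] <- value
    } else {
      params[[field]] <- value
    }
  }
  validate_params(params)
}

#' Get a parameter by path
#'
#' @inheritParams set_param
#' @return The value at `path`.
#' @export
get_param <- function(params, path) {
  m <- regmatches(path, regexec("^([A-Za-z_]+)(\\[([0-9]+)\\])?$", path))[[1]]
  if (length(m) == 0 || !m[2] %in% names(params)) {
    stop(sprintf("unknown parameter path '%s'", path), call. = FALSE)
  }
  if (nzchar(m[4])) params[[m[2]]][as.integer(m[4])] else params[[m[2]]]
}

#' @export
print.niche_params <- function(x, ...) {
  label <- switch(x$scenario,
    additional = "additional resources",
    multiple = "multiple habitats",
    sharing = "interstage resource sharing"
  )
  cat(sprintf("<niche_params: %s>\n", label))
  for (f in setdiff(names(x), "scenario")) {
    v <- x[[f]]
    if (is.null(v)) next
    cat(sprintf("  %-14s %s\n", f, paste(format(v, digits = 4), collapse = " ")))
  }
  invisible(x)
}

# Dimensions of the state vector: resources first (juvenile-side then
# adult-side), then juvenile stage classes, then adult stage classes.
state_dim <- function(params) {
  switch(params$scenario,
    additional = params$n_J + params$n_A + 2L,
    multiple = 2L * (as.integer(params$n_J) + as.integer(params$n_A)),
    sharing = 4L
  )
}

state_names <- function(params) {
  switch(params$scenario,
    additional = c(paste0("R_J", seq_len(params$n_J)),
                   paste0("R_A", seq_len(params$n_A)), "C_J", "C_A"),
    multiple = c(paste0("R_J", seq_len(params$n_J)),
                 paste0("R_A", seq_len(params$n_A)),
                 paste0("C_J", seq_len(params$n_J)),
                 paste0("C_A", seq_len(params$n_A))),
    sharing = c("R_J", "R_A", "C_J", "C_A")
  )
}

# Effective per-habitat carrying capacities for the multiple-habitat scenario.
habitat_K <- function(params, side = c("J", "A")) {
  side <- match.arg(side)
  n <- as.integer(params[[paste0("n_", side)]])
  ov <- params[[paste0("K_", side, "_override")]]
  if (is.null(ov)) rep(params[[paste0("K_", side)]], n) else ov
}

#' Build a state vector
#'
#' Assembles a named, correctly ordered state vector (resources first, then
#' juvenile classes, then adult classes). By default resources start at
#' carrying capacity (or at the donor-control equilibrium `I/l` for subsidy
#' resources, `I` when `l = 0`) and consumers at the given totals, split
#' evenly across classes.
#'
#' @param params A [scenario_params] object.
#' @param C_J,C_A Total juvenile / adult abundance.
#' @param resources Optional resource abundances (recycled); default as above.
#' @param w_J,w_A Allocation weights across juvenile / adult classes
#'   (multiple-habitat scenario only); normalised to sum to 1.
#' @return Named numeric state vector.
#' @export
#' @examples
#' state_template(default_params("multiple"), C_J = 1, w_J = c(1, 0))
state_template <- function(params, C_J = 0, C_A = 0, resources = NULL,
                           w_J = NULL, w_A = NULL) {
  stopifnot(C_J >= 0, C_A >= 0)
  res0 <- switch(params$scenario,
    additional = {
      rj <- ifelse(p_subsidy(params, "J"),
                   donor_eq(params$I_J, params$l_J), params$K_J)
      ra <- ifelse(p_subsidy(params, "A"),
                   donor_eq(params$I_A, params$l_A), params$K_A)
      c(rj, ra)
    },
    multiple = c(habitat_K(params, "J"), habitat_K(params, "A")),
    sharing = c(params$K_J, params$K_A)
  )
  if (!is.null(resources)) res0 <- rep_len(resources, length(res0))
  cons <- switch(params$scenario,
    multiple = {
      nJ <- as.integer(params$n_J); nA <- as.integer(params$n_A)
      w_J <- if (is.null(w_J)) rep(1, nJ) else rep_len(w_J, nJ)
      w_A <- if (is.null(w_A)) rep(1, nA) else rep_len(w_A, nA)
      c(C_J * w_J / sum(w_J), C_A * w_A / sum(w_A))
    },
    c(C_J, C_A)
  )
  stats::setNames(c(res0, cons), state_names(params))
}

p_subsidy <- function(params, side) {
  s <- params[[paste0("subsidy_", side)]]
  if (is.null(s)) rep(FALSE, params[[paste0("n_", side)]]) else s
}

donor_eq <- function(I, l) ifelse(I == 0, 0, I / pmax(l, .Machine$double.eps))

# Structurally present resources: a subsidy channel with zero input is
# identically empty and exempt from interior-positivity requirements.
active_resources <- function(params) {
  if (params$scenario != "additional") {
    return(rep(TRUE, state_dim(params) -
                 switch(params$scenario, multiple =
                          as.integer(params$n_J) + as.integer(params$n_A),
                        2L)))
  }
  c(!(p_subsidy(params, "J") & params$I_J == 0),
    !(p_subsidy(params, "A") & params$I_A == 0))
}
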