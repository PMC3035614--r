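#' Map the ASS region over a two-parameter plane
#'
#' Evaluates the alternative-stable-state diagnosis on a rectangular grid of
#' two parameter axes, either analytically ([ass_condition()]: cubic
#' discriminant plus equilibrium positivity) or by brute-force simulation
#' ([count_attractors()]: at least two distinct interior attractors across a
#' grid of initial conditions).
#'
#' @inheritParams rhs
#' @param x_param,y_param Parameter paths (see [set_param()]), e.g.
#'   `"K_J[2]"`, `"n_J"`, `"a_JA"`.
#' @param x_values,y_values Numeric axis grids (length >= 2).
#' @param mode `"analytic"` or `"simulation"`.
#' @param n_initials Per-axis size of the initial-condition grid
#'   (simulation mode).
#' @param require_resources Passed to [ass_condition()] (analytic mode):
#'   whether a cell needs all resources positive at every candidate
#'   equilibrium, or consumer positivity only (under which alternative
#'   states that exclude an over-exploited resource also count).
#' @param ... Passed to [count_attractors()] in simulation mode.
#' @return A tibble of class `ass_scan` with one row per grid cell: columns
#'   `x`, `y`, `ass` (logical), `boundary`, `n_equilibria`, `error`
#'   (per-cell failure message or `NA`). Attributes `x_param`, `y_param`,
#'   `mode` record provenance.
#' @export
#' @examples
#' sc <- scan_ass_region(default_params("additional"),
#'                       "K_J[2]", seq(5, 30, length.out = 6),
#'                       "K_A[2]", seq(5, 30, length.out = 6))
#' mean(sc$ass)
scan_ass_region <- function(params, x_param, x_values, y_param, y_values,
                            mode = c("analytic", "simulation"),
                            n_initials = 4, require_resources = TRUE, ...) {
  mode <- match.arg(mode)
  stopifnot(length(x_values) >= 2, length(y_values) >= 2)
  grid <- expand.grid(x = x_values, y = y_values)
  cells <- purrr::pmap(grid, function(x, y) {
    cell <- tryCatch({
      p <- set_param(set_param(params, x_param, x), y_param, y)
      if (mode == "analytic") {
        d <- ass_condition(p, require_resources = require_resources)
        tibble::tibble(ass = d$ass_exists, boundary = d$boundary,
                       n_equilibria = d$n_interior, error = NA_character_)
      } else {
        ca <- count_attractors(p, initial_grid(p, n = n_initials), ...)
        interior <- sum(ca$attractors$kind != "boundary")
        tibble::tibble(ass = interior >= 2, boundary = FALSE,
                       n_equilibria = nrow(coexistence_equilibria(p)),
                       error = NA_character_)
      }
    }, error = function(e) {
      tibble::tibble(ass = NA, boundary = NA, n_equilibria = NA_integer_,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(x = x, y = y), cell)
  })
  out <- dplyr::bind_rows(cells)
  structure(out, class = c("ass_scan", class(out)),
            x_param = x_param, y_param = y_param, mode = mode)
}

#' Subsidy-variant ASS map
#'
#' ASS map over the input rates of two allochthonous subsidy resources in the
#' additional-resource scenario (donor-controlled dynamics
#' `dR/dt = I - l R - a R C`). By default the second juvenile-side and
#' second adult-side resources are flagged as subsidies and their input
#' rates form the axes.
#'
#' @inheritParams scan_ass_region
#' @param I_J_values,I_A_values Grids of subsidy input rates for the
#'   juvenile- and adult-side subsidised resource.
#' @param subsidy_index Which resource index on each side is the subsidy.
#' @param loss Subsidy loss rate `l` applied to both subsidised resources.
#' @return An `ass_scan` tibble (axes `x` = juvenile input, `y` = adult
#'   input).
#' @export
subsidy_variant_scan <- function(params, I_J_values, I_A_values,
                                 subsidy_index = 2, loss = 0.5,
                                 mode = c("analytic", "simulation"),
                                 n_initials = 4, ...) {
  stopifnot(inherits(params, "additional_params"))
  params$subsidy_J[subsidy_index] <- TRUE
  params$subsidy_A[subsidy_index] <- TRUE
  params$l_J[subsidy_index] <- loss
  params$l_A[subsidy_index] <- loss
  scan_ass_region(params,
                  sprintf("I_J[%d]", subsidy_index), I_J_values,
                  sprintf("I_A[%d]", subsidy_index), I_A_values,
                  mode = mode, n_initials = n_initials, ...)
}

#' Search for extra stable states under habitat heterogeneity
#'
#' In the two-habitat multiple-habitat scenario, introduces a productivity
#' difference `delta` between the juvenile habitats while preserving their
#' total carrying capacity (`K_J +/- delta`), and counts distinct attractors
#' from a habitat-asymmetric set of initial conditions at each offset. With
#' sufficient heterogeneity the system can hold three or more alternative
#' states: an adult-dominated state plus two juvenile-dominated states
#' distinguished by which juvenile subpopulation dominates.
#'
#' @inheritParams rhs
#' @param deltas Productivity offsets (0 = homogeneous).
#' @param n_initials Per-axis size of the consumer grid; juvenile totals are
#'   additionally allocated to habitat corners (see [initial_grid()]).
#' @param ... Passed to [count_attractors()].
#' @return List with `max_count`, `counts` (tibble: `delta`, `count`,
#'   `n_interior`), and `best` (the `attractor_set` at the offset with the
#'   most attractors).
#' @export
heterogeneous_multistability_search <- function(params, deltas,
                                                n_initials = 4, ...) {
  stopifnot(inherits(params, "habitats_params"),
            params$n_J == 2, params$n_A == 2)
  stopifnot(all(abs(deltas) < params$K_J))
  best <- NULL
  rows <- purrr::map(deltas, function(delta) {
    p <- params
    p$K_J_override <- c(params$K_J + delta, params$K_J - delta)
    p <- validate_params(p)
    ca <- count_attractors(p, initial_grid(p, n = n_initials,
                                           allocations = "corners"), ...)
    n_interior <- sum(ca$attractors$kind != "boundary")
    if (is.null(best) || n_interior > sum(best$set$attractors$kind != "boundary")) {
      best <<- list(delta = delta, set = ca)
    }
    tibble::tibble(delta = delta, count = ca$count, n_interior = n_interior)
  })
  counts <- dplyr::bind_rows(rows)
  list(max_count = max(counts$n_interior), counts = counts, best = best)
}

#' Fraction of grid cells with alternative stable states
#'
#' @param scan An `ass_scan` result.
#' @param na.rm Drop failed cells.
#' @return Proportion of non-boundary cells with `ass = TRUE`.
#' @export
ass_area_fraction <- function(scan, na.rm = TRUE) {
  ok <- !is.na(scan$ass) & !scan$boundary
  mean(scan$ass[ok])
}
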