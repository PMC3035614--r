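#' Integrate the model forward in time
#'
#' Solves the scenario ODEs with `deSolve::ode` (lsoda). Components that fall
#' below the extinction floor are clamped to zero in the reported trajectory;
#' small solver-tolerance negatives are likewise clipped.
#'
#' @inheritParams rhs
#' @param initial Named non-negative initial state (see [state_template()]).
#' @param horizon Integration horizon (time units).
#' @param dt Output time step.
#' @param rtol,atol Solver tolerances.
#' @param floor Extinction floor: abundances below this value are reported
#'   as 0.
#' @return A tibble of class `niche_trajectory`: column `time` plus one
#'   column per state component; solver settings are kept in attributes
#'   `rtol`, `atol`, `params`.
#' @export
#' @examples
#' p <- default_params("sharing")
#' tr <- integrate_model(p, state_template(p, C_J = 1, C_A = 1), horizon = 50)
#' tail(tr)
integrate_model <- function(params, initial, horizon, dt = 1,
                            rtol = 1e-8, atol = 1e-10, floor = 1e-9) {
  stopifnot(horizon > 0, length(initial) == state_dim(params))
  if (any(initial < 0)) stop("initial state must be non-negative",
                             call. = FALSE)
  times <- seq(0, horizon, by = dt)
  f <- function(t, y, parms) list(rhs_raw(params, pmax(y, 0)))
  out <- deSolve::ode(y = stats::setNames(as.numeric(initial),
                                          state_names(params)),
                      times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed; last good time ",
         max(out[, "time"], na.rm = TRUE), call. = FALSE)
  }
  tr <- tibble::as_tibble(as.data.frame(unclass(out)))
  tr[-1][tr[-1] < floor] <- 0
  structure(tr, class = c("niche_trajectory", class(tr)),
            rtol = rtol, atol = atol, params = params)
}

#' Locate the attractor reached from one initial state
#'
#' Integrates through a transient phase (in chunks, stopping early once the
#' state is numerically stationary), then over a measurement window, and
#' classifies the long-run behaviour by the per-component oscillation
#' amplitude over that window:
#'
#' * `fixed-point` — amplitude below `amp_tol` (relative);
#' * `periodic-orbit` — sustained bounded oscillation;
#' * `boundary` — the consumer population is extinct (all stage classes below
#'   the extinction floor).
#'
#' Attractors are summarised by their time-averaged state, which is what
#' distinguishes alternative states (juvenile- vs adult-dominated) regardless
#' of whether they are points or cycles. A run whose window averages are
#' still drifting is flagged `converged = FALSE` and excluded from counts.
#'
#' @inheritParams integrate_model
#' @param transient Maximum transient time before measurement.
#' @param window Measurement window length.
#' @param chunk Transient chunk length between early-stopping checks.
#' @param amp_tol Relative amplitude below which the window is considered
#'   stationary.
#' @return An object of class `niche_attractor`: list with `kind`,
#'   `mean_state` (time-averaged named vector over the window), `amplitude`
#'   (per component), `extinct` (names of extinct components), `converged`,
#'   and `initial`.
#' @export
#' @examples
#' p <- default_params("sharing")
#' find_attractor(p, state_template(p, C_J = 1, C_A = 1))
find_attractor <- function(params, initial, transient = 2000, window = 500,
                           chunk = 250, rtol = 1e-8, atol = 1e-10,
                           amp_tol = 1e-4, floor = 1e-9) {
  state <- stats::setNames(as.numeric(initial), state_names(params))
  if (any(state < 0)) stop("initial state must be non-negative", call. = FALSE)
  f <- function(t, y, parms) list(rhs_raw(params, pmax(y, 0)))
  elapsed <- 0
  repeat {
    out <- deSolve::ode(state, c(0, chunk), f, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    state <- pmax(out[nrow(out), -1], 0)
    state[state < floor] <- 0
    elapsed <- elapsed + chunk
    deriv <- rhs_raw(params, state)
    if (max(abs(deriv)) < 1e-9 * max(1, max(state)) || elapsed >= transient) {
      break
    }
  }
  # measurement window
  times <- seq(0, window, by = min(1, window / 250))
  out <- deSolve::ode(state, times, f, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  m <- pmax(out[, -1, drop = FALSE], 0)
  m[m < floor] <- 0
  mean_state <- colMeans(m)
  amplitude <- apply(m, 2, function(x) diff(range(x)))
  scale <- pmax(mean_state, 1e-6)
  stationary <- all(amplitude / pmax(scale, 1) < amp_tol)
  # drift check: compare window halves
  h <- nrow(m) %/% 2
  drift <- abs(colMeans(m[seq_len(h), , drop = FALSE]) -
                 colMeans(m[(h + 1):nrow(m), , drop = FALSE]))
  converged <- stationary || all(drift <= pmax(1e-6, 0.02 * scale))
  consumers <- grepl("^C_", names(mean_state))
  extinct <- names(mean_state)[mean_state < 1e-6]
  kind <- if (all(mean_state[consumers] < 1e-6)) "boundary"
  else if (stationary) "fixed-point" else "periodic-orbit"
  structure(list(kind = kind, mean_state = mean_state,
                 amplitude = amplitude, extinct = extinct,
                 converged = converged,
                 initial = stats::setNames(as.numeric(initial),
                                           state_names(params))),
            class = "niche_attractor")
}

#' @export
print.niche_attractor <- function(x, ...) {
  cat(sprintf("<attractor: %s%s>\n", x$kind,
              if (!x$converged) ", not converged" else ""))
  print(round(x$mean_state, 4))
  invisible(x)
}

#' Count distinct attractors over a set of initial conditions
#'
#' Runs [find_attractor()] from every initial state and clusters the
#' converged runs by their time-averaged state (two attractors are the same
#' when every component agrees within relative tolerance `cluster_rtol`, with
#' absolute floor `cluster_atol`).
#'
#' @inheritParams find_attractor
#' @param initials List of initial state vectors (>= 2), e.g. from
#'   [initial_grid()].
#' @param cluster_rtol,cluster_atol Clustering tolerances.
#' @param ... Passed on to [find_attractor()].
#' @return An object of class `attractor_set`: list with `count` (number of
#'   distinct attractors among converged runs), `attractors` (tibble: one row
#'   per cluster with `kind`, mean abundances, basin size `n_initials`), and
#'   `runs` (per-initial tibble with cluster assignment). `tidy()` returns
#'   the per-cluster tibble.
#' @export
#' @examples
#' p <- default_params("sharing")
#' ca <- count_attractors(p, initial_grid(p, n = 3), transient = 1000)
#' ca$count
count_attractors <- function(params, initials, cluster_rtol = 1e-2,
                             cluster_atol = 1e-6, ...) {
  stopifnot(length(initials) >= 2)
  runs <- purrr::map(initials, function(x0) find_attractor(params, x0, ...))
  conv <- purrr::map_lgl(runs, "converged")
  if (!any(conv)) stop("no initial condition produced a converged run",
                       call. = FALSE)
  means <- purrr::map(runs, "mean_state")
  cluster <- rep(NA_integer_, length(runs))
  centers <- list()
  for (i in which(conv)) {
    hit <- NA_integer_
    for (k in seq_along(centers)) {
      if (states_match(means[[i]], centers[[k]], cluster_rtol, cluster_atol)) {
        hit <- k
        break
      }
    }
    if (is.na(hit)) {
      centers[[length(centers) + 1]] <- means[[i]]
      hit <- length(centers)
    }
    cluster[i] <- hit
  }
  run_tbl <- tibble::tibble(
    run = seq_along(runs),
    kind = purrr::map_chr(runs, "kind"),
    converged = conv,
    cluster = cluster,
    mean_state = means,
    initial = purrr::map(runs, "initial")
  )
  attr_tbl <- run_tbl |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      kind = dplyr::first(.data$kind),
      n_initials = dplyr::n(),
      mean_state = list(Reduce(`+`, .data$mean_state) /
                          length(.data$mean_state)),
      .groups = "drop"
    )
  mean_mat <- do.call(rbind, attr_tbl$mean_state)
  attr_tbl <- dplyr::bind_cols(
    attr_tbl[c("cluster", "kind", "n_initials")],
    tibble::as_tibble(as.data.frame(mean_mat))
  )
  structure(list(count = length(centers), attractors = attr_tbl,
                 runs = run_tbl),
            class = "attractor_set")
}

states_match <- function(x, y, rtol, atol) {
  all(abs(x - y) <= pmax(atol, rtol * pmax(abs(x), abs(y))))
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor set: %d distinct attractor(s), %d/%d runs converged>\n",
              x$count, sum(x$runs$converged), nrow(x$runs)))
  print(x$attractors)
  invisible(x)
}

#' @rdname count_attractors
#' @param x An `attractor_set`.
#' @method tidy attractor_set
#' @export
tidy.attractor_set <- function(x, ...) {
  x$attractors
}

#' @rdname count_attractors
#' @method glance attractor_set
#' @export
glance.attractor_set <- function(x, ...) {
  tibble::tibble(count = x$count,
                 n_runs = nrow(x$runs),
                 n_converged = sum(x$runs$converged),
                 n_interior = sum(x$attractors$kind != "boundary"))
}

#' Default grid of initial conditions
#'
#' Resources start at carrying capacity; total juvenile and adult abundances
#' are crossed on a log-spaced `n x n` grid spanning `c_range` (by default
#' `1e-2` to twice the largest carrying capacity). For the multiple-habitat
#' scenario, `allocations` controls how consumer totals are split across
#' habitat classes; `"corners"` adds strongly asymmetric juvenile splits,
#' which is needed to reach habitat-asymmetric attractors in heterogeneous
#' settings.
#'
#' @inheritParams rhs
#' @param n Grid points per consumer axis.
#' @param c_range Range of total consumer abundance.
#' @param allocations `"even"` or `"corners"` (multiple-habitat scenario
#'   only).
#' @return List of named initial state vectors.
#' @export
initial_grid <- function(params, n = 10, c_range = NULL,
                         allocations = c("even", "corners")) {
  allocations <- match.arg(allocations)
  if (is.null(c_range)) {
    Kmax <- switch(params$scenario,
      additional = max(params$K_J, params$K_A,
                       donor_eq(params$I_J, params$l_J),
                       donor_eq(params$I_A, params$l_A)),
      multiple = max(habitat_K(params, "J"), habitat_K(params, "A")),
      sharing = max(params$K_J, params$K_A)
    )
    c_range <- c(1e-2, 2 * Kmax)
  }
  vals <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n))
  grid <- expand.grid(C_J = vals, C_A = vals)
  w_sets <- if (params$scenario == "multiple" && allocations == "corners") {
    nJ <- as.integer(params$n_J)
    ws <- list(rep(1, nJ))
    for (i in seq_len(nJ)) {
      w <- rep(0.05, nJ); w[i] <- 1
      ws[[length(ws) + 1]] <- w
    }
    ws
  } else {
    list(NULL)
  }
  out <- list()
  for (w in w_sets) {
    out <- c(out, purrr::pmap(grid, function(C_J, C_A) {
      state_template(params, C_J = C_J, C_A = C_A, w_J = w)
    }))
  }
  out
}
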