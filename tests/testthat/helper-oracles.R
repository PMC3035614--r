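# Independent oracle: intersect the two isoclines by dense sampling and
# bisection of phi(u) = zngi_juvenile(zngi_adult(u)) - u, without touching
# the polynomial-composition path.
oracle_intersections <- function(params, n_grid = 4000, u_max = NULL) {
  if (is.null(u_max)) u_max <- nichestates:::feasible_C_max(params)
  u <- seq(u_max / n_grid, u_max * (1 - 1e-9), length.out = n_grid)
  phi <- rep(NA_real_, n_grid)
  for (i in seq_along(u)) {
    v <- tryCatch(zngi_adult(params, u[i]), error = function(e) NA_real_)
    if (is.finite(v) && v >= 0) {
      phi[i] <- tryCatch(zngi_juvenile(params, v) - u[i],
                         error = function(e) NA_real_)
    }
  }
  roots <- numeric(0)
  f <- function(x) zngi_juvenile(params, max(zngi_adult(params, x), 0)) - x
  for (i in seq_len(n_grid - 1)) {
    if (is.na(phi[i]) || is.na(phi[i + 1])) next
    if (phi[i] * phi[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(f, c(u[i], u[i + 1]), tol = 1e-13)$root)
    }
  }
  sort(roots)
}

# First fixture (fixed stream) of the sharing scenario whose three interior
# equilibria have the stable-unstable-stable structure; cached per session.
sus_sharing_point <- local({
  cache <- NULL
  function(seed = 7) {
    if (!is.null(cache)) return(cache)
    for (p in generate_fixture_params(400, "sharing", seed = seed)) {
      eq <- tryCatch(coexistence_equilibria(p), error = function(e) NULL)
      if (!is.null(eq) && nrow(eq) == 3 &&
          identical(eq$stability, c("stable", "unstable", "stable"))) {
        cache <<- list(params = p, equilibria = eq)
        return(cache)
      }
    }
    stop("no stable-unstable-stable fixture found in the stream")
  }
})

random_state <- function(params, scale = 10) {
  n <- nichestates:::state_dim(params)
  stats::setNames(stats::runif(n, 0, scale),
                  nichestates:::state_names(params))
}
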