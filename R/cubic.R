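# Minimal dense polynomial arithmetic on ascending coefficient vectors.
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i + seq_along(b) - 1] <- out[i + seq_along(b) - 1] + a[i] * b
  }
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

poly_eval <- function(coef, x) {
  out <- 0
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

#' Reduce the coexistence conditions to a cubic
#'
#' Substituting the adult isocline into the juvenile isocline (both taken at
#' resource equilibrium) and factoring out the trivial extinction root yields
#' a cubic \eqn{F(C_J^*) = \Lambda_1 (C_J^*)^3 + \Lambda_2 (C_J^*)^2 +
#' \Lambda_3 C_J^* + \Lambda_4} whose positive real roots enumerate all
#' candidate interior equilibria. For the interstage-sharing scenario the
#' rational isoclines are cleared of denominators first, so `F` is a scaled
#' version of the same object.
#'
#' @inheritParams rhs
#' @return An object of class `reduced_cubic`: list with `lambda` (named
#'   `lambda1`..`lambda4`, descending powers), `scenario`, and `degree` (the
#'   effective degree after dropping numerically zero leading coefficients).
#' @export
#' @examples
#' reduced_cubic(default_params("additional"))
reduced_cubic <- function(params) {
  stopifnot(inherits(params, "niche_params"))
  asc <- switch(params$scenario,
    additional = {
      if (any(p_subsidy(params, "J")) || any(p_subsidy(params, "A"))) {
        stop(paste("subsidy resources make the reduced equation non-cubic;",
                   "use coexistence_equilibria(), which intersects the",
                   "isoclines numerically"), call. = FALSE)
      }
      m <- c(sum(params$b_J * params$a_J * params$K_J),
             -sum(params$b_J * params$a_J^2 * params$K_J / params$r_J)) /
        params$d_A
      w <- c(sum(params$b_A * params$a_A * params$K_A) - params$d_A,
             -sum(params$b_A * params$a_A^2 * params$K_A / params$r_A)) /
        params$d_J
      compose_quadratic_isoclines(m, w)
    },
    multiple = {
      if (!is.null(params$K_J_override) || !is.null(params$K_A_override)) {
        kj <- habitat_K(params, "J"); ka <- habitat_K(params, "A")
        if (length(unique(kj)) > 1 || length(unique(ka)) > 1) {
          stop(paste("the symmetric reduction requires homogeneous habitats;",
                     "analyse heterogeneous settings by simulation"),
               call. = FALSE)
        }
      }
      rho <- params$n_J / params$n_A
      K_J <- habitat_K(params, "J")[1]; K_A <- habitat_K(params, "A")[1]
      m <- rho * params$b_J * params$a_J * K_J *
        c(1, -params$a_J / params$r_J) / params$d_A
      w <- c(params$b_A * params$a_A * K_A - params$d_A,
             -params$b_A * params$a_A^2 * K_A / params$r_A) /
        (rho * params$d_J)
      compose_quadratic_isoclines(m, w)
    },
    sharing = {
      co <- sharing_coefficients(params)
      L_A <- c(co$p0, co$p1)              # juvenile intake at C_A = 0
      D <- c(params$d_A, co$Q)            # adult-isocline denominator
      f <- poly_mul(D, D) * params$d_J
      f <- poly_add(f, poly_mul(c(0, co$S), poly_mul(L_A, D)))
      f <- poly_add(f, -(co$q0 - params$d_A) * poly_mul(L_A, D))
      f <- poly_add(f, -co$q1 * poly_mul(c(0, 1), poly_mul(L_A, L_A)))
      -f  # orient like the quadratic-isocline scenarios
    }
  )
  asc <- c(asc, numeric(4 - length(asc)))[1:4]
  scale <- max(abs(asc))
  degree <- max(which(abs(asc) > 1e-14 * max(scale, 1)), 1) - 1L
  structure(
    list(lambda = stats::setNames(rev(asc), paste0("lambda", 1:4)),
         scenario = params$scenario, degree = degree),
    class = "reduced_cubic"
  )
}

# Both isoclines quadratic through the origin: C_A = u m(u), C_J = v w(v).
# Substituting and dividing by the trivial root u = 0 gives
# F(u) = m(u) w(u m(u)) - 1.
compose_quadratic_isoclines <- function(m, w) {
  g <- c(0, m)                       # u * m(u)
  W <- poly_add(w[1], w[2] * g)      # w evaluated at the adult isocline
  poly_add(poly_mul(m, W), -1)
}

#' @export
print.reduced_cubic <- function(x, ...) {
  cat(sprintf("<reduced cubic, scenario '%s', degree %d>\n",
              x$scenario, x$degree))
  print(x$lambda)
  invisible(x)
}

#' Evaluate the reduced polynomial
#'
#' @param object A `reduced_cubic`.
#' @param C_J Points at which to evaluate (vectorised).
#' @return Numeric vector of `F(C_J)`.
#' @export
eval_cubic <- function(object, C_J) {
  poly_eval(rev(object$lambda), C_J)
}

# Real positive roots of the reduced polynomial. Roots closer than
# `merge_tol` (relative) are merged and flagged; near-real complex pairs are
# accepted as real when the imaginary part is below `imag_tol` relative to
# the root magnitude.
cubic_roots <- function(cubic, merge_tol = 1e-9, imag_tol = 1e-8) {
  asc <- rev(unname(cubic$lambda))
  asc <- asc[seq_len(cubic$degree + 1)]
  if (cubic$degree == 0) {
    return(tibble::tibble(C_J = numeric(), merged = logical()))
  }
  z <- polyroot(asc)
  keep <- abs(Im(z)) <= imag_tol * pmax(1, Mod(z))
  re <- sort(Re(z[keep]))
  if (length(re) == 0) {
    return(tibble::tibble(C_J = numeric(), merged = logical()))
  }
  merged <- logical(0)
  vals <- numeric(0)
  for (r in re) {
    if (length(vals) && abs(r - vals[length(vals)]) <=
        merge_tol * max(1, abs(r))) {
      merged[length(vals)] <- TRUE
    } else {
      vals <- c(vals, r)
      merged <- c(merged, FALSE)
    }
  }
  tibble::tibble(C_J = vals, merged = merged)
}
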