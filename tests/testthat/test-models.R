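test_that("extinction is absorbing and resources rest at carrying capacity", {
  for (scen in c("additional", "multiple", "sharing")) {
    p <- default_params(scen)
    zero <- state_template(p) * 0
    expect_equal(unname(rhs(p, zero)), rep(0, length(zero)))
    at_K <- state_template(p, C_J = 0, C_A = 0)
    expect_equal(unname(rhs(p, at_K)), rep(0, length(at_K)))
  }
})

test_that("rhs rejects malformed states", {
  p <- default_params("sharing")
  expect_error(rhs(p, c(1, 2, 3)), "length")
  expect_error(rhs(p, c(-1, 1, 1, 1)), "non-negative")
})

test_that("rhs vanishes at every reported interior equilibrium", {
  for (scen in c("additional", "multiple", "sharing")) {
    p <- default_params(scen)
    eq <- coexistence_equilibria(p)
    for (s in eq$state) {
      expect_lt(max(abs(rhs(p, s))), 1e-8)
    }
  }
})

test_that("single-habitat multiple-habitat model reduces to the one-resource model", {
  pm <- multiple_habitats(n_J = 1, n_A = 1, K_J = 12, K_A = 8, d_J = 0.15)
  pa <- additional_resources(n_J = 1, n_A = 1, K_J = 12, K_A = 8, d_J = 0.15)
  withr::with_seed(21, {
    for (i in 1:20) {
      s <- random_state(pa)
      expect_equal(unname(rhs(pm, s)), unname(rhs(pa, s)), tolerance = 1e-12)
    }
  })
})

test_that("sharing model with zero cross rates decouples into the one-resource model", {
  ps <- interstage_sharing(K_J = 15, K_A = 12, a_JA = 0, a_AJ = 0)
  pa <- additional_resources(n_J = 1, n_A = 1, K_J = 15, K_A = 12)
  withr::with_seed(22, {
    for (i in 1:20) {
      s <- random_state(pa)
      expect_equal(unname(rhs(ps, s)), unname(rhs(pa, s)), tolerance = 1e-12)
    }
  })
})

test_that("identical habitats commute with habitat permutation", {
  p <- default_params("multiple")
  perm_state <- function(s) s[c(2, 1, 3, 4, 6, 5, 7, 8)]  # swap J habitats
  withr::with_seed(23, {
    for (i in 1:10) {
      s <- random_state(p)
      expect_equal(unname(perm_state(rhs(p, s))), unname(rhs(p, perm_state(s))),
                   tolerance = 1e-12)
    }
  })
  # symmetric states keep their symmetry
  s <- state_template(p, C_J = 3, C_A = 2)
  d <- rhs(p, s)
  expect_equal(d[["C_J1"]], d[["C_J2"]])
  expect_equal(d[["C_A1"]], d[["C_A2"]])
})

test_that("resource equilibria zero the resource rows of the dynamics", {
  expect_equal(unname(resource_equilibrium(default_params("additional"), 0, 0)),
               rep(10, 4))
  p1 <- additional_resources(n_J = 1, n_A = 1, K_J = 10, K_A = 10)
  expect_equal(unname(resource_equilibrium(p1, 10, 0))[1], 0)  # C_J = r/a
  withr::with_seed(24, {
    for (scen in c("additional", "multiple", "sharing")) {
      p <- default_params(scen)
      for (i in 1:10) {
        C_J <- runif(1, 0, 8); C_A <- runif(1, 0, 8)
        R <- resource_equilibrium(p, C_J, C_A)
        n_res <- length(R)
        state <- nichestates:::equilibrium_state(p, C_J, C_A, pmax(R, 0))
        state[seq_len(n_res)] <- R  # allow negative resources in the check
        d <- nichestates:::rhs_raw(p, state)
        expect_lt(max(abs(d[seq_len(n_res)])), 1e-12)
      }
    }
  })
})

test_that("subsidy resources follow donor control", {
  p <- additional_resources(n_J = 2, n_A = 2, subsidy_J = c(FALSE, TRUE),
                            I_J = c(0, 2), l_J = c(0, 0.5))
  R <- resource_equilibrium(p, C_J = 0, C_A = 0)
  expect_equal(unname(R[2]), 2 / 0.5)  # I / l with no consumption
  R2 <- resource_equilibrium(p, C_J = 4, C_A = 0)
  expect_equal(unname(R2[2]), 2 / (0.5 + 0.1 * 4))
  # I - l R - a R C vanishes at the returned abundance
  s <- state_template(p, C_J = 4, C_A = 0,
                      resources = resource_equilibrium(p, 4, 0))
  expect_lt(abs(rhs(p, s)[["R_J2"]]), 1e-12)
  # dormant subsidy channel is empty
  p0 <- additional_resources(n_J = 2, n_A = 2, subsidy_J = c(FALSE, TRUE),
                             I_J = 0, l_J = 0)
  expect_equal(unname(resource_equilibrium(p0, 0, 0)[2]), 0)
})
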