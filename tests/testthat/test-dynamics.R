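test_that("trajectories stay non-negative and equilibria are invariant", {
  p <- default_params("additional")
  eq <- coexistence_equilibria(p)
  stable <- eq$state[[which(eq$stability == "stable")[1]]]
  tr <- integrate_model(p, stable, horizon = 200)
  expect_true(all(as.matrix(tr[-1]) >= 0))
  expect_lt(max(abs(unlist(tr[nrow(tr), -1]) - stable)), 1e-6)
  # consumer-free system rests at carrying capacity
  tr2 <- integrate_model(p, state_template(p), horizon = 50)
  expect_equal(unlist(tr2[nrow(tr2), -1]), state_template(p),
               tolerance = 1e-8)
  expect_true(all(diff(tr$time) > 0))
})

test_that("perturbations of the middle equilibrium split between attractors", {
  pt <- sus_sharing_point()
  p <- pt$params
  eq <- pt$equilibria
  middle <- eq$state[[2]]
  J <- pracma::jacobian(function(x) nichestates:::rhs_raw(p, x),
                        unname(middle))
  ev <- eigen(J)
  lead <- Re(ev$vectors[, which.max(Re(ev$values))])
  lead <- lead / max(abs(lead))
  up <- find_attractor(p, pmax(middle + 1e-3 * lead, 0))
  dn <- find_attractor(p, pmax(middle - 1e-3 * lead, 0))
  expect_false(nichestates:::states_match(up$mean_state, dn$mean_state,
                                          1e-2, 1e-6))
  # each side lands on one of the outer equilibria
  expect_lt(min(abs(up$mean_state[["C_J"]] - eq$C_J[c(1, 3)])), 1e-3)
  expect_lt(min(abs(dn$mean_state[["C_J"]] - eq$C_J[c(1, 3)])), 1e-3)
})

test_that("fixed-point attractors reproduce equilibrium records", {
  pt <- sus_sharing_point()
  p <- pt$params
  eq <- pt$equilibria
  for (i in c(1, 3)) {
    at <- find_attractor(p, pmax(eq$state[[i]] * 1.001, 0))
    expect_equal(at$kind, "fixed-point")
    expect_lt(max(abs(at$mean_state - eq$state[[i]]) /
                    pmax(1, eq$state[[i]])), 1e-4)
  }
})

test_that("attractor counting is idempotent and tolerance-robust", {
  pt <- sus_sharing_point()
  p <- pt$params
  inits <- initial_grid(p, n = 3)
  ca <- count_attractors(p, inits, transient = 3000)
  expect_equal(sum(ca$attractors$kind != "boundary"), 2)
  dup <- count_attractors(p, c(inits, inits), transient = 3000)
  expect_equal(dup$count, ca$count)
  tight <- count_attractors(p, inits, transient = 3000, rtol = 1e-9,
                            atol = 1e-11)
  expect_equal(tight$count, ca$count)
})

test_that("systems without interior equilibria settle on a boundary state", {
  p <- additional_resources(n_J = 2, n_A = 2, K_J = 0.5, K_A = 0.5)
  at <- find_attractor(p, state_template(p, C_J = 1, C_A = 1))
  expect_equal(at$kind, "boundary")
  expect_true(all(c("C_J", "C_A") %in% at$extinct))
})

test_that("homogeneous habitats give permutation-equivariant attractors", {
  p <- default_params("multiple")
  perm <- c(2, 1, 3, 4, 6, 5, 7, 8)  # swap juvenile habitats 1 and 2
  x0 <- state_template(p, C_J = 4, C_A = 1, w_J = c(1, 0.1))
  a1 <- find_attractor(p, x0, transient = 3000)
  a2 <- find_attractor(p, stats::setNames(x0[perm], names(x0)),
                       transient = 3000)
  expect_equal(unname(a2$mean_state), unname(a1$mean_state[perm]),
               tolerance = 1e-6)
})

test_that("attractor sets tidy into per-cluster summaries", {
  p <- default_params("sharing")
  ca <- count_attractors(p, initial_grid(p, n = 2), transient = 1500)
  td <- tidy(ca)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("cluster", "kind", "n_initials") %in% names(td)))
  gl <- glance(ca)
  expect_equal(gl$count, ca$count)
  expect_lte(gl$n_interior, gl$count)
})
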