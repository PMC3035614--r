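test_that("productivity plane shows ASS for balanced, none for one-sided resources", {
  sc <- scan_ass_region(default_params("additional"),
                        "K_J[2]", seq(0.5, 30, length.out = 12),
                        "K_A[2]", seq(0.5, 30, length.out = 12))
  expect_s3_class(sc, "ass_scan")
  expect_true(all(is.na(sc$error)))
  expect_true(all(sc$n_equilibria <= 3, na.rm = TRUE))
  both_large <- sc$ass[sc$x > 20 & sc$y > 20]
  expect_true(all(both_large))
  one_sided <- sc$ass[sc$x > 25 & sc$y < 1]
  expect_false(any(one_sided))
})

test_that("habitat-number plane confines ASS to comparable habitat counts", {
  sc <- scan_ass_region(default_params("multiple"),
                        "n_J", seq(0.5, 6, length.out = 16),
                        "n_A", seq(0.5, 6, length.out = 16))
  expect_gt(sum(sc$ass, na.rm = TRUE), 0)
  ratio <- sc$x[which(sc$ass)] / sc$y[which(sc$ass)]
  expect_true(all(ratio > 1 / 3 & ratio < 3))
  # strongly unequal habitat numbers never admit ASS
  unequal <- sc$ass[sc$x / sc$y > 4 | sc$y / sc$x > 4]
  expect_false(any(unequal, na.rm = TRUE))
})

test_that("cross-feeding suppresses ASS and very strong sharing redevelops them", {
  sc <- scan_ass_region(default_params("sharing"),
                        "a_JA", seq(0.001, 0.45, length.out = 14),
                        "a_AJ", seq(0.001, 0.45, length.out = 14),
                        require_resources = FALSE)
  m <- matrix(sc$ass, 14, 14)
  expect_true(m[1, 1])                     # both cross rates tiny
  expect_false(any(m[8:14, 1:2]))          # only a_JA large
  expect_false(any(m[1:2, 8:14]))          # only a_AJ large
  expect_true(all(m[12:14, 12:14]))        # both very large: redeveloped
})

test_that("analytic and simulation scan modes share the cell interface", {
  pt <- sus_sharing_point()
  base <- pt$params
  x0 <- base$a_JA
  sim <- scan_ass_region(base, "a_JA", c(x0, x0 * 1.5), "a_AJ",
                         c(base$a_AJ, base$a_AJ * 1.5), mode = "simulation",
                         n_initials = 3, transient = 2500)
  expect_true(all(c("x", "y", "ass", "boundary", "n_equilibria") %in%
                    names(sim)))
  ana <- scan_ass_region(base, "a_JA", c(x0, x0 * 1.5), "a_AJ",
                         c(base$a_AJ, base$a_AJ * 1.5), mode = "analytic")
  # at this bistable point the analytic condition and the dynamics agree
  expect_true(ana$ass[1])
  expect_true(sim$ass[1])
})

test_that("dormant subsidy channels reproduce the subsidy-free diagnosis", {
  base <- additional_resources(n_J = 2, n_A = 2, K_J = c(15, 1e-6 + 1),
                               K_A = c(15, 1e-6 + 1))
  p <- base
  p$subsidy_J[2] <- TRUE; p$subsidy_A[2] <- TRUE
  p$I_J[2] <- 0; p$I_A[2] <- 0; p$l_J[2] <- 0.5; p$l_A[2] <- 0.5
  ref <- additional_resources(n_J = 1, n_A = 1, K_J = 15, K_A = 15)
  expect_equal(ass_condition(p)$n_interior, ass_condition(ref)$n_interior)
  expect_equal(coexistence_equilibria(p)$C_J, coexistence_equilibria(ref)$C_J,
               tolerance = 1e-6)
})

test_that("subsidy balance governs the subsidised ASS region", {
  base <- additional_resources(n_J = 2, n_A = 2, K_J = c(10, 1),
                               K_A = c(10, 1))
  sc <- subsidy_variant_scan(base, I_J_values = seq(0.1, 6, length.out = 8),
                             I_A_values = seq(0.1, 6, length.out = 8),
                             loss = 0.5)
  # allochthonous inputs alone can sustain alternative stable states
  expect_gt(sum(sc$ass, na.rm = TRUE), 0)
  expect_true(all(sc$n_equilibria <= 3, na.rm = TRUE))
  # strongly one-sided subsidy corners carry no ASS
  corners <- sc$ass[(sc$x > 4 & sc$y < 0.2) | (sc$x < 0.2 & sc$y > 4)]
  expect_false(any(corners, na.rm = TRUE))
})

test_that("heterogeneity search finds three states with mirrored juvenile dominance", {
  hs <- heterogeneous_multistability_search(default_params("multiple"),
                                            deltas = c(0, 3), n_initials = 3,
                                            transient = 3000)
  expect_gte(hs$max_count, 3)
  expect_equal(nrow(hs$counts), 2)
  att <- hs$best$set$attractors
  att <- att[att$kind != "boundary", ]
  juv <- att[att$C_J1 + att$C_J2 > att$C_A1 + att$C_A2, ]
  expect_equal(nrow(juv), 2)
  # the two juvenile-dominated states mirror which habitat dominates
  expect_true(xor(juv$C_J1[1] > juv$C_J2[1], juv$C_J1[2] > juv$C_J2[2]))
  # and the remaining interior state is adult-dominated
  ad <- att[att$C_J1 + att$C_J2 <= att$C_A1 + att$C_A2, ]
  expect_gte(nrow(ad), 1)
})

test_that("scan results render as region maps", {
  sc <- scan_ass_region(default_params("additional"),
                        "K_J[2]", c(5, 15, 25), "K_A[2]", c(5, 15, 25))
  pl <- ggplot2::autoplot(sc)
  expect_s3_class(pl, "ggplot")
  pz <- plot_zngi(default_params("additional"))
  expect_s3_class(pz, "ggplot")
})
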