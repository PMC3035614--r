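test_that("interior equilibria are verified, sorted and at most three", {
  p <- default_params("additional")
  eq <- coexistence_equilibria(p)
  expect_equal(nrow(eq), 3)
  expect_true(all(diff(eq$C_J) > 0))
  expect_true(all(eq$C_J > 0 & eq$C_A > 0))
  expect_true(all(eq$residual < 1e-8))
  for (s in eq$state) expect_true(all(s > 0))
})

test_that("equilibrium count never exceeds three across random fixtures", {
  for (scen in c("additional", "multiple", "sharing")) {
    counts <- vapply(generate_fixture_params(150, scen, seed = 17),
                     function(p) nrow(coexistence_equilibria(p)), integer(1))
    expect_true(all(counts <= 3))
  }
})

test_that("middle equilibrium is unstable whenever three coexist", {
  found <- 0
  for (scen in c("additional", "multiple", "sharing")) {
    for (p in generate_fixture_params(60, scen, seed = 19)) {
      eq <- coexistence_equilibria(p)
      if (nrow(eq) == 3) {
        found <- found + 1
        expect_equal(eq$stability[2], "unstable")
      }
    }
  }
  expect_gt(found, 0)
})

test_that("ass_exists implies exactly three interior equilibria", {
  hits <- 0
  for (scen in c("additional", "multiple", "sharing")) {
    for (p in generate_fixture_params(60, scen, seed = 23)) {
      d <- ass_condition(p)
      if (d$ass_exists) {
        hits <- hits + 1
        expect_equal(nrow(coexistence_equilibria(p)), 3)
        expect_gt(d$discriminant, 0)
      }
    }
  }
  expect_gt(hits, 0)
})

test_that("strongly imbalanced second resources suppress the analytic condition", {
  p <- default_params("additional")
  imb <- set_param(set_param(p, "K_J[2]", 30), "K_A[2]", 0.05)
  expect_false(ass_condition(imb)$ass_exists)
})

test_that("consumer-free state has a stable resource sub-block", {
  p <- default_params("additional")
  s <- state_template(p)   # resources at K, no consumers
  J <- pracma::jacobian(function(x) nichestates:::rhs_raw(p, x), unname(s))
  res_block <- J[1:4, 1:4]
  expect_true(all(Re(eigen(res_block, only.values = TRUE)$values) < 0))
})

test_that("relabelling the resources leaves the sharing diagnosis invariant", {
  swap <- function(p) {
    interstage_sharing(r_J = p$r_A, r_A = p$r_J, K_J = p$K_A, K_A = p$K_J,
                       a_JJ = p$a_JA, a_JA = p$a_JJ,
                       a_AJ = p$a_AA, a_AA = p$a_AJ,
                       b_JJ = p$b_JA, b_JA = p$b_JJ,
                       b_AJ = p$b_AA, b_AA = p$b_AJ,
                       d_J = p$d_J, d_A = p$d_A)
  }
  for (p in generate_fixture_params(40, "sharing", seed = 29)) {
    for (rr in c(TRUE, FALSE)) {
      d1 <- ass_condition(p, require_resources = rr)
      d2 <- ass_condition(swap(p), require_resources = rr)
      if (!d1$boundary && !d2$boundary) {
        expect_identical(d1$ass_exists, d2$ass_exists)
      }
    }
  }
})

test_that("relaxed positivity admits states with an excluded resource", {
  p <- default_params("sharing")
  big <- set_param(set_param(p, "a_JA", 0.3), "a_AJ", 0.3)
  expect_false(ass_condition(big)$ass_exists)
  relaxed <- ass_condition(big, require_resources = FALSE)
  expect_true(relaxed$ass_exists)
  expect_false(all(tidy(relaxed)$R_pos))
})

test_that("tidy and glance provide tabular diagnostics", {
  d <- ass_condition(default_params("additional"))
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("C_J", "C_A", "C_J_pos", "R_pos") %in% names(td)))
  gl <- glance(d)
  expect_equal(nrow(gl), 1)
  expect_true(is.logical(gl$ass_exists))
})

test_that("subsidy parameter sets are analysed by numeric intersection", {
  p <- additional_resources(n_J = 2, n_A = 2, subsidy_J = c(FALSE, TRUE),
                            subsidy_A = c(FALSE, TRUE),
                            I_J = c(0, 3), I_A = c(0, 3),
                            l_J = c(0, 0.5), l_A = c(0, 0.5))
  expect_error(reduced_cubic(p), "non-cubic")
  eq <- coexistence_equilibria(p)
  expect_lte(nrow(eq), 3)
  for (s in eq$state) expect_lt(max(abs(rhs(p, s))), 1e-7)
  d <- ass_condition(p)
  expect_true(is.na(d$discriminant))
  expect_equal(d$n_interior, nrow(eq))
})
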