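test_that("design grids enumerate and filter exactly", {
  d3 <- enumerate_design("three-param")
  expect_identical(d3$n_total, 13122L)
  expect_identical(d3$n_inadmissible, 4212L)
  expect_identical(d3$n_admissible, 8910L)
  expect_identical(d3$n_infeasible, 0L)

  d4 <- enumerate_design("four-param")
  expect_identical(d4$n_total, 648L)
  expect_identical(d4$n_inadmissible, 208L)
  expect_identical(d4$n_admissible, 440L)

  # inadmissibility is exactly sigma = 0 with any nonzero correlation
  bad <- with(d3$conditions,
              sigma == 0 & (rho_cr != 0 | rho_cu != 0 | rho_ur != 0))
  expect_identical(d3$conditions$admissible, !bad)
})

test_that("factor overrides reshape the grid", {
  d <- enumerate_design("three-param",
                        overrides = list(sigma = c(0, 0.10, 0.20),
                                         n_subj = 100L,
                                         mu_c = 0.5, mu_r = 0.5))
  expect_identical(d$n_total, 2L * 3L * 3L * 27L)
  expect_error(enumerate_design("three-param",
                                overrides = list(nonsense = 1)),
               "unknown design factor")
})

test_that("inadmissible conditions are refused by the runners", {
  d <- enumerate_design("three-param")
  bad <- d$conditions[!d$conditions$admissible, ][1, ]
  expect_error(run_bias_cell(bad, reps = 2), "inadmissible")
  expect_error(run_rejection_cell(bad, reps = 2), "inadmissible")
})

test_that("bias cells are reproducible under a master seed", {
  d <- enumerate_design("three-param")
  cond <- subset(d$conditions,
                 pair_prop == 0.5 & m1 == 20 & n_subj == 10 &
                   mu_c == 0.5 & mu_r == 0.5 & sigma == 0.15 &
                   rho_cr == 0 & rho_cu == 0 & rho_ur == 0)[1, ]
  r1 <- run_bias_cell(cond, reps = 10, seed = 7)
  r2 <- run_bias_cell(cond, reps = 10, seed = 7)
  expect_identical(r1$bias, r2$bias)
  expect_identical(r1$quantiles, r2$quantiles)
  r3 <- run_bias_cell(cond, reps = 10, seed = 8)
  expect_false(identical(r1$bias, r3$bias))
  expect_true(all(r1$quantiles[1, ] <= r1$mean_estimate &
                    r1$mean_estimate <= r1$quantiles[2, ]))
})

test_that("homogeneous conditions show no noticeable bias", {
  d <- enumerate_design("three-param")
  cond <- subset(d$conditions,
                 pair_prop == 0.5 & m1 == 20 & n_subj == 1000 &
                   mu_c == 0.5 & mu_r == 0.5 & sigma == 0 &
                   rho_cr == 0 & rho_cu == 0 & rho_ur == 0)[1, ]
  res <- run_bias_cell(cond, reps = 25, seed = 3)
  expect_true(all(abs(res$bias) < 0.02))
  expect_false(any(res$noticeable))
  expect_equal(res$n_failed, 0L)
})

test_that("rejection cells run all three tests and stay in [0, 1]", {
  d <- enumerate_design("three-param",
                        overrides = list(sigma = c(0, 0.10, 0.20)))
  cond <- subset(d$conditions,
                 pair_prop == 0.5 & m1 == 8 & n_subj == 10 &
                   mu_c == 0.5 & mu_r == 0.5 & sigma == 0 &
                   rho_cr == 0 & rho_cu == 0 & rho_ur == 0)[1, ]
  res <- run_rejection_cell(cond, tests = c("aggregate", "sum"),
                            reps = 20, seed = 5)
  expect_named(res$rejection, c("aggregate", "sum"))
  expect_true(all(res$rejection >= 0 & res$rejection <= 1))
  # under homogeneity the aggregate test is valid: no runaway rejection
  expect_lt(res$rejection["aggregate"], 0.3)
})

test_that("sigma_u_only restricts heterogeneity to the u parameter", {
  d <- enumerate_design("three-param",
                        overrides = list(sigma = 0.2, n_subj = 10L,
                                         m1 = 8L, mu_c = 0.5, mu_r = 0.5))
  cond <- subset(d$conditions,
                 pair_prop == 0.5 & rho_cr == 0 & rho_cu == 0 &
                   rho_ur == 0)[1, ]
  setup3 <- mptagg:::.condition_setup(cond, sigma_u_only = TRUE)
  expect_equal(unname(setup3$dist$sd), c(0, 0, 0.2))
  expect_equal(unname(setup3$dist$mean["u"]), 0.5)
})
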