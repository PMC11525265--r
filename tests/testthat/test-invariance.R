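test_that("SAI verdicts match the pair-clustering analysis", {
  rep3 <- check_sai(mpt_pair_clustering())
  expect_false(rep3$sai)
  # violations sit exactly in the four unclustered word-pair branches
  expect_true(all(rep3$violations$tree == 1))
  expect_setequal(unique(rep3$violations$category), c("C12", "C13", "C14"))
  expect_equal(nrow(unique(rep3$violations[c("category", "branch")])), 4)
  expect_true(all(rep3$violations$parameter == "u"))

  expect_true(check_sai(mpt_pair_clustering(TRUE))$sai)

  # the singleton tree on its own is SAI
  singleton <- parse_eqn(c("single C21 u", "single C22 (1-u)"))
  expect_true(check_sai(singleton)$sai)
})

test_that("co-occurrence sets list exactly the within-branch pairs", {
  pairs3 <- cooccurrence_pairs(mpt_pair_clustering())
  key <- apply(pairs3, 1, paste, collapse = "-")
  expect_setequal(key, c("c-r", "c-u"))       # never (r, u)

  pairs4 <- cooccurrence_pairs(mpt_pair_clustering(TRUE))
  key4 <- apply(pairs4, 1, paste, collapse = "-")
  expect_setequal(key4, c("c-r", "c-u", "c-a", "u-a"))

  one <- parse_eqn(c("t A p", "t B (1-p)"))
  expect_equal(nrow(cooccurrence_pairs(one)), 0)
})

test_that("WEAI depends only on correlations of co-occurring pairs", {
  m <- mpt_pair_clustering()
  R <- diag(3); R[2, 3] <- R[3, 2] <- 0.5     # rho_RU unrestricted
  d <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = 0.2, corr = R)
  expect_true(check_weai(m, d)$weai)

  R2 <- diag(3); R2[1, 2] <- R2[2, 1] <- 0.25
  d2 <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = 0.2, corr = R2)
  w2 <- check_weai(m, d2)
  expect_false(w2$weai)
  expect_equal(w2$offending$s1, "c")
  expect_equal(w2$offending$s2, "r")

  # degenerate distribution: every covariance is zero
  d0 <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = 0)
  expect_true(check_weai(m, d0)$weai)
})

test_that("analytic branch bias is rho times sigma squared", {
  expect_identical(analytic_branch_bias(0.5, 0.3), 0.045)
  expect_identical(analytic_branch_bias(0.5, 0.15), 0.01125)
  expect_equal(analytic_branch_bias(0, 0.4), 0)
  expect_error(analytic_branch_bias(1.5, 0.1), "rho")
  expect_error(analytic_branch_bias(0.5, 0.9), "sigma")
})

test_that("analytic branch bias matches the simulator's empirical moments", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  d <- group_distribution(c("c", "r", "u"), mean = 0.5,
                          sd = c(0.3, 0.3, 0), corr = R)
  th <- sample_parameters(d, 2e5, seed = 99)
  emp_cov <- cov(th[, "c"], th[, "r"])
  emp_rho <- cor(th[, "c"], th[, "r"])
  emp_sd <- sqrt(sd(th[, "c"]) * sd(th[, "r"]))
  # exact identity at the realized probability-scale moments
  expect_equal(emp_cov, analytic_branch_bias(emp_rho, emp_sd),
               tolerance = 1e-10)
  # the nominal probit-scale correlation carries over only approximately
  expect_lt(abs(emp_cov - analytic_branch_bias(0.5, 0.3)), 0.005)
})

test_that("expected aggregate probabilities match closed forms", {
  m <- mpt_pair_clustering()
  # independent parameters, sigma_U = 0.2: E[(1-C)U^2] = 0.5 * (0.25 + 0.04)
  d <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = c(0.1, 0.1, 0.2))
  q <- population_aggregate_probabilities(m, d)
  expect_equal(unname(q$pair[c("C11", "C12", "C13", "C14")]),
               c(0.25, 0.145, 0.21, 0.395), tolerance = 1e-9)
  expect_equal(unname(q$single), c(0.5, 0.5), tolerance = 1e-9)

  # degenerate distribution: plug-in at the means
  d0 <- group_distribution(c("c", "r", "u"), mean = c(0.3, 0.6, 0.45), sd = 0)
  q0 <- population_aggregate_probabilities(m, d0)
  p0 <- category_probabilities(m, c(0.3, 0.6, 0.45))
  expect_equal(q0$pair, p0$pair, tolerance = 1e-12)
  expect_equal(q0$single, p0$single, tolerance = 1e-12)

  # correlated C and R shift E(C11) by their probability-scale covariance
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  dc <- group_distribution(c("c", "r", "u"), mean = 0.5,
                           sd = c(0.3, 0.3, 0), corr = R)
  qc <- population_aggregate_probabilities(m, dc)
  th <- sample_parameters(dc, 5e5, seed = 7)
  cov_cr <- mean(th[, "c"] * th[, "r"]) - mean(th[, "c"]) * mean(th[, "r"])
  expect_lt(abs(unname(qc$pair["C11"]) - (0.25 + cov_cr)), 0.003)
  expect_lt(abs(unname(qc$pair["C11"]) - 0.295), 0.005)
})

test_that("quadrature and Monte Carlo aggregate probabilities agree", {
  m <- mpt_pair_clustering()
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5; R[1, 3] <- R[3, 1] <- 0.25
  dists <- list(
    group_distribution(c("c", "r", "u"), mean = 0.5, sd = c(0.1, 0.1, 0.2)),
    group_distribution(c("c", "r", "u"), mean = c(0.2, 0.8, 0.5), sd = 0.15),
    group_distribution(c("c", "r", "u"), mean = 0.5, sd = 0.3, corr = R))
  for (d in dists) {
    q <- unlist(population_aggregate_probabilities(m, d))
    mc <- population_aggregate_probabilities(m, d, method = "monte-carlo",
                                             draws = 2e5, seed = 11)
    se <- unlist(attr(mc, "se"))
    expect_true(all(abs(unlist(mc) - q) <= 3 * se + 1e-12))
  }
})

test_that("aggregation bias vanishes for SAI models with independent parameters", {
  m4 <- mpt_pair_clustering(TRUE)
  for (s in c(0, 0.15, 0.3)) {
    d <- group_distribution(m4$parameters, mean = c(0.4, 0.6, 0.5, 0.5),
                            sd = s)
    pb <- population_bias(m4, d)
    expect_true(all(abs(pb$bias) < 1e-6))
  }
})

test_that("pairs-only aggregation bias reproduces the closed forms", {
  mp <- mpt_pair_clustering(pairs_only = TRUE)
  d <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = c(0, 0, 0.2))
  pb <- population_bias(mp, d)
  # u-hat = 2 p12 / (2 p12 + p13) = 0.29 / 0.50 on the exact probabilities
  expect_equal(unname(pb$estimates["u"]), 0.58, tolerance = 1e-6)
  expect_equal(unname(pb$bias["u"]), 0.08, tolerance = 1e-5)
  # c-hat = 1 - p12 / u-hat^2, r-hat = p11 / c-hat
  c_hat <- 1 - 0.145 / 0.58^2
  expect_equal(unname(pb$estimates["c"]), c_hat, tolerance = 1e-6)
  expect_equal(unname(pb$estimates["r"]), 0.25 / c_hat, tolerance = 1e-6)
})

test_that("u-bias without singletons is monotone in sigma_U", {
  mp <- mpt_pair_clustering(pairs_only = TRUE)
  biases <- sapply(c(0, 0.15, 0.3), function(s) {
    d <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = c(0, 0, s))
    population_bias(mp, d)$bias["u"]
  })
  expect_equal(biases[1], 0, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(biases[2] > biases[1] && biases[3] > biases[2])
})

test_that("sigma_U = 0 with independent C and R gives zero bias everywhere", {
  m <- mpt_pair_clustering()
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0   # rho_CR = 0; sigma_U = 0
  d <- group_distribution(c("c", "r", "u"), mean = c(0.4, 0.6, 0.5),
                          sd = c(0.3, 0.25, 0), corr = R)
  pb <- population_bias(m, d)
  expect_true(all(abs(pb$bias) < 1e-6))
})
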