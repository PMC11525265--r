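test_that("probit moment matching hits closed-form anchors", {
  expect_equal(probit_moment_match(0.5, 0), c(m = 0, s = 0))
  # pnorm(Z) is Uniform(0, 1): sd 1/sqrt(12) maps to (0, 1)
  mm <- probit_moment_match(0.5, 1 / sqrt(12))
  expect_equal(unname(mm["m"]), 0, tolerance = 1e-7)
  expect_equal(unname(mm["s"]), 1, tolerance = 1e-6)
})

test_that("moment matching agrees with a Gauss-Hermite oracle", {
  gh <- pracma::gaussHermite(120)
  oracle_moments <- function(m, s) {
    th <- pnorm(m + s * sqrt(2) * gh$x)
    mu <- sum(gh$w * th) / sqrt(pi)
    e2 <- sum(gh$w * th^2) / sqrt(pi)
    c(mu, sqrt(max(e2 - mu^2, 0)))
  }
  for (mu in c(0.2, 0.5, 0.8)) {
    for (sg in c(0, 0.15, 0.3)) {
      mm <- probit_moment_match(mu, sg)
      mom <- oracle_moments(mm["m"], mm["s"])
      expect_equal(mom[1], mu, tolerance = 1e-8)
      expect_equal(mom[2], sg, tolerance = 1e-7)
    }
  }
})

test_that("infeasible sigma raises with the attainable supremum", {
  expect_error(probit_moment_match(0.2, 0.41), "sd <")
  expect_error(probit_moment_match(0.5, 0.6), "sigma")
})

test_that("degenerate distributions sample as constants", {
  d <- group_distribution(c("c", "r", "u"), mean = c(0.3, 0.6, 0.5), sd = 0)
  th <- sample_parameters(d, 10, seed = 1)
  expect_true(all(th[, "c"] == 0.3) && all(th[, "r"] == 0.6) &&
                all(th[, "u"] == 0.5))
})

test_that("sampled parameters reproduce the requested moments", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
  d <- group_distribution(c("c", "r", "u"), mean = c(0.5, 0.5, 0.2),
                          sd = c(0.15, 0.15, 0.1), corr = R)
  n <- 2e5
  th <- sample_parameters(d, n, seed = 42)
  for (s in colnames(th)) {
    se_mean <- sd(th[, s]) / sqrt(n)
    expect_lt(abs(mean(th[, s]) - d$mean[s]), 4 * se_mean)
    expect_lt(abs(sd(th[, s]) - d$sd[s]), 4 * d$sd[s] / sqrt(2 * (n - 1)) * 2)
  }
  # correlations hold exactly on the probit scale
  pr <- qnorm(th)
  expect_lt(abs(cor(pr[, 1], pr[, 2]) - 0.5), 4 / sqrt(n))
  expect_lt(abs(cor(pr[, 1], pr[, 3])), 4 / sqrt(n))
})

test_that("the uniform special case passes a Kolmogorov-Smirnov check", {
  d <- group_distribution("p", mean = 0.5, sd = 1 / sqrt(12))
  th <- sample_parameters(d, 2e4, seed = 9)
  expect_gt(suppressWarnings(ks.test(th[, 1], "punif"))$p.value, 0.01)
})

test_that("simulated tables conserve items per tree and are reproducible", {
  m <- mpt_pair_clustering()
  d <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = 0.15)
  a <- simulate_dataset(m, d, 25, c(20, 10), seed = 5)
  expect_equal(unname(rowSums(a$counts[, a$cat_tree == 1])), rep(20, 25))
  expect_equal(unname(rowSums(a$counts[, a$cat_tree == 2])), rep(10, 25))
  b <- simulate_dataset(m, d, 25, c(20, 10), seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$theta, b$theta)
  c2 <- simulate_dataset(m, d, 25, c(20, 10), seed = 6)
  expect_false(identical(a$counts, c2$counts))
})

test_that("pooled homogeneous frequencies converge to the model probabilities", {
  m <- mpt_pair_clustering()
  dat <- simulate_dataset(m, c(0.5, 0.5, 0.5), 5000, c(20, 20), seed = 31)
  pooled <- aggregate_counts(dat)
  prop <- pooled[1:4] / sum(pooled[1:4])
  truth <- c(0.25, 0.125, 0.25, 0.375)
  se <- sqrt(truth * (1 - truth) / 1e5)
  expect_true(all(abs(prop - truth) < 4 * se))
})

test_that("pooled heterogeneous frequencies converge to the population expectation", {
  m <- mpt_pair_clustering()
  d <- group_distribution(c("c", "r", "u"), mean = 0.5, sd = c(0.1, 0.1, 0.2))
  dat <- simulate_dataset(m, d, 5000, c(20, 20), seed = 13)
  pooled <- aggregate_counts(dat)
  prop <- pooled[1:4] / sum(pooled[1:4])
  expected <- c(0.25, 0.145, 0.21, 0.395)
  # participant heterogeneity inflates the multinomial SE; allow 4x a
  # conservative binomial bound
  se <- sqrt(expected * (1 - expected) / 1e5) * 2
  expect_true(all(abs(prop - expected) < 4 * se))
})

test_that("frequency tables round-trip through CSV", {
  m <- mpt_pair_clustering()
  dat <- simulate_dataset(m, c(0.4, 0.6, 0.5), 8, c(8, 8), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_frequencies(dat, path)
  back <- read_frequencies(path, model = m)
  expect_equal(unname(back), unname(dat$counts))
  unlink(path)
})

test_that("distribution spec files are read back faithfully", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("parameters: [c, r, u]",
               "mean: [0.5, 0.5, 0.5]",
               "sd: [0.3, 0.3, 0.0]",
               "corr:",
               "  - [1.0, 0.5, 0.0]",
               "  - [0.5, 1.0, 0.0]",
               "  - [0.0, 0.0, 1.0]"), path)
  d <- read_group_distribution(path)
  expect_equal(d$corr["c", "r"], 0.5)
  expect_equal(unname(d$sd), c(0.3, 0.3, 0))
  unlink(path)
})
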