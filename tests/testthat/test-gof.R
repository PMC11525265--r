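test_that("a perfectly fitting aggregate table gives G2 = 0, p = 1", {
  m <- mpt_pair_clustering()
  res <- g2_aggregate_test(m, c(250, 125, 250, 375, 500, 500))
  expect_equal(res$statistic, 0, tolerance = 1e-8)
  expect_gt(res$p_value, 0.999)
  expect_false(res$reject)
  expect_equal(res$df, 1L)
})

test_that("the aggregate G2 matches a brute-force likelihood-ratio oracle", {
  m <- mpt_pair_clustering()
  counts <- c(250, 145, 210, 395, 500, 500)
  res <- g2_aggregate_test(m, counts)

  # oracle: constrained maximum by recursive grid refinement, saturated
  # log-likelihood in closed form
  ll <- function(th) {
    p <- unlist(category_probabilities(m, unname(as.numeric(th))))
    sum(counts * log(p))
  }
  lo <- rep(0.01, 3); hi <- rep(0.99, 3); best <- NULL
  for (round in 1:6) {
    grid <- expand.grid(seq(lo[1], hi[1], length.out = 11),
                        seq(lo[2], hi[2], length.out = 11),
                        seq(lo[3], hi[3], length.out = 11))
    vals <- apply(grid, 1, ll)
    best <- as.numeric(grid[which.max(vals), ])
    step <- (hi - lo) / 10
    lo <- pmax(best - step, 1e-4); hi <- pmin(best + step, 1 - 1e-4)
  }
  ll_sat <- sum(counts[1:4] * log(counts[1:4] / 1000)) +
    sum(counts[5:6] * log(counts[5:6] / 1000))
  g2_oracle <- 2 * (ll_sat - ll(best))
  expect_equal(res$statistic, g2_oracle, tolerance = 1e-4)
  expect_lt(res$p_value, 0.05)
})

test_that("saturated models refuse the aggregate test", {
  expect_error(g2_aggregate_test(mpt_pair_clustering(TRUE),
                                 c(1, 2, 3, 4, 5, 6)), "saturated")
})

test_that("the sum test corrects zero cells and uses df = N", {
  m <- mpt_pair_clustering()
  counts <- rbind(c(5, 3, 6, 6, 4, 4),     # no zero cell
                  c(8, 0, 6, 6, 0, 8))     # zero cells -> +0.10 everywhere
  res <- g2_sum_test(m, counts)
  expect_equal(res$corrected, c(FALSE, TRUE), ignore_attr = TRUE)
  expect_equal(res$df, 2L)

  dat <- simulate_dataset(m, c(0.5, 0.5, 0.5), 10, c(8, 8), seed = 3)
  res10 <- g2_sum_test(m, dat$counts)
  expect_equal(res10$df, 10L)
  expect_equal(res10$statistic, sum(res10$per_participant))
  expect_true(all(res10$per_participant >= -1e-8))
})

test_that("the correction adds 0.10 to every cell of the offending row", {
  m <- mpt_pair_clustering()
  row <- c(8, 0, 6, 2, 0, 8)               # singleton cell (0, 8) included
  res <- g2_sum_test(m, matrix(row, 1))
  manual <- fit_ml(m, row + 0.10, algorithm = "em")
  expect_true(res$corrected[1])
  expect_equal(res$statistic, manual$g_squared, tolerance = 1e-6)
})

test_that("a perfect per-participant fit gives a zero sum statistic", {
  m <- mpt_pair_clustering()
  row <- c(250, 125, 250, 375, 500, 500)
  res <- g2_sum_test(m, rbind(row, row))
  expect_equal(res$statistic, 0, tolerance = 1e-6)
})

test_that("the sum statistic is invariant under participant permutation", {
  m <- mpt_pair_clustering()
  dat <- simulate_dataset(m, c(0.4, 0.6, 0.5), 12, c(8, 8), seed = 8)
  s1 <- g2_sum_test(m, dat$counts)$statistic
  s2 <- g2_sum_test(m, dat$counts[sample(12), ])$statistic
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("bootstrap p-values are reproducible and use (1+k)/(B+1)", {
  m <- mpt_pair_clustering()
  dat <- simulate_dataset(m, c(0.5, 0.5, 0.5), 10, c(8, 8), seed = 21)
  b1 <- g2_sum_bootstrap_test(m, dat$counts, B = 99, seed = 4)
  b2 <- g2_sum_bootstrap_test(m, dat$counts, B = 99, seed = 4)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$null_statistics, b2$null_statistics)
  k <- sum(b1$null_statistics >= b1$statistic)
  expect_equal(b1$p_value, (1 + k) / 100)
  expect_equal(b1$B, 99L)

  # grossly misfitting data: every bootstrap sum falls below the observed
  bad <- matrix(rep(c(0, 10, 0, 10, 10, 10), 5), 5, byrow = TRUE)
  bb <- g2_sum_bootstrap_test(m, bad, B = 19, seed = 1)
  expect_equal(bb$p_value, 1 / 20)
})
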