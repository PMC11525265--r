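# Goodness-of-fit machinery: the aggregate likelihood-ratio G2 test, the
# per-participant G2 sum test with zero-cell correction, and the parametric
# bootstrap version of the sum test.

#' Aggregate G-squared goodness-of-fit test
#'
#' Fits the model to the frequencies pooled across participants and refers
#' the likelihood-ratio statistic
#' `G2 = 2 sum n log(n / (N_k p_hat))` to the central chi-squared
#' distribution with the model's degrees of freedom.  Valid under parameter
#' homogeneity; under between-participant heterogeneity in parameters that
#' violate SAI/WEAI the test is biased against the model, the more so the
#' larger the heterogeneity and the number of data points.
#'
#' @param model an identified `mpt_model` with `df >= 1`.
#' @param counts aggregated counts vector, counts matrix, or `mpt_data`
#'   (matrices are summed across rows first).
#' @param alpha significance level (default 0.05).
#' @param restarts random restarts passed to [fit_ml()].
#' @return object of class `mpt_test` with `method`, `statistic`, `df`,
#'   `p_value`, `reject`, `alpha`, `fit`.
#' @export
g2_aggregate_test <- function(model, counts, alpha = 0.05, restarts = 5) {
  stopifnot(inherits(model, "mpt_model"))
  df <- suppressWarnings(model_degrees_of_freedom(model))
  if (df < 1) stop("saturated model has no test (df = 0)")
  if (inherits(counts, "mpt_data") || !is.null(dim(counts)))
    counts <- aggregate_counts(counts)
  fit <- fit_ml(model, counts, restarts = restarts)
  structure(list(method = "aggregate-G2",
                 statistic = fit$g_squared,
                 df = as.integer(df),
                 p_value = fit$p_value,
                 reject = fit$p_value < alpha,
                 alpha = alpha,
                 fit = fit),
            class = "mpt_test")
}

# apply the zero-cell rule: +0.10 to every category frequency of any
# participant with at least one empty cell
.zero_cell_correct <- function(counts, constant = 0.10) {
  hit <- apply(counts == 0, 1, any)
  counts[hit, ] <- counts[hit, , drop = FALSE] + constant
  list(counts = counts, corrected = hit)
}

#' Per-participant G-squared sum test
#'
#' Fits the model to every participant separately, sums the individual
#' `G2_n` statistics, and refers the sum to chi-squared with
#' `N * df_individual` degrees of freedom.  Participants with any zero
#' category count have 0.10 added to *all* of their category frequencies
#' before fitting and statistic computation.  Valid under heterogeneity
#' (the model only has to hold per participant), but asymptotic in the
#' per-participant item counts.
#'
#' @param model an `mpt_model` with individual `df >= 1`.
#' @param counts participant-by-category counts matrix or `mpt_data`.
#' @param alpha significance level.
#' @param zero_cell_constant correction constant (default 0.10; set to 0 to
#'   disable).
#' @param restarts random EM restarts per participant fit (default 1).
#' @return `mpt_test` with additional `per_participant` statistics and
#'   `corrected` flags.
#' @export
g2_sum_test <- function(model, counts, alpha = 0.05,
                        zero_cell_constant = 0.10, restarts = 1) {
  stopifnot(inherits(model, "mpt_model"))
  df1 <- suppressWarnings(model_degrees_of_freedom(model))
  if (df1 < 1) stop("saturated model has no test (df = 0)")
  counts <- .align_counts(model, counts)
  zc <- .zero_cell_correct(counts, zero_cell_constant)
  fits <- fit_ml_many(model, zc$counts, restarts = restarts)
  stat <- sum(fits$g_squared)
  N <- nrow(counts)
  df <- as.integer(N * df1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(method = "sum-G2-asymptotic",
                 statistic = stat,
                 df = df,
                 p_value = p,
                 reject = p < alpha,
                 alpha = alpha,
                 per_participant = fits$g_squared,
                 corrected = zc$corrected,
                 theta = fits$theta),
            class = "mpt_test")
}

#' Parametric-bootstrap G-squared sum test
#'
#' As [g2_sum_test()], but the null distribution of the sum statistic is
#' estimated by the parametric bootstrap: each bootstrap replicate redraws
#' every participant's table from that participant's fitted parameters (the
#' no-pooling null) with the same items per tree, and the sum statistic is
#' recomputed identically, including the zero-cell rule.  The p-value uses
#' the exact-test convention `(1 + #(sum* >= sum_obs)) / (B + 1)`.
#'
#' @inheritParams g2_sum_test
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer seed; fixed seeds give reproducible p-values.
#' @return `mpt_test` with `B` and the bootstrap `null_statistics`.
#' @export
g2_sum_bootstrap_test <- function(model, counts, B = 500, alpha = 0.05,
                                  seed = 1L, zero_cell_constant = 0.10,
                                  restarts = 1) {
  stopifnot(inherits(model, "mpt_model"), B >= 19)
  obs <- g2_sum_test(model, counts, alpha = alpha,
                     zero_cell_constant = zero_cell_constant,
                     restarts = restarts)
  counts <- .align_counts(model, counts)
  N <- nrow(counts)
  K <- length(model$tree_names)
  items <- matrix(0, N, K)
  for (k in seq_len(K))
    items[, k] <- rowSums(counts[, model$cat_tree == k, drop = FALSE])
  theta_hat <- obs$theta
  P <- .cat_prob_rows(model, theta_hat)      # N x Jtot null probabilities

  boot <- with_seed(seed, {
    big <- matrix(0L, B * N, ncol(counts))
    for (k in seq_len(K)) {
      jj <- which(model$cat_tree == k)
      for (n in seq_len(N)) {
        if (items[n, k] <= 0) next
        draws <- stats::rmultinom(B, items[n, k], P[n, jj])
        big[(seq_len(B) - 1L) * N + n, jj] <- t(draws)
      }
    }
    big
  })
  zc <- .zero_cell_correct(boot, zero_cell_constant)
  fits <- fit_ml_many(model, zc$counts, restarts = restarts)
  # rows are laid out replicate-major: (b-1)*N + n -> group by replicate
  sums <- rowsum(fits$g_squared, rep(seq_len(B), each = N))[, 1]
  p <- (1 + sum(sums >= obs$statistic)) / (B + 1)
  structure(list(method = "sum-G2-bootstrap",
                 statistic = obs$statistic,
                 df = NA_integer_,
                 p_value = unname(p),
                 reject = unname(p < alpha),
                 alpha = alpha,
                 B = as.integer(B),
                 per_participant = obs$per_participant,
                 null_statistics = as.numeric(sums)),
            class = "mpt_test")
}

#' @export
print.mpt_test <- function(x, ...) {
  cat("MPT goodness-of-fit test [", x$method, "]\n", sep = "")
  cat("  statistic = ", format(round(x$statistic, 4)),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      if (!is.null(x$B)) paste0(", B = ", x$B),
      ", p = ", format(round(x$p_value, 4)),
      if (x$reject) "  -> reject" else "", "\n", sep = "")
  invisible(x)
}
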