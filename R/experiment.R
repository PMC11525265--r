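# Factorial Monte Carlo experiment runner: enumerates the simulation design
# (with admissibility filtering), and runs bias and rejection-rate cells with
# deterministic per-replicate seed substreams so that results do not depend
# on execution order or parallel scheduling.

#' Enumerate the factorial simulation design
#'
#' The three-parameter design crosses pair proportion (50% vs 100%), word
#' pairs per participant `m1` (20, 8, 4), participants `N` (1000, 10, 1),
#' means of `C` and `R` (.2, .5, .8), a common probability-scale standard
#' deviation (.00, .15, .30), and probit-scale correlations `rho_cr`,
#' `rho_cu`, `rho_ur` (.00, .25, .50): `2 * 3^8 = 13122` cells.  The
#' four-parameter design crosses items (20 vs 4, equal pairs and
#' singletons), `N` (1000 vs 10), `E(C) = E(R)` (.2 vs .5), and the same
#' sigma/correlation levels, with `rho_au = 0`, `rho_ca = rho_cu`,
#' `rho_ar = rho_ur`: `2^3 * 3^4 = 648` cells.  The mean of `u` (and `a`)
#' is fixed at .50.  Cells combining `sigma = 0` with any nonzero
#' correlation are flagged inadmissible; cells whose implied probit
#' correlation matrix is not positive semi-definite are flagged infeasible.
#'
#' @param which `"three-param"` or `"four-param"`.
#' @param overrides named list replacing factor level vectors (e.g.
#'   `list(sigma = c(0, 0.10, 0.20))`).
#' @return object of class `mpt_design`: the condition data frame plus
#'   counts `n_total`, `n_inadmissible`, `n_admissible`, `n_infeasible`.
#' @examples
#' d <- enumerate_design("three-param")
#' c(d$n_total, d$n_inadmissible, d$n_admissible)  # 13122 4212 8910
#' @export
enumerate_design <- function(which = c("three-param", "four-param"),
                             overrides = list()) {
  which <- match.arg(which)
  lv <- if (which == "three-param") list(
    pair_prop = c(0.5, 1.0),
    m1 = c(20L, 8L, 4L),
    n_subj = c(1000L, 10L, 1L),
    mu_c = c(0.2, 0.5, 0.8),
    mu_r = c(0.2, 0.5, 0.8),
    sigma = c(0, 0.15, 0.30),
    rho_cr = c(0, 0.25, 0.5),
    rho_cu = c(0, 0.25, 0.5),
    rho_ur = c(0, 0.25, 0.5)
  ) else list(
    m1 = c(20L, 4L),
    n_subj = c(1000L, 10L),
    mu_cr = c(0.2, 0.5),
    sigma = c(0, 0.15, 0.30),
    rho_cr = c(0, 0.25, 0.5),
    rho_cu = c(0, 0.25, 0.5),
    rho_ur = c(0, 0.25, 0.5)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(lv)) stop("unknown design factor: ", nm)
    lv[[nm]] <- overrides[[nm]]
  }
  grid <- do.call(expand.grid, c(lv, KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE))
  grid$model <- which
  rho_cols <- c("rho_cr", "rho_cu", "rho_ur")
  any_rho <- rowSums(abs(as.matrix(grid[rho_cols])) > 0) > 0
  grid$admissible <- !(grid$sigma == 0 & any_rho)
  grid$infeasible <- FALSE
  chk <- which(grid$admissible & grid$sigma > 0 & any_rho)
  for (i in chk) {
    R <- .condition_corr(grid[i, ])
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) grid$infeasible[i] <- TRUE
  }
  grid$condition <- seq_len(nrow(grid))
  structure(list(conditions = grid,
                 which = which,
                 n_total = nrow(grid),
                 n_inadmissible = sum(!grid$admissible),
                 n_admissible = sum(grid$admissible & !grid$infeasible),
                 n_infeasible = sum(grid$infeasible)),
            class = "mpt_design")
}

#' @export
print.mpt_design <- function(x, ...) {
  cat("Monte Carlo design (", x$which, "): ", x$n_total, " cells; ",
      x$n_inadmissible, " inadmissible, ", x$n_admissible, " admissible",
      if (x$n_infeasible) paste0(", ", x$n_infeasible, " infeasible"),
      "\n", sep = "")
  invisible(x)
}

# probit correlation matrix implied by one condition row
.condition_corr <- function(cond) {
  if (cond$model == "three-param") {
    R <- diag(3); dimnames(R) <- list(c("c","r","u"), c("c","r","u"))
    R["c","r"] <- R["r","c"] <- cond$rho_cr
    R["c","u"] <- R["u","c"] <- cond$rho_cu
    R["u","r"] <- R["r","u"] <- cond$rho_ur
  } else {
    nm <- c("c","r","u","a")
    R <- diag(4); dimnames(R) <- list(nm, nm)
    R["c","r"] <- R["r","c"] <- cond$rho_cr
    R["c","u"] <- R["u","c"] <- cond$rho_cu
    R["u","r"] <- R["r","u"] <- cond$rho_ur
    R["c","a"] <- R["a","c"] <- cond$rho_cu   # rho_ca = rho_cu
    R["a","r"] <- R["r","a"] <- cond$rho_ur   # rho_ar = rho_ur
    # rho_au = 0
  }
  R
}

# model, distribution, and items implied by one condition row
.condition_setup <- function(cond, sigma_u_only = FALSE) {
  if (cond$model == "three-param") {
    pairs_only <- !is.null(cond$pair_prop) && cond$pair_prop >= 1
    model <- mpt_pair_clustering(pairs_only = pairs_only)
    mu <- c(c = cond$mu_c, r = cond$mu_r, u = 0.5)
    items <- if (pairs_only) cond$m1 else c(cond$m1, cond$m1)
  } else {
    model <- mpt_pair_clustering(four_param = TRUE)
    mu <- c(c = cond$mu_cr, r = cond$mu_cr, u = 0.5, a = 0.5)
    items <- c(cond$m1, cond$m1)
  }
  sd <- if (sigma_u_only) {
    v <- stats::setNames(rep(0, length(mu)), names(mu)); v["u"] <- cond$sigma; v
  } else rep(cond$sigma, length(mu))
  R <- .condition_corr(cond)[names(mu), names(mu)]
  if (any(sd == 0)) { R[sd == 0, ] <- 0; R[, sd == 0] <- 0; diag(R) <- 1 }
  dist <- group_distribution(names(mu), mean = mu, sd = sd, corr = R)
  list(model = model, dist = dist, items = items)
}

#' Run one bias cell of the Monte Carlo experiment
#'
#' Draws `reps` independent datasets for the condition, fits the model to
#' each aggregated table by maximum likelihood (for `N = 1` this is the
#' single participant's no-pooling fit), and summarizes the per-parameter
#' bias `B_s = mean(theta_hat_s) - mu_s`, the 2.5%/97.5% quantiles of the
#' estimates, and a "noticeable" flag (`|B| > .10`).
#'
#' @param condition a one-row slice of `enumerate_design()$conditions`.
#' @param reps Monte Carlo replicates (default 1000).
#' @param seed master seed; replicate `r` of condition `i` uses an
#'   independent substream keyed by `(seed, i, r)`.
#' @param restarts restarts per fit.
#' @return list of class `mpt_condition_result`.
#' @export
run_bias_cell <- function(condition, reps = 1000, seed = 1L, restarts = 2) {
  stopifnot(nrow(condition) == 1)
  if (!condition$admissible) stop("condition is inadmissible (sigma = 0 with ",
                                  "nonzero correlation)")
  setup <- .condition_setup(condition)
  S <- length(setup$model$parameters)
  est <- matrix(NA_real_, reps, S,
                dimnames = list(NULL, setup$model$parameters))
  failed <- 0L
  for (r in seq_len(reps)) {
    sub <- mix_seed(seed, condition$condition, r)
    dat <- simulate_dataset(setup$model, setup$dist, condition$n_subj,
                            setup$items, seed = sub)
    fit <- tryCatch(fit_ml(setup$model, dat, restarts = restarts),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      failed <- failed + 1L   # non-convergent replicates are excluded
      next
    }
    est[r, ] <- fit$estimates
  }
  ok <- stats::complete.cases(est)
  mu <- setup$dist$mean[colnames(est)]
  bias <- colMeans(est[ok, , drop = FALSE]) - mu
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  structure(list(condition = condition,
                 reps = reps,
                 n_used = sum(ok),
                 n_failed = failed,
                 flagged = failed > 0.01 * reps,
                 bias = bias,
                 mean_estimate = colMeans(est[ok, , drop = FALSE]),
                 quantiles = qs,
                 noticeable = abs(bias) > 0.10,
                 seed = seed),
            class = "mpt_condition_result")
}

#' Run one rejection-rate cell of the Monte Carlo experiment
#'
#' Draws `reps` datasets for the condition and records, for each requested
#' test, the proportion of replicates with `p < alpha` under the
#' three-parameter pair-clustering null.  Heterogeneity here varies all
#' parameters jointly by default; `sigma_u_only = TRUE` restricts it to
#' the `u` parameter.
#'
#' @param condition one-row condition slice (three-parameter, both trees).
#' @param tests subset of `c("aggregate", "sum", "bootstrap")`.
#' @param reps Monte Carlo replicates.
#' @param alpha significance level (default .05).
#' @param B bootstrap replicates per dataset (default 500).
#' @param seed master seed (substreams per replicate).
#' @param sigma_u_only restrict heterogeneity to `u`.
#' @return list of class `mpt_condition_result` with `rejection` rates.
#' @export
run_rejection_cell <- function(condition,
                               tests = c("aggregate", "sum", "bootstrap"),
                               reps = 1000, alpha = 0.05, B = 500,
                               seed = 1L, sigma_u_only = FALSE) {
  stopifnot(nrow(condition) == 1)
  tests <- match.arg(tests, several.ok = TRUE)
  if (!condition$admissible) stop("condition is inadmissible")
  setup <- .condition_setup(condition, sigma_u_only = sigma_u_only)
  if (suppressWarnings(model_degrees_of_freedom(setup$model)) < 1)
    stop("rejection cells need a testable (df >= 1) model")
  rej <- matrix(FALSE, reps, length(tests), dimnames = list(NULL, tests))
  for (r in seq_len(reps)) {
    sub <- mix_seed(seed, condition$condition, r)
    dat <- simulate_dataset(setup$model, setup$dist, condition$n_subj,
                            setup$items, seed = sub)
    if ("aggregate" %in% tests)
      rej[r, "aggregate"] <-
        g2_aggregate_test(setup$model, dat, alpha = alpha)$reject
    if ("sum" %in% tests)
      rej[r, "sum"] <- g2_sum_test(setup$model, dat$counts,
                                   alpha = alpha)$reject
    if ("bootstrap" %in% tests)
      rej[r, "bootstrap"] <-
        g2_sum_bootstrap_test(setup$model, dat$counts, B = B, alpha = alpha,
                              seed = mix_seed(seed, condition$condition,
                                              r, 7L))$reject
  }
  structure(list(condition = condition,
                 reps = reps,
                 alpha = alpha,
                 rejection = colMeans(rej),
                 seed = seed),
            class = "mpt_condition_result")
}

#' @export
print.mpt_condition_result <- function(x, ...) {
  cat("Monte Carlo cell (condition ", x$condition$condition, ", ",
      x$reps, " replicates)\n", sep = "")
  if (!is.null(x$bias)) {
    print(data.frame(bias = round(x$bias, 4),
                     q2.5 = round(x$quantiles[1, ], 4),
                     q97.5 = round(x$quantiles[2, ], 4),
                     noticeable = x$noticeable))
    if (x$n_failed) cat(" ", x$n_failed, "replicate(s) non-convergent",
                        if (x$flagged) " [cell flagged]", "\n")
  }
  if (!is.null(x$rejection)) {
    cat("  rejection rates at alpha =", x$alpha, "\n")
    print(round(x$rejection, 4))
  }
  invisible(x)
}
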