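# Maximum-likelihood estimation for MPT models under product-multinomial
# sampling.  Two interchangeable engines: the classical EM algorithm with
# expected branch-completion counts (vectorized across many frequency rows)
# and quasi-Newton optimization on logit-transformed parameters with an
# analytic gradient.  Their log-likelihood agreement is used as a
# correctness safeguard throughout the test suite.

.EPS <- 1e-12

# log-likelihood kernel sum(n * log p) per row; counts R x J, theta R x S
.loglik_rows <- function(model, counts, theta) {
  P <- .cat_prob_rows(model, theta)
  rowSums(counts * log(pmax(P, .EPS)))
}

# saturated log-likelihood kernel per row (0 log 0 = 0)
.loglik_sat <- function(model, counts) {
  K <- length(model$tree_names)
  ll <- numeric(nrow(counts))
  for (k in seq_len(K)) {
    jj <- which(model$cat_tree == k)
    nk <- rowSums(counts[, jj, drop = FALSE])
    x <- counts[, jj, drop = FALSE]
    ll <- ll + rowSums(ifelse(x > 0, x * log(ifelse(x > 0, x, 1)), 0)) -
      ifelse(nk > 0, nk * log(ifelse(nk > 0, nk, 1)), 0)
  }
  ll
}

# EM iterations, vectorized over rows of `counts`, with an active set so
# converged rows drop out of the computation; returns list(theta, loglik,
# iterations, converged).  One branch/category probability evaluation per
# iteration serves both the convergence check and the E-step.
.em_rows <- function(model, counts, theta0, tol = 1e-10, maxit = 10000L) {
  A <- model$a; B <- model$b; AB <- A + B
  bc <- model$branch_cat
  J <- length(model$cat_labels)
  cat_of <- lapply(seq_len(J), function(j) which(bc == j))
  R <- nrow(counts)
  theta <- matrix(pmin(pmax(theta0, 1e-9), 1 - 1e-9), R)
  ll <- rep(-Inf, R)
  active <- rep(TRUE, R)
  it <- 0L
  while (any(active) && it < maxit) {
    it <- it + 1L
    idx <- which(active)
    th <- theta[idx, , drop = FALSE]
    cn <- counts[idx, , drop = FALSE]
    lt  <- log(pmax(th, .EPS)); lct <- log(pmax(1 - th, .EPS))
    Pb <- exp(tcrossprod(lt, A) + tcrossprod(lct, B))   # active x nb
    Pc <- matrix(0, length(idx), J)
    for (j in seq_len(J)) {
      jj <- cat_of[[j]]
      if (length(jj) == 1L) Pc[, j] <- Pb[, jj]
      else if (length(jj) > 1L) Pc[, j] <- rowSums(Pb[, jj, drop = FALSE])
    }
    ll_now <- rowSums(cn * log(pmax(Pc, .EPS)))
    done <- (ll_now - ll[idx]) < tol
    ll[idx] <- ll_now
    active[idx[done]] <- FALSE
    if (all(done)) break
    up <- which(!done)
    W <- cn[up, , drop = FALSE] / pmax(Pc[up, , drop = FALSE], .EPS)
    Nb <- W[, bc, drop = FALSE] * Pb[up, , drop = FALSE]  # expected branch n
    num <- Nb %*% A
    den <- Nb %*% AB
    old <- th[up, , drop = FALSE]
    new <- ifelse(den > 0, num / den, old)
    theta[idx[up], ] <- pmin(pmax(new, 1e-9), 1 - 1e-9)
  }
  list(theta = theta, loglik = ll, iterations = it,
       converged = !any(active))
}

# analytic negative log-likelihood and gradient on the logit scale (one row)
.nll_logit <- function(model, counts) {
  A <- model$a; B <- model$b; bc <- model$branch_cat
  function(eta, gradient = FALSE) {
    theta <- stats::plogis(eta)
    theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
    pb <- .branch_prob(model, theta)
    pc <- numeric(length(model$cat_labels))
    agg <- tapply(pb, bc, sum)
    pc[as.integer(names(agg))] <- agg
    nll <- -sum(counts * log(pmax(pc, .EPS)))
    if (!gradient) return(nll)
    w <- counts / pmax(pc, .EPS)                    # dll/dp_cat
    # dp_branch/dtheta_s = p_branch * (a/theta - b/(1-theta))
    gtheta <- colSums(pb * w[bc] *
                        (sweep(A, 2, theta, `/`) - sweep(B, 2, 1 - theta, `/`)))
    -(gtheta * theta * (1 - theta))
  }
}

# single-row gradient fit from one start; BFGS followed by a Newton polish
# (numeric Hessian of the analytic gradient) so the gradient-norm convergence
# criterion is met even on large-count tables; returns theta, loglik, grad_norm
.gradient_fit_once <- function(model, counts, start, reltol = 1e-14) {
  total <- sum(counts)
  # optimize the mean log-likelihood: same optimum, but gradients stay on an
  # O(1) scale so the 1e-6 gradient-norm criterion is meaningful for any n
  obj <- .nll_logit(model, counts / total)
  eta0 <- stats::qlogis(pmin(pmax(start, 1e-6), 1 - 1e-6))
  opt <- stats::optim(eta0, fn = function(e) obj(e, FALSE),
                      gr = function(e) obj(e, TRUE),
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = reltol))
  eta <- opt$par
  val <- opt$value
  g <- obj(eta, TRUE)
  for (step in seq_len(25)) {
    if (sqrt(sum(g^2)) < 1e-8 || any(abs(eta) > 12)) break
    H <- .jacobian(function(e) obj(e, TRUE), eta, h = 1e-5)
    H <- (H + t(H)) / 2
    dir <- tryCatch(solve(H + diag(1e-10, length(eta)), g),
                    error = function(e) NULL)
    if (is.null(dir)) break
    lam <- 1
    repeat {
      cand <- eta - lam * dir
      vc <- obj(cand, FALSE)
      if (vc <= val + 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    if (vc > val + 1e-12) break
    eta <- cand; val <- vc; g <- obj(eta, TRUE)
  }
  theta <- stats::plogis(eta)
  list(theta = theta, loglik = -val * total, grad_norm = sqrt(sum(g^2)))
}

#' Maximum-likelihood fit of an MPT model to aggregated frequencies
#'
#' Maximizes the product-multinomial log-likelihood
#' `sum_kj n_kj log p(C_kj | theta)` for a single (typically aggregated)
#' frequency row.  The default engine is quasi-Newton on logit-transformed
#' parameters with an analytic gradient, run from a moment-informed start
#' (a short EM refinement of the centre of the parameter space) plus
#' `restarts` deterministic random starts; the best solution by
#' log-likelihood is returned, ties broken by lexicographically smallest
#' parameter vector.  `algorithm = "em"` uses the EM engine throughout.
#'
#' @param model an `mpt_model`.
#' @param counts named numeric vector of aggregated category counts (or an
#'   `mpt_data`, which is aggregated first); fractional counts are allowed.
#' @param restarts number of additional random starts (default 5).
#' @param tolerance convergence tolerance on log-likelihood improvements.
#' @param algorithm `"gradient"` (default) or `"em"`.
#' @return object of class `mpt_fit`: `estimates`, `loglik`, `g_squared`,
#'   `df`, `p_value`, `converged`, `n_restarts`, `boundary` (per-parameter
#'   flags), `gradient_norm`, `algorithm`.
#' @examples
#' m <- mpt_pair_clustering()
#' fit_ml(m, c(250, 125, 250, 375, 500, 500))
#' @export
fit_ml <- function(model, counts, restarts = 5, tolerance = 1e-10,
                   algorithm = c("gradient", "em")) {
  stopifnot(inherits(model, "mpt_model"))
  algorithm <- match.arg(algorithm)
  if (inherits(counts, "mpt_data")) counts <- aggregate_counts(counts)
  counts <- drop(.align_counts(model, counts))
  K <- length(model$tree_names)
  for (k in seq_len(K))
    if (sum(counts[model$cat_tree == k]) <= 0)
      stop("tree '", model$tree_names[k], "' has no observations")
  S <- length(model$parameters)
  cmat <- matrix(counts, 1)

  # moment-informed start: short EM refinement from the centre
  informed <- .em_rows(model, cmat, matrix(0.5, 1, S), tol = 1e-6,
                       maxit = 50L)$theta
  starts <- rbind(informed,
                  matrix(0.5, 1, S))
  if (restarts > 0) {
    rs <- with_seed(104729L, matrix(stats::runif(restarts * S, 0.05, 0.95),
                                    restarts, S))
    starts <- rbind(starts, rs)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    cand <- if (algorithm == "gradient") {
      g <- .gradient_fit_once(model, counts, starts[i, ])
      list(theta = g$theta, loglik = g$loglik, grad_norm = g$grad_norm,
           converged = g$grad_norm < 1e-6)
    } else {
      e <- .em_rows(model, cmat, matrix(starts[i, ], 1), tol = tolerance)
      list(theta = drop(e$theta), loglik = e$loglik,
           grad_norm = NA_real_, converged = e$converged)
    }
    lex_smaller <- function(x, y) {       # x strictly before y lexicographically
      d <- which(abs(x - y) > 1e-12)
      length(d) > 0 && x[d[1]] < y[d[1]]
    }
    take <- is.null(best) || cand$loglik > best$loglik + 1e-12 ||
      (abs(cand$loglik - best$loglik) <= 1e-12 &&
         lex_smaller(cand$theta, best$theta))
    if (take) best <- cand
  }

  theta <- stats::setNames(pmin(pmax(best$theta, 0), 1), model$parameters)
  ll_sat <- .loglik_sat(model, cmat)
  g2 <- max(2 * (ll_sat - best$loglik), 0)
  df <- suppressWarnings(model_degrees_of_freedom(model))
  p <- if (df >= 1) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_
  structure(list(estimates = theta,
                 loglik = best$loglik,
                 g_squared = g2,
                 df = as.integer(df),
                 p_value = p,
                 converged = best$converged,
                 n_restarts = restarts,
                 boundary = theta < 1e-6 | theta > 1 - 1e-6,
                 gradient_norm = best$grad_norm,
                 algorithm = algorithm),
            class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("MPT maximum-likelihood fit (", x$algorithm, ")\n", sep = "")
  print(round(x$estimates, 4))
  cat("logLik ", format(x$loglik), ";  G2 = ", format(round(x$g_squared, 4)),
      ", df = ", x$df,
      if (!is.na(x$p_value)) paste0(", p = ", format(round(x$p_value, 4))),
      "\n", sep = "")
  if (!x$converged) cat("WARNING: convergence not reached\n")
  invisible(x)
}

#' Fit an MPT model separately to many frequency rows
#'
#' Vectorized no-pooling estimation: every row of `counts` is fitted by EM
#' (all rows iterated jointly in matrix form), with one common start plus
#' optional random restarts.  Used by the per-participant G-squared sum
#' tests, where thousands of small fits are needed.
#'
#' @param model an `mpt_model`.
#' @param counts matrix of category counts, one row per participant.
#' @param restarts additional random starts per row (default 2).
#' @param tolerance EM convergence tolerance on the log-likelihood.
#' @return list with `theta` (matrix), `loglik`, `g_squared` (vectors),
#'   `df` (scalar).
#' @export
fit_ml_many <- function(model, counts, restarts = 2, tolerance = 1e-10) {
  stopifnot(inherits(model, "mpt_model"))
  counts <- .align_counts(model, counts)
  R <- nrow(counts); S <- length(model$parameters)
  informed <- .em_rows(model, counts, matrix(0.5, R, S), tol = tolerance)
  best_theta <- informed$theta; best_ll <- informed$loglik
  if (restarts > 0) {
    starts <- with_seed(104729L,
                        lapply(seq_len(restarts), function(i)
                          matrix(stats::runif(R * S, 0.05, 0.95), R, S)))
    for (st in starts) {
      e <- .em_rows(model, counts, st, tol = tolerance)
      gain <- e$loglik > best_ll + 1e-10
      if (any(gain)) {
        best_theta[gain, ] <- e$theta[gain, , drop = FALSE]
        best_ll[gain] <- e$loglik[gain]
      }
    }
  }
  g2 <- pmax(2 * (.loglik_sat(model, counts) - best_ll), 0)
  colnames(best_theta) <- model$parameters
  list(theta = best_theta, loglik = best_ll, g_squared = g2,
       df = as.integer(suppressWarnings(model_degrees_of_freedom(model))))
}
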