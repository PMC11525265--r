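# Exact population-level (infinite-sample) aggregate category probabilities
# under a latent-trait group distribution, and the aggregation bias they
# induce in complete-pooling ML estimates.

# Gauss-Hermite nodes/weights, cached
.gh_cache <- new.env(parent = emptyenv())
.gh <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

# connected components of the non-degenerate correlation structure
.corr_blocks <- function(dist) {
  nd <- which(dist$sd > 0)
  if (!length(nd)) return(list())
  adj <- abs(dist$corr[nd, nd, drop = FALSE]) > 1e-12
  comp <- rep(0L, length(nd)); cur <- 0L
  for (i in seq_along(nd)) if (comp[i] == 0L) {
    cur <- cur + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0 &
                                  comp == 0L), frontier)
    }
  }
  lapply(seq_len(cur), function(cc) nd[comp == cc])
}

# E[ prod_{s in block} theta_s^a (1-theta_s)^b ] by tensor Gauss-Hermite over
# the block's probit-scale normal
.block_moment <- function(dist, block, a, b, nodes) {
  gh <- .gh(nodes)
  d <- length(block)
  R <- dist$corr[block, block, drop = FALSE]
  L <- t(chol(R + diag(1e-12, d)))
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nodes)), d)))
  Z <- matrix(gh$x[idx], nrow(idx), d) * sqrt(2)
  Zc <- Z %*% t(L)
  W <- exp(rowSums(matrix(log(gh$w[idx]), nrow(idx), d))) / pi^(d / 2)
  theta <- stats::pnorm(
    sweep(sweep(Zc, 2, dist$probit_sd[block], `*`), 2,
          dist$probit_mean[block], `+`))
  lv <- numeric(nrow(theta))
  for (jj in seq_len(d)) {
    s <- block[jj]
    if (a[s] > 0) lv <- lv + a[s] * log(pmax(theta[, jj], 1e-300))
    if (b[s] > 0) lv <- lv + b[s] * log(pmax(1 - theta[, jj], 1e-300))
  }
  sum(W * exp(lv))
}

#' Expected aggregate category probabilities under parameter heterogeneity
#'
#' Computes `E(P(C_kj | Theta))` over the latent-trait distribution: the
#' category probabilities of the frequency table pooled over infinitely many
#' heterogeneous participants.  Quadrature factorizes the expectation over
#' independent blocks of the probit correlation matrix and applies
#' tensor-product Gauss-Hermite quadrature within each block; Monte Carlo
#' averages the model's category probabilities over random parameter draws.
#'
#' @param model an `mpt_model`.
#' @param dist a [group_distribution()] matching the model's parameters.
#' @param method `"quadrature"` (default) or `"monte-carlo"`.
#' @param nodes Gauss-Hermite nodes per dimension (default 32).
#' @param draws Monte Carlo draws (default 1e6).
#' @param seed seed for the Monte Carlo method.
#' @return named list of per-tree expected probability vectors.  For the
#'   Monte Carlo method an attribute `"se"` carries per-category standard
#'   errors.
#' @export
population_aggregate_probabilities <- function(model, dist,
                                               method = c("quadrature",
                                                          "monte-carlo"),
                                               nodes = 32, draws = 1e6,
                                               seed = 1L) {
  stopifnot(inherits(model, "mpt_model"), inherits(dist, "mpt_group_dist"))
  if (!identical(dist$parameters, model$parameters))
    stop("distribution parameters do not match the model")
  method <- match.arg(method)
  J <- length(model$cat_labels)
  if (method == "quadrature") {
    blocks <- .corr_blocks(dist)
    if (any(lengths(blocks) > 6))
      stop("more than 6 correlated dimensions in one block; ",
           "use method = 'monte-carlo'")
    const <- dist$sd == 0
    ebranch <- numeric(nrow(model$a))
    for (i in seq_along(ebranch)) {
      a <- model$a[i, ]; b <- model$b[i, ]
      v <- 1
      for (s in which(const & (a + b) > 0))
        v <- v * dist$mean[s]^a[s] * (1 - dist$mean[s])^b[s]
      for (bl in blocks) {
        if (!any((a + b)[bl] > 0)) next
        v <- v * .block_moment(dist, bl, a, b, nodes)
      }
      ebranch[i] <- v
    }
    pr <- numeric(J)
    agg <- tapply(ebranch, model$branch_cat, sum)
    pr[as.integer(names(agg))] <- agg
    se <- NULL
  } else {
    theta <- sample_parameters(dist, draws, seed = seed)
    P <- .cat_prob_rows(model, theta)
    pr <- colMeans(P)
    se <- sqrt(apply(P, 2, stats::var) / draws)
  }
  out <- lapply(seq_along(model$tree_names), function(k) {
    v <- pr[model$cat_tree == k]
    names(v) <- model$cat_labels[model$cat_tree == k]
    v
  })
  names(out) <- model$tree_names
  if (!is.null(se)) {
    attr(out, "se") <- lapply(seq_along(model$tree_names), function(k)
      se[model$cat_tree == k])
  }
  out
}

#' Population-level aggregation bias of complete-pooling ML estimates
#'
#' Fits the model to the *exact* expected aggregate probabilities (an
#' infinite-sample frequency table) and returns the fitted parameters minus
#' the probability-scale group means.  When the model is structurally
#' aggregation invariant and all co-occurring parameters are independent,
#' the bias is zero: the aggregate fit recovers the group means exactly.
#'
#' @param model an identified `mpt_model`.
#' @param dist a [group_distribution()].
#' @param nodes quadrature nodes per dimension.
#' @return list: `bias` (named vector, fitted minus mean), `estimates`,
#'   `expected` (the aggregate probabilities used).
#' @export
population_bias <- function(model, dist, nodes = 32) {
  id <- check_identifiability(model)
  if (!id$identified)
    stop("model is not locally identified (rank ",
         paste(unique(id$rank), collapse = "/"), " < ", id$S,
         "); population bias is not well defined")
  ep <- population_aggregate_probabilities(model, dist, nodes = nodes)
  counts <- unlist(ep, use.names = FALSE)
  names(counts) <- paste(model$tree_names[model$cat_tree], model$cat_labels,
                         sep = ":")
  fit <- fit_ml(model, counts, restarts = 5)
  bias <- fit$estimates - dist$mean[model$parameters]
  list(bias = bias, estimates = fit$estimates, expected = ep)
}
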