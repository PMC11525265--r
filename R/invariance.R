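#' Structural aggregation invariance (SAI) check
#'
#' A model is structurally aggregation invariant when every branch count
#' exponent is 0 or 1 and no parameter co-occurs with its own complement in
#' the same branch.  Under SAI, expected aggregate category probabilities
#' depend on parameter distributions only through products of first moments,
#' which is what makes aggregation across heterogeneous participants safe
#' (given independence of co-occurring parameters).
#'
#' @param model an `mpt_model`.
#' @return list of class `sai_report`: `sai` (logical verdict) and
#'   `violations`, a data frame with columns `parameter`, `tree`, `category`,
#'   `branch`, `reason` (`"repeated-parameter"` or
#'   `"parameter-with-complement"`).
#' @examples
#' check_sai(mpt_pair_clustering())         # violated in four pair branches
#' check_sai(mpt_pair_clustering(TRUE))     # holds
#' @export
check_sai <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  bc <- branch_counts(model)
  viol <- list()
  for (i in seq_len(nrow(bc$a))) {
    for (s in seq_along(model$parameters)) {
      a <- bc$a[i, s]; b <- bc$b[i, s]
      reason <- NULL
      if (a > 1 || b > 1) reason <- "repeated-parameter"
      else if (a == 1 && b == 1) reason <- "parameter-with-complement"
      if (a > 1 && b >= 1) reason <- "repeated-parameter"  # both counts, report once
      if (!is.null(reason))
        viol[[length(viol) + 1L]] <- data.frame(
          parameter = model$parameters[s],
          tree = bc$branch_index$tree[i],
          category = bc$branch_index$category[i],
          branch = bc$branch_index$branch[i],
          reason = reason,
          stringsAsFactors = FALSE
        )
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(parameter = character(0), tree = integer(0),
               category = character(0), branch = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(list(sai = nrow(violations) == 0, violations = violations),
            class = "sai_report")
}

#' @export
print.sai_report <- function(x, ...) {
  cat("Structural aggregation invariance (SAI):",
      if (x$sai) "holds" else "violated", "\n")
  if (!x$sai) print(x$violations)
  invisible(x)
}

#' Parameter pairs that co-occur within a branch
#'
#' Returns the set of unordered parameter pairs that occur (as parameter or
#' complement) together in at least one branch.  These are exactly the pairs
#' whose between-participant covariance must vanish for weak empirical
#' aggregation invariance.
#'
#' @param model an `mpt_model`.
#' @return two-column character matrix of parameter pairs (possibly 0 rows).
#' @examples
#' cooccurrence_pairs(mpt_pair_clustering())  # (c,r) and (c,u); never (r,u)
#' @export
cooccurrence_pairs <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  x <- (model$a + model$b) > 0
  pairs <- matrix(character(0), 0, 2,
                  dimnames = list(NULL, c("s1", "s2")))
  S <- length(model$parameters)
  if (S < 2) return(pairs)
  seen <- matrix(FALSE, S, S)
  for (i in seq_len(nrow(x))) {
    on <- which(x[i, ])
    if (length(on) >= 2)
      for (u in utils::combn(on, 2, simplify = FALSE))
        seen[u[1], u[2]] <- TRUE
  }
  idx <- which(seen, arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    pairs <- cbind(s1 = model$parameters[idx[, 1]],
                   s2 = model$parameters[idx[, 2]])
  }
  pairs
}

#' Weak empirical aggregation invariance (WEAI) check
#'
#' WEAI requires zero covariance between every pair of parameters that
#' co-occur in at least one branch.  For the probit-normal group
#' distribution used here, a pair has zero covariance iff its probit-scale
#' correlation is zero or at least one member is degenerate (sd 0).
#' Correlations between parameters that never share a branch are
#' unrestricted.
#'
#' @param model an `mpt_model`.
#' @param dist a [group_distribution()] covering all model parameters.
#' @return list: `weai` (logical), `offending` (pairs matrix with their
#'   probit correlations).
#' @export
check_weai <- function(model, dist) {
  stopifnot(inherits(model, "mpt_model"), inherits(dist, "mpt_group_dist"))
  if (!all(model$parameters %in% dist$parameters))
    stop("distribution does not cover all model parameters")
  pairs <- cooccurrence_pairs(model)
  off <- list()
  for (i in seq_len(nrow(pairs))) {
    s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
    if (dist$sd[s1] == 0 || dist$sd[s2] == 0) next
    rho <- dist$corr[s1, s2]
    if (abs(rho) > 1e-12)
      off[[length(off) + 1L]] <- data.frame(
        s1 = s1, s2 = s2, rho = rho, stringsAsFactors = FALSE)
  }
  offending <- if (length(off)) do.call(rbind, off) else
    data.frame(s1 = character(0), s2 = character(0), rho = numeric(0),
               stringsAsFactors = FALSE)
  list(weai = nrow(offending) == 0, offending = offending)
}

#' Analytic bias bound for a two-parameter branch
#'
#' For a branch whose probability is the product of two parameters with
#' common standard deviation `sigma` and correlation `rho` across
#' participants, the expected branch probability deviates from the product
#' of the means by exactly `Cov = rho * sigma^2`.  This gives the worst-case
#' aggregation bias of a branch probability under empirical (not structural)
#' invariance violation.
#'
#' @param rho correlation in `[-1, 1]`.
#' @param sigma common probability-scale standard deviation in `[0, 0.5]`.
#' @return the bias `rho * sigma^2`.
#' @examples
#' analytic_branch_bias(0.5, 0.3)   # 0.045
#' analytic_branch_bias(0.5, 0.15)  # 0.01125
#' @export
analytic_branch_bias <- function(rho, sigma) {
  if (any(rho < -1 | rho > 1)) stop("rho must lie in [-1, 1]")
  if (any(sigma < 0 | sigma > 0.5)) stop("sigma must lie in [0, 0.5]")
  rho * sigma^2
}
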