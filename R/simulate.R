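#' Draw heterogeneous participant parameters from a group distribution
#'
#' Samples `N` parameter vectors: multivariate-normal draws on the probit
#' scale (moment-matched means/SDs, specified correlations) pushed through
#' `pnorm`.  Parameters with `sd = 0` are constant and replicated.
#'
#' @param dist a [group_distribution()].
#' @param n_participants number of rows to draw.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return `n_participants x S` matrix of parameter values in (0, 1).
#' @export
sample_parameters <- function(dist, n_participants, seed = NULL) {
  stopifnot(inherits(dist, "mpt_group_dist"), n_participants >= 1)
  draw <- function() {
    S <- length(dist$parameters)
    theta <- matrix(rep(dist$mean, each = n_participants), n_participants, S,
                    dimnames = list(NULL, dist$parameters))
    nd <- which(dist$sd > 0)
    if (length(nd)) {
      R <- dist$corr[nd, nd, drop = FALSE]
      ee <- eigen(R, symmetric = TRUE)
      L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), length(nd)) %*%
        t(ee$vectors)
      Z <- matrix(stats::rnorm(n_participants * length(nd)),
                  n_participants, length(nd)) %*% L
      probit <- sweep(sweep(Z, 2, dist$probit_sd[nd], `*`),
                      2, dist$probit_mean[nd], `+`)
      theta[, nd] <- stats::pnorm(probit)
    }
    theta
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a frequency table from an MPT model with heterogeneous participants
#'
#' For each participant, a parameter vector is drawn from `dist` and category
#' counts are generated independently per tree as
#' `Multinomial(items[k], p(C_k. | theta_n))`.
#'
#' @param model an `mpt_model`.
#' @param dist a [group_distribution()] over the model's parameters, or a
#'   plain numeric parameter vector for homogeneous participants.
#' @param n_participants number of participants `N`.
#' @param items integer vector of items per tree (`m_k`), recycled to the
#'   number of trees; a tree with `items = 0` is dropped from the table.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   tables.
#' @return object of class `mpt_data`: list with `counts`
#'   (`N x sum(J_k)` integer matrix, columns named `tree:category`),
#'   `cat_tree`, `items`, and the true `theta` matrix.
#' @export
simulate_dataset <- function(model, dist, n_participants, items, seed = NULL) {
  stopifnot(inherits(model, "mpt_model"), n_participants >= 1)
  K <- length(model$tree_names)
  items <- rep_len(as.integer(items), K)
  if (any(items < 0)) stop("items must be non-negative")
  if (all(items == 0)) stop("at least one tree needs items")
  run <- function() {
    theta <- if (inherits(dist, "mpt_group_dist")) {
      if (!identical(dist$parameters, model$parameters))
        stop("distribution parameters do not match the model")
      sample_parameters(dist, n_participants)
    } else {
      th <- .check_theta(model, dist)
      matrix(rep(th, each = n_participants), n_participants,
             length(th), dimnames = list(NULL, model$parameters))
    }
    P <- .cat_prob_rows(model, theta)   # N x Jtot
    counts <- matrix(0L, n_participants, length(model$cat_labels))
    for (k in which(items > 0)) {
      jj <- which(model$cat_tree == k)
      for (n in seq_len(n_participants))
        counts[n, jj] <- stats::rmultinom(1, items[k], P[n, jj])
    }
    list(theta = theta, counts = counts)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  keep_tree <- items > 0
  keep <- model$cat_tree %in% which(keep_tree)
  counts <- res$counts[, keep, drop = FALSE]
  colnames(counts) <- paste(model$tree_names[model$cat_tree],
                            model$cat_labels, sep = ":")[keep]
  structure(list(counts = counts,
                 cat_tree = model$cat_tree[keep],
                 cat_labels = model$cat_labels[keep],
                 tree_names = model$tree_names,
                 items = items,
                 theta = res$theta),
            class = "mpt_data")
}

#' @export
print.mpt_data <- function(x, ...) {
  cat("MPT frequency table:", nrow(x$counts), "participant(s),",
      ncol(x$counts), "categories; items per tree:",
      paste(x$items, collapse = ", "), "\n")
  print(utils::head(x$counts, 5))
  if (nrow(x$counts) > 5) cat("...\n")
  invisible(x)
}

#' Aggregate a frequency table across participants
#'
#' @param data an `mpt_data` or a counts matrix.
#' @return named numeric vector of summed category counts.
#' @export
aggregate_counts <- function(data) {
  counts <- if (inherits(data, "mpt_data")) data$counts else as.matrix(data)
  colSums(counts)
}

#' Read / write participant-by-category frequency tables
#'
#' CSV layout: one row per participant, one column per category named
#' `tree:category` (matching [simulate_dataset()] output).
#'
#' @param data an `mpt_data` or counts matrix.
#' @param path file path.
#' @export
write_frequencies <- function(data, path) {
  counts <- if (inherits(data, "mpt_data")) data$counts else as.matrix(data)
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequencies
#' @param model optional `mpt_model` used to check and order the columns.
#' @return `read_frequencies` returns a counts matrix with `tree:category`
#'   columns.
#' @export
read_frequencies <- function(path, model = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df)
  if (!is.null(model)) {
    expected <- paste(model$tree_names[model$cat_tree], model$cat_labels,
                      sep = ":")
    if (!all(expected %in% colnames(counts)))
      stop("frequency table is missing columns: ",
           paste(setdiff(expected, colnames(counts)), collapse = ", "))
    counts <- counts[, expected, drop = FALSE]
  }
  counts
}

# align a counts vector/matrix with a model's category layout; returns a
# matrix with one column per (retained) category in model order
.align_counts <- function(model, counts, items = NULL) {
  if (inherits(counts, "mpt_data")) {
    lab <- paste(counts$tree_names[counts$cat_tree], counts$cat_labels,
                 sep = ":")
    mat <- counts$counts
    colnames(mat) <- lab
    counts <- mat
  }
  if (is.null(dim(counts))) counts <- matrix(counts, 1,
                                             dimnames = list(NULL, names(counts)))
  full <- paste(model$tree_names[model$cat_tree], model$cat_labels, sep = ":")
  if (!is.null(colnames(counts)) && all(full %in% colnames(counts)))
    return(counts[, full, drop = FALSE])
  if (ncol(counts) == length(full)) return(counts)
  stop("counts do not match the model's ", length(full), " categories")
}
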