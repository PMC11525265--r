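#' Construct a multinomial processing tree model
#'
#' An MPT model expresses, for each of `K` independent trees, the probability
#' of each response category as a sum of branch probabilities, where every
#' branch is a product of latent process probabilities `theta_s` and/or their
#' complements `1 - theta_s`.  Branches store the *ordered* sequence of
#' parameter occurrences; the classical integer count exponents (how often a
#' parameter and its complement occur in a branch) are derived views, see
#' [branch_counts()].
#'
#' @param parameters character vector of parameter names, in order.
#' @param trees list with one element per tree: `list(name = , categories = )`
#'   where `categories` is a character vector of category labels (length >= 2).
#' @param branches list with one element per branch:
#'   `list(tree = , category = , occ = )` where `tree` is a tree index or name,
#'   `category` a category label of that tree, and `occ` a two-column integer
#'   matrix, column 1 the parameter index, column 2 equal to 1 if the
#'   occurrence is the complement `1 - theta` and 0 otherwise.  Rows are in
#'   branch (root-to-leaf) order.
#' @param validate logical; check sum-to-one and structural invariants.
#'
#' @return An object of class `mpt_model`.
#' @seealso [parse_eqn()], [category_probabilities()], [check_sai()]
#' @export
mpt_model <- function(parameters, trees, branches, validate = TRUE) {
  stopifnot(is.character(parameters), length(parameters) >= 1,
            !anyDuplicated(parameters))
  K <- length(trees)
  stopifnot(K >= 1)
  tree_names <- vapply(trees, function(t) as.character(t$name), "")
  cat_tree <- integer(0)
  cat_labels <- character(0)
  for (k in seq_len(K)) {
    cats <- trees[[k]]$categories
    if (length(cats) < 2)
      stop("tree '", tree_names[k], "' has fewer than 2 categories")
    if (anyDuplicated(cats))
      stop("duplicated category label in tree '", tree_names[k], "'")
    cat_tree <- c(cat_tree, rep.int(k, length(cats)))
    cat_labels <- c(cat_labels, cats)
  }
  S <- length(parameters)

  br <- lapply(branches, function(b) {
    k <- if (is.character(b$tree)) match(b$tree, tree_names) else as.integer(b$tree)
    if (is.na(k) || k < 1 || k > K)
      stop("branch refers to unknown tree: ", b$tree)
    j_global <- which(cat_tree == k & cat_labels == as.character(b$category))
    if (length(j_global) != 1)
      stop("branch refers to unknown category '", b$category,
           "' in tree '", tree_names[k], "'")
    occ <- matrix(as.integer(b$occ), ncol = 2,
                  dimnames = list(NULL, c("param", "comp")))
    if (nrow(occ) == 0) stop("branch with empty occurrence sequence")
    if (any(occ[, 1] < 1 | occ[, 1] > S))
      stop("occurrence refers to parameter index outside 1..S")
    if (any(!occ[, 2] %in% c(0L, 1L)))
      stop("complement flag must be 0 or 1")
    list(tree = k, cat = j_global, occ = occ)
  })

  # derived exponent matrices: a (plain occurrences), b (complemented)
  nb <- length(br)
  A <- matrix(0L, nb, S, dimnames = list(NULL, parameters))
  B <- matrix(0L, nb, S, dimnames = list(NULL, parameters))
  for (i in seq_len(nb)) {
    occ <- br[[i]]$occ
    for (r in seq_len(nrow(occ))) {
      s <- occ[r, 1]
      if (occ[r, 2] == 1L) B[i, s] <- B[i, s] + 1L else A[i, s] <- A[i, s] + 1L
    }
  }

  m <- structure(list(
    parameters = parameters,
    tree_names = tree_names,
    cat_tree = cat_tree,
    cat_labels = cat_labels,
    branches = br,
    a = A, b = B,
    branch_tree = vapply(br, function(x) x$tree, 1L),
    branch_cat = vapply(br, function(x) x$cat, 1L)
  ), class = "mpt_model")

  if (validate) validate_mpt_model(m)
  m
}

#' @rdname mpt_model
#' @param model an `mpt_model`.
#' @export
validate_mpt_model <- function(model) {
  S <- length(model$parameters)
  used <- colSums(model$a + model$b) > 0
  if (any(!used))
    stop("parameter(s) never used in any branch: ",
         paste(model$parameters[!used], collapse = ", "))
  # numerical sum-to-one check at random interior points
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20240101L)
  for (p in seq_len(10)) {
    theta <- stats::runif(S, 0.05, 0.95)
    pr <- .cat_prob(model, theta)
    sums <- tapply(pr, model$cat_tree, sum)
    if (any(abs(sums - 1) > 1e-10))
      stop("per-tree category probabilities do not sum to 1 ",
           "(max deviation ", format(max(abs(sums - 1))), "); ",
           "the branch set is not a complete processing tree")
  }
  invisible(model)
}

# -- internal evaluation ------------------------------------------------------

# branch probabilities for a single theta vector
.branch_prob <- function(model, theta) {
  lt  <- log(pmax(theta, 1e-300))
  lct <- log(pmax(1 - theta, 1e-300))
  exp(drop(model$a %*% lt + model$b %*% lct))
}

# category probabilities, single theta, vector over global categories
.cat_prob <- function(model, theta) {
  pb <- .branch_prob(model, theta)
  pr <- numeric(length(model$cat_labels))
  agg <- tapply(pb, model$branch_cat, sum)
  pr[as.integer(names(agg))] <- agg
  pr
}

# category probabilities for a matrix of theta rows (N x S) -> N x Jtot
.cat_prob_rows <- function(model, theta_mat) {
  lt  <- log(pmax(theta_mat, 1e-300))
  lct <- log(pmax(1 - theta_mat, 1e-300))
  pb <- exp(tcrossprod(lt, model$a) + tcrossprod(lct, model$b))  # N x nb
  J <- length(model$cat_labels)
  out <- matrix(0, nrow(theta_mat), J)
  for (j in seq_len(J)) {
    idx <- which(model$branch_cat == j)
    if (length(idx) == 1L) out[, j] <- pb[, idx]
    else if (length(idx) > 1L) out[, j] <- rowSums(pb[, idx, drop = FALSE])
  }
  out
}

# -- exported operations ------------------------------------------------------

#' Category probabilities of an MPT model
#'
#' Evaluates `p(C_kj | theta) = sum_i prod_s theta_s^a (1-theta_s)^b` for
#' every response category, returning one named probability vector per tree.
#'
#' @param model an `mpt_model`.
#' @param theta numeric vector of parameter values in `[0, 1]`, aligned with
#'   `model$parameters` (names, if present, are checked).
#' @return named list of per-tree probability vectors; each sums to 1.
#' @examples
#' m <- mpt_pair_clustering()
#' category_probabilities(m, c(c = 0.5, r = 0.5, u = 0.5))
#' @export
category_probabilities <- function(model, theta) {
  stopifnot(inherits(model, "mpt_model"))
  theta <- .check_theta(model, theta)
  pr <- .cat_prob(model, theta)
  out <- lapply(seq_along(model$tree_names), function(k) {
    v <- pr[model$cat_tree == k]
    names(v) <- model$cat_labels[model$cat_tree == k]
    v
  })
  names(out) <- model$tree_names
  out
}

.check_theta <- function(model, theta) {
  S <- length(model$parameters)
  if (length(theta) != S)
    stop("theta has length ", length(theta), " but the model has ", S,
         " parameters")
  if (!is.null(names(theta)) && !all(names(theta) == model$parameters)) {
    if (!setequal(names(theta), model$parameters))
      stop("theta names do not match model parameters")
    theta <- theta[model$parameters]
  }
  if (any(theta < 0 | theta > 1)) stop("theta entries must lie in [0, 1]")
  as.numeric(theta)
}

#' Branch count exponents of an MPT model
#'
#' Returns the integer count variables of the general MPT model equation:
#' `a[s, k, j, i]` counts plain occurrences of parameter `s` in the `i`-th
#' branch terminating in category `C_kj`, `b` counts complemented occurrences,
#' and `x = (a + b > 0)` flags whether the parameter occurs at all.  Counts
#' are returned as branch-by-parameter matrices together with the branch
#' bookkeeping (tree, category, within-category branch index).
#'
#' @param model an `mpt_model`.
#' @return list with matrices `a`, `b`, `x` (branches x parameters) and a
#'   data frame `branch_index` with columns `tree`, `category`, `branch`
#'   (1-based within category).
#' @export
branch_counts <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  nb <- nrow(model$a)
  within <- integer(nb)
  seen <- integer(length(model$cat_labels))
  for (i in seq_len(nb)) {
    j <- model$branch_cat[i]
    seen[j] <- seen[j] + 1L
    within[i] <- seen[j]
  }
  idx <- data.frame(
    tree = model$branch_tree,
    category = model$cat_labels[model$branch_cat],
    branch = within,
    stringsAsFactors = FALSE
  )
  list(a = model$a, b = model$b,
       x = (model$a + model$b > 0) * 1L,
       branch_index = idx)
}

#' Degrees of freedom of an MPT model
#'
#' The number of independent category proportions minus the number of free
#' parameters, `sum_k (J_k - 1) - S`.  Zero for saturated models; a negative
#' value signals overparameterization and carries a warning attribute.
#'
#' @param model an `mpt_model`.
#' @return integer degrees of freedom.
#' @export
model_degrees_of_freedom <- function(model) {
  stopifnot(inherits(model, "mpt_model"))
  J <- tabulate(model$cat_tree)
  df <- sum(J - 1L) - length(model$parameters)
  if (df < 0) {
    warning("model has more parameters than independent category proportions",
            call. = FALSE)
    attr(df, "overparameterized") <- TRUE
  }
  df
}

#' Local identifiability check by Jacobian rank
#'
#' Computes the Jacobian of the independent category probabilities (all but
#' the last category of each tree) with respect to the parameters at several
#' random interior points and reports whether its numerical rank equals the
#' number of parameters everywhere.  A heuristic local check, not a symbolic
#' proof.
#'
#' @param model an `mpt_model`.
#' @param probes number of random interior points (default 5).
#' @param seed integer seed for the probe points (default 1).
#' @return list with `identified` (logical), `rank` (per probe), `S`.
#' @export
check_identifiability <- function(model, probes = 5, seed = 1L) {
  stopifnot(inherits(model, "mpt_model"), probes >= 1)
  S <- length(model$parameters)
  # independent coordinates: drop the last category of each tree
  keep <- !rev(!duplicated(rev(model$cat_tree)))  # FALSE at last cat per tree
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ranks <- integer(probes)
  for (p in seq_len(probes)) {
    theta <- stats::runif(S, 0.2, 0.8)
    Jc <- .jacobian(function(th) .cat_prob(model, th)[keep], theta)
    d <- svd(Jc, nu = 0, nv = 0)$d
    ranks[p] <- sum(d > max(d[1], 1e-12) * 1e-8)
  }
  list(identified = all(ranks == S), rank = ranks, S = S)
}

# central-difference Jacobian of f: R^S -> R^m
.jacobian <- function(f, x, h = 1e-6) {
  m <- length(f(x))
  J <- matrix(0, m, length(x))
  for (s in seq_along(x)) {
    e <- numeric(length(x)); e[s] <- h
    J[, s] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

#' @export
print.mpt_model <- function(x, ...) {
  J <- tabulate(x$cat_tree)
  cat("MPT model: ", length(x$parameters), " parameters (",
      paste(x$parameters, collapse = ", "), "), ",
      length(x$tree_names), " tree(s), ",
      nrow(x$a), " branches\n", sep = "")
  for (k in seq_along(x$tree_names))
    cat("  tree ", x$tree_names[k], ": ",
        paste(x$cat_labels[x$cat_tree == k], collapse = " "), "\n", sep = "")
  df <- suppressWarnings(model_degrees_of_freedom(x))
  cat("  degrees of freedom: ", df,
      if (df == 0) " (saturated)" else "", "\n", sep = "")
  invisible(x)
}
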