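# Random processing-tree generators for property-style tests.
#
# A model is grown as one full binary tree per response-category system:
# every internal node carries a parameter (left edge = success, right edge =
# complement), every leaf is a response category.  Grown this way the
# per-tree category probabilities sum to 1 by construction.  With distinct
# parameters along every root-to-leaf path (here: distinct per tree) the
# model is structurally aggregation invariant, and with one category per
# leaf it is saturated and locally identified.

# one random binary tree; returns list of branches (occ matrices) per leaf
.grow_tree <- function(depth_left, param_pool, rng) {
  if (depth_left == 0 || length(param_pool) == 0 || rng() < 0.3)
    return(list(matrix(integer(0), 0, 2)))
  s <- param_pool[1 + floor(rng() * length(param_pool))]
  rest <- setdiff(param_pool, s)
  left <- .grow_tree(depth_left - 1, rest, rng)
  right <- .grow_tree(depth_left - 1, rest, rng)
  c(lapply(left, function(o) rbind(c(s, 0L), o)),
    lapply(right, function(o) rbind(c(s, 1L), o)))
}

# deterministic uniform stream from a seed (keeps the global RNG untouched)
.make_rng <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

# random SAI model: <= `max_depth` parameters per branch, unique category
# per leaf (saturated, identified)
random_sai_model <- function(seed, n_trees = 2, max_depth = 3, n_params = 5) {
  rng <- .make_rng(seed)
  repeat {
    params <- paste0("p", seq_len(n_params))
    trees <- list()
    branches <- list()
    cat_id <- 0
    for (k in seq_len(n_trees)) {
      leaves <- .grow_tree(max_depth, seq_len(n_params), rng)
      if (length(leaves) < 2) next
      cats <- paste0("T", k, "C", seq_along(leaves))
      trees[[length(trees) + 1]] <- list(name = paste0("t", k),
                                         categories = cats)
      for (j in seq_along(leaves))
        branches[[length(branches) + 1]] <- list(
          tree = paste0("t", k), category = cats[j],
          occ = cbind(leaves[[j]][, 1], leaves[[j]][, 2]))
    }
    if (length(trees) == 0) next
    used <- sort(unique(unlist(lapply(branches, function(b) b$occ[, 1]))))
    if (length(used) == 0) next
    remap <- match(seq_len(n_params), used)
    for (i in seq_along(branches))
      branches[[i]]$occ[, 1] <- remap[branches[[i]]$occ[, 1]]
    m <- mpt_model(params[used], trees, branches)
    if (check_sai(m)$sai) return(m)
  }
}

# random model that may violate SAI: parameters can repeat along a path
random_mpt_model <- function(seed, n_trees = 2, max_depth = 3, n_params = 3) {
  rng <- .make_rng(seed)
  grow <- function(depth_left) {
    if (depth_left == 0 || rng() < 0.3)
      return(list(matrix(integer(0), 0, 2)))
    s <- 1 + floor(rng() * n_params)
    left <- grow(depth_left - 1)
    right <- grow(depth_left - 1)
    c(lapply(left, function(o) rbind(c(s, 0L), o)),
      lapply(right, function(o) rbind(c(s, 1L), o)))
  }
  repeat {
    trees <- list(); branches <- list()
    for (k in seq_len(n_trees)) {
      leaves <- grow(max_depth)
      if (length(leaves) < 2) next
      cats <- paste0("T", k, "C", seq_along(leaves))
      trees[[length(trees) + 1]] <- list(name = paste0("t", k),
                                         categories = cats)
      for (j in seq_along(leaves))
        branches[[length(branches) + 1]] <- list(
          tree = paste0("t", k), category = cats[j], occ = leaves[[j]])
    }
    if (length(trees) == 0) next
    used <- sort(unique(unlist(lapply(branches, function(b) b$occ[, 1]))))
    if (length(used) == 0) next
    remap <- match(seq_len(n_params), used)
    for (i in seq_along(branches))
      branches[[i]]$occ[, 1] <- remap[branches[[i]]$occ[, 1]]
    return(mpt_model(paste0("q", seq_len(n_params))[used], trees, branches))
  }
}

# exact binomial acceptance interval for an observed rejection proportion
accept_interval <- function(n, p = 0.05, level = 0.95) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}
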