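#' Transform an MPT model into a structurally aggregation-invariant one
#'
#' Mechanically removes SAI violations by renaming parameter occurrences:
#' within each branch, the first occurrence of a parameter (in branch order,
#' counting plain and complemented forms together) keeps its name; every
#' later occurrence is renamed to a fresh parameter.  Renaming is consistent
#' across branches by occurrence position: the `t`-th occurrence of `p` in
#' any branch becomes `p_t` (`t >= 2`).  Fresh names can be overridden via
#' `naming`, which also supports tree-scoped reassignment of non-violating
#' occurrences (entry name `"tree:param"`), as used to rename the
#' singleton-tree `u` to `a` in the four-parameter pair-clustering model.
#'
#' The result is guaranteed SAI but may be overparameterized; its local
#' identifiability is checked and reported in the plan.  Setting all fresh
#' parameters equal to their originals reproduces the original model's
#' category probabilities exactly.
#'
#' @param model an `mpt_model`.
#' @param naming named character vector: names are fresh default names
#'   (e.g. `"u_2"`) or tree-scoped originals (`"single:u"`), values the
#'   desired parameter names.
#' @return list of class `mpt_transform_plan`: `model` (the SAI result),
#'   `renamings` (data frame: tree, category, branch, occurrence, from, to),
#'   `identifiability`, `overparameterized`, `original_parameters`.
#' @examples
#' plan <- transform_to_sai(mpt_pair_clustering(),
#'                          naming = c(u_2 = "a", "single:u" = "a"))
#' plan$model   # the four-parameter pair-clustering model
#' @export
transform_to_sai <- function(model, naming = NULL) {
  stopifnot(inherits(model, "mpt_model"))
  params <- model$parameters
  new_params <- params
  ren <- list()
  branches <- vector("list", length(model$branches))

  resolve <- function(default, tree_key) {
    if (!is.null(naming)) {
      if (tree_key %in% names(naming)) return(naming[[tree_key]])
      if (default %in% names(naming)) return(naming[[default]])
    }
    default
  }
  ensure <- function(nm) {
    if (!nm %in% new_params) new_params <<- c(new_params, nm)
    match(nm, new_params)
  }

  for (i in seq_along(model$branches)) {
    b <- model$branches[[i]]
    tree_name <- model$tree_names[b$tree]
    occ <- b$occ
    count <- integer(length(params))
    new_occ <- occ
    for (rr in seq_len(nrow(occ))) {
      s <- occ[rr, 1]
      count[s] <- count[s] + 1L
      orig <- params[s]
      tree_key <- paste0(tree_name, ":", orig)
      nm <- if (count[s] == 1L) resolve(orig, tree_key)
      else resolve(paste0(orig, "_", count[s]), tree_key)
      if (count[s] > 1L && nm == orig)
        stop("naming maps a repeated occurrence of '", orig,
             "' back to itself; the result would violate SAI")
      new_occ[rr, 1] <- ensure(nm)
      if (nm != orig)
        ren[[length(ren) + 1L]] <- data.frame(
          tree = tree_name,
          category = model$cat_labels[b$cat],
          branch = i,
          occurrence = count[s],
          from = orig, to = nm,
          stringsAsFactors = FALSE)
    }
    branches[[i]] <- list(tree = tree_name,
                          category = model$cat_labels[b$cat],
                          occ = new_occ)
  }

  used <- sort(unique(unlist(lapply(branches, function(b) b$occ[, 1]))))
  remap <- match(seq_along(new_params), used)
  final_params <- new_params[used]
  for (i in seq_along(branches))
    branches[[i]]$occ[, 1] <- remap[branches[[i]]$occ[, 1]]

  trees <- lapply(seq_along(model$tree_names), function(k)
    list(name = model$tree_names[k],
         categories = model$cat_labels[model$cat_tree == k]))
  result <- mpt_model(final_params, trees, branches)

  sai <- check_sai(result)
  if (!sai$sai) stop("internal error: transform result is not SAI")
  df <- suppressWarnings(model_degrees_of_freedom(result))
  overp <- isTRUE(attr(df, "overparameterized"))
  id <- check_identifiability(result)
  if (overp)
    warning("transformed model has more parameters than independent ",
            "category proportions; it may lead to overparameterization",
            call. = FALSE)

  renamings <- if (length(ren)) do.call(rbind, ren) else
    data.frame(tree = character(0), category = character(0),
               branch = integer(0), occurrence = integer(0),
               from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  structure(list(model = result,
                 renamings = renamings,
                 identifiability = id,
                 overparameterized = overp,
                 original_parameters = params),
            class = "mpt_transform_plan")
}

#' @export
print.mpt_transform_plan <- function(x, ...) {
  cat("SAI transform plan:", nrow(x$renamings), "occurrence renaming(s)\n")
  if (nrow(x$renamings)) print(x$renamings)
  cat("result is ",
      if (x$identifiability$identified) "locally identified"
      else "NOT identified", " (rank ",
      paste(unique(x$identifiability$rank), collapse = "/"),
      " of ", x$identifiability$S, ")\n", sep = "")
  invisible(x)
}
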