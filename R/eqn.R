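#' Parse an EQN-format MPT model definition
#'
#' The accepted dialect: an optional first line holding a single integer
#' (a branch count, checked if present); every other non-blank line is
#' `tree category expression`, where `tree` is an integer or label,
#' `category` a label, and `expression` a `*`-separated product of terms
#' `p` or `(1-p)` for parameter names `p`.  `#` starts a comment; blank
#' lines are ignored.  Parameter, tree, and category order follow first
#' appearance.
#'
#' @param text a character scalar (possibly multi-line) or vector of lines.
#' @param validate logical; run model validation (default TRUE).
#' @return a validated [mpt_model()].
#' @examples
#' eqn <- "
#' pair C11 c*r
#' pair C14 c*(1-r)
#' pair C12 (1-c)*u*u
#' pair C13 (1-c)*u*(1-u)
#' pair C13 (1-c)*(1-u)*u
#' pair C14 (1-c)*(1-u)*(1-u)
#' single C21 u
#' single C22 (1-u)"
#' parse_eqn(eqn)
#' @export
parse_eqn <- function(text, validate = TRUE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0) stop("empty EQN input")

  declared <- NA_integer_
  if (grepl("^[0-9]+$", lines[1])) {
    declared <- as.integer(lines[1])
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (length(lines) == 0) stop("EQN input contains no branch lines")
  if (!is.na(declared) && declared != length(lines))
    stop("EQN header declares ", declared, " branches but ",
         length(lines), " branch lines found")

  params <- character(0)
  tree_labels <- character(0)
  cats <- list()     # per tree label: character vector
  branches <- list()

  for (ii in seq_along(lines)) {
    fields <- strsplit(lines[ii], "[ \t]+")[[1]]
    if (length(fields) < 3)
      stop("line ", lineno[ii], ": expected 'tree category expression'")
    tr <- fields[1]
    ct <- fields[2]
    expr <- paste(fields[-(1:2)], collapse = "")
    if (grepl("^\\*|\\*$|\\*\\*", expr))
      stop("line ", lineno[ii], ": malformed branch expression '", expr, "'")
    terms <- strsplit(expr, "*", fixed = TRUE)[[1]]
    if (length(terms) == 0 || any(!nzchar(terms)))
      stop("line ", lineno[ii], ": malformed branch expression '", expr, "'")
    occ <- matrix(0L, length(terms), 2)
    for (tt in seq_along(terms)) {
      term <- terms[tt]
      comp <- 0L
      if (grepl("^\\(1-.+\\)$", term)) {
        comp <- 1L
        term <- sub("^\\(1-(.+)\\)$", "\\1", term)
      }
      if (!grepl("^[A-Za-z][A-Za-z0-9._]*$", term))
        stop("line ", lineno[ii], ": malformed term '", terms[tt], "'")
      s <- match(term, params)
      if (is.na(s)) { params <- c(params, term); s <- length(params) }
      occ[tt, ] <- c(s, comp)
    }
    if (!tr %in% tree_labels) {
      tree_labels <- c(tree_labels, tr)
      cats[[tr]] <- character(0)
    }
    if (!ct %in% cats[[tr]]) cats[[tr]] <- c(cats[[tr]], ct)
    branches[[length(branches) + 1L]] <-
      list(tree = tr, category = ct, occ = occ)
  }

  trees <- lapply(tree_labels, function(tl)
    list(name = tl, categories = cats[[tl]]))
  mpt_model(params, trees, branches, validate = validate)
}

#' @rdname parse_eqn
#' @param path path to an EQN file.
#' @export
read_eqn <- function(path, validate = TRUE) {
  parse_eqn(readLines(path, warn = FALSE), validate = validate)
}

#' Write an MPT model in EQN format
#'
#' Emits the headerless dialect accepted by [parse_eqn()], one branch per
#' line, ordered deterministically by tree, category, and branch.
#'
#' @param model an `mpt_model`.
#' @param path optional file path; if `NULL`, the EQN text is returned.
#' @return the EQN lines, invisibly when written to a file.
#' @export
write_eqn <- function(model, path = NULL) {
  stopifnot(inherits(model, "mpt_model"))
  ord <- order(model$branch_tree, model$branch_cat)
  lines <- vapply(ord, function(i) {
    b <- model$branches[[i]]
    terms <- apply(b$occ, 1, function(o) {
      p <- model$parameters[o[1]]
      if (o[2] == 1L) paste0("(1-", p, ")") else p
    })
    paste(model$tree_names[b$tree],
          model$cat_labels[b$cat],
          paste(terms, collapse = "*"))
  }, "")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(lines)
}
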