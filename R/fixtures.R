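#' Built-in pair-clustering models
#'
#' The pair-clustering model describes free recall of semantically related
#' word pairs and unrelated singletons with three latent processes: cluster
#' storage (`c`), cluster retrieval (`r`), and single-word storage-plus-
#' retrieval (`u`).  Word pairs fall in four categories (both words recalled
#' adjacently, both nonadjacently, one word, neither word); singletons are
#' recalled or not.  The three-parameter version uses `u` for both words of
#' an unclustered pair and for singletons, so `u` occurs twice in four
#' word-pair branches: the model violates structural aggregation invariance.
#' The four-parameter version renames the second-word occurrence and the
#' singleton occurrence of `u` to a fresh parameter `a`, yielding a saturated
#' but structurally aggregation-invariant model.
#'
#' @param four_param logical; return the four-parameter (SAI) extension.
#' @param pairs_only logical; drop the singleton tree (the four-parameter
#'   model is then no longer identified).
#' @return an [mpt_model()].
#' @examples
#' mpt_pair_clustering()
#' mpt_pair_clustering(four_param = TRUE)
#' @export
mpt_pair_clustering <- function(four_param = FALSE, pairs_only = FALSE) {
  second <- if (four_param) "a" else "u"
  pair_lines <- c(
    "pair C11 c*r",
    sprintf("pair C12 (1-c)*u*%s", second),
    sprintf("pair C13 (1-c)*u*(1-%s)", second),
    sprintf("pair C13 (1-c)*(1-u)*%s", second),
    "pair C14 c*(1-r)",
    sprintf("pair C14 (1-c)*(1-u)*(1-%s)", second)
  )
  single <- if (four_param) "a" else "u"
  single_lines <- c(
    sprintf("single C21 %s", single),
    sprintf("single C22 (1-%s)", single)
  )
  lines <- if (pairs_only) pair_lines else c(pair_lines, single_lines)
  parse_eqn(lines)
}
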