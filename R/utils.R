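#' Derive a deterministic seed substream
#'
#' Mixes a master seed with one or more stream indices (condition, replicate,
#' ...) into a new integer seed, so that simulation cells and replicates are
#' reproducible independently of execution order or parallel scheduling.
#' All arithmetic stays below 2^53 and the result below 2^31.
#'
#' @param master integer master seed.
#' @param ... integer stream indices.
#' @return a positive integer seed.
#' @export
mix_seed <- function(master, ...) {
  m <- 2147483563
  s <- as.numeric(master) %% m
  for (k in c(...)) s <- (s * 69069 + as.numeric(k) + 1) %% m
  as.integer(s + 1)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# exact binomial acceptance interval for a proportion: the central 95% range
# of X/n when X ~ Binomial(n, p)
binomial_interval <- function(n, p = 0.05, level = 0.95) {
  a <- (1 - level) / 2
  c(stats::qbinom(a, n, p), stats::qbinom(1 - a, n, p)) / n
}
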