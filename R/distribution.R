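# Latent-trait group distribution: probit-transformed parameters are jointly
# multivariate normal across participants; means and SDs are specified on the
# probability scale and matched by moments, correlations on the probit scale.

#' Match probability-scale moments of a probit-normal parameter
#'
#' Finds `(m, s)` such that `Theta = pnorm(m + s * Z)`, `Z ~ N(0,1)`, has
#' mean `mu` and standard deviation `sigma` on the probability scale.  The
#' mean constraint has the closed form `E(Theta) = pnorm(m / sqrt(1 + s^2))`,
#' so matching reduces to a one-dimensional root find in `s` for the second
#' moment, evaluated by adaptive quadrature.  Residuals are below 1e-8.
#'
#' The family cannot reach every `(mu, sigma)`: as `s` grows, `Theta`
#' approaches a Bernoulli(`mu`) variable, so `sigma` must stay below
#' `sqrt(mu * (1 - mu))`.  Infeasible requests raise an error reporting the
#' supremum.
#'
#' @param mu probability-scale mean in (0, 1).
#' @param sigma probability-scale standard deviation, `0 <= sigma < 0.5`.
#' @return named numeric vector `c(m = , s = )` on the probit scale.
#' @examples
#' probit_moment_match(0.5, 0)            # (0, 0)
#' probit_moment_match(0.5, 1 / sqrt(12)) # ~ (0, 1): pnorm(Z) is Uniform(0,1)
#' @export
probit_moment_match <- function(mu, sigma) {
  stopifnot(length(mu) == 1, length(sigma) == 1)
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)")
  if (sigma < 0 || sigma >= 0.5) stop("sigma must lie in [0, 0.5)")
  if (sigma == 0) return(c(m = stats::qnorm(mu), s = 0))
  sup <- sqrt(mu * (1 - mu))
  if (sigma >= sup - 1e-10)
    stop("sigma = ", sigma, " is infeasible for mu = ", mu,
         ": the probit-normal family only reaches sd < ", format(sup))
  h <- stats::qnorm(mu)
  sd_at <- function(s) {
    m <- h * sqrt(1 + s^2)          # keeps the mean exactly mu for every s
    e2 <- stats::integrate(function(z)
      stats::dnorm(z) * stats::pnorm(m + s * z)^2,
      -Inf, Inf, rel.tol = 1e-13, abs.tol = 1e-14)$value
    sqrt(max(e2 - mu^2, 0))
  }
  hi <- 1
  while (sd_at(hi) < sigma && hi < 64) hi <- hi * 2
  if (sd_at(hi) < sigma)
    stop("sigma = ", sigma, " not attainable below the search bound for mu = ", mu)
  s <- stats::uniroot(function(s) sd_at(s) - sigma, c(0, hi),
                      tol = 1e-12)$root
  c(m = h * sqrt(1 + s^2), s = s)
}

#' Group-level distribution of MPT parameters (latent-trait form)
#'
#' Describes between-participant heterogeneity: each parameter `Theta_s` is
#' `pnorm` of a normal variable; the normals are jointly multivariate normal
#' with correlation matrix `corr` (probit scale).  Means and standard
#' deviations are given on the probability scale and converted by
#' [probit_moment_match()].  Parameters with `sd = 0` are constants and are
#' excluded from the multivariate normal; their `corr` rows must be zero
#' off-diagonal.
#'
#' @param parameters character vector of parameter names.
#' @param mean probability-scale means, recycled to length `S`, each in (0,1).
#' @param sd probability-scale standard deviations, recycled, each in [0, .5).
#' @param corr probit-scale correlation matrix (default identity); symmetric,
#'   unit diagonal, positive semi-definite on the non-degenerate block.
#' @return object of class `mpt_group_dist` with fields `parameters`, `mean`,
#'   `sd`, `corr`, `probit_mean`, `probit_sd`.
#' @examples
#' group_distribution(c("c", "r", "u"), mean = 0.5, sd = c(0.3, 0.3, 0))
#' @export
group_distribution <- function(parameters, mean = 0.5, sd = 0, corr = NULL) {
  stopifnot(is.character(parameters), length(parameters) >= 1)
  S <- length(parameters)
  mean <- rep_len(mean, S); sd <- rep_len(sd, S)
  names(mean) <- names(sd) <- parameters
  if (is.null(corr)) corr <- diag(S)
  corr <- as.matrix(corr)
  stopifnot(nrow(corr) == S, ncol(corr) == S)
  dimnames(corr) <- list(parameters, parameters)
  if (max(abs(corr - t(corr))) > 1e-12) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-12) stop("corr must have unit diagonal")
  deg <- sd == 0
  for (s in which(deg))
    if (any(abs(corr[s, -s]) > 1e-12))
      stop("parameter '", parameters[s], "' has sd = 0; its correlations ",
           "must be zero")
  if (any(!deg)) {
    ev <- eigen(corr[!deg, !deg, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("corr is not positive semi-definite on the non-degenerate block ",
           "(min eigenvalue ", format(min(ev)), ")")
  }
  pm <- vapply(seq_len(S), function(s) probit_moment_match(mean[s], sd[s]),
               c(m = 0, s = 0))
  structure(list(parameters = parameters, mean = mean, sd = sd, corr = corr,
                 probit_mean = stats::setNames(pm["m", ], parameters),
                 probit_sd = stats::setNames(pm["s", ], parameters)),
            class = "mpt_group_dist")
}

#' @export
print.mpt_group_dist <- function(x, ...) {
  cat("Latent-trait group distribution over",
      length(x$parameters), "parameters\n")
  print(data.frame(mean = x$mean, sd = x$sd,
                   probit_mean = x$probit_mean, probit_sd = x$probit_sd))
  if (any(abs(x$corr[upper.tri(x$corr)]) > 0)) {
    cat("probit-scale correlations:\n"); print(x$corr)
  }
  invisible(x)
}

#' Read a group distribution from a YAML or JSON spec file
#'
#' The file holds `parameters`, `mean`, `sd` (probability scale) and an
#' optional `corr` matrix (probit scale, row-major list of rows).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `mpt_group_dist`.
#' @export
read_group_distribution <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  corr <- spec$corr
  if (!is.null(corr) && !is.matrix(corr))
    corr <- do.call(rbind, lapply(corr, as.numeric))
  group_distribution(as.character(spec$parameters),
                     mean = as.numeric(spec$mean),
                     sd = as.numeric(spec$sd),
                     corr = corr)
}
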