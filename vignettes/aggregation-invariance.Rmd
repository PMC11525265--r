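---
title: "Aggregation invariance of MPT models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregation invariance of MPT models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptagg)
```

## The model class and the aggregation problem

A multinomial processing tree (MPT) model explains the response counts of a
single participant. Tree `k` has `J_k` response categories; the probability
of category `C_kj` is a sum over the `I_kj` branches terminating in it, each
branch a product of latent process probabilities `θ_s` or complements
`1 − θ_s`:

$$p(C_{kj} \mid \theta) = \sum_{i=1}^{I_{kj}} \prod_{s=1}^{S}
  \theta_s^{a_{skji}} (1-\theta_s)^{b_{skji}},$$

with integer count exponents `a`, `b`. Response counts are
product-multinomial across trees. `mptagg` stores branches as *ordered
occurrence sequences* and derives the exponents from them; the order is
irrelevant for evaluation but essential for the SAI transform, which must
distinguish *which* occurrence of a repeated parameter is renamed.

When participants differ, `θ` is a random vector `Θ` and pooled data have
expected category probabilities `E[p(C_kj | Θ)]`. Whether these still follow
the same MPT model — with parameters equal to `E(Θ)` — is the aggregation
invariance question. The answer decomposes into:

* **SAI** (structural): all exponents 0/1 and no parameter together with its
  own complement in one branch. Then every branch probability is multilinear
  in `Θ`.
* **WEAI** (weak empirical): zero covariance for every pair of parameters
  that co-occur in a branch. Together with SAI this yields exact invariance
  whenever at most two parameters share a branch, or when the parameter
  distribution excludes higher-order dependencies — in particular under the
  probit-normal (latent-trait) distribution the simulator uses. Full EAI
  (joint-CDF factorization per branch) has no implementable data-side check
  and is represented here only through the independence structure of
  `group_distribution()`; `check_weai()` is the operational diagnostic.

The running example is the pair-clustering model of free recall:
`c` (cluster storage), `r` (cluster retrieval), `u` (single-word
storage-retrieval). `u` appears twice in four word-pair branches, so the
three-parameter model violates SAI; renaming the second occurrence (and the
singleton occurrence) to a fresh parameter `a` yields the saturated but
identified four-parameter SAI version. The singleton reassignment `u → a`
is *not* derivable from a general rule — the transform's default keeps the
first occurrence in branch order and renames later ones (`u_2`, `u_3`, ...),
and the assignment encoded in the built-in four-parameter fixture is
expressed through the explicit naming map `c(u_2 = "a", "single:u" = "a")`.

## The latent-trait simulator

`group_distribution()` specifies between-participant heterogeneity: probit
transforms of the parameters are jointly multivariate normal. Means and
standard deviations are requested on the **probability scale** (the scale on
which bias is reported) and converted by moment matching; correlations are
specified and enforced on the **probit scale**, where they hold exactly —
on the probability scale they carry over only approximately, which the test
suite accounts for when comparing against the analytic `ρσ²` bound.

Moment matching exploits that `E[Φ(m + sZ)] = Φ(m/√(1+s²))` is available in
closed form, reducing the two-dimensional matching problem to a
one-dimensional root find in `s` with the second moment evaluated by
adaptive quadrature (`stats::integrate`, residuals < 1e-8). The family
cannot reach every pair: as `s → ∞` the parameter degenerates to a
Bernoulli(μ) variable, so `σ < √(μ(1−μ))` is required — at μ = .2 the
supremum is .4, so the design's σ = .30 level is feasible at every design
mean. Infeasible requests raise an error reporting the supremum rather than
silently clamping. Degenerate parameters (σ = 0) are excluded from the
multivariate normal entirely, keeping its covariance positive definite.

What the generator emulates: multinomial sampling noise per participant and
tree, and smooth unimodal parameter heterogeneity with (possibly) correlated
parameters. What it does not: item heterogeneity, response dependencies
within a participant beyond the tree structure, discrete subgroups/mixtures,
or model misfit at the individual level. Passing tests therefore speak to
aggregation artifacts under the latent-trait data-generating process, not to
robustness against individual-level model violations.

## Estimation

`fit_ml()` maximizes the product-multinomial likelihood of one (usually
aggregated) frequency row. Two engines are kept deliberately interchangeable
as a correctness safeguard, since their agreement in log-likelihood (within
1e-8) is asserted across the test fixtures:

* **gradient** (default): BFGS on logit-transformed parameters with an
  analytic gradient, followed by a damped Newton polish (numeric Hessian of
  the analytic gradient). The objective is the *mean* log-likelihood: the
  optimum is unchanged, but gradients stay O(1) so the convergence criterion
  (gradient norm < 1e-6 on the unconstrained scale) is attainable in double
  precision for tables of any size.
* **EM**: the classical expected-branch-completion algorithm, vectorized
  across many frequency rows simultaneously with an active set; this is what
  makes per-participant fitting of thousands of small bootstrap tables
  affordable (`fit_ml_many()`).

Starts: a short EM refinement of the centre of the parameter space plus
deterministic random restarts (drawn under a fixed internal seed and
restoring the caller's RNG state, so fits are pure functions). Ties are
broken by log-likelihood, then lexicographically smallest estimate.
Estimates are clamped to `[1e-9, 1 − 1e-9]` internally; boundary flags are
raised within 1e-6 of 0/1. `G² = 2Σ n log(n/(N_k p̂))` with `0·log 0 = 0`,
`df = Σ(J_k − 1) − S`.

## Population-level bias

`population_aggregate_probabilities()` computes `E[p(C_kj | Θ)]` exactly:
the probit correlation matrix is split into independent blocks (connected
components), the expectation factorizes across blocks, and each block is
integrated by tensor-product Gauss–Hermite quadrature after a Cholesky
rotation (default 32 nodes per dimension — ample for these smooth
Φ-transformed integrands at design-range SDs; blocks beyond 6 correlated
dimensions are refused with a pointer to the Monte Carlo method, ≥10⁶
draws). `population_bias()` then fits the model to these exact probabilities
as an infinite-sample table: the fitted parameters minus the probability-
scale means are the *exact* aggregation bias, free of sampling noise. An
identifiability check (Jacobian rank at random interior points) runs first,
since bias is undefined for non-identified models.

This is the quantity behind the headline facts: the four-parameter SAI
model has |bias| < 1e-6 under independent heterogeneity of any magnitude,
while the pairs-only three-parameter model at σ_U = .2 yields
û = 2p₁₂/(2p₁₂+p₁₃) = .29/.50 = .58, i.e. +.08 bias in `u`, with
ĉ = 1 − p₁₂/û² = .5690 and r̂ = p₁₁/ĉ = .4394.

## Goodness-of-fit tests

The aggregate G² test (df = Σ(J_k−1) − S) assumes homogeneity; under
heterogeneity in parameters involved in SAI/WEAI violations it is biased
against the model, increasingly so with heterogeneity and with the number
of data points. The per-participant sum test refers `Σ_n G²_n` to χ² with
`N·df` degrees of freedom and is valid under heterogeneity but asymptotic in
the per-participant item counts. Zero cells are handled by adding +0.10 to
*all* category frequencies of any participant with an empty cell — applied
per offending participant (the more conservative of the two possible
readings of the rule; the constant is exposed as an argument), and only
inside the sum tests, never in aggregate fits. The parametric bootstrap
variant re-draws each participant's table from that participant's fitted
parameters (the no-pooling null — the natural null for a sum of
per-participant statistics), recomputes the sum identically including the
zero-cell rule, and uses the exact-test convention `p = (1+k)/(B+1)` with
B = 500 by default.

## The Monte Carlo designs

`enumerate_design("three-param")` crosses pair proportion {50%, 100%} ×
m₁ {20, 8, 4} × N {1000, 10, 1} × μ_C, μ_R {.2, .5, .8} × σ {0, .15, .30} ×
ρ_CR, ρ_CU, ρ_UR {0, .25, .50} = 13,122 cells, of which 4,212 are
inadmissible (σ = 0 cannot support a nonzero correlation), leaving 8,910.
The four-parameter grid (m {20, 4} × N {1000, 10} × μ {.2, .5} × σ × three
ρs, with ρ_AU = 0, ρ_CA = ρ_CU, ρ_AR = ρ_UR) gives 648 / 208 / 440. μ_U
(and μ_A) is fixed at .50 throughout. Conditions whose implied correlation
matrix fails positive semi-definiteness would be flagged `infeasible`
(distinct from inadmissible); none of the default cells is.

`run_bias_cell()` draws datasets, fits the aggregated table per replicate
(N = 1 being the no-pooling case), and reports per-parameter bias, 2.5%/97.5%
estimate quantiles, and a |B| > .10 "noticeable" flag; non-convergent
replicates are excluded and counted, and the cell is flagged if they exceed
1% of replicates. `run_rejection_cell()` reports rejection proportions at
α = .05 for the aggregate, asymptotic-sum, and bootstrap-sum tests. For
G²-level studies the generating σ levels are {.00, .10, .20}; whether
heterogeneity applies to all parameters jointly or to `u` only is ambiguous
in the source design, so the runner exposes both (`sigma_u_only`), with
joint σ as the default and means at .50 (the documented assumption for
means not printed in the design tables).

Every replicate draws its seed from `mix_seed(master, condition, replicate)`
— a multiply-mix hash whose arithmetic stays below 2⁵³ — so results are
independent of execution order and worker scheduling, and identical master
seeds give bit-identical cells.

## Problem sizes and tolerances in the shipped checks

The package's own test suite runs the heavy claims at reduced but
informative scale, chosen so each check resolves the effect it targets by a
comfortable margin: the over-rejection condition (σ = .20, N = 100,
m₁ = m₂ = 20) at 500 replicates; the zero-heterogeneity sanity cell at 100
replicates with an exact binomial acceptance interval around α = .05; bias
directions (pairs-only, σ = .30, N = 1000) at 200 replicates, where the
Monte Carlo error of a mean estimate is ~.001 against biases of order .05;
and the bootstrap level check at 100 outer replicates with B = 199.
Deterministic claims (quadrature bias of SAI models, closed-form fits,
grid counts) are asserted at 1e-6 or exactly.

## Known limitations

* Beta-distributed heterogeneity (beta-MPT generation) is a stated
  extension point, not implemented; nor is item-level heterogeneity.
* `check_identifiability()` is a numerical local check, not a symbolic
  proof; rank decisions use an SVD threshold of 1e-8 relative to the
  largest singular value.
* No standard errors or confidence intervals for aggregated-data estimates
  are provided — under heterogeneity they are exactly the quantities that
  cannot be trusted, and interval estimation is out of scope.
* The transform never searches for a *minimal* identifiable SAI
  reparameterization; it reports non-identifiability and leaves equality
  constraints to the analyst.
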