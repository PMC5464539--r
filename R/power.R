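#' Analytic power for two-sample MR with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio per SD of
#' exposure in a case-control outcome GWAS: with total size
#' \eqn{N = n_{cases} + n_{controls}}, case fraction \eqn{\phi}, instrument
#' variance explained \eqn{R^2} and \eqn{\theta = \ln OR},
#' \deqn{power = \Phi\left(|\theta| \sqrt{N R^2 \phi (1-\phi)} -
#'   z_{1-\alpha/2}\right).}
#' At \eqn{OR = 1} the expression degenerates to \eqn{\alpha/2} (one tail of
#' the two-sided test); power increases monotonically in \eqn{N}, \eqn{R^2}
#' and \eqn{|\ln OR|}, and is symmetric under \eqn{OR \leftrightarrow 1/OR}.
#'
#' @param n_cases,n_controls Outcome GWAS composition (each `>= 1`).
#' @param r2 Exposure variance explained by the instruments, in (0, 1).
#' @param or_per_sd Causal odds ratio per SD of exposure (`> 0`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\] (vectorized over the numeric arguments).
#' @export
mr_power_binary <- function(n_cases, n_controls, r2, or_per_sd, alpha = 0.05) {
  if (any(n_cases < 1) || any(n_controls < 1))
    stop("n_cases and n_controls must be >= 1")
  if (any(r2 <= 0 | r2 >= 1)) stop("r2 must be in (0, 1)")
  if (any(or_per_sd <= 0)) stop("or_per_sd must be > 0")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
  n <- n_cases + n_controls
  phi <- n_cases / n
  theta <- log(or_per_sd)
  pnorm(abs(theta) * sqrt(n * r2 * phi * (1 - phi)) - qnorm(1 - alpha / 2))
}

#' Power grid over variance explained and odds ratios
#'
#' Cartesian product of `r2_values` and `or_values` with the analytic power
#' for each cell, e.g. the five instrument strengths 1%, 2.5%, 5%, 10% and
#' 15% against a range of ORs.
#'
#' @param n_cases,n_controls Outcome GWAS composition.
#' @param r2_values,or_values Non-empty numeric grids.
#' @param alpha Two-sided significance level (default 0.05).
#' @return `data.frame` with columns `r2, or, power`, ordered by `r2` then
#'   `or`.
#' @export
power_grid <- function(n_cases, n_controls, r2_values, or_values,
                       alpha = 0.05) {
  if (length(r2_values) == 0 || length(or_values) == 0)
    stop("r2_values and or_values must be non-empty")
  grid <- expand.grid(or = or_values, r2 = r2_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("r2", "or")]
  grid$power <- mr_power_binary(n_cases, n_controls, grid$r2, grid$or, alpha)
  rownames(grid) <- NULL
  grid
}
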