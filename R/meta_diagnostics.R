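#' Standard error from a reported confidence interval
#'
#' Inverts the Wald CI construction: `(ci_high - ci_low) / (2 * 1.959964)` at
#' the 95% level (general levels use the corresponding normal quantile). For
#' OR-scale inputs, log-transform first. Rounded published CIs that do not
#' exactly bracket the estimate are tolerated with a warning rather than an
#' error, since 2-decimal rounding routinely breaks exact bracketing.
#'
#' @param estimate Point estimate on the same (additive) scale as the bounds.
#' @param ci_low,ci_high CI bounds (`ci_low < ci_high`).
#' @param level Confidence level (default 0.95).
#' @return The implied standard error.
#' @export
se_from_ci <- function(estimate, ci_low, ci_high, level = 0.95) {
  if (any(ci_low >= ci_high)) stop("ci_low must be below ci_high")
  z <- if (level == 0.95) .z95 else qnorm(1 - (1 - level) / 2)
  if (any(estimate < ci_low | estimate > ci_high))
    warning("estimate outside its CI bounds (rounded inputs?)")
  (ci_high - ci_low) / (2 * z)
}

#' Two-sided Wald P-value
#'
#' `P = 2 * (1 - Phi(|estimate / se|))`; with [se_from_ci()] this recovers
#' the P-value implied by a printed estimate and confidence interval.
#'
#' @param estimate Point estimate.
#' @param se Standard error (`> 0`).
#' @return Two-sided normal P-value.
#' @export
wald_p <- function(estimate, se) {
  if (any(se <= 0)) stop("se must be > 0")
  2 * pnorm(-abs(estimate / se))
}

.strata_theta_se <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "mr_estimate"))) {
    return(data.frame(theta = vapply(estimates, `[[`, numeric(1), "theta"),
                      se = vapply(estimates, `[[`, numeric(1), "se")))
  }
  if (is.data.frame(estimates)) {
    if (all(c("theta", "se") %in% names(estimates)))
      return(estimates[, c("theta", "se")])
    if (all(c("or", "lci", "uci") %in% names(estimates)))
      return(data.frame(theta = log(estimates$or),
                        se = se_from_ci(log(estimates$or), log(estimates$lci),
                                        log(estimates$uci))))
  }
  stop("estimates must be a list of mr_estimate objects or a data.frame ",
       "with columns theta/se or or/lci/uci")
}

#' Between-strata heterogeneity of causal estimates
#'
#' Fixed-effect meta-analysis of stratum-specific causal estimates on the
#' log-OR scale (OR-scale inputs are log-transformed, with SEs recovered from
#' the CI bounds): pooled effect
#' \eqn{\bar\theta = \sum \theta_s / se_s^2 / \sum 1/se_s^2}, Cochran
#' \eqn{Q = \sum (\theta_s - \bar\theta)^2 / se_s^2} with \eqn{S - 1} degrees
#' of freedom, chi-square upper-tail P, and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} (0 when \eqn{Q = 0}).
#'
#' @param estimates Stratum estimates: a list of [mr_estimate] objects, or a
#'   `data.frame` with columns `theta`/`se` (log-OR scale) or `or`/`lci`/`uci`
#'   (OR scale, 95% bounds).
#' @param exposure,outcome Labels carried into the pooled estimate.
#' @return A `heterogeneity_result`: list with `q`, `df`, `pvalue`, `i2`,
#'   `n_strata` and `pooled` (the fixed-effect [mr_estimate]).
#' @export
strata_heterogeneity <- function(estimates, exposure = NA_character_,
                                 outcome = NA_character_) {
  d <- .strata_theta_se(estimates)
  if (nrow(d) < 2) stop("heterogeneity requires >= 2 strata")
  if (any(d$se <= 0)) stop("all stratum SEs must be > 0")
  w <- 1 / d$se^2
  pooled_theta <- sum(w * d$theta) / sum(w)
  q <- sum(w * (d$theta - pooled_theta)^2)
  df <- nrow(d) - 1L
  pvalue <- pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  pooled <- mr_estimate("pooled", pooled_theta, 1 / sqrt(sum(w)), nrow(d),
                        exposure = exposure, outcome = outcome)
  structure(list(q = q, df = df, pvalue = pvalue, i2 = i2,
                 n_strata = nrow(d), pooled = pooled),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Between-strata heterogeneity (%d strata): Q = %.3f (df %d), ",
              x$n_strata, x$q, x$df))
  cat(sprintf("P = %.3g, I^2 = %.1f%%\n", x$pvalue, x$i2))
  cat(sprintf("  fixed-effect pooled OR %.3f [%.3f-%.3f]\n",
              x$pooled$or, x$pooled$or_low, x$pooled$or_high))
  invisible(x)
}

#' Funnel-plot coordinates for an instrument set
#'
#' Per SNP, the fold risk increase \eqn{\exp(\beta_{GD}/\beta_{GP})} against
#' the instrument strength \eqn{\beta_{GP}/SE_{GD}^2}. Asymmetry of the cloud
#' around the causal estimate suggests directional pleiotropy.
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame` with
#'   all `beta_exposure > 0`.
#' @return Plot-ready `data.frame` with columns `rsid, fold_risk, strength`.
#' @export
funnel_points <- function(x) {
  inst <- as_instrument_df(x)
  if (any(inst$beta_exposure <= 0))
    stop("funnel points require beta_exposure > 0 (harmonized orientation)")
  data.frame(rsid = inst$rsid,
             fold_risk = exp(inst$beta_outcome / inst$beta_exposure),
             strength = inst$beta_exposure / inst$se_outcome^2,
             stringsAsFactors = FALSE)
}

#' Forest-plot table of causal estimates
#'
#' Flattens a collection of estimates into ordered plot-ready rows (input
#' order preserved).
#'
#' @param estimates List of [mr_estimate] objects.
#' @param labels Row labels; defaults to `exposure -> outcome (method)`.
#' @return `data.frame` with columns `label, or, lci, uci, p, n_snps`.
#' @export
forest_table <- function(estimates, labels = NULL) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  labels <- labels %||% vapply(estimates, function(e)
    sprintf("%s -> %s (%s)", e$exposure, e$outcome, e$method), character(1))
  data.frame(label = labels,
             or = vapply(estimates, `[[`, numeric(1), "or"),
             lci = vapply(estimates, `[[`, numeric(1), "or_low"),
             uci = vapply(estimates, `[[`, numeric(1), "or_high"),
             p = vapply(estimates, `[[`, numeric(1), "pvalue"),
             n_snps = vapply(estimates, `[[`, integer(1), "n_snps"),
             stringsAsFactors = FALSE)
}
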