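#' Construct a causal-effect estimate
#'
#' Container for a causal estimate on the log-OR-per-SD scale with its
#' OR-scale view. Unless supplied, the 95% CI is Wald-type
#' (`theta +/- 1.959964 * se`) and the P-value two-sided normal. `se` may be
#' `NA` when no uncertainty was computed (e.g. a weighted median with the
#' bootstrap disabled), in which case CI and P are `NA` too.
#'
#' @param method Method label (`"wald"`, `"ivw"`, `"mle"`, `"wmedian"`,
#'   `"egger-slope"`, ...).
#' @param theta Log odds ratio per SD of exposure.
#' @param se Standard error of `theta` (`> 0`, or `NA`).
#' @param n_snps Number of instruments used.
#' @param pvalue,ci_low,ci_high Optional overrides (e.g. t-based for MR-Egger).
#' @param exposure,outcome Labels.
#' @return Object of class `mr_estimate` with fields `method, theta, se,
#'   ci_low, ci_high, pvalue, n_snps, or, or_low, or_high, exposure, outcome`.
#' @export
mr_estimate <- function(method, theta, se, n_snps, pvalue = NULL,
                        ci_low = NULL, ci_high = NULL,
                        exposure = NA_character_, outcome = NA_character_) {
  if (!is.na(se) && se <= 0) stop("se must be > 0")
  if (is.na(se)) {
    ci_low <- ci_low %||% NA_real_
    ci_high <- ci_high %||% NA_real_
    pvalue <- pvalue %||% NA_real_
  } else {
    ci_low <- ci_low %||% (theta - .z95 * se)
    ci_high <- ci_high %||% (theta + .z95 * se)
    pvalue <- pvalue %||% (2 * pnorm(-abs(theta / se)))
  }
  structure(list(method = method, theta = theta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                 n_snps = as.integer(n_snps),
                 or = exp(theta), or_low = exp(ci_low), or_high = exp(ci_high),
                 exposure = exposure, outcome = outcome),
            class = "mr_estimate")
}

#' Fill the odds-ratio view of an estimate
#'
#' Sets `or = exp(theta)` and OR-scale CI bounds from the theta-scale fields.
#' Estimates built by [mr_estimate()] already carry these; the function is
#' idempotent.
#'
#' @param est An `mr_estimate`.
#' @return The estimate with `or`, `or_low`, `or_high` filled.
#' @export
to_odds_scale <- function(est) {
  est$or <- exp(est$theta)
  est$or_low <- exp(est$ci_low)
  est$or_high <- exp(est$ci_high)
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s)%s: OR %.3f [%.3f-%.3f] per SD\n",
              x$method,
              if (is.na(x$exposure)) "" else
                sprintf(" %s -> %s", x$exposure, x$outcome),
              x$or, x$or_low, x$or_high))
  cat(sprintf("  theta = %.4f, se = %.4f, P = %.3g, J = %d\n",
              x$theta, x$se, x$pvalue, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) as_results_rows(x)
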