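#' Per-SNP Wald ratio estimates
#'
#' For each harmonized instrument, the ratio estimate
#' \eqn{\theta_j = \beta_{GD,j} / \beta_{GP,j}} with first-order delta-method
#' standard error \eqn{SE_{GD,j} / \beta_{GP,j}} (default) or the
#' second-order form
#' \eqn{\sqrt{SE_{GD}^2/\beta_{GP}^2 + \beta_{GD}^2 SE_{GP}^2 / \beta_{GP}^4}},
#' and inverse-variance weight \eqn{1/se_j^2} (for the first-order SE this is
#' \eqn{\beta_{GP}^2 / SE_{GD}^2}, the weighting convention shared by IVW and
#' the weighted median).
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame`.
#' @param se_method `"first"` (default) or `"second"` order delta-method SE.
#' @return `data.frame` with columns `rsid, theta_j, se_j, weight`.
#' @export
wald_ratio <- function(x, se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  inst <- as_instrument_df(x)
  zero <- inst$beta_exposure == 0
  if (any(zero))
    stop("undefined Wald ratio (beta_exposure = 0) for SNP(s): ",
         paste(inst$rsid[zero], collapse = ", "))
  theta_j <- inst$beta_outcome / inst$beta_exposure
  se_j <- switch(se_method,
    first = inst$se_outcome / abs(inst$beta_exposure),
    second = sqrt(inst$se_outcome^2 / inst$beta_exposure^2 +
                    inst$beta_outcome^2 * inst$se_exposure^2 /
                      inst$beta_exposure^4))
  data.frame(rsid = inst$rsid, theta_j = theta_j, se_j = se_j,
             weight = 1 / se_j^2, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effect combination of the per-SNP Wald ratios with weights
#' \eqn{w_j = \beta_{GP,j}^2 / SE_{GD,j}^2}:
#' \eqn{\hat\theta = \sum w_j \theta_j / \sum w_j},
#' \eqn{se = 1/\sqrt{\sum w_j}}; equivalent to weighted least squares of
#' `beta_outcome` on `beta_exposure` through the origin.
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame`.
#' @return An [mr_estimate] with method `"ivw"` (`"wald"` for a single SNP).
#' @export
mr_ivw <- function(x) {
  inst <- as_instrument_df(x)
  if (nrow(inst) < 1) stop("at least one instrument is required")
  r <- wald_ratio(inst)
  w <- r$weight
  theta <- sum(w * r$theta_j) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_estimate(if (nrow(inst) == 1) "wald" else "ivw", theta, se, nrow(inst),
              exposure = .label(x, "exposure"), outcome = .label(x, "outcome"))
}

.label <- function(x, which) {
  if (inherits(x, "instrument_set")) x[[which]] else NA_character_
}

# profile log-likelihood of the bivariate-normal summary model; for fixed
# theta the true per-SNP exposure effects xi_j have the closed form below,
# so the (J+1)-dimensional likelihood reduces to a 1-D profile in theta
profile_loglik <- function(theta, inst) {
  xi <- (inst$beta_exposure * inst$se_outcome^2 +
           theta * inst$beta_outcome * inst$se_exposure^2) /
    (inst$se_outcome^2 + theta^2 * inst$se_exposure^2)
  -sum((inst$beta_exposure - xi)^2 / (2 * inst$se_exposure^2) +
         (inst$beta_outcome - theta * xi)^2 / (2 * inst$se_outcome^2))
}

#' Likelihood-based causal estimate
#'
#' Maximum-likelihood estimate under the bivariate-normal summary model: the
#' observed SNP-exposure effect is \eqn{N(\xi_j, SE_{GP,j}^2)} and the
#' SNP-outcome effect \eqn{N(\theta \xi_j, SE_{GD,j}^2)}, independently
#' across SNPs and samples. The likelihood is quadratic in each \eqn{\xi_j},
#' so they are profiled out in closed form and \eqn{\theta} found by 1-D
#' maximization of the profile log-likelihood, initialized at the IVW
#' estimate. The standard error comes from the curvature (negative inverse
#' second derivative, central differences) of the profile log-likelihood at
#' the maximum; the 95% CI is Wald-type. This accounts for uncertainty in the
#' SNP-exposure effects, which IVW ignores; as \eqn{SE_{GP} \to 0} the two
#' coincide.
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame`.
#' @param tol Convergence tolerance on theta (default `1e-10`).
#' @return An [mr_estimate] with method `"mle"`.
#' @export
mr_mle <- function(x, tol = 1e-10) {
  inst <- as_instrument_df(x)
  if (nrow(inst) < 1) stop("at least one instrument is required")
  ivw <- mr_ivw(inst)
  half <- max(1, 50 * ivw$se)
  lower <- ivw$theta - half
  upper <- ivw$theta + half
  for (attempt in 1:6) {
    opt <- optimize(profile_loglik, c(lower, upper), inst = inst,
                    maximum = TRUE, tol = tol)
    width <- upper - lower
    at_edge <- opt$maximum - lower < 1e-6 * width ||
      upper - opt$maximum < 1e-6 * width
    if (!at_edge) break
    lower <- lower - width
    upper <- upper + width
    if (attempt == 6)
      stop("profile-likelihood maximization did not converge; ",
           sprintf("last interval [%g, %g], candidate %g", lower, upper,
                   opt$maximum))
  }
  that <- opt$maximum
  h <- 1e-5 * max(1, abs(that))
  d2 <- (profile_loglik(that + h, inst) - 2 * profile_loglik(that, inst) +
           profile_loglik(that - h, inst)) / h^2
  if (!is.finite(d2) || d2 >= 0)
    stop("profile log-likelihood curvature is not negative at the optimum")
  se <- 1 / sqrt(-d2)
  mr_estimate("mle", that, se, nrow(inst),
              exposure = .label(x, "exposure"), outcome = .label(x, "outcome"))
}

# interpolated weighted median of ratio estimates; weights normalized to 1
weighted_median_point <- function(theta_j, weight) {
  ord <- order(theta_j)
  th <- theta_j[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The interpolated weighted median of the per-SNP Wald ratios, with
#' inverse-variance weights: consistent when instruments carrying at least
#' half of the weight are valid, hence robust to a minority of pleiotropic
#' SNPs. The standard error is a parametric bootstrap: both samples' effects
#' are resampled independently from
#' \eqn{N(\hat\beta_{GP}, SE_{GP}^2)} and \eqn{N(\hat\beta_{GD}, SE_{GD}^2)},
#' the estimate recomputed, and the SD over replicates taken. With
#' `n_boot = 0` only the point estimate is returned (`se`, CI and P are `NA`).
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame`
#'   (at least 3 instruments).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @param se_method Ratio-SE order for the weights, as in [wald_ratio()].
#' @return An [mr_estimate] with method `"wmedian"`.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed = 1,
                               se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  inst <- as_instrument_df(x)
  if (nrow(inst) < 3) stop("the weighted median requires >= 3 instruments")
  r <- wald_ratio(inst, se_method = se_method)
  theta <- weighted_median_point(r$theta_j, r$weight)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bgp <- rnorm(nrow(inst), inst$beta_exposure, inst$se_exposure)
        bgd <- rnorm(nrow(inst), inst$beta_outcome, inst$se_outcome)
        tj <- bgd / bgp
        wj <- if (se_method == "first") bgp^2 / inst$se_outcome^2 else
          1 / (inst$se_outcome^2 / bgp^2 +
                 bgd^2 * inst$se_exposure^2 / bgp^4)
        weighted_median_point(tj, wj)
      }, numeric(1))
    })
    se <- sd(boots)
  }
  mr_estimate("wmedian", theta, se, nrow(inst),
              exposure = .label(x, "exposure"), outcome = .label(x, "outcome"))
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with an unconstrained intercept and weights \eqn{1/SE_{GD}^2},
#' fitted on instruments oriented to the exposure-increasing allele
#' (all `beta_exposure > 0`, which the intercept's interpretation requires).
#' The intercept estimates average directional pleiotropy; the slope is the
#' pleiotropy-adjusted causal effect. Inference follows the multiplicative
#' random-effects convention: the residual scale is
#' \eqn{\hat\sigma = \max(1, \sqrt{RSS_w / (J - 2)})} (no underdispersion),
#' coefficient SEs are scaled by \eqn{\hat\sigma}, and P-values use the t
#' distribution with \eqn{J - 2} degrees of freedom. Per-SNP outlier flags
#' come from [detect_outliers()].
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame`
#'   (at least 3 instruments; at J = 2 there are no residual df).
#' @param alpha Significance level for the Bonferroni outlier flags.
#' @return An `egger_result`: list with `slope` (an [mr_estimate], method
#'   `"egger-slope"`, t-based CI and P), `intercept`, `intercept_se`,
#'   `intercept_p`, `residual_scale`, `n_snps`, `coefficients`, `outliers`.
#' @export
mr_egger <- function(x, alpha = 0.05) {
  inst <- as_instrument_df(x)
  J <- nrow(inst)
  if (J < 3) stop("MR-Egger requires >= 3 instruments")
  if (any(inst$beta_exposure <= 0))
    stop("MR-Egger requires all beta_exposure > 0 (harmonized orientation)")
  w <- 1 / inst$se_outcome^2
  fit <- lm(beta_outcome ~ beta_exposure, data = inst, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma                      # sqrt(weighted RSS / (J - 2))
  est <- coef(fit)
  # unscaled covariance so the residual-scale floor applies cleanly even at
  # an exact fit (sigma = 0)
  ses <- sqrt(diag(sm$cov.unscaled)) * max(1, sigma)
  names(ses) <- names(est)
  tq <- qt(0.975, J - 2)
  pvals <- 2 * pt(-abs(est / ses), J - 2)
  slope <- mr_estimate("egger-slope", est[["beta_exposure"]],
                       ses[["beta_exposure"]], J,
                       pvalue = pvals[["beta_exposure"]],
                       ci_low = est[["beta_exposure"]] - tq * ses[["beta_exposure"]],
                       ci_high = est[["beta_exposure"]] + tq * ses[["beta_exposure"]],
                       exposure = .label(x, "exposure"),
                       outcome = .label(x, "outcome"))
  res <- structure(list(slope = slope,
                        intercept = est[["(Intercept)"]],
                        intercept_se = ses[["(Intercept)"]],
                        intercept_p = pvals[["(Intercept)"]],
                        residual_scale = max(1, sigma),
                        n_snps = J,
                        coefficients = c(intercept = est[["(Intercept)"]],
                                         slope = est[["beta_exposure"]]),
                        outliers = NULL),
                   class = "egger_result")
  res$outliers <- detect_outliers(res, inst, alpha = alpha)
  res
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger (J = %d): slope OR %.3f [%.3f-%.3f], P = %.3g\n",
              x$n_snps, x$slope$or, x$slope$or_low, x$slope$or_high,
              x$slope$pvalue))
  cat(sprintf("  intercept = %.4f (se %.4f), P = %.3g; residual scale %.3f\n",
              x$intercept, x$intercept_se, x$intercept_p, x$residual_scale))
  nf <- sum(x$outliers$flagged)
  cat(sprintf("  outliers flagged (Bonferroni): %d\n", nf))
  invisible(x)
}

#' Flag genetic outliers from an MR-Egger fit
#'
#' Standardizes each instrument's weighted residual from the Egger line by
#' its outcome SE times the fitted residual scale, converts to a two-sided
#' normal P-value, applies a Bonferroni correction
#' (\eqn{\min(1, p \times J)}) and flags SNPs below `alpha`.
#'
#' @param egger An `egger_result` from [mr_egger()].
#' @param x The instruments the fit was computed on.
#' @param alpha Flagging threshold on the Bonferroni-corrected P (default
#'   0.05).
#' @return `data.frame` with columns `rsid, raw_p, bonferroni_p, flagged`.
#' @export
detect_outliers <- function(egger, x, alpha = 0.05) {
  inst <- as_instrument_df(x)
  J <- nrow(inst)
  fitted <- egger$coefficients[["intercept"]] +
    egger$coefficients[["slope"]] * inst$beta_exposure
  z <- (inst$beta_outcome - fitted) / (inst$se_outcome * egger$residual_scale)
  raw_p <- 2 * pnorm(-abs(z))
  bonf <- pmin(1, raw_p * J)
  data.frame(rsid = inst$rsid, raw_p = raw_p, bonferroni_p = bonf,
             flagged = bonf < alpha, stringsAsFactors = FALSE)
}
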