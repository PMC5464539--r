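#' Simulation configuration for two-sample summary statistics
#'
#' Defines the generative model used by [simulate_two_sample()]: `n_snps`
#' independent instruments with true per-allele exposure effects `xi_j` (SD
#' units) scaled so the instrument set explains exactly `target_r2` of the
#' exposure variance, a causal log-OR per SD `theta`, and a
#' `floor(invalid_fraction * n_snps)`-sized subset of invalid instruments
#' carrying direct (pleiotropic) outcome effects
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` drawn independently of
#' `xi_j` (so the InSIDE condition holds). Defaults mirror a large
#' adiposity-on-lung-cancer analysis: exposure GWAS of 339,224 individuals,
#' outcome GWAS of 29,266 cases and 56,450 controls, 25 instruments
#' explaining 2.7% of exposure variance.
#'
#' @param n_snps Number of instruments J (`>= 1`).
#' @param theta True causal log odds ratio per SD of exposure.
#' @param n_exposure Exposure (continuous-trait) GWAS sample size.
#' @param n_cases,n_controls Outcome (case-control) GWAS composition.
#' @param target_r2 Total exposure variance explained, in (0, 1).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5\].
#' @param invalid_fraction Fraction of invalid (pleiotropic) instruments,
#'   in \[0, 1\].
#' @param pleiotropy_mean,pleiotropy_sd Mean (log-odds) and SD (`>= 0`) of
#'   the pleiotropic effects on invalid instruments; a zero mean gives
#'   balanced, a nonzero mean directional pleiotropy.
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G alleles,
#'   to exercise [resolve_palindromes()] (default 0).
#' @param flip_fraction Fraction of outcome rows whose allele labels are
#'   swapped (effect negated), to exercise [harmonize()] (default 0).
#' @param sampling_noise If `FALSE`, observed effects equal the true effects
#'   exactly (the infinite-sample limit); SEs keep their formula values so
#'   the tables remain valid.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 25, theta = 0, n_exposure = 339224,
                       n_cases = 29266, n_controls = 56450,
                       target_r2 = 0.027, maf_range = c(0.05, 0.5),
                       invalid_fraction = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0, palindromic_fraction = 0,
                       flip_fraction = 0, sampling_noise = TRUE, seed = 1L) {
  stopifnot(n_snps >= 1, n_exposure >= 1, n_cases >= 1, n_controls >= 1,
            target_r2 > 0, target_r2 < 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            invalid_fraction >= 0, invalid_fraction <= 1,
            pleiotropy_sd >= 0, palindromic_fraction >= 0,
            palindromic_fraction <= 1, flip_fraction >= 0,
            flip_fraction <= 1)
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, target_r2 = target_r2,
                 maf_range = maf_range, invalid_fraction = invalid_fraction,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 palindromic_fraction = palindromic_fraction,
                 flip_fraction = flip_fraction,
                 sampling_noise = isTRUE(sampling_noise),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the [sim_config()] arguments; absent keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(sim_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Named simulation scenarios
#'
#' Presets over the default study conditions ([sim_config()]):
#' \describe{
#'   \item{`null`}{no causal effect, all instruments valid
#'     (`theta = 0, invalid_fraction = 0`).}
#'   \item{`valid`}{causal effect `theta = 0.2`, all instruments valid.}
#'   \item{`balanced`}{`theta = 0.2` with 30% invalid instruments whose
#'     pleiotropy is balanced (`pleiotropy_mean = 0, pleiotropy_sd = 0.05`).}
#'   \item{`directional`}{`theta = 0.2` with 30% invalid instruments whose
#'     pleiotropy is directional (`pleiotropy_mean = 0.05,
#'     pleiotropy_sd = 0.02`).}
#'   \item{`thirty_invalid`}{alias of `directional` (30% invalid).}
#' }
#'
#' @param name One of `"null"`, `"valid"`, `"balanced"`, `"directional"`,
#'   `"thirty_invalid"`.
#' @param seed Seed stored in the returned configuration.
#' @return A fully specified `sim_config`.
#' @export
mr_scenario <- function(name, seed = 1L) {
  presets <- list(
    null = list(theta = 0, invalid_fraction = 0),
    valid = list(theta = 0.2, invalid_fraction = 0),
    balanced = list(theta = 0.2, invalid_fraction = 0.3,
                    pleiotropy_mean = 0, pleiotropy_sd = 0.05),
    directional = list(theta = 0.2, invalid_fraction = 0.3,
                       pleiotropy_mean = 0.05, pleiotropy_sd = 0.02),
    thirty_invalid = list(theta = 0.2, invalid_fraction = 0.3,
                          pleiotropy_mean = 0.05, pleiotropy_sd = 0.02))
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  do.call(sim_config, c(presets[[name]], list(seed = seed)))
}

# ordered non-palindromic allele pairs
.np_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                   c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates matched exposure and outcome association tables under the model
#' the summary-level estimators assume. Per SNP j: MAF ~ Uniform(`maf_range`);
#' true exposure effects \eqn{\xi_j = c |Z_j|} (exposure-increasing
#' orientation) with the scale c chosen so
#' \eqn{\sum_j 2 \xi_j^2 f_j (1 - f_j)} equals `target_r2` exactly;
#' pleiotropic effects \eqn{\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)} on
#' a random `floor(invalid_fraction * J)`-subset, 0 elsewhere, independent of
#' \eqn{\xi} (InSIDE). Sampling SEs follow the asymptotic formulas
#' \eqn{SE_{GP,j} = 1/\sqrt{2 n_{exp} f_j (1-f_j)}} and
#' \eqn{SE_{GD,j} = 1/\sqrt{2 f_j (1-f_j) N \phi (1-\phi)}}; observed effects
#' are \eqn{\hat\beta_{GP,j} \sim N(\xi_j, SE_{GP,j}^2)} and
#' \eqn{\hat\beta_{GD,j} \sim N(\theta \xi_j + \alpha_j, SE_{GD,j}^2)}.
#' Summary statistics are drawn directly from these sampling distributions
#' rather than from individual-level genotypes: it is fast and matches
#' exactly the model the estimators fit. P-values come from the Wald z of
#' each observed effect; alleles are non-palindromic unless
#' `palindromic_fraction > 0`.
#'
#' @param config A [sim_config()].
#' @return A list of class `mr_simulation`: `exposure` and `outcome`
#'   association tables in canonical [read_association_table()] layout,
#'   `truth` (`data.frame` `rsid xi alpha invalid` with attribute
#'   `realized_r2`), and the `config`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snps
  n_invalid <- floor(config$invalid_fraction * J)
  if (n_invalid >= J && J > 0 && config$invalid_fraction >= 1)
    warning("all instruments are invalid; causal recovery is not identified")
  with_seed(config$seed, {
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    xi_raw <- abs(rnorm(J))
    het <- 2 * maf * (1 - maf)
    xi <- xi_raw * sqrt(config$target_r2 / sum(xi_raw^2 * het))
    invalid <- rep(FALSE, J)
    invalid[sample.int(J, n_invalid)] <- TRUE
    alpha <- ifelse(invalid,
                    rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd), 0)
    n_out <- config$n_cases + config$n_controls
    phi <- config$n_cases / n_out
    se_gp <- 1 / sqrt(het * config$n_exposure)
    se_gd <- 1 / sqrt(het * n_out * phi * (1 - phi))
    if (config$sampling_noise) {
      beta_gp <- rnorm(J, xi, se_gp)
      beta_gd <- rnorm(J, config$theta * xi + alpha, se_gd)
    } else {
      beta_gp <- xi
      beta_gd <- config$theta * xi + alpha
    }
    n_pal <- floor(config$palindromic_fraction * J)
    pair_idx <- sample.int(nrow(.np_pairs), J, replace = TRUE)
    alleles <- .np_pairs[pair_idx, , drop = FALSE]
    if (n_pal > 0) {
      which_pal <- sample.int(J, n_pal)
      alleles[which_pal, ] <- .pal_pairs[sample.int(nrow(.pal_pairs), n_pal,
                                                    replace = TRUE), ,
                                         drop = FALSE]
    }
    rsid <- sprintf("rs%07d", seq_len(J))
    chrom <- as.character(sample.int(22, J, replace = TRUE))
    pos <- sample.int(2e8, J)
    exposure <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                           effect_allele = alleles[, 1],
                           other_allele = alleles[, 2],
                           eaf = maf, beta = beta_gp, se = se_gp,
                           pvalue = pmax(2 * pnorm(-abs(beta_gp / se_gp)),
                                         1e-300),
                           n = config$n_exposure, info = NA_real_,
                           unit = "SD", stringsAsFactors = FALSE)
    outcome <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                          effect_allele = alleles[, 1],
                          other_allele = alleles[, 2],
                          eaf = maf, beta = beta_gd, se = se_gd,
                          pvalue = pmax(2 * pnorm(-abs(beta_gd / se_gd)),
                                        1e-300),
                          n = n_out, info = NA_real_,
                          unit = "log-odds", stringsAsFactors = FALSE)
    if (config$flip_fraction > 0) {
      n_flip <- floor(config$flip_fraction * J)
      fl <- sample.int(J, n_flip)
      ea <- outcome$effect_allele[fl]
      outcome$effect_allele[fl] <- outcome$other_allele[fl]
      outcome$other_allele[fl] <- ea
      outcome$beta[fl] <- -outcome$beta[fl]
      outcome$eaf[fl] <- 1 - outcome$eaf[fl]
    }
    truth <- data.frame(rsid = rsid, xi = xi, alpha = alpha,
                        invalid = invalid, stringsAsFactors = FALSE)
    attr(truth, "realized_r2") <- sum(xi^2 * het)
    structure(list(exposure = exposure, outcome = outcome, truth = truth,
                   config = config),
              class = "mr_simulation")
  })
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf(paste0("Simulated two-sample summary statistics: J = %d, ",
                     "theta = %g, %d invalid, realized r2 = %.4f\n"),
              x$config$n_snps, x$config$theta, sum(x$truth$invalid),
              attr(x$truth, "realized_r2")))
  invisible(x)
}

fit_one_method <- function(method, iset, n_boot, rep_seed) {
  switch(method,
         ivw = mr_ivw(iset),
         mle = mr_mle(iset),
         wmedian = mr_weighted_median(iset, n_boot = n_boot, seed = rep_seed),
         egger = mr_egger(iset)$slope,
         stop("unknown method '", method, "'"))
}

#' Monte-Carlo calibration of an estimator
#'
#' Repeatedly simulates two-sample data under `config`, runs the full
#' harmonization-plus-estimation path, and summarizes mean bias, empirical
#' and mean model SE, 95% CI coverage and the rejection rate at alpha = 0.05.
#' Replicate r uses seed `seed + r`; failed replicates are excluded and
#' counted.
#'
#' @param method One of `"ivw"`, `"mle"`, `"wmedian"`, `"egger"` (the Egger
#'   slope; the per-replicate intercept is also recorded).
#' @param config A [sim_config()]; `config$theta` is the estimand.
#' @param reps Number of replicates.
#' @param seed Base seed for the replicate stream.
#' @param n_boot Bootstrap replicates for the weighted-median SE (default
#'   200 to keep calibration studies affordable).
#' @return List with `results` (per-replicate `data.frame`
#'   `rep estimate se covered rejected intercept`) and `summary` (one-row
#'   `data.frame`).
#' @export
calibration_study <- function(method, config, reps = 100, seed = 1,
                              n_boot = 200) {
  rows <- vector("list", reps)
  n_fail <- 0L
  for (r in seq_len(reps)) {
    rep_seed <- (seed + r) %% .Machine$integer.max
    cfg <- config
    cfg$seed <- as.integer(rep_seed)
    row <- tryCatch({
      sim <- simulate_two_sample(cfg)
      iset <- suppressWarnings(harmonize(sim$exposure, sim$outcome))
      intercept <- NA_real_
      if (method == "egger") {
        eg <- mr_egger(iset)
        est <- eg$slope
        intercept <- eg$intercept
      } else {
        est <- fit_one_method(method, iset, n_boot, rep_seed)
      }
      data.frame(rep = r, estimate = est$theta, se = est$se,
                 covered = !is.na(est$se) && est$ci_low <= config$theta &&
                   config$theta <= est$ci_high,
                 rejected = !is.na(est$pvalue) && est$pvalue < 0.05,
                 intercept = intercept)
    }, error = function(e) NULL)
    if (is.null(row)) n_fail <- n_fail + 1L else rows[[r]] <- row
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0)
    stop("all ", reps, " replicates failed for method '", method, "'")
  summ <- data.frame(method = method, reps = reps, n_fail = n_fail,
                     true_theta = config$theta,
                     mean_estimate = mean(res$estimate),
                     mean_bias = mean(res$estimate) - config$theta,
                     empirical_se = sd(res$estimate),
                     mean_model_se = mean(res$se),
                     coverage = mean(res$covered),
                     rejection_rate = mean(res$rejected),
                     mean_intercept = mean(res$intercept),
                     stringsAsFactors = FALSE)
  list(results = res, summary = summ)
}
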