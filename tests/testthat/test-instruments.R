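test_that("genome-wide selection uses a strict threshold and sorts by P", {
  assocs <- make_assoc(3, pvalue = c(4.9e-8, 5e-8, 1e-9))
  kept <- select_genomewide(assocs)
  expect_equal(kept$rsid, c("rs3", "rs1"))   # 5e-8 excluded, sorted ascending

  all_null <- make_assoc(4, pvalue = rep(1, 4))
  expect_equal(nrow(select_genomewide(all_null)), 0)

  # brute-force oracle on random records
  set.seed(21)
  assocs <- make_assoc(200, pvalue = 10^runif(200, -12, 0))
  kept <- select_genomewide(assocs)
  expect_setequal(kept$rsid, assocs$rsid[assocs$pvalue < 5e-8])
  expect_false(is.unsorted(kept$pvalue))
})

test_that("LD pruning is greedy by significance and matches a brute-force oracle", {
  assocs <- make_assoc(2, pvalue = c(1e-10, 1e-9))
  ld <- data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.5)
  expect_equal(ld_prune(assocs, ld)$rsid, "rs1")

  # unlinked SNPs are all retained
  expect_equal(nrow(ld_prune(assocs, NULL)), 2)
  expect_equal(nrow(ld_prune(assocs, data.frame(rsid_a = "rs1",
                                                rsid_b = "rs2", r2 = 0))), 2)

  expect_error(ld_prune(assocs, data.frame(rsid_a = "rs1", rsid_b = "rs2",
                                           r2 = 1.2)), "\\[0, 1\\]")

  # 50 SNPs with a random R^2 matrix against an independent greedy reference
  set.seed(31)
  n <- 50
  assocs <- make_assoc(n, pvalue = 10^runif(n, -30, -8))
  pairs <- t(combn(n, 2))
  r2 <- ifelse(runif(nrow(pairs)) < 0.1, runif(nrow(pairs)), 0)
  ld <- data.frame(rsid_a = assocs$rsid[pairs[, 1]],
                   rsid_b = assocs$rsid[pairs[, 2]], r2 = r2)
  got <- ld_prune(assocs, ld)

  mat <- matrix(0, n, n, dimnames = list(assocs$rsid, assocs$rsid))
  mat[cbind(ld$rsid_a, ld$rsid_b)] <- ld$r2
  mat[cbind(ld$rsid_b, ld$rsid_a)] <- ld$r2
  kept <- character(0)
  for (rs in assocs$rsid[order(assocs$pvalue)])
    if (all(mat[rs, kept] < 0.01)) kept <- c(kept, rs)
  expect_equal(got$rsid, kept)

  # every retained pair re-queries below the threshold
  lk <- outer(got$rsid, got$rsid, function(a, b) mat[cbind(a, b)])
  diag(lk) <- 0
  expect_true(all(lk < 0.01))
})

test_that("covariate-adjusted filtering keeps SNPs at or below the cut", {
  assocs <- make_assoc(3)
  padj <- c(rs1 = 0.04, rs2 = 0.05, rs3 = 0.06)
  expect_equal(filter_covariate_adjusted(assocs, padj)$rsid, c("rs1", "rs2"))

  expect_error(filter_covariate_adjusted(assocs, padj[1:2]), "rs3")
  expect_warning(out <- filter_covariate_adjusted(assocs, c(rs0 = 0.5),
                                                  strict = FALSE),
                 "without covariate-adjusted")
  expect_equal(nrow(out), 0)

  set.seed(41)
  assocs <- make_assoc(100)
  padj <- setNames(runif(100), assocs$rsid)
  got <- filter_covariate_adjusted(assocs, padj)
  expect_equal(got$rsid, assocs$rsid[padj <= 0.05])
})

test_that("pooled SD is the sample-size-weighted mean of study SDs", {
  expect_equal(pooled_sd(c(1000, 3000), c(4, 5)), 4.75)
  expect_equal(pooled_sd(500, 4.6), 4.6)

  set.seed(51)
  n <- sample(100:10000, 10)
  s <- runif(10, 0.5, 5)
  acc <- 0
  for (i in 1:10) acc <- acc + n[i] * s[i]
  expect_equal(pooled_sd(n, s), acc / sum(n), tolerance = 1e-12)
  expect_equal(pooled_sd(n, s, method = "rms"),
               sqrt(sum(n * s^2) / sum(n)), tolerance = 1e-12)

  expect_error(pooled_sd(numeric(0), numeric(0)), "at least one")
  expect_error(pooled_sd(c(10, 0), c(1, 1)), ">= 1")
})

test_that("SD recalibration divides beta and se and commutes with selection", {
  assocs <- make_assoc(1, beta = 0.046, se = 0.0092)
  out <- recalibrate_to_sd(assocs, 4.6)      # one BMI-like kg/m^2 SD
  expect_equal(out$beta, 0.01)
  expect_equal(out$se, 0.002)
  expect_equal(out$unit, "SD")

  expect_equal(recalibrate_to_sd(assocs, 1)$beta, assocs$beta)

  # inverse property
  back <- recalibrate_to_sd(assocs, 4.6)
  back$beta <- back$beta * 4.6
  back$se <- back$se * 4.6
  expect_equal(back$beta, assocs$beta, tolerance = 1e-15)

  # P-values untouched, so recalibration commutes with selection
  set.seed(61)
  assocs <- make_assoc(50, pvalue = 10^runif(50, -12, 0))
  a <- select_genomewide(recalibrate_to_sd(assocs, 4.6))
  b <- recalibrate_to_sd(select_genomewide(assocs), 4.6)
  expect_equal(a, b)
})

test_that("palindromic SNPs are proxied above the LD cut or dropped", {
  exposure <- make_assoc(4,
                         effect_allele = c("A", "A", "C", "C"),
                         other_allele = c("T", "G", "G", "G"))
  proxies <- data.frame(rsid = c("rs3", "rs4"),
                        proxy_rsid = c("rs103", "rs104"),
                        r2 = c(0.9, 0.8),
                        effect_allele = c("A", "A"),
                        other_allele = c("C", "C"),
                        beta = c(0.05, 0.05), se = c(0.01, 0.01),
                        pvalue = c(1e-9, 1e-9), stringsAsFactors = FALSE)
  out <- resolve_palindromes(exposure, proxies)
  # rs1 (A/T, no proxy) dropped; rs2 passes; rs3 replaced (r2 = 0.9 > 0.8);
  # rs4 dropped (r2 = 0.8 is not > 0.8)
  expect_equal(out$rsid, c("rs2", "rs103"))
  expect_equal(out$proxy_of, c("", "rs3"))
  expect_equal(out$beta[2], 0.05)
  expect_equal(attr(out, "n_palindromic"), 3L)
  expect_equal(attr(out, "n_replaced"), 1L)
  expect_equal(attr(out, "n_dropped"), 2L)

  # a palindromic proxy is refused (no chained lookup)
  pal_proxy <- data.frame(rsid = "rs3", proxy_rsid = "rs203", r2 = 0.95,
                          effect_allele = "G", other_allele = "C",
                          beta = 0.04, se = 0.01, pvalue = 1e-9,
                          stringsAsFactors = FALSE)
  expect_warning(out2 <- resolve_palindromes(exposure[3, ], pal_proxy),
                 "itself palindromic")
  expect_equal(nrow(out2), 0)

  # property: the output never contains a palindromic SNP
  sim <- simulate_two_sample(sim_config(n_snps = 40,
                                        palindromic_fraction = 0.4,
                                        seed = 9))
  res <- resolve_palindromes(sim$exposure)
  expect_false(any(is_palindromic <- (res$effect_allele == "A" &
                                        res$other_allele == "T") |
                     (res$effect_allele == "T" & res$other_allele == "A") |
                     (res$effect_allele == "C" & res$other_allele == "G") |
                     (res$effect_allele == "G" & res$other_allele == "C")))
})

test_that("harmonization follows the allele truth table", {
  # exposure: EA = A, OA = G, beta = 0.1; outcome beta = 0.05 under every
  # reconcilable outcome allele configuration
  exposure <- make_assoc(1, effect_allele = "A", other_allele = "G",
                         beta = 0.1)
  cases <- list(list(ea = "A", oa = "G", sign = +1),   # identical
                list(ea = "G", oa = "A", sign = -1),   # swapped
                list(ea = "T", oa = "C", sign = +1),   # strand complement
                list(ea = "C", oa = "T", sign = -1))   # complement + swap
  for (cs in cases) {
    outcome <- make_assoc(1, effect_allele = cs$ea, other_allele = cs$oa,
                          beta = 0.05, se = 0.02)
    iset <- harmonize(exposure, outcome)
    expect_equal(iset$instruments$beta_exposure, 0.1)
    expect_equal(iset$instruments$beta_outcome, cs$sign * 0.05,
                 info = paste(cs$ea, cs$oa))
  }

  # irreconcilable allele sets are dropped with a named diagnostic
  outcome <- make_assoc(1, effect_allele = "A", other_allele = "C",
                        beta = 0.05)
  expect_warning(iset <- harmonize(exposure, outcome), "rs1")
  expect_equal(nrow(iset$instruments), 0)
  expect_equal(iset$provenance$dropped_rsids, "rs1")

  # orientation to the exposure-increasing allele flips both effects
  exposure_neg <- make_assoc(1, effect_allele = "A", other_allele = "G",
                             beta = -0.1)
  outcome <- make_assoc(1, effect_allele = "A", other_allele = "G",
                        beta = 0.05)
  iset <- harmonize(exposure_neg, outcome)
  expect_equal(iset$instruments$beta_exposure, 0.1)
  expect_equal(iset$instruments$beta_outcome, -0.05)
  expect_equal(iset$instruments$eaf, 0.7)
})

test_that("harmonized sets are exposure-increasing and stable under re-runs", {
  sim <- simulate_two_sample(sim_config(n_snps = 30, theta = 0.2,
                                        flip_fraction = 0.4, seed = 17))
  iset <- harmonize(sim$exposure, sim$outcome)
  expect_true(all(iset$instruments$beta_exposure >= 0))

  # label-flipped outcome alleles recover the same instruments as unflipped
  cfg0 <- sim$config
  cfg0$flip_fraction <- 0
  iset0 <- harmonize(simulate_two_sample(cfg0)$exposure,
                     simulate_two_sample(cfg0)$outcome)
  expect_equal(iset$instruments$beta_outcome, iset0$instruments$beta_outcome,
               tolerance = 1e-12)

  # already-aligned tables pass through harmonization unchanged
  iset2 <- harmonize(sim$exposure, simulate_two_sample(cfg0)$outcome)
  iset3 <- harmonize(sim$exposure, simulate_two_sample(cfg0)$outcome)
  expect_identical(iset2$instruments, iset3$instruments)
})

test_that("variance explained follows the standardized-trait approximation", {
  inst <- data.frame(rsid = "rs1", beta_exposure = 0.1, se_exposure = 0.01,
                     beta_outcome = 0, se_outcome = 0.01, eaf = 0.5)
  expect_equal(variance_explained(inst), 0.005)

  inst$beta_exposure <- 0
  expect_equal(variance_explained(inst), 0)

  inst$eaf <- NA_real_
  expect_error(variance_explained(inst), "rs1")
  expect_equal(variance_explained(inst, na_eaf = "drop"), 0)

  # instruments built to a target R^2 recover it from observed effects
  sim <- simulate_two_sample(sim_config(n_snps = 25, target_r2 = 0.027,
                                        seed = 23))
  iset <- harmonize(sim$exposure, sim$outcome)
  expect_lt(abs(variance_explained(iset) / 0.027 - 1), 0.02)
})
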