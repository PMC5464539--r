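#' Select genome-wide significant SNPs
#'
#' Keeps records whose association P-value is strictly below the genome-wide
#' threshold and returns them sorted by ascending P-value (most significant
#' first), the order expected by [ld_prune()].
#'
#' @param assocs Association `data.frame`; `pvalue` must be present on all rows.
#' @param p_threshold Significance threshold (default `5e-8`; the comparison
#'   is strict, so a SNP at exactly the threshold is excluded).
#' @return The significant subset, sorted by P-value.
#' @export
select_genomewide <- function(assocs, p_threshold = 5e-8) {
  if (any(is.na(assocs$pvalue)))
    stop("pvalue must be present on all records for genome-wide selection")
  out <- assocs[assocs$pvalue < p_threshold, , drop = FALSE]
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# symmetric pairwise R^2 lookup built from a long-format table
ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0) return(function(a, b) 0)
  if (any(is.na(ld$r2)) || any(ld$r2 < 0 | ld$r2 > 1))
    stop("LD R^2 values must lie in [0, 1]")
  key <- paste(pmin(ld$rsid_a, ld$rsid_b), pmax(ld$rsid_a, ld$rsid_b))
  tab <- setNames(ld$r2, key)
  function(a, b) {
    v <- tab[paste(pmin(a, b), pmax(a, b))]
    ifelse(is.na(v), 0, unname(v))
  }
}

#' Prune instruments to pairwise LD independence
#'
#' Greedy, clumping-style selection: records are scanned from most to least
#' significant and a SNP is kept iff its R-squared with every already-kept SNP
#' is below `r2_max`. Ties in significance are broken by (chrom, pos, rsid)
#' so the result is deterministic. Pairs absent from the LD table are treated
#' as unlinked (R-squared 0).
#'
#' @param assocs Association `data.frame` (typically the output of
#'   [select_genomewide()]).
#' @param ld Pairwise LD table: `data.frame` with columns `rsid_a`, `rsid_b`,
#'   `r2`, or `NULL` for no LD information (all SNPs treated as independent).
#' @param r2_max Maximum tolerated pairwise R-squared (default 0.01).
#' @return The pruned subset, in significance order, with attribute
#'   `dropped` listing removed rsids.
#' @export
ld_prune <- function(assocs, ld = NULL, r2_max = 0.01) {
  if (nrow(assocs) == 0) return(assocs)
  lk <- ld_lookup(ld)
  ord <- order(assocs$pvalue, assocs$chrom, assocs$pos, assocs$rsid)
  assocs <- assocs[ord, , drop = FALSE]
  kept <- character(0)
  keep_row <- logical(nrow(assocs))
  for (i in seq_len(nrow(assocs))) {
    rs <- assocs$rsid[i]
    if (length(kept) == 0 || all(lk(rs, kept) < r2_max)) {
      keep_row[i] <- TRUE
      kept <- c(kept, rs)
    }
  }
  out <- assocs[keep_row, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- assocs$rsid[!keep_row]
  out
}

#' Exclude SNPs whose association vanishes after covariate adjustment
#'
#' For metabolic exposures, instruments whose trait association is no longer
#' significant once adjusted for BMI (adjusted P > `p_cut`) are excluded to
#' limit pleiotropy via adiposity; SNPs with adjusted P at or below the cut
#' are retained.
#'
#' @param assocs Association `data.frame`.
#' @param adjusted_p Named numeric vector (rsid -> adjusted P) or a
#'   `data.frame` with columns `rsid`, `pvalue`.
#' @param p_cut Retention threshold: SNPs with adjusted P \eqn{\le} `p_cut`
#'   are kept (default 0.05).
#' @param strict If `TRUE` (default) a SNP missing from `adjusted_p` is an
#'   error naming the SNP; if `FALSE` missing SNPs are dropped with a warning.
#' @return The retained subset, input order preserved.
#' @export
filter_covariate_adjusted <- function(assocs, adjusted_p, p_cut = 0.05,
                                      strict = TRUE) {
  if (is.data.frame(adjusted_p))
    adjusted_p <- setNames(adjusted_p$pvalue, adjusted_p$rsid)
  p_adj <- adjusted_p[assocs$rsid]
  missing <- assocs$rsid[is.na(p_adj) & !assocs$rsid %in% names(adjusted_p)]
  if (length(missing)) {
    if (strict)
      stop("no covariate-adjusted P-value for SNP(s): ",
           paste(missing, collapse = ", "))
    warning("dropping ", length(missing),
            " SNP(s) without covariate-adjusted P-value: ",
            paste(missing, collapse = ", "))
  }
  keep <- !is.na(p_adj) & p_adj <= p_cut
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample-size-weighted mean SD across studies
#'
#' Pools per-study trait standard deviations as the sample-size-weighted
#' arithmetic mean \eqn{\sum n_i sd_i / \sum n_i} — the divisor used to
#' recalibrate per-allele effects to trait-SD units when the contributing
#' studies report different dispersions. A root-mean-square alternative
#' (weighted mean of variances) is available via `method = "rms"`.
#'
#' @param n Integer vector of per-study sample sizes (all `>= 1`).
#' @param sd Numeric vector of per-study SDs (all `> 0`), same length as `n`.
#' @param method `"weighted_mean"` (default) or `"rms"`.
#' @return The pooled SD (trait units).
#' @export
pooled_sd <- function(n, sd, method = c("weighted_mean", "rms")) {
  method <- match.arg(method)
  if (length(n) == 0) stop("at least one study is required")
  if (length(n) != length(sd)) stop("n and sd must have the same length")
  if (any(n < 1)) stop("all study sample sizes must be >= 1")
  if (any(sd <= 0)) stop("all study SDs must be > 0")
  switch(method,
         weighted_mean = sum(n * sd) / sum(n),
         rms = sqrt(sum(n * sd^2) / sum(n)))
}

#' Recalibrate per-allele effects to trait-SD units
#'
#' Divides `beta` and `se` by the trait SD and tags the unit as `"SD"`. Both
#' are divided so that the effect and its uncertainty stay on the same scale;
#' P-values are untouched, so recalibration commutes with significance
#' filtering.
#'
#' @param assocs Association `data.frame`.
#' @param trait_sd Trait standard deviation in the original units (`> 0`),
#'   e.g. from [pooled_sd()].
#' @return `assocs` with `beta`, `se` rescaled and `unit = "SD"`.
#' @export
recalibrate_to_sd <- function(assocs, trait_sd) {
  if (!is.numeric(trait_sd) || length(trait_sd) != 1 || trait_sd <= 0)
    stop("trait_sd must be a single positive number")
  assocs$beta <- assocs$beta / trait_sd
  assocs$se <- assocs$se / trait_sd
  assocs$unit <- "SD"
  assocs
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Replace or drop strand-ambiguous (palindromic) SNPs
#'
#' A/T and C/G variants cannot be strand-resolved from alleles alone in a
#' two-sample design. Each palindromic SNP is replaced by a supplied proxy in
#' tight LD (R-squared > `r2_min`) when one exists, and removed otherwise.
#' Allele frequency is deliberately not used to rescue palindromes. A proxy
#' that is itself palindromic is not used (no chained lookup); the SNP is
#' dropped with a warning.
#'
#' @param exposure Association `data.frame` for the exposure GWAS.
#' @param proxies Proxy table, or `NULL` for none: a `data.frame` with one row
#'   per candidate proxy carrying the proxy's own association fields
#'   (`proxy_rsid`, `effect_allele`, `other_allele`, `beta`, `se`, plus any
#'   optional canonical fields) together with `rsid` (the palindromic SNP it
#'   substitutes) and `r2` (LD with it).
#' @param r2_min Minimum proxy LD (strict; default 0.8).
#' @return Association `data.frame` with a `proxy_of` column (original rsid
#'   for replacements, `""` otherwise) and attributes `n_palindromic`,
#'   `n_replaced`, `n_dropped`. Never contains a palindromic SNP.
#' @export
resolve_palindromes <- function(exposure, proxies = NULL, r2_min = 0.8) {
  pal <- is_palindromic(exposure$effect_allele, exposure$other_allele)
  exposure$proxy_of <- if (is.null(exposure$proxy_of))
    rep("", nrow(exposure)) else exposure$proxy_of
  keep <- !pal
  replacements <- list()
  for (i in which(pal)) {
    rs <- exposure$rsid[i]
    if (!is.null(proxies)) {
      cand <- proxies[proxies$rsid == rs & proxies$r2 > r2_min, , drop = FALSE]
      if (nrow(cand)) {
        best <- cand[which.max(cand$r2), , drop = FALSE]
        if (is_palindromic(toupper(best$effect_allele),
                           toupper(best$other_allele))) {
          warning("proxy ", best$proxy_rsid, " for ", rs,
                  " is itself palindromic; SNP dropped")
          next
        }
        row <- exposure[i, , drop = FALSE]
        for (f in setdiff(intersect(.canonical_cols, names(best)), "rsid"))
          row[[f]] <- if (f %in% c("effect_allele", "other_allele"))
            toupper(best[[f]]) else best[[f]]
        row$rsid <- best$proxy_rsid
        row$proxy_of <- rs
        replacements[[as.character(i)]] <- row
      }
    }
  }
  out <- exposure
  for (i in names(replacements)) {
    out[as.integer(i), ] <- replacements[[i]]
    keep[as.integer(i)] <- TRUE
  }
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_palindromic") <- sum(pal)
  attr(res, "n_replaced") <- length(replacements)
  attr(res, "n_dropped") <- sum(pal) - length(replacements)
  res
}

#' Harmonize exposure and outcome effects onto a common allele orientation
#'
#' Inner-joins the two tables on rsid and aligns each outcome effect to the
#' exposure's effect allele: identical allele pairs pass through, swapped
#' pairs negate the outcome effect, strand-complementary pairs are
#' complemented first and then the same logic applies, and irreconcilable
#' pairs are dropped with a named diagnostic. Finally every pair is oriented
#' to the exposure-increasing allele (if the exposure effect is negative,
#' both effects are negated, alleles swapped and frequency complemented), so
#' the harmonized `beta_exposure` is always non-negative. Palindromic SNPs
#' must be resolved beforehand ([resolve_palindromes()]); any reaching this
#' step are dropped as strand-ambiguous.
#'
#' @param exposure,outcome Association `data.frame`s keyed by rsid. Exposure
#'   effects are expected in SD units, outcome effects in log-odds.
#' @param exposure_name,outcome_name Labels carried into downstream estimates.
#' @return An `instrument_set`: list with `exposure`, `outcome` (labels),
#'   `instruments` (a `data.frame` with columns `rsid beta_exposure
#'   se_exposure beta_outcome se_outcome eaf proxy_of`) and `provenance`
#'   (join/flip/drop counts).
#' @export
harmonize <- function(exposure, outcome, exposure_name = "exposure",
                      outcome_name = "outcome") {
  if (anyDuplicated(exposure$rsid) || anyDuplicated(outcome$rsid))
    stop("rsids must be unique within each table")
  common <- intersect(exposure$rsid, outcome$rsid)
  ei <- exposure[match(common, exposure$rsid), , drop = FALSE]
  oi <- outcome[match(common, outcome$rsid), , drop = FALSE]
  n <- length(common)
  sign_gd <- rep(NA_real_, n)
  strand_flip <- logical(n)
  dropped <- character(0)
  for (j in seq_len(n)) {
    eea <- ei$effect_allele[j]; eoa <- ei$other_allele[j]
    oea <- oi$effect_allele[j]; ooa <- oi$other_allele[j]
    if (is_palindromic(eea, eoa)) {
      dropped <- c(dropped, common[j])
      next
    }
    if (oea == eea && ooa == eoa) {
      sign_gd[j] <- 1
    } else if (oea == eoa && ooa == eea) {
      sign_gd[j] <- -1
    } else if (.complement[oea] == eea && .complement[ooa] == eoa) {
      sign_gd[j] <- 1; strand_flip[j] <- TRUE
    } else if (.complement[oea] == eoa && .complement[ooa] == eea) {
      sign_gd[j] <- -1; strand_flip[j] <- TRUE
    } else {
      dropped <- c(dropped, common[j])
    }
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " SNP(s) during harmonization: ",
            paste(dropped, collapse = ", "))
  ok <- !is.na(sign_gd)
  inst <- data.frame(rsid = common[ok],
                     beta_exposure = ei$beta[ok],
                     se_exposure = ei$se[ok],
                     beta_outcome = sign_gd[ok] * oi$beta[ok],
                     se_outcome = oi$se[ok],
                     eaf = if (is.null(ei$eaf)) rep(NA_real_, sum(ok)) else
                       ei$eaf[ok],
                     proxy_of = if (is.null(ei$proxy_of))
                       rep("", sum(ok)) else ei$proxy_of[ok],
                     stringsAsFactors = FALSE)
  flip <- inst$beta_exposure < 0
  inst$beta_exposure[flip] <- -inst$beta_exposure[flip]
  inst$beta_outcome[flip] <- -inst$beta_outcome[flip]
  inst$eaf[flip] <- 1 - inst$eaf[flip]
  rownames(inst) <- NULL
  prov <- list(n_exposure = nrow(exposure), n_outcome = nrow(outcome),
               n_matched = nrow(inst),
               n_allele_swapped = sum(sign_gd[ok] < 0),
               n_strand_flipped = sum(strand_flip[ok]),
               n_oriented = sum(flip), n_dropped = length(dropped),
               dropped_rsids = dropped)
  instrument_set(exposure_name, outcome_name, inst, prov)
}

#' Construct an instrument set
#'
#' @param exposure,outcome Character labels.
#' @param instruments Harmonized instrument `data.frame` (columns
#'   `rsid beta_exposure se_exposure beta_outcome se_outcome`, optionally
#'   `eaf`, `proxy_of`).
#' @param provenance Named list of pipeline counts.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(exposure = "exposure", outcome = "outcome",
                           instruments = NULL, provenance = list()) {
  req <- c("rsid", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(req %in% names(instruments)))
    stop("instruments must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(instruments$rsid)) stop("instrument rsids must be unique")
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0))
    stop("instrument standard errors must be > 0")
  if (is.null(instruments$eaf)) instruments$eaf <- NA_real_
  if (is.null(instruments$proxy_of)) instruments$proxy_of <- ""
  structure(list(exposure = exposure, outcome = outcome,
                 instruments = instruments, provenance = provenance),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s -> %s (%d SNPs)\n",
              x$exposure, x$outcome, nrow(x$instruments)))
  if (length(x$provenance))
    cat("  provenance:",
        paste(names(x$provenance)[1:min(7, length(x$provenance))],
              unlist(x$provenance[1:min(7, length(x$provenance))]),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

as_instrument_df <- function(x) {
  if (inherits(x, "instrument_set")) return(x$instruments)
  if (is.data.frame(x) &&
      all(c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome") %in%
            names(x))) {
    if (is.null(x$rsid)) x$rsid <- paste0("snp", seq_len(nrow(x)))
    return(x)
  }
  stop("expected an instrument_set or a data.frame of harmonized instruments")
}

#' Exposure variance explained by an instrument set
#'
#' For a standardized exposure, the variance explained is approximated as
#' \eqn{\sum_j 2 \beta_j^2 f_j (1 - f_j)} over instruments with per-allele
#' effect \eqn{\beta_j} (SD units) and effect-allele frequency \eqn{f_j};
#' the sum is clipped to \[0, 1\].
#'
#' @param x An `instrument_set` or harmonized instrument `data.frame`.
#' @param na_eaf Handling of missing allele frequencies: `"error"` (default)
#'   aborts listing the SNPs, `"drop"` excludes them from the sum.
#' @return Fraction of exposure variance explained.
#' @export
variance_explained <- function(x, na_eaf = c("error", "drop")) {
  na_eaf <- match.arg(na_eaf)
  inst <- as_instrument_df(x)
  miss <- is.na(inst$eaf)
  if (any(miss)) {
    if (na_eaf == "error")
      stop("missing eaf for SNP(s): ", paste(inst$rsid[miss], collapse = ", "))
    inst <- inst[!miss, , drop = FALSE]
  }
  r2 <- sum(2 * inst$beta_exposure^2 * inst$eaf * (1 - inst$eaf))
  min(max(r2, 0), 1)
}
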