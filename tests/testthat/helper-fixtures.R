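# fixture builders shared across test files

make_assoc <- function(n = 3, rsid = sprintf("rs%d", seq_len(n)),
                       effect_allele = rep("A", n),
                       other_allele = rep("G", n),
                       beta = seq(0.01, by = 0.01, length.out = n),
                       se = rep(0.005, n), pvalue = rep(1e-10, n),
                       eaf = rep(0.3, n), chrom = rep("1", n),
                       pos = seq(1000, by = 1000, length.out = n),
                       n_samples = rep(1e5, n), info = rep(NA_real_, n),
                       unit = rep("SD", n)) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue,
             n = n_samples, info = info, unit = unit,
             stringsAsFactors = FALSE)
}

make_instruments <- function(n = 10, seed = 1, exposure = "exposure",
                             outcome = "outcome") {
  set.seed(seed)
  inst <- data.frame(rsid = sprintf("rs%d", seq_len(n)),
                     beta_exposure = abs(rnorm(n, 0.04, 0.01)),
                     se_exposure = runif(n, 0.002, 0.005),
                     beta_outcome = rnorm(n, 0.012, 0.01),
                     se_outcome = runif(n, 0.008, 0.02),
                     eaf = runif(n, 0.1, 0.5),
                     stringsAsFactors = FALSE)
  instrument_set(exposure, outcome, inst)
}

write_assoc_tsv <- function(assocs, path = tempfile(fileext = ".tsv"),
                            sep = "\t") {
  utils::write.table(assocs, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  path
}
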