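# Canonical per-SNP association columns. `beta` is per copy of the effect
# allele: trait units (or SD) for an exposure GWAS, log-odds for a case-control
# outcome GWAS.
.canonical_cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pvalue", "n", "info", "unit")
.mandatory_cols <- c("rsid", "effect_allele", "other_allele", "beta", "se")
.numeric_cols <- c("pos", "eaf", "beta", "se", "pvalue", "n", "info")

.nucleotides <- c("A", "C", "G", "T")
.complement <- c(A = "T", C = "G", G = "C", T = "A")

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c("\t", ",", ";"), function(d)
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) "\t" else names(counts)[which.max(counts)]
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file with a header row into a validated association
#' table (one row per SNP). Mandatory fields are `rsid`, `effect_allele`,
#' `other_allele`, `beta` and `se`; `chrom`, `pos`, `eaf`, `pvalue`, `n`,
#' `info` and `unit` are carried when present. Alleles are upper-cased and
#' must be single nucleotides (indels are rejected: downstream strand logic is
#' defined only for SNVs). Rows violating the record invariants (`se > 0`,
#' `eaf` in \[0,1\], `pvalue` in (0,1\], distinct single-nucleotide alleles,
#' parseable numerics) abort the read with a diagnostic naming every invalid
#' row and field exactly once.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical field
#'   names (names) to source column headers (values), e.g.
#'   `c(rsid = "SNP", beta = "Effect")`. Unmapped canonical names are looked
#'   up verbatim.
#' @param delim Field delimiter; by default auto-detected among tab, comma and
#'   semicolon from the header line.
#' @return A `data.frame` with the canonical columns
#'   `rsid chrom pos effect_allele other_allele eaf beta se pvalue n info unit`
#'   (absent optional fields are `NA`).
#' @seealso [write_results()], [filter_imputation_quality()]
#' @export
read_association_table <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delim %||% detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  map <- setNames(.canonical_cols, .canonical_cols)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .canonical_cols)
    if (length(bad)) stop("unknown canonical field(s) in column_map: ",
                          paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing_mand <- .mandatory_cols[!map[.mandatory_cols] %in% names(raw)]
  if (length(missing_mand))
    stop("mandatory column(s) not found in ", path, ": ",
         paste(map[missing_mand], collapse = ", "))

  out <- data.frame(matrix(NA, nrow = nrow(raw), ncol = length(.canonical_cols)),
                    stringsAsFactors = FALSE)
  names(out) <- .canonical_cols
  for (f in .canonical_cols)
    if (map[[f]] %in% names(raw)) out[[f]] <- raw[[map[[f]]]]

  diags <- character(0)
  for (f in intersect(.numeric_cols, .canonical_cols)) {
    x <- out[[f]]
    if (!is.character(x)) next
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(num))
    if (length(bad))
      diags <- c(diags, sprintf("row %d: field '%s' is not numeric (%s)",
                                bad, f, x[bad]))
    out[[f]] <- num
  }
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)
  # rows already reported for a parse failure are not re-reported by the
  # invariant checks, so each invalid row is enumerated exactly once per fault
  parse_rows <- as.integer(sub("^row (\\d+):.*$", "\\1", diags))
  inv <- validate_associations(out)
  inv_rows <- as.integer(sub("^row (\\d+):.*$", "\\1", inv))
  diags <- c(diags, inv[!inv_rows %in% parse_rows])
  if (length(diags))
    stop(sprintf("%d invalid row(s) in %s:\n%s", length(diags), path,
                 paste(diags, collapse = "\n")))
  rownames(out) <- NULL
  out
}

#' Validate association-table invariants
#'
#' Checks every row of an association table against the record invariants and
#' returns one diagnostic string per violation (empty when all rows are
#' valid). Used internally by [read_association_table()]; exported so that
#' programmatically built tables (e.g. simulated ones) can be checked too.
#'
#' @param assocs Association `data.frame` with canonical columns.
#' @return Character vector of row-indexed diagnostics.
#' @export
validate_associations <- function(assocs) {
  n <- nrow(assocs)
  d <- character(0)
  note <- function(rows, msg) if (length(rows)) sprintf("row %d: %s", rows, msg) else character(0)
  ea <- assocs$effect_allele
  oa <- assocs$other_allele
  d <- c(d, note(which(is.na(ea) | !ea %in% .nucleotides),
                 "effect_allele must be one of A/C/G/T"))
  d <- c(d, note(which(is.na(oa) | !oa %in% .nucleotides),
                 "other_allele must be one of A/C/G/T"))
  ok_alleles <- !is.na(ea) & !is.na(oa) & ea %in% .nucleotides & oa %in% .nucleotides
  d <- c(d, note(which(ok_alleles & ea == oa), "effect_allele equals other_allele"))
  d <- c(d, note(which(is.na(assocs$rsid) | assocs$rsid == ""), "missing rsid"))
  d <- c(d, note(which(is.na(assocs$beta)), "missing beta"))
  d <- c(d, note(which(is.na(assocs$se) | assocs$se <= 0), "se must be > 0"))
  d <- c(d, note(which(!is.na(assocs$eaf) & (assocs$eaf < 0 | assocs$eaf > 1)),
                 "eaf must be in [0, 1]"))
  d <- c(d, note(which(!is.na(assocs$pvalue) &
                         (assocs$pvalue <= 0 | assocs$pvalue > 1)),
                 "pvalue must be in (0, 1]"))
  d <- c(d, note(which(!is.na(assocs$info) & (assocs$info < 0 | assocs$info > 1)),
                 "info must be in [0, 1]"))
  d[order(as.integer(sub("^row (\\d+):.*$", "\\1", d)))]
}

#' Filter SNPs on imputation quality
#'
#' Removes records whose imputation quality score (`info`, an imputation
#' R-squared) falls below `min_info`. Records with no `info` value pass: they
#' are treated as directly genotyped, which the filter does not target. Input
#' order is preserved; the removed count is reported via `message()` and
#' attached as attribute `n_removed`.
#'
#' @param assocs Association `data.frame`.
#' @param min_info Minimum imputation quality retained (default 0.7).
#' @return The retained subset of `assocs` (a subsequence of the input).
#' @export
filter_imputation_quality <- function(assocs, min_info = 0.7) {
  keep <- is.na(assocs$info) | assocs$info >= min_info
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("filter_imputation_quality: removed %d of %d record(s)",
                  sum(!keep), length(keep)))
  attr(out, "n_removed") <- sum(!keep)
  out
}

.format_sig12 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

as_results_rows <- function(x) UseMethod("as_results_rows")

#' @export
as_results_rows.mr_estimate <- function(x) {
  data.frame(method = x$method, exposure = x$exposure, outcome = x$outcome,
             n_snps = x$n_snps, theta = x$theta, se = x$se,
             or = x$or, lci = x$or_low, uci = x$or_high, p = x$pvalue,
             stringsAsFactors = FALSE)
}

#' @export
as_results_rows.egger_result <- function(x) {
  rbind(as_results_rows(x$slope),
        data.frame(method = "egger-intercept", exposure = x$slope$exposure,
                   outcome = x$slope$outcome, n_snps = x$n_snps,
                   theta = x$intercept, se = x$intercept_se,
                   or = exp(x$intercept),
                   lci = exp(x$intercept - qt(0.975, x$n_snps - 2) * x$intercept_se),
                   uci = exp(x$intercept + qt(0.975, x$n_snps - 2) * x$intercept_se),
                   p = x$intercept_p, stringsAsFactors = FALSE))
}

#' @export
as_results_rows.heterogeneity_result <- function(x) {
  # heterogeneity rows reuse the estimate layout: theta carries Q, n_snps the
  # strata count; OR-scale fields do not apply
  rbind(as_results_rows(x$pooled),
        data.frame(method = "heterogeneity", exposure = x$pooled$exposure,
                   outcome = x$pooled$outcome, n_snps = x$n_strata,
                   theta = x$q, se = NA_real_, or = NA_real_, lci = NA_real_,
                   uci = NA_real_, p = x$pvalue, stringsAsFactors = FALSE))
}

#' @export
as_results_rows.data.frame <- function(x) x

#' @export
as_results_rows.list <- function(x) {
  do.call(rbind, lapply(x, as_results_rows))
}

#' Write MR results to disk
#'
#' Serializes a collection of results ([mr_estimate] objects, [mr_egger()]
#' fits, [strata_heterogeneity()] results, or a list mixing them) as a
#' tab-delimited table with the ten contract fields
#' `method exposure outcome n_snps theta se or lci uci p` plus a JSON
#' rendering of the same rows at `<path>.json`. `theta` is the log odds ratio
#' per SD of exposure; `or`/`lci`/`uci` are the OR-scale estimate and 95%
#' bounds. Heterogeneity rows carry the Cochran Q statistic in the `theta`
#' column and the strata count in `n_snps`. Numbers are written with 12
#' significant digits so a write/read round trip is numerically faithful.
#'
#' @param results A result object, list of result objects, or a prebuilt
#'   results `data.frame`.
#' @param path Output TSV path; a JSON sidecar is written at `<path>.json`.
#' @param json Write the JSON sidecar (default `TRUE`).
#' @return Invisibly, the results `data.frame` written.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path, json = TRUE) {
  if (inherits(results, c("mr_estimate", "egger_result", "heterogeneity_result")))
    results <- list(results)
  tab <- as_results_rows(results)
  if (is.null(tab) || nrow(tab) == 0) stop("no results to write")
  fmt <- tab
  for (f in c("theta", "se", "or", "lci", "uci", "p"))
    fmt[[f]] <- .format_sig12(tab[[f]])
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json)
    jsonlite::write_json(tab, paste0(path, ".json"), dataframe = "rows",
                         digits = NA, na = "null")
  invisible(tab)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV written by [write_results()].
#' @return The results `data.frame` with numeric columns restored.
#' @export
read_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("n_snps", "theta", "se", "or", "lci", "uci", "p"))
    if (f %in% names(tab)) tab[[f]] <- suppressWarnings(as.numeric(tab[[f]]))
  tab
}

#' Write a structured run record
#'
#' Emits a JSON record of a pipeline run: package version, seed, configuration
#' echo and per-stage record counts. Intended for provenance alongside
#' [write_results()] output.
#'
#' @param path Output JSON path.
#' @param config Named list echoed verbatim.
#' @param seed Integer seed used for any stochastic stage.
#' @param counts Named list of per-stage record counts.
#' @return Invisibly, the record list.
#' @export
write_run_record <- function(path, config = list(), seed = NULL, counts = list()) {
  rec <- list(package = "mrpipe",
              version = as.character(utils::packageVersion("mrpipe")),
              seed = seed, config = config, counts = counts)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(rec)
}
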