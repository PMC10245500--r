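# Reading, validating and writing GWAS summary-statistic tables.
#
# A summary-statistic table has one row per SNP with the conventional
# columns: snp_id, chrom, pos (1-based), effect_allele, other_allele, eaf,
# beta (per-allele additive effect; SD units for continuous traits, log-odds
# for binary), se, pval, n. Alleles are upper-cased on construction; indel
# alleles (length > 1) are accepted and are never treated as palindromic.

STANDARD_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n")
REQUIRED_COLUMNS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")

#' Construct a validated GWAS summary-statistic table
#'
#' Coerces a data frame of per-SNP association statistics into a
#' `gwas_table`. Rows failing hard invariants are dropped with a logged
#' count: non-ACGT or identical alleles, non-positive `se`, `pval` outside
#' (0, 1], non-finite `beta`, or `eaf` outside (0, 1) when supplied.
#' Duplicate `snp_id`s keep the first occurrence. When both `beta`/`se` and
#' `pval` are present, p-values more than 10% (relative) away from the
#' two-sided normal p implied by `beta/se` trigger a warning-level log line
#' (published files round p-values, so this is never an error).
#'
#' @param records data frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optionally `chrom`, `pos`, `eaf`,
#'   `n`.
#' @param trait_name,trait_unit trait label and unit (e.g. `"SD"`,
#'   `"log-odds"`, `"50% change"`), stored as attributes.
#' @param check_pval run the p-value/z-score consistency check.
#' @return a `gwas_table` (a data frame with the standard columns).
#' @export
gwas_table <- function(records, trait_name = "trait", trait_unit = "SD",
                       check_pval = TRUE) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  missing_req <- setdiff(REQUIRED_COLUMNS, names(records))
  if (length(missing_req)) {
    stop("missing required columns: ", paste(missing_req, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(STANDARD_COLUMNS, names(records))) records[[col]] <- NA
  records <- records[STANDARD_COLUMNS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  n_in <- nrow(records)
  ok_allele <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  bad <- !ok_allele(records$effect_allele) | !ok_allele(records$other_allele) |
    records$effect_allele == records$other_allele |
    !is.finite(records$beta) |
    !is.finite(records$se) | records$se <= 0 |
    !is.finite(records$pval) | records$pval <= 0 | records$pval > 1 |
    (!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1))
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    mrp_log("%s: dropped %d of %d rows failing hard invariants",
            trait_name, sum(bad), n_in, level = "warn")
    records <- records[!bad, , drop = FALSE]
  }
  dup <- duplicated(records$snp_id)
  if (any(dup)) {
    mrp_log("%s: dropped %d duplicated snp_id rows (first kept)",
            trait_name, sum(dup), level = "warn")
    records <- records[!dup, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no valid rows after validation for trait '", trait_name, "'")
  }
  if (check_pval) {
    p_implied <- 2 * stats::pnorm(-abs(records$beta / records$se))
    inconsistent <- p_implied > 0 & !is.na(records$pval) &
      abs(records$pval - p_implied) / p_implied > 0.1
    if (any(inconsistent)) {
      mrp_log("%s: %d rows have p-values inconsistent with beta/se beyond 10%% relative tolerance",
              trait_name, sum(inconsistent), level = "warn")
    }
  }
  rownames(records) <- NULL
  structure(records, class = c("gwas_table", "data.frame"),
            trait_name = trait_name, trait_unit = trait_unit,
            n_dropped = n_in - nrow(records))
}

# rebuild a gwas_table after row filtering, preserving trait metadata
restore_gwas <- function(df, template) {
  rownames(df) <- NULL
  structure(as.data.frame(df), class = c("gwas_table", "data.frame"),
            trait_name = attr(template, "trait_name"),
            trait_unit = attr(template, "trait_unit"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_unit"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a GWAS summary-statistic table from TSV
#'
#' Reads a tab-separated file (optionally gzip-compressed, detected by
#' extension through R's connection machinery) with a header row. Column
#' naming differs across consortia (UK Biobank, FinnGen, GIANT, ...), so the
#' mapping from standard field names to file column names is explicit and
#' never sniffed.
#'
#' @param path file path.
#' @param column_map named character vector mapping standard names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. `NULL` assumes
#'   the file already uses standard names.
#' @inheritParams gwas_table
#' @return a [gwas_table()].
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = "trait",
                          trait_unit = "SD") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent)) {
      stop("mapped columns absent from file: ", paste(absent, collapse = ", "))
    }
    raw <- stats::setNames(raw[unname(column_map)], names(column_map))
  } else {
    raw <- raw[intersect(STANDARD_COLUMNS, names(raw))]
  }
  tab <- gwas_table(raw, trait_name = trait_name, trait_unit = trait_unit)
  mrp_log("read %d SNPs for %s from %s (%d dropped in validation)",
          nrow(tab), trait_name, path, attr(tab, "n_dropped"))
  tab
}

#' Write a GWAS summary-statistic table to TSV
#'
#' @param table a [gwas_table()] or plain data frame.
#' @param path output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write MR or mediation results to a TSV table
#'
#' One row per method x exposure x cohort with the columns
#' `exposure, outcome, cohort, method, n_snps, beta, se, OR, ci_low,
#' ci_high, pval, Q, Q_pval, egger_intercept_pval` (mediation results carry
#' their own columns). Numeric values are written at full precision
#' (>= 6 significant digits) so the table round-trips through
#' [read_results_table()].
#'
#' @param results a data frame (e.g. from [as.data.frame.mr_estimate()] rows
#'   bound together), a single estimate object, or a list of estimate
#'   objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  df <- results_to_df(results)
  if (nrow(df) == 0L) stop("`results` is empty")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

results_to_df <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, c("mr_estimate", "mediation_result", "meta_result"))) {
    return(as.data.frame(results))
  }
  if (is.list(results)) {
    return(do.call(rbind, lapply(results, as.data.frame)))
  }
  stop("unsupported `results` type")
}

#' Read back a results table written by [write_results_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a labeled LD r-squared matrix as TSV
#'
#' @param ld square symmetric matrix of r-squared values with SNP ids as
#'   dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(as.data.frame(ld), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Analysis run configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow the
#' conventional two-sample MR settings: genome-wide significance
#' `p < 5e-8`, LD pruning at `r^2 < 0.01` within a 10,000 kb window, and
#' palindromic SNPs resolved by allele-frequency inference with an
#' ambiguity band of (0.42, 0.58).
#'
#' @param p_threshold instrument significance cutoff (strict `<`), in (0,1).
#' @param clump_r2 LD r-squared cutoff, in (0,1).
#' @param clump_window_kb clumping window in kilobases, > 0.
#' @param palindrome_policy `"eaf_infer"` or `"drop_all"`.
#' @param eaf_ambiguity_band frequency pair; palindromic SNPs whose `eaf`
#'   falls strictly inside the band on either side are dropped under
#'   `eaf_infer`.
#' @param seed integer seed driving every stochastic stage.
#' @param n_boot bootstrap replicates for the weighted-median SE.
#' @param n_presso_sim MR-PRESSO simulation draws.
#' @return a `run_config` list.
#' @export
run_config <- function(p_threshold = 5e-8, clump_r2 = 0.01,
                       clump_window_kb = 10000,
                       palindrome_policy = c("eaf_infer", "drop_all"),
                       eaf_ambiguity_band = c(0.42, 0.58),
                       seed = 1L, n_boot = 1000L, n_presso_sim = 1000L) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 > 0, clump_r2 < 1,
            clump_window_kb > 0,
            length(eaf_ambiguity_band) == 2L,
            eaf_ambiguity_band[1] < eaf_ambiguity_band[2],
            n_boot >= 1, n_presso_sim >= 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 palindrome_policy = palindrome_policy,
                 eaf_ambiguity_band = eaf_ambiguity_band,
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 n_presso_sim = as.integer(n_presso_sim)),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON key-value file
#' @param path file path; keys mirror the arguments of [run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    mrp_log("ignoring unknown config keys: %s",
            paste(unknown, collapse = ", "), level = "warn")
  }
  do.call(run_config, vals[intersect(names(vals), known)])
}
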