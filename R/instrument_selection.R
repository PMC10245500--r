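# Selection of genome-wide-significant, mutually independent instruments
# and instrument-strength diagnostics.

#' Filter SNPs by association p-value
#'
#' Strict inequality (`pval < p_threshold`), original row order preserved.
#' An empty result is allowed and logged, not an error.
#'
#' @param table a [gwas_table()].
#' @param p_threshold significance cutoff (conventionally `5e-8`; `5e-6`
#'   for weakly instrumented exposures).
#' @return a [gwas_table()] subset.
#' @export
select_by_pvalue <- function(table, p_threshold = 5e-8) {
  stopifnot(nrow(table) > 0, p_threshold > 0, p_threshold < 1)
  keep <- table$pval < p_threshold
  mrp_log("%s: %d of %d SNPs pass p < %g", attr(table, "trait_name"),
          sum(keep), nrow(table), p_threshold)
  restore_gwas(as.data.frame(table)[keep, , drop = FALSE], table)
}

#' Greedy LD clumping
#'
#' Iterates SNPs by ascending p-value (ties broken by chromosome, position,
#' then snp_id, for determinism) and keeps a SNP iff no already-kept SNP on
#' the same chromosome within `clump_window_kb` has LD `r^2 >= clump_r2`
#' with it. SNP pairs absent from `ld` are assumed independent (r^2 = 0)
#' with a warning, since LD reference panels rarely cover every SNP. The
#' result is returned sorted by (chrom, pos, snp_id) so it is invariant to
#' input row order.
#'
#' @param table a [gwas_table()] with `chrom` and `pos` populated.
#' @param ld symmetric matrix of r-squared values in `[0, 1]` with SNP ids
#'   as dimnames.
#' @param clump_r2 r-squared cutoff (kept pairs are strictly below it).
#' @param clump_window_kb window in kilobases; pairs farther apart (or on
#'   different chromosomes) are never pruned.
#' @return a [gwas_table()] of retained SNPs.
#' @export
clump <- function(table, ld, clump_r2 = 0.01, clump_window_kb = 10000) {
  stopifnot(nrow(table) > 0, clump_r2 > 0, clump_r2 < 1, clump_window_kb > 0)
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    stop("`ld` must be a square matrix")
  }
  if (is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld))) {
    stop("`ld` must carry identical snp_id row and column names")
  }
  if (max(abs(ld - t(ld))) > 1e-8) stop("`ld` must be symmetric")
  if (any(ld < 0) || any(ld > 1)) stop("`ld` entries must lie in [0, 1]")
  if (any(is.na(table$chrom)) || any(is.na(table$pos))) {
    stop("clumping requires chrom and pos for every SNP")
  }

  df <- as.data.frame(table)
  absent <- setdiff(df$snp_id, rownames(ld))
  if (length(absent)) {
    mrp_log("%d SNPs absent from LD matrix; pairs involving them treated as r2 = 0",
            length(absent), level = "warn")
  }
  r2 <- function(a, b) {
    if (a %in% rownames(ld) && b %in% rownames(ld)) ld[a, b] else 0
  }
  ord <- order(df$pval, df$chrom, df$pos, df$snp_id)
  kept <- integer(0)
  window_bp <- clump_window_kb * 1000
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      if (df$chrom[k] == df$chrom[i] &&
          abs(df$pos[k] - df$pos[i]) <= window_bp &&
          r2(df$snp_id[k], df$snp_id[i]) >= clump_r2) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  out <- df[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  mrp_log("clumping kept %d of %d SNPs (r2 < %g, window %g kb)",
          nrow(out), nrow(df), clump_r2, clump_window_kb)
  restore_gwas(out, table)
}

#' Variance in a standardized phenotype explained by one SNP
#'
#' The conventional summary-data approximation `2 eaf (1 - eaf) beta^2`
#' for a unit-variance phenotype; symmetric in `eaf` vs `1 - eaf`. The
#' total explained variance of an instrument set is the sum over SNPs.
#'
#' @param beta per-allele effect in SD units.
#' @param eaf effect-allele frequency in (0, 1).
#' @return explained variance (vectorized).
#' @export
snp_r2 <- function(beta, eaf) {
  stopifnot(all(eaf > 0), all(eaf < 1))
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `F = R2 (N - k - 1) / (k (1 - R2))` for total explained variance `R2`,
#' GWAS sample size `N` and `k` instruments. F > 10 conventionally
#' indicates low weak-instrument bias; the returned object flags
#' `weak_instruments = (F <= 10)`.
#'
#' @param r2_total total proportion of variance explained, in `[0, 1)`.
#' @param n sample size (must exceed `k + 1`).
#' @param k number of instruments (>= 1).
#' @return list with `f_statistic` and `weak_instruments`.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) stop("`r2_total` must lie in [0, 1)")
  if (k < 1) stop("`k` must be >= 1")
  if (n <= k + 1) stop("`n` must exceed k + 1")
  f <- r2_total * (n - k - 1) / (k * (1 - r2_total))
  list(f_statistic = f, weak_instruments = f <= 10)
}

#' Summarize an instrument set's strength
#'
#' Computes per-SNP and total explained variance (via [snp_r2()]), the
#' overall F-statistic (via [f_statistic()]) and approximate per-SNP F
#' values `(beta / se)^2`.
#'
#' @param table a [gwas_table()] of selected instruments with `eaf`.
#' @param n study sample size entering the F formula; defaults to the
#'   maximum of the table's per-SNP `n`.
#' @return list with `records`, `r2_total`, `f_statistic`,
#'   `weak_instruments`, `per_snp_f`, `per_snp_r2`.
#' @export
instrument_set <- function(table, n = NULL) {
  stopifnot(nrow(table) > 0)
  if (is.null(n)) {
    n <- suppressWarnings(max(table$n, na.rm = TRUE))
    if (!is.finite(n)) stop("sample size unavailable: supply `n`")
  }
  if (any(is.na(table$eaf))) stop("instrument_set requires eaf for every SNP")
  per_r2 <- snp_r2(table$beta, table$eaf)
  r2_total <- sum(per_r2)
  fs <- f_statistic(r2_total, n, nrow(table))
  list(records = table, r2_total = r2_total,
       f_statistic = fs$f_statistic, weak_instruments = fs$weak_instruments,
       per_snp_f = stats::setNames((table$beta / table$se)^2, table$snp_id),
       per_snp_r2 = stats::setNames(per_r2, table$snp_id))
}
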