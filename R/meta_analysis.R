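# Fixed-effect inverse-variance meta-analysis of per-cohort causal
# estimates, with I-squared heterogeneity banding.

#' Recover (beta, se) from a point estimate and its 95% CI
#'
#' Intended for consuming published per-cohort results: the SE is derived
#' as `(log upper - log lower) / (2 * 1.96)` using the 1.96 convention of
#' printed tables (not the exact normal quantile), so published arithmetic
#' is reproduced without quantile drift.
#'
#' @param point effect estimate, on the OR scale (`scale = "or"`) or log /
#'   linear scale (`scale = "log"`).
#' @param ci_low,ci_high 95% interval bounds bracketing `point`.
#' @param scale `"or"` or `"log"`.
#' @return list with `beta` and `se` (log scale).
#' @export
from_ci <- function(point, ci_low, ci_high, scale = c("or", "log")) {
  scale <- match.arg(scale)
  if (scale == "or") {
    if (any(c(point, ci_low, ci_high) <= 0)) {
      stop("OR-scale values must be positive")
    }
    point <- log(point); ci_low <- log(ci_low); ci_high <- log(ci_high)
  }
  if (!(ci_low < point && point < ci_high)) {
    stop("confidence interval must bracket the point estimate")
  }
  se <- (ci_high - ci_low) / (2 * 1.96)
  if (se <= 0) stop("degenerate confidence interval: se must be > 0")
  list(beta = point, se = se)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools log-scale estimates with weights `1/se^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, between-study
#' `Q = sum(w (b - beta)^2)` on `k - 1` df, and
#' `I2 = max(0, (Q - (k-1))/Q) * 100` banded at the 25/50/75 cutpoints
#' (low / medium / high / extreme).
#'
#' @param estimates data frame with columns `beta`, `se` (> 0) and
#'   optionally `cohort`.
#' @return a `meta_result` list: `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `q`, `q_df`, `q_pval`, `i2`, `i2_band`, `k`, plus the OR
#'   scale (`or`, `or_ci_low`, `or_ci_high`). A single estimate passes
#'   through with a warning.
#' @export
fixed_effect_meta <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("beta", "se") %in% names(estimates)))
  if (any(estimates$se <= 0)) stop("all standard errors must be positive")
  k <- nrow(estimates)
  if (k < 1L) stop("no estimates to pool")
  if (k == 1L) {
    warning("single estimate supplied; returning it unpooled")
    beta <- estimates$beta[1]
    se <- estimates$se[1]
    q <- 0; i2 <- 0
  } else {
    w <- 1 / estimates$se^2
    beta <- sum(w * estimates$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    q <- sum(w * (estimates$beta - beta)^2)
    i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  }
  q_df <- max(k - 1L, 0L)
  band <- cut(i2, breaks = c(-Inf, 25, 50, 75, Inf),
              labels = c("low", "medium", "high", "extreme"), right = FALSE)
  ci_low <- beta - z95() * se
  ci_high <- beta + z95() * se
  structure(list(beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
                 pval = 2 * stats::pnorm(-abs(beta / se)),
                 q = q, q_df = q_df,
                 q_pval = if (q_df > 0) {
                   stats::pchisq(q, q_df, lower.tail = FALSE)
                 } else NA_real_,
                 i2 = i2, i2_band = as.character(band), k = k,
                 or = exp(beta), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high),
                 cohorts = estimates$cohort %||% NULL),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d estimates\n", x$k))
  cat(sprintf("  beta = %.4f (SE %.4f), OR = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
              x$beta, x$se, x$or, x$or_ci_low, x$or_ci_high, x$pval))
  cat(sprintf("  Q = %.3f on %d df, I2 = %.1f%% (%s heterogeneity)\n",
              x$q, x$q_df, x$i2, x$i2_band))
  invisible(x)
}

#' @export
as.data.frame.meta_result <- function(x, ...) {
  data.frame(exposure = x$exposure %||% NA_character_,
             outcome = x$outcome %||% NA_character_,
             cohort = "combined", method = "fixed_effect_meta",
             n_snps = NA_integer_, beta = x$beta, se = x$se, OR = x$or,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             Q = x$q, Q_pval = x$q_pval %||% NA_real_,
             egger_intercept_pval = NA_real_,
             i2 = x$i2, i2_band = x$i2_band,
             stringsAsFactors = FALSE)
}

#' Pool published per-cohort results given as point estimates and CIs
#'
#' Convenience wrapper: converts each row with [from_ci()] and pools with
#' [fixed_effect_meta()].
#'
#' @param table data frame with columns `point`, `ci_low`, `ci_high`,
#'   optionally `cohort` and `scale` (default `"or"` for every row).
#' @param scale default scale when the table has no `scale` column.
#' @return a `meta_result`.
#' @export
meta_from_ci_table <- function(table, scale = "or") {
  stopifnot(is.data.frame(table),
            all(c("point", "ci_low", "ci_high") %in% names(table)))
  scales <- table$scale %||% rep(scale, nrow(table))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    est <- from_ci(table$point[i], table$ci_low[i], table$ci_high[i],
                   scale = scales[i])
    data.frame(beta = est$beta, se = est$se,
               cohort = (table$cohort %||% rep(NA_character_, nrow(table)))[i],
               stringsAsFactors = FALSE)
  })
  fixed_effect_meta(do.call(rbind, rows))
}
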