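# Core causal estimators on harmonized instruments: per-SNP Wald ratios,
# random-effects IVW, MR-Egger, weighted median, Cochran's Q, leave-one-out,
# and unit rescaling. All estimates are on the log-odds scale with the OR
# scale carried alongside.

new_mr_estimate <- function(method, beta, se, n_snps, use_t = FALSE,
                            df = NA_real_, unit = NA_character_,
                            extra = list()) {
  if (!is.finite(se) || se <= 0) stop("estimate standard error must be positive")
  q <- if (use_t) stats::qt(0.975, df) else z95()
  z <- beta / se
  pval <- if (use_t) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  ci_low <- beta - q * se
  ci_high <- beta + q * se
  est <- c(list(method = method, beta = beta, se = se,
                ci_low = ci_low, ci_high = ci_high, pval = pval,
                n_snps = as.integer(n_snps),
                or = exp(beta), or_ci_low = exp(ci_low),
                or_ci_high = exp(ci_high), unit = unit),
           extra)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNPs\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI (%.4f, %.4f), p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.4f (95%% CI %.4f, %.4f)\n",
              x$or, x$or_ci_low, x$or_ci_high))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$q, x$q_df, x$q_pval))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.5f (SE %.5f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(exposure = x$exposure %||% NA_character_,
             outcome = x$outcome %||% NA_character_,
             cohort = x$cohort %||% NA_character_,
             method = x$method, n_snps = x$n_snps,
             beta = x$beta, se = x$se, OR = x$or,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             Q = x$q %||% NA_real_, Q_pval = x$q_pval %||% NA_real_,
             egger_intercept_pval = x$egger_intercept_pval %||% NA_real_,
             stringsAsFactors = FALSE)
}

# attach exposure/outcome/cohort labels to an estimate
label_estimate <- function(est, exposure = NULL, outcome = NULL,
                           cohort = NULL) {
  est$exposure <- exposure %||% est$exposure
  est$outcome <- outcome %||% est$outcome
  est$cohort <- cohort %||% est$cohort
  est
}

#' Per-SNP Wald ratios and first-order weights
#'
#' `ratio_j = beta_y / beta_x` with first-order inverse-variance weight
#' `w_j = beta_x^2 / se_y^2` (the delta-method `1 / Var(ratio)` treating
#' `beta_x` as fixed). SNPs with `beta_x == 0` are dropped with a warning.
#'
#' @param instruments a `harmonized_instruments` data frame.
#' @return data frame with `snp_id`, `ratio`, `weight`.
#' @export
ratio_estimates <- function(instruments) {
  check_harmonized(instruments, 1L, "ratio estimates")
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    mrp_log("dropping %d SNPs with zero exposure beta", sum(zero),
            level = "warn")
    instruments <- instruments[!zero, , drop = FALSE]
  }
  if (nrow(instruments) < 1L) stop_insufficient(0L, 1L, "ratio estimates")
  data.frame(snp_id = instruments$snp_id,
             ratio = instruments$beta_outcome / instruments$beta_exposure,
             weight = instruments$beta_exposure^2 / instruments$se_outcome^2,
             stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio estimate
#'
#' Degenerate one-instrument causal estimate `beta_y / beta_x` with
#' first-order SE `se_y / |beta_x|`.
#'
#' @inheritParams ratio_estimates
#' @return an `mr_estimate` (method `"wald_ratio"`).
#' @export
wald_ratio <- function(instruments) {
  check_harmonized(instruments, 1L, "the Wald ratio")
  if (nrow(instruments) != 1L) stop("wald_ratio expects exactly one SNP")
  if (instruments$beta_exposure == 0) stop("exposure beta is zero")
  beta <- instruments$beta_outcome / instruments$beta_exposure
  se <- instruments$se_outcome / abs(instruments$beta_exposure)
  new_mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' Weighted mean of per-SNP Wald ratios with first-order weights:
#' `beta = sum(w r) / sum(w)`; `Q = sum(w (r - beta)^2)` on `n - 1` df;
#' fixed-effect SE `1/sqrt(sum(w))` inflated by `max(1, sqrt(Q/(n-1)))`
#' (multiplicative random effects, so the CI never narrows below the
#' fixed-effect one); two-sided normal p.
#'
#' @inheritParams ratio_estimates
#' @return an `mr_estimate` (method `"ivw_re"`) carrying `q`, `q_df`,
#'   `q_pval` and the uninflated `se_fixed`.
#' @export
mr_ivw <- function(instruments) {
  check_harmonized(instruments, 2L, "IVW")
  r <- ratio_estimates(instruments)
  n <- nrow(r)
  if (n < 2L) stop_insufficient(n, 2L, "IVW")
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - beta)^2)
  df <- n - 1L
  se_fixed <- 1 / sqrt(sum(w))
  se <- se_fixed * max(1, sqrt(q / df))
  new_mr_estimate("ivw_re", beta, se, n,
                  extra = list(q = q, q_df = df,
                               q_pval = stats::pchisq(q, df, lower.tail = FALSE),
                               se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` with intercept and
#' weights `1/se_y^2`, after orienting every SNP so `beta_x >= 0`
#' (sign-flipping both betas where needed). The slope is the causal
#' estimate; the intercept estimates the average directional pleiotropy
#' and its p-value is the pleiotropy test. Parameter variances are
#' inflated by `max(1, RSS/(n-2))`; inference uses the t distribution on
#' `n - 2` df by default (`p_method = "normal"` switches to normal
#' quantiles).
#'
#' @inheritParams ratio_estimates
#' @param p_method `"t"` (default) or `"normal"`.
#' @return an `mr_estimate` (method `"egger"`) with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pval`.
#' @export
mr_egger <- function(instruments, p_method = c("t", "normal")) {
  p_method <- match.arg(p_method)
  check_harmonized(instruments, 3L, "MR-Egger")
  n <- nrow(instruments)
  s <- ifelse(instruments$beta_exposure < 0, -1, 1)
  x <- s * instruments$beta_exposure
  y <- s * instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  X <- cbind(intercept = 1, slope = x)
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * y)
  coef <- drop(solve(xtwx, xtwy))
  fitted <- drop(X %*% coef)
  rss <- sum(w * (y - fitted)^2)
  inflation <- max(1, rss / (n - 2))
  vcov <- inflation * solve(xtwx)
  use_t <- p_method == "t"
  slope_se <- sqrt(vcov[2, 2])
  int_se <- sqrt(vcov[1, 1])
  int_z <- coef[1] / int_se
  int_p <- if (use_t) 2 * stats::pt(-abs(int_z), n - 2) else
    2 * stats::pnorm(-abs(int_z))
  new_mr_estimate("egger", unname(coef[2]), slope_se, n, use_t = use_t,
                  df = n - 2,
                  extra = list(egger_intercept = unname(coef[1]),
                               egger_intercept_se = int_se,
                               egger_intercept_pval = unname(int_p),
                               residual_inflation = inflation))
}

# weighted median of `values` under weights `w` (midpoint-interpolated
# weighted empirical CDF crossing 0.5)
weighted_median_point <- function(values, w) {
  ord <- order(values)
  v <- values[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p) - p / 2
  n <- length(v)
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[n]) return(v[n])
  j <- max(which(s < 0.5))
  v[j] + (v[j + 1] - v[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median estimate with parametric bootstrap SE
#'
#' Orders Wald ratios and takes the value at which the cumulative
#' normalized weight (midpoint convention) crosses 0.5, interpolating
#' linearly between the bracketing ratios. Consistent when at least half
#' the weight comes from valid instruments. The SE is a parametric
#' bootstrap: each replicate redraws `(beta_x, beta_y)` from normals at the
#' observed values with their SEs and recomputes the weighted median.
#'
#' @inheritParams ratio_estimates
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (required, for reproducibility).
#' @return an `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed) {
  if (missing(seed)) stop("`seed` is required for the bootstrap SE")
  check_harmonized(instruments, 3L, "the weighted median")
  r <- ratio_estimates(instruments)
  if (nrow(r) < 3L) stop_insufficient(nrow(r), 3L, "the weighted median")
  est <- weighted_median_point(r$ratio, r$weight)
  n <- nrow(instruments)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, instruments$beta_exposure, instruments$se_exposure)
      by <- stats::rnorm(n, instruments$beta_outcome, instruments$se_outcome)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok],
                            bx[ok]^2 / instruments$se_outcome[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", est, se, n,
                  extra = list(n_boot = as.integer(n_boot),
                               seed = as.integer(seed)))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (ratio_j - beta)^2)` against a reference causal estimate,
#' with an upper-tail chi-square p on `n - 1` df.
#'
#' @inheritParams ratio_estimates
#' @param beta reference causal estimate (e.g. the IVW beta).
#' @return a `heterogeneity_result` list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(instruments, beta) {
  check_harmonized(instruments, 2L, "Cochran's Q")
  r <- ratio_estimates(instruments)
  q <- sum(r$weight * (r$ratio - beta)^2)
  df <- nrow(r) - 1L
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument omitted in turn. A row
#' is flagged when omitting its SNP changes the sign of the estimate or
#' moves it by more than the full-sample fixed-effect SE (the uninflated
#' SE: a gross outlier inflates the random-effects SE and would otherwise
#' mask its own influence).
#'
#' @inheritParams ratio_estimates
#' @return data frame with one row per omitted SNP: `snp_id_omitted`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `flagged`.
#' @export
leave_one_out <- function(instruments) {
  check_harmonized(instruments, 3L, "leave-one-out")
  full <- mr_ivw(instruments)
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    est <- mr_ivw(instruments[-i, , drop = FALSE])
    data.frame(snp_id_omitted = instruments$snp_id[i],
               beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               flagged = sign(est$beta) != sign(full$beta) ||
                 abs(est$beta - full$beta) > full$se_fixed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rescale an estimate to different exposure units
#'
#' Multiplies beta, SE and CI bounds by `factor` (e.g. `log(1.5)` to
#' express a per-log-unit estimate per 50% increase) and recomputes the OR
#' scale; the z-score, and hence the p-value, is unchanged.
#'
#' @param estimate an `mr_estimate`.
#' @param factor positive scale multiplier.
#' @param new_unit replacement unit label.
#' @return the rescaled `mr_estimate`.
#' @export
rescale_estimate <- function(estimate, factor, new_unit = NULL) {
  stopifnot(inherits(estimate, "mr_estimate"))
  if (!is.numeric(factor) || factor <= 0) stop("`factor` must be > 0")
  for (f in c("beta", "se", "ci_low", "ci_high")) {
    estimate[[f]] <- estimate[[f]] * factor
  }
  estimate$or <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$ci_low)
  estimate$or_ci_high <- exp(estimate$ci_high)
  if (!is.null(new_unit)) estimate$unit <- new_unit
  estimate
}

#' Run the full estimator battery on one harmonized set
#'
#' IVW (always), MR-Egger (>= 3 SNPs), weighted median (>= 3 SNPs) and
#' optionally MR-PRESSO (>= 4 SNPs), returned as one results data frame in
#' the layout of [write_results_table()].
#'
#' @inheritParams ratio_estimates
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed for the bootstrap (and PRESSO when enabled).
#' @param presso also run [mr_presso()].
#' @param n_presso_sim PRESSO simulation draws.
#' @param exposure,outcome,cohort labels attached to every row.
#' @return data frame of estimates, one row per method.
#' @export
mr_all <- function(instruments, n_boot = 1000L, seed = 1L, presso = FALSE,
                   n_presso_sim = 1000L, exposure = NA, outcome = NA,
                   cohort = NA) {
  ests <- list(mr_ivw(instruments))
  if (nrow(instruments) >= 3L) {
    ests <- c(ests, list(mr_egger(instruments),
                         mr_weighted_median(instruments, n_boot, seed)))
  }
  if (presso && nrow(instruments) >= 4L) {
    pr <- mr_presso(instruments, n_sim = n_presso_sim, seed = seed)
    if (!is.null(pr$corrected)) ests <- c(ests, list(pr$corrected))
  }
  ests <- lapply(ests, label_estimate, exposure = exposure,
                 outcome = outcome, cohort = cohort)
  do.call(rbind, lapply(ests, as.data.frame))
}
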