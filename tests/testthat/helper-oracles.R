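# independent oracles: each re-derives an estimator through a different
# route (stats::lm, approx(), naive loops) than the package's own code

# IVW as weighted least squares through the origin with weights 1/se_y^2
ivw_oracle <- function(h) {
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = h,
                   weights = 1 / h$se_outcome^2)
  unname(stats::coef(fit))
}

# Egger as lm with intercept; parameter SEs rescaled to the multiplicative
# residual-inflation convention max(1, RSS_w/(n-2))
egger_oracle <- function(h) {
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  x <- s * h$beta_exposure
  y <- s * h$beta_outcome
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(y ~ x, weights = w)
  n <- length(x)
  rss <- sum(w * stats::resid(fit)^2)
  sigma2_lm <- rss / (n - 2)
  scale <- max(1, rss / (n - 2)) / sigma2_lm
  se <- sqrt(diag(stats::vcov(fit)) * scale)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       intercept_se = unname(se[1]), slope_se = unname(se[2]))
}

# weighted median via approx() over the midpoint-cumulative-weight curve
wm_oracle <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  p <- weight[ord] / sum(weight)
  s <- cumsum(p) - p / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# PLINK-style clumping: repeatedly take the most significant remaining SNP
# as an index and discard everything linked to it, until none remain
clump_oracle <- function(df, ld, r2_cut, window_kb) {
  df <- df[order(df$pval, df$chrom, df$pos, df$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(df) > 0) {
    idx <- df[1, ]
    kept <- c(kept, idx$snp_id)
    linked <- vapply(seq_len(nrow(df)), function(i) {
      r2 <- if (idx$snp_id %in% rownames(ld) && df$snp_id[i] %in% rownames(ld))
        ld[idx$snp_id, df$snp_id[i]] else 0
      df$chrom[i] == idx$chrom &&
        abs(df$pos[i] - idx$pos) <= window_kb * 1000 &&
        r2 >= r2_cut
    }, logical(1))
    linked[1] <- TRUE
    df <- df[!linked, , drop = FALSE]
  }
  sort(kept)
}

# fixed-effect pooling by explicit elementwise arithmetic
meta_oracle <- function(beta, se) {
  w <- se^-2
  b <- sum(beta * w) / sum(w)
  list(beta = b, se = sum(w)^-0.5,
       q = sum(w * (beta - b)^2))
}
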