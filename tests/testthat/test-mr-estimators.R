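test_that("Wald ratios and first-order weights follow the delta method", {
  h <- make_h(bx = 0.1, by = 0.02, sx = 0.001, sy = 0.01)
  r <- ratio_estimates(h)
  expect_equal(r$ratio, 0.2)
  expect_equal(r$weight, 100)
  # weight is 1/Var(ratio) to first order: check against a Monte-Carlo
  # variance with negligible exposure-side noise
  draws <- withr::with_seed(1, 0.02 + stats::rnorm(2e5, 0, 0.01)) / 0.1
  expect_lt(abs(var(draws) * r$weight - 1), 0.02)
  # zero exposure beta is excluded with a warning log
  h2 <- make_h(bx = c(0.1, 0), by = c(0.02, 0.01))
  expect_message(
    withr::with_options(list(mrpipe.verbose = TRUE), r2 <- ratio_estimates(h2)),
    "zero exposure")
  expect_equal(nrow(suppressMessages(ratio_estimates(h2))), 1L)
})

test_that("IVW reduces to the Wald ratio and to fixed effects when homogeneous", {
  h1 <- make_h(bx = 0.1, by = 0.02, sy = 0.01)
  wr <- wald_ratio(h1)
  expect_equal(wr$beta, 0.2)
  expect_equal(wr$se, 0.1)
  # identical ratios: Q = 0 and the multiplicative inflation is inactive
  h <- make_h(bx = c(0.1, 0.2, 0.4), by = c(0.02, 0.04, 0.08))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$q, 0)
  expect_equal(est$se, est$se_fixed)
  expect_error(mr_ivw(h1), "insufficient")
})

test_that("IVW agrees with weighted least squares through the origin", {
  h <- sim_h(seed = 21, n_snps = 10)
  est <- mr_ivw(h)
  expect_equal(est$beta, ivw_oracle(h), tolerance = 1e-10)
  # random-effects SE never undercuts the fixed-effect SE
  for (seed in 22:31) {
    e <- mr_ivw(sim_h(seed = seed, n_snps = 8))
    expect_gte(e$se, e$se_fixed)
  }
})

test_that("Egger matches the weighted-lm oracle and detects no pleiotropy in clean data", {
  h <- sim_h(seed = 33, n_snps = 5)
  est <- mr_egger(h)
  orc <- egger_oracle(h)
  expect_equal(est$beta, orc$slope, tolerance = 1e-10)
  expect_equal(est$egger_intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(est$se, orc$slope_se, tolerance = 1e-10)
  expect_equal(est$egger_intercept_se, orc$intercept_se, tolerance = 1e-10)
  # exact proportional effects: intercept 0, slope = common ratio
  hx <- make_h(bx = c(0.1, 0.2, 0.3, 0.4), by = c(0.02, 0.04, 0.06, 0.08))
  ex <- mr_egger(hx)
  expect_equal(ex$beta, 0.2, tolerance = 1e-12)
  expect_equal(ex$egger_intercept, 0, tolerance = 1e-12)
  # constraining the intercept to zero on the same weights recovers IVW
  w <- 1 / hx$se_outcome^2
  slope0 <- sum(w * hx$beta_exposure * hx$beta_outcome) /
    sum(w * hx$beta_exposure^2)
  expect_equal(slope0, mr_ivw(hx)$beta, tolerance = 1e-12)
  expect_error(mr_egger(make_h(bx = c(0.1, 0.2), by = c(0.01, 0.02))),
               "insufficient")
})

test_that("the weighted median interpolates the cumulative weight at one half", {
  h <- make_h(bx = c(0.1, 0.1, 0.1), by = c(0.01, 0.02, 0.09))
  est <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.2)  # equal weights: middle ratio
  # 6-SNP fixture against the cumulative-CDF oracle
  h6 <- sim_h(seed = 40, n_snps = 6)
  r <- ratio_estimates(h6)
  expect_equal(mr_weighted_median(h6, n_boot = 100, seed = 2)$beta,
               wm_oracle(r$ratio, r$weight), tolerance = 1e-10)
  # bootstrap SE is seeded and reproducible
  e1 <- mr_weighted_median(h6, n_boot = 200, seed = 7)
  e2 <- mr_weighted_median(h6, n_boot = 200, seed = 7)
  expect_identical(e1$se, e2$se)
  expect_error(mr_weighted_median(h6, n_boot = 100), "seed")
})

test_that("the weighted median resists 30% invalid instruments where IVW does not", {
  # 3 of 10 instruments carry gross directional pleiotropy; the weighted
  # median (<50% invalid weight) stays near the truth while IVW is dragged
  res <- vapply(1:40, function(seed) {
    h <- sim_h(seed = 150 + seed, theta = 0.2, n_snps = 10)
    h$beta_outcome[1:3] <- h$beta_outcome[1:3] + 0.1
    wm <- mr_weighted_median(h, n_boot = 200, seed = seed)
    c(wm$beta, wm$se, mr_ivw(h)$beta)
  }, numeric(3))
  z <- abs(res[1, ] - 0.2) / res[2, ]
  expect_lt(median(z), 3)  # typically within 3 bootstrap SEs of the truth
  expect_gt(abs(mean(res[3, ]) - 0.2), 3 * abs(mean(res[1, ]) - 0.2))
})

test_that("Cochran's Q is zero when homogeneous and additive over subsets", {
  h <- make_h(bx = c(0.1, 0.2, 0.4), by = c(0.02, 0.04, 0.08))
  q <- cochran_q(h, mr_ivw(h)$beta)
  expect_equal(q$q, 0)
  expect_equal(q$pval, 1)
  h2 <- sim_h(seed = 60, n_snps = 12)
  beta_ref <- mr_ivw(h2)$beta
  q_all <- cochran_q(h2, beta_ref)$q
  q_a <- cochran_q(h2[1:6, ], beta_ref)$q
  q_b <- cochran_q(h2[7:12, ], beta_ref)$q
  expect_equal(q_all, q_a + q_b, tolerance = 1e-12)
})

test_that("Q p-values are uniform under the exact null", {
  pvals <- vapply(1:200, function(seed) {
    h <- sim_h(seed = seed, theta = 0)
    est <- mr_ivw(h)
    cochran_q(h, est$beta)$pval
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("leave-one-out flags influential outliers and nothing else", {
  h <- sim_h(seed = 71, theta = 0.2, n_snps = 12)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 12L)
  expect_equal(loo$snp_id_omitted, h$snp_id)
  # a gross planted outlier dominates the estimate; omitting it moves the
  # estimate by more than the full-sample SE
  h$beta_outcome[5] <- h$beta_outcome[5] + 0.1
  loo2 <- leave_one_out(h)
  expect_true(loo2$flagged[5])
  # identical instruments: every row equals the full estimate
  hid <- make_h(bx = rep(0.1, 4), by = rep(0.02, 4))
  loo3 <- leave_one_out(hid)
  expect_true(all(abs(loo3$beta - mr_ivw(hid)$beta) < 1e-12))
  expect_false(any(loo3$flagged))
})

test_that("estimators are sign-equivariant in the outcome", {
  h <- sim_h(seed = 80, theta = 0.15, n_snps = 10)
  hneg <- h
  hneg$beta_outcome <- -h$beta_outcome
  expect_equal(mr_ivw(hneg)$beta, -mr_ivw(h)$beta, tolerance = 1e-14)
  expect_equal(mr_egger(hneg)$beta, -mr_egger(h)$beta, tolerance = 1e-14)
  expect_equal(mr_weighted_median(hneg, n_boot = 100, seed = 5)$beta,
               -mr_weighted_median(h, n_boot = 100, seed = 5)$beta,
               tolerance = 1e-14)
})

test_that("rescaling multiplies the effect scale and leaves the p-value alone", {
  est <- mr_ivw(sim_h(seed = 90, n_snps = 8))
  same <- rescale_estimate(est, 1)
  expect_equal(same$beta, est$beta)
  doubled <- rescale_estimate(est, 2, new_unit = "2 SD")
  expect_equal(doubled$beta, 2 * est$beta)
  expect_equal(doubled$se, 2 * est$se)
  expect_equal(doubled$or, est$or^2)
  expect_equal(doubled$pval, est$pval)
  expect_equal(doubled$unit, "2 SD")
  # per-50%-increase convention: factor log(1.5) on a per-log-unit estimate
  coffee <- rescale_estimate(est, log(1.5), new_unit = "50% increase")
  expect_equal(coffee$beta, est$beta * log(1.5))
  expect_error(rescale_estimate(est, 0))
  expect_error(rescale_estimate(est, -2))
})

test_that("estimate objects expose coherent log and odds-ratio scales", {
  est <- mr_ivw(sim_h(seed = 95, n_snps = 8))
  expect_lt(est$ci_low, est$beta)
  expect_gt(est$ci_high, est$beta)
  expect_equal(est$or, exp(est$beta), tolerance = 1e-12)
  expect_equal(est$or_ci_low, exp(est$ci_low), tolerance = 1e-12)
  expect_equal(est$or_ci_high, exp(est$ci_high), tolerance = 1e-12)
  df <- as.data.frame(est)
  expect_equal(df$beta, est$beta)
  expect_equal(df$method, "ivw_re")
})
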