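test_that("identical seeds reproduce the dataset exactly", {
  cfg <- simulation_config(seed = 42, theta = 0.1, n_snps = 40)
  d1 <- simulate_two_sample(cfg)
  d2 <- simulate_two_sample(cfg)
  expect_identical(d1$exposure_table, d2$exposure_table)
  expect_identical(d1$outcome_table, d2$outcome_table)
  expect_identical(d1$ld_matrix, d2$ld_matrix)
  d3 <- simulate_two_sample(simulation_config(seed = 43, theta = 0.1,
                                              n_snps = 40))
  expect_false(identical(d1$exposure_table$beta, d3$exposure_table$beta))
})

test_that("outcome missingness, palindrome and strand-flip fractions are exact", {
  cfg <- simulation_config(seed = 5, n_snps = 100,
                           frac_missing_in_outcome = 0.1,
                           frac_palindromic = 0.2,
                           frac_strand_flipped = 0.15)
  d <- simulate_two_sample(cfg)
  expect_equal(nrow(d$exposure_table), 100L)
  expect_equal(nrow(d$outcome_table), 90L)
  is_pal <- with(d$exposure_table,
                 effect_allele == chartr("ACGT", "TGCA", other_allele))
  expect_equal(sum(is_pal), 20L)
  # strand-flipped rows have complemented (non-identical) labels vs exposure
  m <- merge(as.data.frame(d$exposure_table), as.data.frame(d$outcome_table),
             by = "snp_id")
  flipped <- m$effect_allele.x != m$effect_allele.y
  pal_m <- m$effect_allele.x == chartr("ACGT", "TGCA", m$other_allele.x)
  # flips are only visible on non-palindromic SNPs (palindromic flips are
  # label-equivalent to swaps); expect close to 15% of the surviving rows
  expect_gt(sum(flipped & !pal_m), 0)
  expect_lte(sum(flipped), 15L)
})

test_that("sampling error of simulated betas matches the analytic SE", {
  # one SNP configuration replicated many times within one table:
  # fixed MAF and zero gamma spread make every row an iid draw
  cfg <- simulation_config(seed = 8, n_snps = 10000, gamma_mean = 0.03,
                           gamma_sd = 0, maf_range = c(0.3, 0.3),
                           frac_missing_in_outcome = 0)
  d <- simulate_two_sample(cfg)
  se_analytic <- 1 / sqrt(2 * 0.3 * 0.7 * cfg$n_exposure)
  expect_equal(unique(round(d$exposure_table$se, 12)), round(se_analytic, 12))
  expect_lt(abs(sd(d$exposure_table$beta) / se_analytic - 1), 0.05)
  expect_lt(abs(mean(d$exposure_table$beta) - 0.03),
            3 * se_analytic / sqrt(10000))
})

test_that("under the null the mean Wald ratio is centred at zero", {
  d <- simulate_two_sample(simulation_config(seed = 1, theta = 0,
                                             n_snps = 50,
                                             frac_missing_in_outcome = 0))
  h <- harmonize(d$exposure_table, d$outcome_table)
  r <- ratio_estimates(h)
  expect_lt(abs(mean(r$ratio)), 3 * sd(r$ratio) / sqrt(nrow(r)))
})

test_that("the LD matrix is block-diagonal, symmetric, unit-diagonal", {
  cfg <- simulation_config(seed = 2, n_snps = 12, ld_block_size = 4,
                           ld_rho = 0.8)
  d <- simulate_two_sample(cfg)
  ld <- d$ld_matrix
  expect_equal(ld, t(ld))
  expect_equal(unname(diag(ld)), rep(1, 12))
  expect_true(all(ld >= 0 & ld <= 1))
  expect_equal(ld[1, 2], 0.8)
  expect_equal(ld[1, 3], 0.64)
  expect_equal(ld[1, 5], 0)  # across blocks
  expect_true(all(rownames(ld) == d$exposure_table$snp_id))
})

test_that("pleiotropy modes shape the direct effects as configured", {
  base <- list(seed = 9, n_snps = 400, frac_missing_in_outcome = 0)
  none <- do.call(simulation_config,
                  c(base, list(pleiotropy_mode = "none")))
  expect_true(all(simulate_two_sample(none)$truth$alpha == 0))
  dir_cfg <- do.call(simulation_config,
                     c(base, list(pleiotropy_mode = "directional",
                                  alpha_mean = 0.003, alpha_sd = 0.001)))
  a <- simulate_two_sample(dir_cfg)$truth$alpha
  expect_lt(abs(mean(a) - 0.003), 3 * 0.001 / sqrt(400))
  iv_cfg <- do.call(simulation_config,
                    c(base, list(pleiotropy_mode = "inside_violated",
                                 alpha_sd = 0.002, alpha_gamma_corr = 0.7)))
  d <- simulate_two_sample(iv_cfg)
  expect_gt(cor(d$truth$alpha, d$truth$gamma), 0.5)
})

test_that("mediation triple truth encodes the product-of-coefficients identity", {
  cfg <- simulation_config(seed = 4, theta = -0.0103, n_snps = 25)
  d <- simulate_mediation_triple(cfg, beta_em = -0.196, beta_mo = 0.019)
  expect_equal(d$truth$total, -0.0103 + (-0.196) * 0.019)
  expect_equal(d$truth$proportion,
               (-0.196 * 0.019) / d$truth$total)
  expect_equal(nrow(d$exposure_table), 50L)
  expect_equal(nrow(d$mediator_table), 50L)
  expect_length(d$truth$exposure_instruments, 25L)
  # mediator-specific instruments carry no exposure effect
  expect_true(all(d$truth$gamma[d$truth$mediator_instruments] == 0))
  z <- simulate_mediation_triple(cfg, beta_em = 0, beta_mo = 0.3)
  expect_equal(z$truth$beta_em * z$truth$beta_mo, 0)
  expect_equal(z$truth$proportion, 0)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(maf_range = c(0, 0)))
  expect_error(simulation_config(n_snps = 2))
  expect_error(simulation_config(frac_palindromic = 1.2))
  expect_error(simulation_config(n_exposure = 10))
})

test_that("a dataset writes to TSVs plus truth sidecar and reads back", {
  dir <- withr::local_tempdir()
  d <- simulate_mediation_triple(simulation_config(seed = 6, n_snps = 10),
                                 beta_em = -0.2, beta_mo = 0.3)
  write_synthetic_dataset(d, dir)
  expect_setequal(list.files(dir),
                  c("exposure.tsv", "outcome.tsv", "mediator.tsv",
                    "ld_matrix.tsv", "truth.json"))
  back <- read_sumstats(file.path(dir, "exposure.tsv"), trait_name = "exposure")
  expect_equal(back$beta, d$exposure_table$beta, tolerance = 1e-12)
  ld <- read_ld_matrix(file.path(dir, "ld_matrix.tsv"))
  expect_equal(ld, d$ld_matrix, tolerance = 1e-12)
})
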