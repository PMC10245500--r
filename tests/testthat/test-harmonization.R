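exp_one <- function(ea, oa, eaf = 0.3) {
  make_gwas(effect_allele = ea, other_allele = oa, eaf = eaf,
            beta = rep_len(0.1, length(ea)), trait_name = "exposure")
}
out_one <- function(ea, oa, beta, eaf = 0.3) {
  make_gwas(effect_allele = ea, other_allele = oa, beta = beta, eaf = eaf,
            trait_name = "outcome")
}

test_that("allele-order swaps flip the outcome beta and frequency", {
  h <- harmonize(exp_one("A", "G"), out_one("G", "A", -0.05, eaf = 0.7))
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.3)
})

test_that("opposite-strand reports are recoded by complement", {
  h <- harmonize(exp_one("A", "G"), out_one("T", "C", 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$beta_outcome, 0.05)
  h2 <- harmonize(exp_one("A", "G"), out_one("C", "T", 0.05, eaf = 0.7))
  expect_equal(h2$action, "strand_flipped_and_sign_flipped")
  expect_equal(h2$beta_outcome, -0.05)
  expect_equal(h2$eaf_outcome, 0.3)
})

test_that("palindromic SNPs resolve by allele frequency or are dropped", {
  # ambiguous frequency inside the band: dropped
  expect_error(
    harmonize(exp_one("A", "T", eaf = 0.50), out_one("A", "T", 0.05, eaf = 0.50),
              policy = "eaf_infer", ambiguity_band = c(0.42, 0.58)),
    "no instruments survived")
  # clear frequencies, concordant: kept as-is
  h <- harmonize(exp_one("A", "T", eaf = 0.2), out_one("A", "T", 0.05, eaf = 0.25))
  expect_equal(h$action, "as_is")
  expect_true(h$palindromic)
  expect_equal(h$beta_outcome, 0.05)
  # discordant frequencies imply the other strand: sign flips
  h2 <- harmonize(exp_one("C", "G", eaf = 0.2), out_one("C", "G", 0.05, eaf = 0.8))
  expect_equal(h2$beta_outcome, -0.05)
  expect_equal(h2$eaf_outcome, 0.2)
  # drop_all removes palindromes regardless of frequency
  mixed_e <- exp_one(c("A", "A"), c("T", "G"), eaf = c(0.2, 0.3))
  mixed_o <- out_one(c("A", "A"), c("T", "G"), c(0.05, 0.02),
                     eaf = c(0.2, 0.3))
  h3 <- suppressMessages(harmonize(mixed_e, mixed_o, policy = "drop_all"))
  expect_equal(h3$snp_id, "rs2")
  expect_equal(attr(h3, "dropped")$reason, "palindromic_dropped")
  # missing eaf on one side: that palindrome is dropped under eaf_infer
  part_o <- out_one(c("A", "A"), c("T", "G"), c(0.05, 0.02),
                    eaf = c(NA, 0.3))
  h4 <- suppressMessages(harmonize(mixed_e, part_o))
  expect_equal(h4$snp_id, "rs2")
  expect_equal(attr(h4, "dropped")$reason, "palindromic_missing_eaf")
})

test_that("instruments missing from the outcome are counted, not proxied", {
  d <- simulate_two_sample(simulation_config(
    seed = 11, n_snps = 100, frac_missing_in_outcome = 0.1,
    frac_palindromic = 0, frac_strand_flipped = 0))
  h <- suppressMessages(harmonize(d$exposure_table, d$outcome_table))
  expect_equal(attr(h, "n_missing_in_outcome"), 10L)
  expect_equal(nrow(h), 90L)
})

test_that("irreconcilable allele pairs and indels are handled", {
  # A/G vs A/C matches under no strand/swap interpretation
  h <- suppressMessages(harmonize(
    exp_one(c("A", "A"), c("G", "G")),
    out_one(c("A", "T"), c("C", "C"), c(0.05, 0.02))))
  expect_equal(attr(h, "dropped")$reason, "irreconcilable_alleles")
  # indel alleles: swap works, complement never applies, not palindromic
  hi <- harmonize(exp_one("AT", "A"), out_one("A", "AT", -0.05))
  expect_equal(hi$action, "sign_flipped")
  expect_false(hi$palindromic)
  expect_equal(hi$beta_outcome, 0.05)
})

test_that("self-harmonization is the identity and harmonization is idempotent", {
  d <- simulate_two_sample(simulation_config(
    seed = 13, n_snps = 40, frac_palindromic = 0.2,
    frac_strand_flipped = 0, frac_missing_in_outcome = 0,
    maf_range = c(0.05, 0.4)))  # frequencies clear of the ambiguity band
  tab <- d$exposure_table
  h <- harmonize(tab, tab)
  expect_equal(nrow(h), 40L)
  expect_true(all(h$action == "as_is"))
  expect_equal(h$beta_outcome, tab$beta)
  expect_equal(h$eaf_outcome, tab$eaf)

  # idempotence: re-harmonizing the harmonized outcome changes nothing
  o <- simulate_two_sample(simulation_config(
    seed = 13, n_snps = 40, frac_palindromic = 0.2,
    frac_strand_flipped = 0.3, frac_missing_in_outcome = 0,
    maf_range = c(0.05, 0.4)))
  h1 <- harmonize(o$exposure_table, o$outcome_table)
  aligned <- gwas_table(
    data.frame(snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
               effect_allele = h1$effect_allele, other_allele = h1$other_allele,
               eaf = h1$eaf_outcome, beta = h1$beta_outcome,
               se = h1$se_outcome,
               pval = 2 * pnorm(-abs(h1$beta_outcome / h1$se_outcome))),
    trait_name = "outcome", trait_unit = "log-odds", check_pval = FALSE)
  h2 <- harmonize(o$exposure_table[o$exposure_table$snp_id %in% h1$snp_id, ],
                  aligned)
  expect_true(all(h2$action == "as_is"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
})

test_that("the causal ratio is invariant to which table was recoded", {
  # same SNP reported both ways: flipping exposure labels instead of
  # outcome labels must leave beta_y / beta_x unchanged
  e1 <- exp_one("A", "G")
  o1 <- out_one("G", "A", -0.05, eaf = 0.7)
  h1 <- harmonize(e1, o1)
  e2 <- make_gwas(effect_allele = "G", other_allele = "A", eaf = 0.7,
                  beta = -0.1, trait_name = "exposure")
  o2 <- out_one("G", "A", -0.05, eaf = 0.7)
  h2 <- harmonize(e2, o2)
  expect_equal(h1$beta_outcome / h1$beta_exposure,
               h2$beta_outcome / h2$beta_exposure)
})
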