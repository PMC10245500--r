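# fixture builders used across test files

# minimal gwas_table from field overrides; defaults are 3 well-formed SNPs
make_gwas <- function(..., trait_name = "trait", trait_unit = "SD") {
  base <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1e6, 2e6, 1e6),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.2, 0.4),
    beta = c(0.10, 0.08, -0.12),
    se = c(0.01, 0.01, 0.012),
    pval = c(1e-23, 1e-15, 1e-23),
    n = 100000,
    stringsAsFactors = FALSE)
  over <- list(...)
  if (length(over)) {
    n <- max(vapply(over, length, 1L))
    base <- base[rep_len(seq_len(nrow(base)), n), , drop = FALSE]
    base$snp_id <- sprintf("rs%d", seq_len(n))
    for (nm in names(over)) base[[nm]] <- over[[nm]]
  }
  gwas_table(base, trait_name = trait_name, trait_unit = trait_unit,
             check_pval = FALSE)
}

# harmonized set straight from per-SNP statistics
make_h <- function(bx, by, sx = rep(0.01, length(bx)),
                   sy = rep(0.01, length(bx))) {
  harmonized_instruments(sprintf("rs%d", seq_along(bx)), bx, sx, by, sy)
}

# a harmonized set simulated under known truth, for estimator tests
sim_h <- function(seed, theta = 0.2, n_snps = 25, ...) {
  d <- simulate_two_sample(simulation_config(
    seed = seed, theta = theta, n_snps = n_snps,
    frac_palindromic = 0, frac_strand_flipped = 0,
    frac_missing_in_outcome = 0, ...))
  harmonize(d$exposure_table, d$outcome_table)
}
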