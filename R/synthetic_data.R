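# Simulator for two-sample GWAS summary statistics with known causal truth.
#
# Summary statistics are simulated directly, without individual-level
# genotypes: for SNP j with minor-allele frequency p_j and GWAS sample size
# N, the sampling SE of an additive per-allele effect on a unit-variance
# trait is sigma_j = 1/sqrt(2 p_j (1-p_j) N). Observed betas are drawn from
# normals centred on the true effects. Binary-outcome betas are treated as
# log-odds with the same normal sampling error, which is how two-sample MR
# consumes FinnGen / UK Biobank log-ORs.

NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                    ncol = 2, byrow = TRUE)

#' Configuration of a synthetic two-sample MR dataset
#'
#' Defaults emulate the structure of a typical anthropometric-exposure /
#' biobank-outcome analysis: 25 candidate instruments of strength comparable
#' to published genome-wide hits (per-SNP F of order 10^2) measured in an
#' exposure GWAS of ~224k individuals, with a binary-outcome GWAS of ~108k.
#'
#' @param n_snps number of candidate instruments (>= 3).
#' @param theta true causal effect of exposure on outcome (log-odds per
#'   exposure SD). In [simulate_mediation_triple()] this is the *direct*
#'   (non-mediated) effect.
#' @param gamma_mean,gamma_sd distribution of true SNP-exposure effects.
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"` or
#'   `"inside_violated"` direct SNP-outcome effects.
#' @param alpha_mean,alpha_sd distribution of direct SNP-outcome effects.
#' @param alpha_gamma_corr correlation between direct effects and instrument
#'   strengths (Gaussian copula; used only for `"inside_violated"`).
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes (>= 100).
#' @param maf_range minor-allele frequency range, within (0, 0.5].
#' @param frac_palindromic fraction of SNPs given complementary (A/T or C/G)
#'   allele pairs.
#' @param frac_strand_flipped fraction of outcome rows reported on the
#'   opposite strand.
#' @param frac_missing_in_outcome fraction of SNPs absent from the outcome
#'   table.
#' @param ld_block_size,ld_rho LD structure: blocks of consecutive SNPs with
#'   r-squared `ld_rho^|i-j|` between within-block pairs, 0 across blocks.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_snps = 25L, theta = 0,
                              gamma_mean = 0.03, gamma_sd = 0.005,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional",
                                                  "inside_violated"),
                              alpha_mean = 0, alpha_sd = 0,
                              alpha_gamma_corr = 0,
                              n_exposure = 224459L, n_outcome = 107814L,
                              n_mediator = 210088L,
                              maf_range = c(0.05, 0.5),
                              frac_palindromic = 0.2,
                              frac_strand_flipped = 0.1,
                              frac_missing_in_outcome = 0.05,
                              ld_block_size = 1L, ld_rho = 0,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  fracs <- c(frac_palindromic, frac_strand_flipped, frac_missing_in_outcome)
  stopifnot(n_snps >= 3,
            all(fracs >= 0), all(fracs <= 1),
            n_exposure >= 100, n_outcome >= 100, n_mediator >= 100,
            length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            gamma_sd >= 0, alpha_sd >= 0,
            abs(alpha_gamma_corr) <= 1)
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleiotropy_mode = pleiotropy_mode,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 alpha_gamma_corr = alpha_gamma_corr,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 n_mediator = as.integer(n_mediator),
                 maf_range = maf_range,
                 frac_palindromic = frac_palindromic,
                 frac_strand_flipped = frac_strand_flipped,
                 frac_missing_in_outcome = frac_missing_in_outcome,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# draw direct SNP->outcome effects for one pleiotropy mode
draw_alpha <- function(config, gamma) {
  n <- length(gamma)
  switch(config$pleiotropy_mode,
    none = rep(0, n),
    balanced = stats::rnorm(n, 0, config$alpha_sd),
    directional = stats::rnorm(n, config$alpha_mean, config$alpha_sd),
    inside_violated = {
      rho <- config$alpha_gamma_corr
      zg <- if (config$gamma_sd > 0) {
        (gamma - config$gamma_mean) / config$gamma_sd
      } else rep(0, n)
      z2 <- stats::rnorm(n)
      config$alpha_mean + config$alpha_sd * (rho * zg + sqrt(1 - rho^2) * z2)
    })
}

# genomic coordinates: one LD block per stretch of `ld_block_size`
# consecutive SNPs, blocks separated by 50 Mb (beyond any clumping window)
# and rotated across chromosomes 1..22; 10 kb between SNPs within a block.
sim_coords <- function(n, block_size) {
  block <- ceiling(seq_len(n) / block_size)
  within <- seq_len(n) - (block - 1L) * block_size
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  tier <- (block - 1L) %/% 22L
  pos <- 1e6 + tier * 5e7 + (within - 1L) * 1e4
  list(block = block, chrom = chrom, pos = pos)
}

sim_alleles <- function(n, frac_palindromic) {
  n_pal <- round(frac_palindromic * n)
  pal_idx <- if (n_pal > 0) sample.int(n, n_pal) else integer(0)
  ea <- oa <- character(n)
  pick_np <- sample.int(nrow(NONPAL_PAIRS), n, replace = TRUE)
  ea <- NONPAL_PAIRS[pick_np, 1]; oa <- NONPAL_PAIRS[pick_np, 2]
  if (n_pal > 0) {
    pick_p <- sample.int(nrow(PAL_PAIRS), n_pal, replace = TRUE)
    ea[pal_idx] <- PAL_PAIRS[pick_p, 1]
    oa[pal_idx] <- PAL_PAIRS[pick_p, 2]
  }
  list(ea = ea, oa = oa, pal_idx = pal_idx)
}

sim_block_ld <- function(block, rho, snp_ids) {
  n <- length(block)
  idx <- seq_len(n)
  same <- outer(block, block, "==")
  dist <- abs(outer(idx, idx, "-"))
  ld <- ifelse(same, rho^dist, 0)
  diag(ld) <- 1
  dimnames(ld) <- list(snp_ids, snp_ids)
  ld
}

complement_alleles <- function(a) chartr("ACGT", "TGCA", a)

# assemble one trait's gwas_table from true effects and sampling SEs
sim_trait_table <- function(snp_id, coords, ea, oa, eaf, true_beta, se, n,
                            trait_name, trait_unit) {
  beta_hat <- stats::rnorm(length(true_beta), true_beta, se)
  pval <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300)
  gwas_table(data.frame(snp_id = snp_id, chrom = coords$chrom,
                        pos = coords$pos, effect_allele = ea,
                        other_allele = oa, eaf = eaf, beta = beta_hat,
                        se = se, pval = pval, n = n,
                        stringsAsFactors = FALSE),
             trait_name = trait_name, trait_unit = trait_unit,
             check_pval = FALSE)
}

# apply strand flips and missingness to form the outcome-style table
perturb_outcome <- function(tab, frac_strand_flipped, frac_missing) {
  n <- nrow(tab)
  df <- as.data.frame(tab)
  n_flip <- round(frac_strand_flipped * n)
  if (n_flip > 0) {
    flip_idx <- sample.int(n, n_flip)
    df$effect_allele[flip_idx] <- complement_alleles(df$effect_allele[flip_idx])
    df$other_allele[flip_idx] <- complement_alleles(df$other_allele[flip_idx])
  }
  n_miss <- round(frac_missing * n)
  if (n_miss > 0) df <- df[-sample.int(n, n_miss), , drop = FALSE]
  restore_gwas(df, tab)
}

#' Simulate a two-sample MR dataset with known truth
#'
#' For each SNP j: MAF uniform in `maf_range`; instrument strength
#' `gamma_j ~ N(gamma_mean, gamma_sd^2)`; direct outcome effect `alpha_j`
#' per `pleiotropy_mode`; sampling SEs `1/sqrt(2 maf (1-maf) N)`; observed
#' `beta_x ~ N(gamma_j, se_x^2)` and `beta_y ~ N(theta gamma_j + alpha_j,
#' se_y^2)`; two-sided normal p-values. Exactly `round(frac_palindromic *
#' n_snps)` SNPs receive complementary allele pairs; the outcome table has
#' the configured fractions of strand-flipped and missing rows; the LD
#' matrix is block-diagonal with r-squared `ld_rho^|i-j|` within blocks.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_dataset` list with elements `exposure_table`,
#'   `outcome_table`, `mediator_table` (`NULL` here), `ld_matrix`, `truth`
#'   (theta, per-SNP gamma/alpha/maf, ids of invalid instruments) and
#'   `config`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_snps
    snp_id <- sprintf("rs%06d", seq_len(n) * 13L + 100000L)
    coords <- sim_coords(n, config$ld_block_size)
    al <- sim_alleles(n, config$frac_palindromic)
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(n, config$gamma_mean, config$gamma_sd)
    alpha <- draw_alpha(config, gamma)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)

    exposure <- sim_trait_table(snp_id, coords, al$ea, al$oa, maf,
                                gamma, se_x, config$n_exposure,
                                "exposure", "SD")
    outcome_full <- sim_trait_table(snp_id, coords, al$ea, al$oa, maf,
                                    config$theta * gamma + alpha, se_y,
                                    config$n_outcome, "outcome", "log-odds")
    outcome <- perturb_outcome(outcome_full, config$frac_strand_flipped,
                               config$frac_missing_in_outcome)
    truth <- list(theta = config$theta,
                  gamma = stats::setNames(gamma, snp_id),
                  alpha = stats::setNames(alpha, snp_id),
                  maf = stats::setNames(maf, snp_id),
                  invalid_instruments = snp_id[alpha != 0])
    structure(list(exposure_table = exposure, outcome_table = outcome,
                   mediator_table = NULL,
                   ld_matrix = sim_block_ld(coords$block, config$ld_rho, snp_id),
                   truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' Simulate an exposure / mediator / outcome triple for two-step MR
#'
#' Generates `n_snps` exposure instruments (SNP-exposure effects `gamma_j`;
#' mediator effects `beta_em * gamma_j`; outcome effects `theta * gamma_j +
#' beta_mo * beta_em * gamma_j + alpha_j`, so the true total effect is
#' `theta + beta_em * beta_mo`) plus `n_snps` mediator-specific instruments
#' (direct mediator effects `delta_j` drawn from the same distribution as
#' `gamma_j`; outcome effects `beta_mo * delta_j`; null exposure effects).
#' Each step of a two-step MR analysis thus has its own identifiable
#' instrument set: the exposure's instruments recover `beta_em` (step A) and
#' the total effect, while the mediator's own genome-wide-significant
#' instruments recover `beta_mo` (step B).
#'
#' @inheritParams simulate_two_sample
#' @param beta_em true effect of exposure on mediator (mediator SD per
#'   exposure SD).
#' @param beta_mo true effect of mediator on outcome (log-odds per mediator
#'   SD).
#' @return a `synthetic_dataset` whose three tables each contain all
#'   `2 * n_snps` SNPs; `truth` records `theta_direct`, `beta_em`,
#'   `beta_mo`, `total = theta + beta_em * beta_mo`, the true mediated
#'   `proportion`, and the two instrument-id sets.
#' @export
simulate_mediation_triple <- function(config, beta_em, beta_mo) {
  stopifnot(inherits(config, "simulation_config"),
            is.numeric(beta_em), is.numeric(beta_mo))
  with_seed(config$seed, {
    n <- config$n_snps
    m <- 2L * n
    snp_id <- sprintf("rs%06d", seq_len(m) * 13L + 500000L)
    exp_idx <- seq_len(n)
    med_idx <- n + seq_len(n)
    coords <- sim_coords(m, config$ld_block_size)
    al <- sim_alleles(m, config$frac_palindromic)
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

    gamma <- c(stats::rnorm(n, config$gamma_mean, config$gamma_sd), rep(0, n))
    delta <- c(rep(0, n), stats::rnorm(n, config$gamma_mean, config$gamma_sd))
    alpha <- draw_alpha(config, gamma)

    true_x <- gamma
    true_m <- beta_em * gamma + delta
    total <- config$theta + beta_em * beta_mo
    true_y <- config$theta * gamma + beta_mo * true_m + alpha

    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_m <- 1 / sqrt(2 * maf * (1 - maf) * config$n_mediator)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)

    exposure <- sim_trait_table(snp_id, coords, al$ea, al$oa, maf, true_x,
                                se_x, config$n_exposure, "exposure", "SD")
    mediator <- sim_trait_table(snp_id, coords, al$ea, al$oa, maf, true_m,
                                se_m, config$n_mediator, "mediator", "SD")
    outcome_full <- sim_trait_table(snp_id, coords, al$ea, al$oa, maf, true_y,
                                    se_y, config$n_outcome, "outcome",
                                    "log-odds")
    outcome <- perturb_outcome(outcome_full, config$frac_strand_flipped,
                               config$frac_missing_in_outcome)
    truth <- list(theta_direct = config$theta, beta_em = beta_em,
                  beta_mo = beta_mo, total = total,
                  proportion = if (total != 0) beta_em * beta_mo / total else NA_real_,
                  gamma = stats::setNames(gamma, snp_id),
                  delta = stats::setNames(delta, snp_id),
                  alpha = stats::setNames(alpha, snp_id),
                  maf = stats::setNames(maf, snp_id),
                  exposure_instruments = snp_id[exp_idx],
                  mediator_instruments = snp_id[med_idx],
                  invalid_instruments = snp_id[alpha != 0])
    structure(list(exposure_table = exposure, outcome_table = outcome,
                   mediator_table = mediator,
                   ld_matrix = sim_block_ld(coords$block, config$ld_rho, snp_id),
                   truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to a directory of TSVs plus a truth sidecar
#'
#' Emits `exposure.tsv`, `outcome.tsv`, optionally `mediator.tsv`, a square
#' labeled `ld_matrix.tsv`, and `truth.json`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(dataset$exposure_table, file.path(dir, "exposure.tsv"))
  write_sumstats(dataset$outcome_table, file.path(dir, "outcome.tsv"))
  if (!is.null(dataset$mediator_table)) {
    write_sumstats(dataset$mediator_table, file.path(dir, "mediator.tsv"))
  }
  write_ld_matrix(dataset$ld_matrix, file.path(dir, "ld_matrix.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
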