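# Alignment of exposure and outcome summary statistics to a shared effect
# allele, resolving allele-order swaps, strand flips and palindromic
# ambiguity.

#' Harmonize exposure and outcome tables to a shared effect allele
#'
#' Records are matched by `snp_id`; SNPs absent from the outcome are
#' dropped and counted (no proxy substitution). For each shared SNP the
#' outcome's allele pair is reconciled with the exposure's:
#'
#' * identical pair in the same order: kept `as_is`;
#' * identical pair in swapped order: outcome beta sign-flipped and its
#'   frequency complemented (`sign_flipped`);
#' * pair matching after complementing the outcome alleles (A<->T, C<->G):
#'   `strand_flipped`, with the swap logic applied on top
#'   (`strand_flipped_and_sign_flipped`);
#' * palindromic SNPs (single-base A/T or C/G pairs, for which strand and
#'   swap are indistinguishable): under `policy = "drop_all"` they are
#'   removed; under `"eaf_infer"` the orientation is inferred by comparing
#'   each side's effect-allele frequency to 0.5, and SNPs whose frequency
#'   on either side falls strictly inside `ambiguity_band` (or is missing)
#'   are dropped;
#' * anything irreconcilable under every strand/swap interpretation is
#'   dropped with a reason code.
#'
#' Indel alleles (length > 1) are never treated as palindromic and are
#' matched by exact or swapped labels only.
#'
#' @param exposure a [gwas_table()] of selected instruments.
#' @param outcome a [gwas_table()] for the outcome trait.
#' @param policy palindrome policy, `"eaf_infer"` (default) or
#'   `"drop_all"`.
#' @param ambiguity_band frequency pair, default `c(0.42, 0.58)`.
#' @return a `harmonized_instruments` data frame with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `action`, `palindromic`, plus attributes
#'   `n_input`, `n_missing_in_outcome` and a `dropped` data frame
#'   (snp_id, reason).
#' @export
harmonize <- function(exposure, outcome, policy = c("eaf_infer", "drop_all"),
                      ambiguity_band = c(0.42, 0.58)) {
  policy <- match.arg(policy)
  stopifnot(length(ambiguity_band) == 2L,
            ambiguity_band[1] < ambiguity_band[2])
  e <- as.data.frame(exposure)
  o <- as.data.frame(outcome)
  n_input <- nrow(e)
  shared <- e$snp_id[e$snp_id %in% o$snp_id]
  n_missing <- n_input - length(shared)
  if (n_missing > 0) {
    mrp_log("%d of %d instruments missing in outcome (dropped, no proxies)",
            n_missing, n_input, level = "warn")
  }
  if (length(shared) == 0L) stop("no instruments shared with the outcome table")
  m <- merge(e, o, by = "snp_id", suffixes = c("_exposure", "_outcome"))
  m <- m[match(shared, m$snp_id), , drop = FALSE]

  a1 <- m$effect_allele_exposure; a2 <- m$other_allele_exposure
  b1 <- m$effect_allele_outcome;  b2 <- m$other_allele_outcome
  single <- nchar(a1) == 1L & nchar(a2) == 1L & nchar(b1) == 1L & nchar(b2) == 1L
  pal <- single & a1 == complement_alleles(a2)

  asis <- b1 == a1 & b2 == a2
  swap <- b1 == a2 & b2 == a1
  cb1 <- complement_alleles(b1); cb2 <- complement_alleles(b2)
  flip_asis <- single & !pal & cb1 == a1 & cb2 == a2 & !asis & !swap
  flip_swap <- single & !pal & cb1 == a2 & cb2 == a1 & !asis & !swap

  nr <- nrow(m)
  sign <- rep(NA_real_, nr)
  action <- rep(NA_character_, nr)
  drop_reason <- rep(NA_character_, nr)

  np <- !pal
  sign[np & asis] <- 1;  action[np & asis] <- "as_is"
  sign[np & swap] <- -1; action[np & swap] <- "sign_flipped"
  sign[flip_asis] <- 1;  action[flip_asis] <- "strand_flipped"
  sign[flip_swap] <- -1; action[flip_swap] <- "strand_flipped_and_sign_flipped"
  drop_reason[np & is.na(sign)] <- "irreconcilable_alleles"

  if (any(pal)) {
    # for a palindromic pair the complemented pair is the same set, so the
    # outcome labels must already match as-is or swapped
    pal_ok <- pal & (asis | swap)
    drop_reason[pal & !pal_ok] <- "irreconcilable_alleles"
    if (policy == "drop_all") {
      drop_reason[pal_ok] <- "palindromic_dropped"
    } else {
      if (any(pal_ok) &&
          (all(is.na(e$eaf)) || all(is.na(o$eaf)))) {
        stop("palindrome policy 'eaf_infer' requires effect-allele ",
             "frequencies on both tables; use policy = 'drop_all' instead")
      }
      eafx <- m$eaf_exposure
      eafy0 <- ifelse(swap, 1 - m$eaf_outcome, m$eaf_outcome)
      miss <- pal_ok & (is.na(eafx) | is.na(m$eaf_outcome))
      drop_reason[miss] <- "palindromic_missing_eaf"
      in_band <- function(f) f > ambiguity_band[1] & f < ambiguity_band[2]
      amb <- pal_ok & !miss & (in_band(eafx) | in_band(eafy0))
      drop_reason[amb] <- "palindromic_ambiguous_eaf"
      ok <- pal_ok & !miss & !amb
      concordant <- (eafx < 0.5) == (eafy0 < 0.5)
      s0 <- ifelse(swap, -1, 1)
      sign[ok] <- ifelse(concordant[ok], s0[ok], -s0[ok])
      # a strand flip of a palindrome is label-equivalent to a swap, so the
      # four action labels remain well defined
      action[ok] <- ifelse(concordant[ok],
                           ifelse(swap[ok], "sign_flipped", "as_is"),
                           ifelse(swap[ok], "strand_flipped",
                                  "strand_flipped_and_sign_flipped"))
    }
  }

  keep <- !is.na(sign) & is.na(drop_reason)
  dropped <- data.frame(snp_id = m$snp_id[!keep],
                        reason = drop_reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped)) {
    tab <- table(dropped$reason)
    mrp_log("harmonization dropped %d SNPs (%s)", nrow(dropped),
            paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
            level = "warn")
  }
  if (!any(keep)) stop("no instruments survived harmonization")

  out <- data.frame(
    snp_id = m$snp_id[keep],
    chrom = m$chrom_exposure[keep],
    pos = m$pos_exposure[keep],
    effect_allele = a1[keep],
    other_allele = a2[keep],
    beta_exposure = m$beta_exposure[keep],
    se_exposure = m$se_exposure[keep],
    eaf_exposure = m$eaf_exposure[keep],
    beta_outcome = sign[keep] * m$beta_outcome[keep],
    se_outcome = m$se_outcome[keep],
    eaf_outcome = ifelse(sign[keep] < 0, 1 - m$eaf_outcome[keep],
                         m$eaf_outcome[keep]),
    action = action[keep],
    palindromic = pal[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("harmonized_instruments", "data.frame"),
            n_input = n_input, n_missing_in_outcome = n_missing,
            dropped = dropped,
            exposure_name = attr(exposure, "trait_name"),
            outcome_name = attr(outcome, "trait_name"))
}

# validate an object carrying harmonized (beta_x, se_x, beta_y, se_y)
check_harmonized <- function(h, min_n = 1L, what = "this estimator") {
  need <- c("snp_id", "beta_exposure", "se_exposure",
            "beta_outcome", "se_outcome")
  if (!is.data.frame(h) || !all(need %in% names(h))) {
    stop("expected a harmonized_instruments data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(h$se_exposure <= 0) || any(h$se_outcome <= 0)) {
    stop("standard errors must be positive")
  }
  if (nrow(h) < min_n) stop_insufficient(nrow(h), min_n, what)
  invisible(h)
}

#' Build a harmonized-instruments table directly from aligned statistics
#'
#' Convenience constructor for already-aligned per-SNP statistics (e.g.
#' published instrument tables), bypassing allele reconciliation.
#'
#' @param snp_id SNP identifiers.
#' @param beta_exposure,se_exposure SNP-exposure effects and SEs.
#' @param beta_outcome,se_outcome SNP-outcome effects and SEs.
#' @return a `harmonized_instruments` data frame (action `as_is`).
#' @export
harmonized_instruments <- function(snp_id, beta_exposure, se_exposure,
                                   beta_outcome, se_outcome) {
  out <- data.frame(snp_id = as.character(snp_id),
                    chrom = NA_character_, pos = NA_real_,
                    effect_allele = NA_character_, other_allele = NA_character_,
                    beta_exposure = beta_exposure, se_exposure = se_exposure,
                    eaf_exposure = NA_real_,
                    beta_outcome = beta_outcome, se_outcome = se_outcome,
                    eaf_outcome = NA_real_,
                    action = "as_is", palindromic = FALSE,
                    stringsAsFactors = FALSE)
  check_harmonized(out)
  structure(out, class = c("harmonized_instruments", "data.frame"),
            n_input = nrow(out), n_missing_in_outcome = 0L,
            dropped = data.frame(snp_id = character(0), reason = character(0)))
}
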