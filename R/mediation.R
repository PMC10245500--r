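# Two-step MR mediation: product-of-coefficients indirect effect and
# mediated proportion for an exposure -> mediator -> outcome triple.

as_beta_se <- function(x, what) {
  if (inherits(x, "mr_estimate")) return(c(beta = x$beta, se = x$se))
  if (is.list(x) && !is.null(x$beta)) {
    return(c(beta = x$beta, se = x$se %||% NA_real_))
  }
  if (is.numeric(x) && length(x) == 2L) return(c(beta = x[1], se = x[2]))
  if (is.numeric(x) && length(x) == 1L) return(c(beta = x, se = NA_real_))
  stop("`", what, "` must be an mr_estimate, a list with beta/se, or a ",
       "numeric (beta[, se])")
}

#' Two-step MR mediation by the product of coefficients
#'
#' The indirect effect of the exposure on the outcome through the mediator
#' is `beta_A * beta_B`, where `beta_A` is the exposure->mediator effect
#' (step A) and `beta_B` the mediator->outcome effect (step B); the
#' mediated proportion is `indirect / total`. The indirect-effect SE uses
#' the first-order delta method `sqrt(bA^2 sB^2 + bB^2 sA^2)` (no
#' covariance term: in two-sample MR the two steps come from
#' non-overlapping instrument-outcome regressions).
#'
#' The proportion is reported even when it falls outside `[0, 1]`, with an
#' `inconsistent_mediation` flag; it is undefined (NA, flagged) when the
#' total effect is zero. For table output the proportion is conventionally
#' rounded to an integer percentage; full precision is retained here.
#'
#' @param total total exposure->outcome effect: an `mr_estimate`, a
#'   `c(beta, se)` pair, or a bare beta.
#' @param step_a exposure->mediator effect, same forms.
#' @param step_b mediator->outcome effect, same forms.
#' @param exposure,mediator,outcome,cohort optional labels.
#' @return a `mediation_result` list: `total_beta`, `total_se`, `a_beta`,
#'   `a_se`, `b_beta`, `b_se`, `indirect`, `indirect_se`,
#'   `indirect_ci_low`, `indirect_ci_high`, `proportion` (fraction),
#'   `proportion_pct`, flags, labels.
#' @export
two_step_mediation <- function(total, step_a, step_b, exposure = NA,
                               mediator = NA, outcome = NA, cohort = NA) {
  tot <- as_beta_se(total, "total")
  a <- as_beta_se(step_a, "step_a")
  b <- as_beta_se(step_b, "step_b")
  for (v in list(tot, a, b)) {
    if (!is.na(v["se"]) && v["se"] < 0) stop("standard errors must be >= 0")
  }
  indirect <- unname(a["beta"] * b["beta"])
  indirect_se <- unname(sqrt(a["beta"]^2 * b["se"]^2 + b["beta"]^2 * a["se"]^2))
  undefined <- tot["beta"] == 0
  proportion <- if (undefined) NA_real_ else unname(indirect / tot["beta"])
  if (undefined) {
    mrp_log("total effect is zero: mediated proportion undefined",
            level = "warn")
  }
  inconsistent <- !undefined && (proportion < 0 || proportion > 1)
  structure(list(total_beta = unname(tot["beta"]), total_se = unname(tot["se"]),
                 a_beta = unname(a["beta"]), a_se = unname(a["se"]),
                 b_beta = unname(b["beta"]), b_se = unname(b["se"]),
                 indirect = indirect, indirect_se = indirect_se,
                 indirect_ci_low = indirect - z95() * indirect_se,
                 indirect_ci_high = indirect + z95() * indirect_se,
                 proportion = proportion,
                 proportion_pct = 100 * proportion,
                 proportion_undefined = unname(undefined),
                 inconsistent_mediation = inconsistent,
                 exposure = exposure, mediator = mediator,
                 outcome = outcome, cohort = cohort),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  total effect      = %.4f\n", x$total_beta))
  cat(sprintf("  direct effect A   = %.4f (exposure -> mediator)\n", x$a_beta))
  cat(sprintf("  direct effect B   = %.4f (mediator -> outcome)\n", x$b_beta))
  cat(sprintf("  indirect (A x B)  = %.4f (SE %.4f)\n",
              x$indirect, x$indirect_se))
  if (isTRUE(x$proportion_undefined)) {
    cat("  mediated proportion undefined (total effect is zero)\n")
  } else {
    cat(sprintf("  mediated proportion = %.1f%% (%d%% rounded)%s\n",
                x$proportion_pct, round(x$proportion_pct),
                if (x$inconsistent_mediation) " [inconsistent mediation]" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure, mediator = x$mediator,
             outcome = x$outcome, cohort = x$cohort,
             total_beta = x$total_beta, total_se = x$total_se,
             direct_a_beta = x$a_beta, direct_a_se = x$a_se,
             direct_b_beta = x$b_beta, direct_b_se = x$b_se,
             indirect = x$indirect, indirect_se = x$indirect_se,
             proportion = x$proportion,
             mediated_proportion_pct = round(x$proportion_pct),
             inconsistent_mediation = x$inconsistent_mediation,
             stringsAsFactors = FALSE)
}

#' Full two-step MR mediation pipeline on three summary-statistic tables
#'
#' Step A regresses the mediator on the exposure's genome-wide-significant
#' instruments (IVW); step B regresses the outcome on the *mediator's own*
#' instruments, selected independently from the mediator table at the same
#' threshold; the total effect is the IVW of the exposure's instruments on
#' the outcome. Instrument selection (and clumping, when an LD matrix is
#' given) and harmonization use the thresholds in `config`.
#'
#' @param exposure,mediator,outcome [gwas_table()]s.
#' @param config a [run_config()].
#' @param ld optional LD r-squared matrix for clumping.
#' @return a `mediation_result`; the component IVW fits are attached as
#'   attribute `"steps"`.
#' @export
mediation_pipeline <- function(exposure, mediator, outcome,
                               config = run_config(), ld = NULL) {
  stopifnot(inherits(config, "run_config"))
  select <- function(tab, step) {
    sel <- select_by_pvalue(tab, config$p_threshold)
    if (nrow(sel) > 0 && !is.null(ld)) {
      sel <- clump(sel, ld, config$clump_r2, config$clump_window_kb)
    }
    if (nrow(sel) < 2L) {
      stop(sprintf("step '%s': %d instruments selected, need at least 2",
                   step, nrow(sel)), call. = FALSE)
    }
    sel
  }
  fit <- function(sel, target, step) {
    h <- harmonize(sel, target, policy = config$palindrome_policy,
                   ambiguity_band = config$eaf_ambiguity_band)
    if (nrow(h) < 2L) {
      stop(sprintf("step '%s': %d instruments after harmonization, need at least 2",
                   step, nrow(h)), call. = FALSE)
    }
    mrp_log("step %s: IVW on %d instruments", step, nrow(h))
    mr_ivw(h)
  }
  exp_sel <- select(exposure, "total (exposure instruments)")
  med_sel <- select(mediator, "B (mediator instruments)")
  total <- fit(exp_sel, outcome, "total (exposure -> outcome)")
  step_a <- fit(exp_sel, mediator, "A (exposure -> mediator)")
  step_b <- fit(med_sel, outcome, "B (mediator -> outcome)")
  res <- two_step_mediation(total, step_a, step_b,
                            exposure = attr(exposure, "trait_name"),
                            mediator = attr(mediator, "trait_name"),
                            outcome = attr(outcome, "trait_name"))
  attr(res, "steps") <- list(total = total, step_a = step_a, step_b = step_b)
  res
}
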