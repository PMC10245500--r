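# End-to-end orchestration: select -> harmonize -> estimate -> PRESSO ->
# meta-analysis -> mediation from a single plan, writing a directory of
# result tables plus a manifest with content hashes.

#' Describe an end-to-end analysis plan
#'
#' @param exposures list of exposures; each a list with `name`, `table` (a
#'   [gwas_table()] or a TSV path), optional `unit` and `p_threshold`
#'   (overriding the config's, e.g. `5e-6` for weakly instrumented
#'   exposures).
#' @param outcomes list of outcome cohorts; each a list with `cohort` and
#'   `table`.
#' @param mediators optional list shaped like `exposures`.
#' @param mediations optional list of `list(exposure =, mediator =)` name
#'   pairs to run two-step mediation on (defaults to every exposure x
#'   mediator combination when mediators are given).
#' @param ld optional LD r-squared matrix (or TSV path) for clumping.
#' @param config a [run_config()].
#' @param output_dir directory for result tables.
#' @return an `analysis_plan` list.
#' @export
analysis_plan <- function(exposures, outcomes, mediators = NULL,
                          mediations = NULL, ld = NULL,
                          config = run_config(), output_dir = tempfile("mrrun")) {
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L,
            inherits(config, "run_config"))
  structure(list(exposures = exposures, outcomes = outcomes,
                 mediators = mediators, mediations = mediations,
                 ld = ld, config = config, output_dir = output_dir),
            class = "analysis_plan")
}

load_table <- function(x, name, unit = "SD") {
  if (inherits(x, "gwas_table")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(read_sumstats(x, trait_name = name, trait_unit = unit))
  }
  stop("table for '", name, "' must be a gwas_table or a file path")
}

#' Run an analysis plan end to end
#'
#' For every exposure x cohort: instrument selection (p-value filter plus
#' clumping when LD is available), harmonization, the estimator battery
#' (IVW, Egger, weighted median, MR-PRESSO), and leave-one-out, each
#' written as a TSV. Per exposure, cohort IVW estimates are pooled by
#' fixed-effect meta-analysis. Requested mediation triples produce
#' mediation TSVs. A `manifest.json` records the configuration, seed,
#' per-stage instrument counts, any failed branches, and an md5 content
#' hash for every output file. A stage failure aborts only its
#' exposure x cohort branch.
#'
#' @param plan an [analysis_plan()].
#' @return the manifest, invisibly; outputs under `plan$output_dir`.
#' @export
run_plan <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  config <- plan$config
  dir.create(plan$output_dir, recursive = TRUE, showWarnings = FALSE)
  ld <- plan$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  outcomes <- lapply(plan$outcomes, function(o) {
    list(cohort = o$cohort,
         table = load_table(o$table, o$cohort, unit = "log-odds"))
  })

  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = list(), errors = list(),
                   note = paste("p-values are reported unadjusted across",
                                "exposures; borderline results are",
                                "suggestive only"))
  seed_counter <- 0L
  next_seed <- function() {
    seed_counter <<- seed_counter + 1L
    (config$seed + 7919L * seed_counter) %% .Machine$integer.max
  }
  outfile <- function(...) file.path(plan$output_dir, paste0(...))

  ivw_by_exposure <- list()
  for (e in plan$exposures) {
    unit <- e$unit %||% "SD"
    thr <- e$p_threshold %||% config$p_threshold
    tab <- load_table(e$table, e$name, unit)
    sel <- select_by_pvalue(tab, thr)
    if (nrow(sel) > 0 && !is.null(ld)) {
      sel <- clump(sel, ld, config$clump_r2, config$clump_window_kb)
    }
    write_sumstats(sel, outfile(e$name, "_instruments.tsv"))
    qc <- list(exposure = e$name, p_threshold = thr,
               n_candidates = nrow(tab), n_selected = nrow(sel))
    if (nrow(sel) >= 1L && !any(is.na(sel$eaf))) {
      strength <- instrument_set(sel)
      qc$r2_total <- strength$r2_total
      qc$f_statistic <- strength$f_statistic
      qc$weak_instruments <- strength$weak_instruments
    }
    manifest$stages[[e$name]] <- qc

    per_cohort <- list()
    for (o in outcomes) {
      branch <- paste(e$name, o$cohort, sep = " x ")
      result <- tryCatch({
        h <- harmonize(sel, o$table, policy = config$palindrome_policy,
                       ambiguity_band = config$eaf_ambiguity_band)
        prefix <- paste0(e$name, "_", o$cohort)
        utils::write.table(as.data.frame(h), outfile(prefix, "_harmonized.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res <- mr_all(h, n_boot = config$n_boot, seed = next_seed(),
                      presso = nrow(h) >= 4L,
                      n_presso_sim = config$n_presso_sim,
                      exposure = e$name, outcome = "outcome",
                      cohort = o$cohort)
        write_results_table(res, outfile(prefix, "_mr_results.tsv"))
        if (nrow(h) >= 3L) {
          utils::write.table(leave_one_out(h),
                             outfile(prefix, "_leave_one_out.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        if (nrow(h) >= 4L) {
          pr <- mr_presso(h, n_sim = config$n_presso_sim, seed = next_seed())
          presso_df <- data.frame(snp_id = names(pr$outlier_pvals),
                                  outlier_pval = unname(pr$outlier_pvals),
                                  flagged = names(pr$outlier_pvals) %in%
                                    pr$outlier_ids)
          utils::write.table(presso_df, outfile(prefix, "_presso_outliers.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          summ <- data.frame(global_rss = pr$global_rss,
                             global_pval = pr$global_pval,
                             n_outliers = length(pr$outlier_ids),
                             corrected_beta = pr$corrected$beta %||% NA_real_,
                             corrected_or = pr$corrected$or %||% NA_real_,
                             distortion_pval = pr$distortion_pval)
          utils::write.table(summ, outfile(prefix, "_presso_summary.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        ivw_row <- res[res$method == "ivw_re", , drop = FALSE]
        list(beta = ivw_row$beta, se = ivw_row$se, cohort = o$cohort)
      }, error = function(err) {
        mrp_log("branch %s failed: %s", branch, conditionMessage(err),
                level = "error")
        manifest$errors[[branch]] <<- conditionMessage(err)
        NULL
      })
      if (!is.null(result)) per_cohort[[o$cohort]] <- result
    }
    if (length(per_cohort) >= 2L) {
      meta <- fixed_effect_meta(do.call(rbind, lapply(per_cohort, function(p) {
        data.frame(beta = p$beta, se = p$se, cohort = p$cohort,
                   stringsAsFactors = FALSE)
      })))
      meta$exposure <- e$name
      write_results_table(as.data.frame(meta), outfile(e$name, "_meta.tsv"))
    }
    ivw_by_exposure[[e$name]] <- per_cohort
  }

  if (!is.null(plan$mediators)) {
    pairs <- plan$mediations %||% unlist(lapply(plan$exposures, function(e) {
      lapply(plan$mediators, function(m) list(exposure = e$name,
                                              mediator = m$name))
    }), recursive = FALSE)
    med_tables <- stats::setNames(
      lapply(plan$mediators, function(m) {
        load_table(m$table, m$name, m$unit %||% "SD")
      }),
      vapply(plan$mediators, `[[`, "", "name"))
    exp_tables <- stats::setNames(
      lapply(plan$exposures, function(e) {
        load_table(e$table, e$name, e$unit %||% "SD")
      }),
      vapply(plan$exposures, `[[`, "", "name"))
    for (pair in pairs) {
      for (o in outcomes) {
        branch <- paste("mediation", pair$exposure, pair$mediator, o$cohort)
        tryCatch({
          med <- mediation_pipeline(exp_tables[[pair$exposure]],
                                    med_tables[[pair$mediator]],
                                    o$table, config = config, ld = ld)
          med$cohort <- o$cohort
          write_results_table(med, outfile("mediation_", pair$exposure, "_",
                                           pair$mediator, "_", o$cohort,
                                           ".tsv"))
        }, error = function(err) {
          mrp_log("branch %s failed: %s", branch, conditionMessage(err),
                  level = "error")
          manifest$errors[[branch]] <<- conditionMessage(err)
        })
      }
    }
  }

  files <- list.files(plan$output_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) list(md5 = unname(tools::md5sum(f))))
  manifest$r_version <- as.character(getRversion())
  manifest$package_version <-
    as.character(utils::packageVersion("mrpipe"))
  jsonlite::write_json(manifest, file.path(plan$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
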