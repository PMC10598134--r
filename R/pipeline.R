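# Orchestration: align (1/K0, RT) -> Mason-Schamp CCS conversion ->
# filter -> top-evidence -> replicate aggregation -> pair matching ->
# statistics. The stage order is fixed; CCS conversion always happens
# AFTER 1/K0 alignment (corrections are additive on the mobility scale,
# never applied to CCS directly). Disabling alignment is the only
# permitted variation, used for the "before" arm of precision
# comparisons. All randomness lives in the synthetic generator; the
# pipeline itself is deterministic.

#' Pipeline configuration
#'
#' @param evidence Evidence feature data.frame or path to an evidence
#'   TSV.
#' @param refs Reference-peptide data.frame or path
#'   ([read_reference_table()]).
#' @param col_map `column_map` used when `evidence` is a path.
#' @param constants `ccs_constants` for the CCS conversion.
#' @param rules `filter_rules`.
#' @param min_refs Minimum matched reference peptides per run.
#' @param align If FALSE, skip run alignment (before-arm of CV
#'   comparisons).
#' @param mod_masses Modification mass data.frame, path, or NULL.
#' @param gradient_mode `"absolute"` or `"relative"` delta-CCS in the
#'   gradient regression.
#' @param intensity_weighted Intensity-weight the charge profile.
#' @param pooled_charges Charges pooled for the MED (default 2 and 3).
#' @param exclude_from_correlation Modifications excluded from the
#'   MED-vs-mass correlation.
#' @param out_dir If non-NULL, all result tables are written there as
#'   TSV with the temperature/gas assumptions as comment headers.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(evidence, refs,
                            col_map = column_map(),
                            constants = physical_constants(),
                            rules = filter_rules(),
                            min_refs = 3L,
                            align = TRUE,
                            mod_masses = NULL,
                            gradient_mode = c("absolute", "relative"),
                            intensity_weighted = FALSE,
                            pooled_charges = c(2L, 3L),
                            exclude_from_correlation = character(),
                            out_dir = NULL) {
  structure(list(evidence = evidence, refs = refs, col_map = col_map,
                 constants = constants, rules = rules,
                 min_refs = as.integer(min_refs), align = align,
                 mod_masses = mod_masses,
                 gradient_mode = match.arg(gradient_mode),
                 intensity_weighted = intensity_weighted,
                 pooled_charges = as.integer(pooled_charges),
                 exclude_from_correlation = exclude_from_correlation,
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_if_path <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the full delta-CCS analysis pipeline
#'
#' Executes the fixed stage order and returns every intermediate and
#' final table, plus a per-stage row-count report. Identical
#' configuration and inputs produce identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return List of class `ccsdelta_results`: `corrections`, `features`
#'   (aligned, CCS-converted), `precision`, `records_all_charges`,
#'   `records`, `pairs`, `summaries`, `charge_profile`, `clouds`,
#'   `gradients`, `correlation_mass`, `correlation_rt`, `report`
#'   (stage/row-count data.frame), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  note <- function(stage, n) report[[length(report) + 1L]] <<-
    data.frame(stage = stage, rows = n)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  features <- tryCatch(load_if_path(config$evidence, read_evidence_table,
                                    col_map = config$col_map),
                       error = function(e) fail("read_evidence", e))
  note("input_evidence", nrow(features))
  refs <- tryCatch(load_if_path(config$refs, read_reference_table),
                   error = function(e) fail("read_reference", e))
  mod_masses <- if (is.null(config$mod_masses)) NULL else
    tryCatch(load_if_path(config$mod_masses, read_mod_mass_table),
             error = function(e) fail("read_mod_masses", e))

  corrections <- NULL
  if (config$align) {
    corrections <- tryCatch(
      compute_run_corrections(features, refs, config$min_refs),
      error = function(e) fail("compute_corrections", e))
    features <- tryCatch(apply_corrections(features, corrections),
                         error = function(e) fail("apply_corrections", e))
    note("aligned", nrow(features))
  }

  features <- tryCatch(convert_features_to_ccs(features, config$constants),
                       error = function(e) fail("ccs_conversion", e))

  precision <- tryCatch(suppressWarnings(precision_summary(features)),
                        error = function(e) NULL)

  # charge profile consumes data before the charge filter
  records_all <- aggregate_replicates(select_top_evidence(features))
  note("records_all_charges", nrow(records_all))
  profile <- tryCatch(
    charge_state_profile(records_all,
                         intensity_weighted = config$intensity_weighted),
    error = function(e) fail("charge_profile", e))

  filtered <- tryCatch(suppressWarnings(
    filter_features(features, config$rules)),
    error = function(e) fail("filter", e))
  note("filtered", nrow(filtered))
  top <- select_top_evidence(filtered)
  note("top_evidence", nrow(top))
  records <- aggregate_replicates(top)
  note("records", nrow(records))

  unmod <- records[records$modification_name == "Unmodified", ,
                   drop = FALSE]
  modr <- records[records$modification_name != "Unmodified", ,
                  drop = FALSE]
  pairs <- tryCatch(suppressMessages(match_pairs(modr, unmod)),
                    error = function(e) fail("match_pairs", e))
  pairs <- tryCatch(compute_deltas(pairs, mod_masses),
                    error = function(e) fail("compute_deltas", e))
  note("pairs", nrow(pairs))

  summaries <- tryCatch(suppressWarnings(
    summarize_modifications(pairs, pooled_charges = config$pooled_charges)),
    error = function(e) fail("summaries", e))

  clouds <- list()
  gradients <- NULL
  for (z in config$pooled_charges) {
    cl <- tryCatch(fit_ion_cloud(unmod, z), error = function(e) NULL)
    if (is.null(cl)) next
    clouds[[as.character(z)]] <- cl
    gradients <- rbind(gradients,
                       suppressWarnings(
                         deltaccs_gradient(pairs, cl,
                                           mode = config$gradient_mode)))
  }

  corr_mass <- tryCatch(
    deltaccs_mass_correlation(summaries, "delta_mass",
                              config$exclude_from_correlation),
    error = function(e) NULL)
  corr_rt <- tryCatch(
    deltaccs_mass_correlation(summaries, "median_delta_rt",
                              config$exclude_from_correlation),
    error = function(e) NULL)

  report_df <- do.call(rbind, report)
  out <- structure(list(corrections = corrections, features = features,
                        precision = precision,
                        records_all_charges = records_all,
                        records = records, pairs = pairs,
                        summaries = summaries, charge_profile = profile,
                        clouds = clouds, gradients = gradients,
                        correlation_mass = corr_mass,
                        correlation_rt = corr_rt,
                        report = report_df, config = config),
                   class = "ccsdelta_results")
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- constants_header(results$config$constants)
  wr <- function(df, name) if (!is.null(df) && is.data.frame(df))
    write_table(df, file.path(out_dir, paste0(name, ".tsv")), hdr)
  wr(results$corrections, "run_corrections")
  wr(results$records, "peptide_records")
  wr(results$pairs, "matched_pairs")
  wr(results$summaries, "modification_summaries")
  wr(results$charge_profile, "charge_profile")
  wr(results$gradients, "deltaccs_gradients")
  wr(results$report, "stage_report")
  invisible(out_dir)
}

#' @export
print.ccsdelta_results <- function(x, ...) {
  cat("delta-CCS pipeline results\n")
  print(x$report, row.names = FALSE)
  if (!is.null(x$summaries)) {
    cat("\nModification summaries:\n")
    print(x$summaries, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
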