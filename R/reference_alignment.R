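# Run-wise alignment of 1/K0 and retention time against spiked reference
# peptides, and coefficient-of-variation precision metrics.
#
# The correction for a run is the median, over the reference peptides
# detected in that run, of (measured - reference); subtracting it from all
# measured values makes the run's reference median deviation exactly zero.
# Deviations are computed on the 1/K0 scale, never on CCS; CCS is always
# recomputed after alignment.

#' Compute the alignment correction for a single run
#'
#' Matches the run's features against the reference set by sequence and
#' charge (when a reference peptide is detected more than once in the run,
#' its most intense occurrence is used) and returns the median deviation
#' of measured minus reference 1/K0 and RT.
#'
#' @param run_features Feature data.frame from one run.
#' @param refs Reference-peptide data.frame ([read_reference_table()]).
#' @param min_refs Minimum matched reference peptides for the run to be
#'   alignable. Default 3, mirroring the at-least-three-ions calibration
#'   rule: a median of fewer points is fragile.
#' @return One-row data.frame: `run_id`, `delta_inv_k0`, `delta_rt`,
#'   `n_refs_used`, `alignable`. For unalignable runs the deltas are NA.
#' @export
compute_run_correction <- function(run_features, refs, min_refs = 3L) {
  stopifnot(is.data.frame(run_features), is.data.frame(refs))
  run_id <- unique(run_features$run_id)
  if (length(run_id) != 1L)
    stop("compute_run_correction expects features of exactly one run")
  key <- paste(run_features$sequence, run_features$charge)
  rkey <- paste(refs$sequence, refs$charge)
  hits <- run_features[key %in% rkey, , drop = FALSE]
  if (nrow(hits)) {
    # most intense occurrence per reference peptide
    hkey <- paste(hits$sequence, hits$charge)
    ord <- order(hkey, -hits$intensity)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$sequence, hits$charge)), ,
                 drop = FALSE]
    idx <- match(paste(hits$sequence, hits$charge), rkey)
    dev_k0 <- hits$inv_k0 - refs$ref_inv_k0[idx]
    dev_rt <- hits$rt - refs$ref_rt[idx]
  } else {
    dev_k0 <- dev_rt <- numeric()
  }
  n <- nrow(hits)
  if (n < min_refs) {
    warning("run '", run_id, "' unalignable: ", n, " matched reference ",
            "peptide(s) < min_refs = ", min_refs)
    return(data.frame(run_id = run_id, delta_inv_k0 = NA_real_,
                      delta_rt = NA_real_, n_refs_used = n,
                      alignable = FALSE))
  }
  data.frame(run_id = run_id,
             delta_inv_k0 = stats::median(dev_k0),
             delta_rt = stats::median(dev_rt),
             n_refs_used = n, alignable = TRUE)
}

#' Compute alignment corrections for every run in a feature table
#'
#' @param features Feature data.frame spanning one or more runs.
#' @inheritParams compute_run_correction
#' @return data.frame with one row per run (see
#'   [compute_run_correction()]).
#' @export
compute_run_corrections <- function(features, refs, min_refs = 3L) {
  runs <- unique(features$run_id)
  out <- do.call(rbind, lapply(runs, function(r) {
    compute_run_correction(features[features$run_id == r, , drop = FALSE],
                           refs, min_refs)
  }))
  rownames(out) <- NULL
  out
}

#' Apply run corrections to a feature table
#'
#' Subtracts each run's `delta_inv_k0` from its features' `inv_k0` and
#' `delta_rt` from `rt`. Features from unalignable runs (or runs without a
#' correction row) are dropped; the dropped count is attached as attribute
#' `n_dropped_unalignable`. Intensity, m/z, charge and within-run RT order
#' are untouched. Alignment is idempotent: recomputing corrections on the
#' output yields zero for every alignable run.
#'
#' @param features Feature data.frame.
#' @param corrections data.frame from [compute_run_corrections()].
#' @return Aligned feature data.frame.
#' @export
apply_corrections <- function(features, corrections) {
  stopifnot(is.data.frame(features), is.data.frame(corrections))
  idx <- match(features$run_id, corrections$run_id)
  ok <- !is.na(idx) & corrections$alignable[idx]
  n_drop <- sum(!ok)
  if (n_drop)
    warning("dropping ", n_drop,
            " feature(s) from unalignable or uncorrected run(s)")
  out <- features[ok, , drop = FALSE]
  idx <- idx[ok]
  out$inv_k0 <- out$inv_k0 - corrections$delta_inv_k0[idx]
  out$rt <- out$rt - corrections$delta_rt[idx]
  rownames(out) <- NULL
  attr(out, "n_dropped_unalignable") <- n_drop
  out
}

#' Replicate precision of CCS measurements
#'
#' Computes the per-peptide coefficient of variation of CCS across
#' replicate runs — sample standard deviation (n-1) over mean, in percent,
#' per (modified_sequence, charge) — together with the median CV and the
#' fraction of peptides detected in every run. Expects at most one feature
#' per run and peptide (apply [select_top_evidence()] first); duplicates
#' are reduced to the most intense occurrence.
#'
#' @param features Feature data.frame with a populated `ccs` column,
#'   spanning at least two runs.
#' @param require_complete If TRUE (default), only peptides present in
#'   every run enter the CV computation, mirroring a
#'   complete-in-all-replicates analysis; the completeness fraction is
#'   reported either way.
#' @return List of class `precision_metrics`: `per_peptide` (data.frame
#'   with `modified_sequence`, `charge`, `n_runs`, `cv_pct`), `median_cv`
#'   (%), `n_peptides`, `completeness_fraction`, `n_runs_total`.
#' @export
precision_summary <- function(features, require_complete = TRUE) {
  stopifnot(is.data.frame(features))
  if (!"ccs" %in% names(features) || all(is.na(features$ccs)))
    stop("precision_summary requires a populated ccs column")
  n_runs_total <- length(unique(features$run_id))
  if (n_runs_total < 2L) stop("precision requires >= 2 runs")
  features <- select_top_evidence(features)

  key <- paste(features$modified_sequence, features$charge, sep = "\r")
  n_runs <- tapply(features$run_id, key, function(x) length(unique(x)))
  cv <- tapply(features$ccs, key,
               function(x) 100 * stats::sd(x) / mean(x))
  ks <- names(n_runs)
  per <- data.frame(
    modified_sequence = sub("\r.*$", "", ks),
    charge = as.integer(sub("^.*\r", "", ks)),
    n_runs = as.integer(n_runs),
    cv_pct = as.numeric(cv))
  completeness <- mean(per$n_runs == n_runs_total)
  keep <- if (require_complete) per$n_runs == n_runs_total else per$n_runs >= 2L
  per_cv <- per[keep, , drop = FALSE]
  if (nrow(per_cv) == 0L) stop("no peptides for CV")
  rownames(per_cv) <- NULL
  structure(list(per_peptide = per_cv,
                 median_cv = stats::median(per_cv$cv_pct),
                 n_peptides = nrow(per_cv),
                 completeness_fraction = completeness,
                 n_runs_total = n_runs_total),
            class = "precision_metrics")
}

#' @export
print.precision_metrics <- function(x, ...) {
  cat(sprintf(
    "CCS precision: median CV %.3f%% over %d peptides (%d runs, %.0f%% complete)\n",
    x$median_cv, x$n_peptides, x$n_runs_total,
    100 * x$completeness_fraction))
  invisible(x)
}
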