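# Matching modified peptides to their unmodified counterparts and the
# pairwise delta quantities:
#   delta_ccs_rel = (CCS_mod - CCS_unmod) / CCS_unmod
#   delta_ccs_abs = CCS_mod - CCS_unmod        [A^2]
#   delta_rt, delta_mass.
# Pairing is by unmodified base sequence + charge; a sequence observed in
# both charge states yields two independent pairs, because doubly and
# triply charged ions occupy distinct ion-mobility regimes.

#' Match modified peptide records to unmodified counterparts
#'
#' Joins each modified record to the unmodified record with the same
#' (sequence, charge). Unmatched modified records are counted in the
#' `n_unmatched` attribute. Pairing is deterministic and independent of
#' input order; a duplicate unmodified record for one key violates the
#' aggregation contract and raises an error.
#'
#' @param modified Peptide-record data.frame ([aggregate_replicates()])
#'   of modified peptides.
#' @param unmodified Peptide-record data.frame of unmodified peptides,
#'   unique per (sequence, charge).
#' @return data.frame of matched pairs with `sequence`,
#'   `modification_name`, `mod_position`, `charge`, `ccs_modified`,
#'   `ccs_unmodified`, `rt_modified`, `rt_unmodified`, `mz_unmodified`;
#'   attribute `n_unmatched`.
#' @export
match_pairs <- function(modified, unmodified) {
  stopifnot(is.data.frame(modified), is.data.frame(unmodified))
  ukey <- paste(unmodified$sequence, unmodified$charge)
  dup <- ukey[duplicated(ukey)]
  if (length(dup))
    stop("duplicate unmodified record(s) for key(s): ",
         paste(unique(dup), collapse = "; "),
         " (aggregation contract violated)")
  mkey <- paste(modified$sequence, modified$charge)
  idx <- match(mkey, ukey)
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched)
  if (n_unmatched)
    message(n_unmatched, " modified record(s) without unmodified counterpart")
  mi <- modified[matched, , drop = FALSE]
  ui <- unmodified[idx[matched], , drop = FALSE]
  ord <- order(mi$modification_name, mi$sequence, mi$charge)
  out <- data.frame(
    sequence = mi$sequence,
    modification_name = mi$modification_name,
    mod_position = mi$mod_position,
    charge = mi$charge,
    ccs_modified = mi$ccs_mean,
    ccs_unmodified = ui$ccs_mean,
    rt_modified = mi$rt_mean,
    rt_unmodified = ui$rt_mean,
    mz_unmodified = ui$mz)[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Populate the delta fields of matched pairs
#'
#' Computes `delta_ccs_rel` (fraction), `delta_ccs_abs` (A^2),
#' `delta_rt` (minutes) and looks up `delta_mass` (Da) from the
#' modification mass table.
#'
#' @param pairs Matched-pair data.frame from [match_pairs()].
#' @param mod_masses Modification mass table
#'   ([read_mod_mass_table()]) with `modification_name` and
#'   `delta_mass_Da`; NULL to skip the mass lookup.
#' @return The pair table with delta columns added.
#' @export
compute_deltas <- function(pairs, mod_masses = NULL) {
  stopifnot(is.data.frame(pairs))
  if (any(pairs$ccs_unmodified <= 0))
    stop("ccs_unmodified must be > 0")
  pairs$delta_ccs_abs <- pairs$ccs_modified - pairs$ccs_unmodified
  pairs$delta_ccs_rel <- pairs$delta_ccs_abs / pairs$ccs_unmodified
  pairs$delta_rt <- pairs$rt_modified - pairs$rt_unmodified
  if (!is.null(mod_masses)) {
    idx <- match(pairs$modification_name, mod_masses$modification_name)
    if (anyNA(idx))
      stop("modification(s) absent from mass table: ",
           paste(unique(pairs$modification_name[is.na(idx)]),
                 collapse = ", "))
    pairs$delta_mass <- mod_masses$delta_mass_Da[idx]
  }
  pairs
}
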