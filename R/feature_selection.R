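# Filtering and replicate aggregation: evidence rows -> one record per
# (modified sequence, charge).

#' Filtering rules for modified-peptide evidence
#'
#' The defaults reproduce a standard modified-peptide CCS analysis: keep
#' charge states 2 and 3; among modified peptides keep only those with a
#' single modification site that is not the C-terminal residue; exclude
#' oxidized peptides. Unmodified peptides are subject to the charge rule
#' only.
#'
#' @param allowed_charges Integer vector of charge states to keep.
#' @param exclude_cterm_mod Drop modified peptides whose site is the last
#'   residue (1-based position == sequence length).
#' @param exclude_oxidized Drop peptides carrying oxidation.
#' @param require_single_site Drop modified peptides with more than one
#'   annotated site.
#' @return List of class `filter_rules`.
#' @export
filter_rules <- function(allowed_charges = c(2L, 3L),
                         exclude_cterm_mod = TRUE,
                         exclude_oxidized = TRUE,
                         require_single_site = TRUE) {
  if (length(allowed_charges) == 0L)
    stop("allowed_charges must be non-empty")
  structure(list(allowed_charges = as.integer(allowed_charges),
                 exclude_cterm_mod = exclude_cterm_mod,
                 exclude_oxidized = exclude_oxidized,
                 require_single_site = require_single_site),
            class = "filter_rules")
}

is_unmodified <- function(features) {
  features$modification_name == "Unmodified"
}

#' Filter evidence features by charge and modification-site rules
#'
#' Rules are applied in the fixed order charge, oxidized, multisite,
#' C-terminal site; each dropped row is counted against the first rule it
#' violates, so the per-rule counts plus survivors always sum to the input
#' row count. The counts are attached as attribute `drop_counts`.
#'
#' @param features Feature data.frame; modified rows must carry
#'   `mod_position` (and `n_mod_sites` where multi-site evidence exists).
#' @param rules A `filter_rules` object.
#' @return Filtered feature data.frame with attribute `drop_counts`, a
#'   named integer vector (`charge`, `oxidized`, `multisite`, `cterm`).
#' @export
filter_features <- function(features, rules = filter_rules()) {
  stopifnot(is.data.frame(features), inherits(rules, "filter_rules"))
  unmod <- is_unmodified(features)
  n_sites <- if ("n_mod_sites" %in% names(features)) features$n_mod_sites
             else ifelse(unmod, 0L, 1L)
  seq_len_ <- nchar(features$sequence)
  oxidized <- grepl("Oxidation", features$modification_name, fixed = TRUE) |
    grepl("(ox)", features$modified_sequence, fixed = TRUE)

  bad_charge <- !(features$charge %in% rules$allowed_charges)
  bad_ox <- rules$exclude_oxidized & oxidized
  bad_multi <- rules$require_single_site & !unmod & n_sites > 1L
  bad_cterm <- rules$exclude_cterm_mod & !unmod & n_sites == 1L &
    !is.na(features$mod_position) & features$mod_position == seq_len_

  reason <- rep(NA_character_, nrow(features))
  reason[bad_cterm] <- "cterm"
  reason[bad_multi] <- "multisite"
  reason[bad_ox] <- "oxidized"
  reason[bad_charge] <- "charge"

  keep <- is.na(reason)
  counts <- c(charge = sum(reason == "charge", na.rm = TRUE),
              oxidized = sum(reason == "oxidized", na.rm = TRUE),
              multisite = sum(reason == "multisite", na.rm = TRUE),
              cterm = sum(reason == "cterm", na.rm = TRUE))
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no features survive filtering")
  attr(out, "drop_counts") <- counts
  out
}

#' Keep the most abundant evidence per run, peptide and charge
#'
#' Within each (run_id, modified_sequence, charge) group, retains exactly
#' the highest-intensity row. Ties are broken by earliest retention time,
#' then first occurrence in the input — a deterministic rule so repeated
#' pipeline runs are reproducible. Idempotent.
#'
#' @param features Feature data.frame.
#' @return Feature data.frame with at most one row per group.
#' @export
select_top_evidence <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) return(features)
  key <- paste(features$run_id, features$modified_sequence,
               features$charge, sep = "\r")
  ord <- order(key, -features$intensity, features$rt,
               seq_len(nrow(features)))
  out <- features[ord, , drop = FALSE]
  out <- out[!duplicated(paste(out$run_id, out$modified_sequence,
                               out$charge, sep = "\r")), , drop = FALSE]
  # restore input order of the surviving rows
  out <- out[order(match(rownames(out), rownames(features))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate replicate runs into one record per peptide and charge
#'
#' Collapses aligned, top-selected features to one record per
#' (modified_sequence, charge): arithmetic mean of CCS, RT and m/z over
#' the replicate runs, maximum intensity, and the replicate count.
#' Permutation-invariant in run order.
#'
#' @param features Aligned feature data.frame with `ccs` populated and at
#'   most one row per run and peptide ([select_top_evidence()]).
#' @return data.frame of peptide records: `sequence`,
#'   `modified_sequence`, `modification_name`, `mod_position`, `charge`,
#'   `mz`, `ccs_mean`, `rt_mean`, `intensity_max`, `n_replicates`.
#' @export
aggregate_replicates <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L)
    return(data.frame(sequence = character(),
                      modified_sequence = character(),
                      modification_name = character(),
                      mod_position = integer(), charge = integer(),
                      mz = numeric(), ccs_mean = numeric(),
                      rt_mean = numeric(), intensity_max = numeric(),
                      n_replicates = integer()))
  key <- paste(features$modified_sequence, features$charge, sep = "\r")
  first <- !duplicated(key)
  agg <- function(v, fun) as.numeric(tapply(v, key, fun)[unique(key)])
  ukey <- unique(key)
  idx <- match(ukey, key)
  out <- data.frame(
    sequence = features$sequence[idx],
    modified_sequence = features$modified_sequence[idx],
    modification_name = features$modification_name[idx],
    mod_position = features$mod_position[idx],
    charge = features$charge[idx],
    mz = as.numeric(tapply(features$mz, key, mean)[ukey]),
    ccs_mean = as.numeric(tapply(features$ccs, key, mean)[ukey]),
    rt_mean = as.numeric(tapply(features$rt, key, mean)[ukey]),
    intensity_max = as.numeric(tapply(features$intensity, key, max)[ukey]),
    n_replicates = as.integer(tapply(features$run_id, key,
                                     function(x) length(unique(x)))[ukey]))
  rownames(out) <- NULL
  out
}
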