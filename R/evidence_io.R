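# Reading and writing the tab-separated tables the pipeline consumes and
# emits. Dialect: tab separator, UTF-8, "." decimal, mandatory header row,
# lines starting with '#' are comment headers (used to record the CCS
# temperature/gas assumptions in output files).

# Canonical feature fields. mod_position and ccs are optional on input.
.feature_fields <- c("run_id", "sequence", "modified_sequence",
                     "modification_name", "mod_position", "charge",
                     "mz", "inv_k0", "rt", "intensity", "ccs")
.feature_numeric <- c("mod_position", "charge", "mz", "inv_k0", "rt",
                      "intensity", "ccs")
.feature_required <- setdiff(.feature_fields, c("mod_position", "ccs"))

#' Column mapping for evidence-table dialects
#'
#' Maps canonical feature field names to the column headers used in a
#' source file, so the same reader handles both this package's canonical
#' headers and the MaxQuant `evidence.txt` dialect.
#'
#' @param ... Named overrides, e.g. `inv_k0 = "1/K0"`. Names must be
#'   canonical field names; values are source headers.
#' @return Named character vector (canonical name -> source header) of
#'   class `column_map`.
#' @export
#' @examples
#' column_map()                       # identity mapping
#' column_map(inv_k0 = "1/K0", run_id = "Raw file")
column_map <- function(...) {
  map <- stats::setNames(.feature_fields, .feature_fields)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), .feature_fields)
    if (length(bad)) stop("unknown canonical field(s) in column map: ",
                          paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  structure(map, class = "column_map")
}

#' MaxQuant evidence.txt column mapping
#'
#' @return A `column_map` matching the default MaxQuant evidence headers.
#' @export
maxquant_column_map <- function() {
  column_map(run_id = "Raw file",
             sequence = "Sequence",
             modified_sequence = "Modified sequence",
             modification_name = "Modifications",
             charge = "Charge",
             mz = "m/z",
             inv_k0 = "1/K0",
             rt = "Retention time",
             intensity = "Intensity",
             ccs = "CCS")
}

#' Locate the modification site in a bracket-annotated sequence
#'
#' Parses MaxQuant-style modified sequences such as `"_AAK(su)PK_"`:
#' underscores delimit the peptide, a parenthesized tag follows the
#' modified residue. Only the site position and site count are extracted;
#' the chemistry inside the brackets is not interpreted.
#'
#' @param modified_sequence Character vector of annotated sequences.
#' @return data.frame with columns `n_sites` and `mod_position` (1-based
#'   residue index of the first site; NA when unmodified).
#' @export
#' @examples
#' locate_mod_site("_AAK(su)PEPK_")   # 1 site at position 3
locate_mod_site <- function(modified_sequence) {
  core <- gsub("^_|_$", "", modified_sequence)
  n_sites <- integer(length(core))
  pos <- rep(NA_integer_, length(core))
  opens <- gregexpr("\\(", core)
  for (i in seq_along(core)) {
    o <- opens[[i]]
    if (o[1L] == -1L) next
    n_sites[i] <- length(o)
    # residues before the first '(' = index of the modified residue
    head <- substr(core[i], 1L, o[1L] - 1L)
    pos[i] <- nchar(gsub("\\([^)]*\\)", "", head))
  }
  data.frame(n_sites = n_sites, mod_position = pos)
}

#' Read an evidence table of detected peptide features
#'
#' Reads a tab-separated evidence table (one row per detected peptide ion
#' per run) into the canonical feature data.frame. Rows whose numeric
#' fields fail to parse are rejected with a per-row report attached as the
#' `rejects` attribute — never silently dropped. Row order is preserved
#' and rows are never deduplicated.
#'
#' If the source has no modification-position column, the position and
#' site count are derived from the bracket annotation in
#' `modified_sequence` via [locate_mod_site()].
#'
#' @param path Path to a TSV file with a header row.
#' @param col_map A `column_map`; defaults to canonical headers.
#' @return data.frame with columns `run_id`, `sequence`,
#'   `modified_sequence`, `modification_name`, `mod_position`, `charge`,
#'   `mz`, `inv_k0`, `rt`, `intensity`, `ccs`, `n_mod_sites`; attribute
#'   `rejects` is a data.frame (`row`, `reason`) of rejected source rows.
#' @export
read_evidence_table <- function(path, col_map = column_map()) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  stopifnot(inherits(col_map, "column_map"))
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", sep = "\t",
                           comment.char = "#", quote = "",
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) {
    warning("evidence file is empty: ", path)
    return(empty_feature_table())
  }
  required_src <- unname(col_map[.feature_required])
  miss <- setdiff(required_src, names(raw))
  if (length(miss))
    stop("evidence file is missing mapped column(s): ",
         paste(miss, collapse = ", "))

  cols <- lapply(.feature_fields, function(f) {
    src <- col_map[[f]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  })
  out <- data.frame(stats::setNames(cols, .feature_fields),
                    check.names = FALSE)

  reject_reason <- rep(NA_character_, nrow(out))
  for (f in .feature_numeric) {
    vals <- suppressWarnings(as.numeric(out[[f]]))
    if (f %in% .feature_required) {
      newly <- is.na(vals) & is.na(reject_reason)
      reject_reason[newly] <- paste0("non-numeric ", f, ": '",
                                     out[[f]][newly], "'")
    }
    out[[f]] <- vals
  }
  # optional integer coercion
  out$charge <- as.integer(out$charge)
  out$mod_position <- as.integer(out$mod_position)

  keep <- is.na(reject_reason)
  rejects <- data.frame(row = which(!keep),
                        reason = reject_reason[!keep])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL

  # derive site info from the annotation where not supplied
  sites <- locate_mod_site(out$modified_sequence)
  out$n_mod_sites <- sites$n_sites
  no_pos <- is.na(out$mod_position) & sites$n_sites > 0L
  out$mod_position[no_pos] <- sites$mod_position[no_pos]

  if (nrow(rejects))
    warning(nrow(rejects), " evidence row(s) rejected; see attr(x, 'rejects')")
  attr(out, "rejects") <- rejects
  out
}

empty_feature_table <- function() {
  out <- data.frame(run_id = character(), sequence = character(),
                    modified_sequence = character(),
                    modification_name = character(),
                    mod_position = integer(), charge = integer(),
                    mz = numeric(), inv_k0 = numeric(), rt = numeric(),
                    intensity = numeric(), ccs = numeric(),
                    n_mod_sites = integer())
  attr(out, "rejects") <- data.frame(row = integer(), reason = character())
  out
}

#' Read a reference-peptide table
#'
#' Reads the spiked reference-standard table (one row per reference
#' peptide) used for run alignment: sequence, reference 1/K0, reference
#' retention time and charge state.
#'
#' @param path TSV with columns `sequence`, `ref_inv_k0`, `ref_rt` and
#'   optionally `charge` (default 2, the doubly protonated species).
#' @return data.frame of unique reference peptides.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  refs <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                            comment.char = "#", quote = "",
                            fileEncoding = "UTF-8")
  if (nrow(refs) == 0L) stop("reference set empty: ", path)
  need <- c("sequence", "ref_inv_k0", "ref_rt")
  miss <- setdiff(need, names(refs))
  if (length(miss)) stop("reference table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"charge" %in% names(refs)) refs$charge <- 2L
  dup <- refs$sequence[duplicated(refs$sequence)]
  if (length(dup)) stop("duplicate reference sequence(s): ",
                        paste(unique(dup), collapse = ", "))
  if (any(refs$ref_inv_k0 <= 0)) stop("ref_inv_k0 must be > 0")
  refs
}

#' Read a modification mass table
#'
#' @param path TSV with columns `modification_name`, `delta_mass_Da`,
#'   `target_residue`. The package ships a table of common PTM mass
#'   shifts at `system.file("extdata", "mod_masses.tsv", package =
#'   "ccsdelta")`.
#' @return data.frame of modification masses.
#' @export
read_mod_mass_table <- function(path) {
  if (!file.exists(path)) stop("modification mass file not found: ", path)
  mm <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          comment.char = "#", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("modification_name", "delta_mass_Da", "target_residue")
  miss <- setdiff(need, names(mm))
  if (length(miss)) stop("modification mass table missing column(s): ",
                         paste(miss, collapse = ", "))
  mm
}

#' Write a result table as TSV
#'
#' Writes any tabular result as tab-separated UTF-8 with a header row.
#' Optional comment lines (prefixed `#`) record provenance such as the
#' temperature and drift-gas assumptions behind CCS values; the package
#' readers skip them.
#'
#' @param records data.frame to write.
#' @param path Output path.
#' @param header_comments Character vector of comment lines (without the
#'   leading `#`).
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, header_comments = character()) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

constants_header <- function(constants) {
  c(sprintf("CCS computed with Mason-Schamp at T = %g K, gas mass = %g Da (N2 convention)",
            constants$temperature_K, constants$gas_mass_Da))
}
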