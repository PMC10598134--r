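# Per-modification statistics: median relative CCS shift (MED) with
# one-sample Wilcoxon significance and Benjamini-Hochberg correction,
# charge-state profiles, ion-cloud fits, sequence-dependent delta-CCS
# gradients, mass/RT correlations and rank concordance across
# modifications.

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of location against `mu0`. Exact null
#' enumeration (tie-aware, via convolution of the signed-rank
#' distribution) is used for n <= 25 after zero removal; above that, the
#' normal approximation with continuity correction and tie-corrected
#' variance. Exact zeros are dropped before ranking (the classic Wilcoxon
#' convention — package defaults differ across ecosystems, so the policy
#' is pinned here).
#'
#' @param values Numeric vector of observations.
#' @param mu0 Null location, default 0.
#' @param exact_max_n Largest n for which the exact distribution is
#'   enumerated. Default 25.
#' @return Two-sided p-value. All values equal to `mu0` yield p = 1 with
#'   a warning.
#' @export
#' @examples
#' wilcoxon_one_sample(c(1, 2, 3, 4, 5))   # exact p = 2/32
wilcoxon_one_sample <- function(values, mu0 = 0, exact_max_n = 25L) {
  d <- values[!is.na(values)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all values equal mu0; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # doubled midranks are integers; convolve the subset-sum distribution
    d2 <- as.integer(round(2 * r))
    counts <- numeric(sum(d2) + 1L)
    counts[1L] <- 1
    for (v in d2) {
      shifted <- c(numeric(v), counts[seq_len(length(counts) - v)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / tot
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with enforced monotonicity; the output
#' preserves the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))  # all 0.03
benjamini_hochberg <- function(p_values) {
  p <- p_values
  if (anyNA(p)) stop("p-values must not be NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(adj))))
  q <- numeric(m)
  q[o] <- adj
  q
}

#' Per-modification CCS-shift summary
#'
#' For each modification: the median relative CCS deviation (MED, %) over
#' the pooled charge-2 and charge-3 pairs, per-charge pair counts, the
#' one-sample Wilcoxon p-value of the pooled deltas against zero, the
#' Benjamini-Hochberg q-value across all modifications summarized in this
#' call (the multiple-testing family is this invocation), the
#' modification mass and the median RT shift.
#'
#' @param pairs Matched-pair data.frame with delta fields
#'   ([compute_deltas()]).
#' @param mod_masses Optional mass table to (re)populate `delta_mass`.
#' @param pooled_charges Charges pooled for the MED. Default c(2, 3).
#' @return data.frame with one row per modification: `modification_name`,
#'   `n_pairs_total`, `n_pairs_z2`, `n_pairs_z3`, `med_pct`, `p_value`,
#'   `q_value`, `delta_mass`, `median_delta_rt`.
#' @export
summarize_modifications <- function(pairs, mod_masses = NULL,
                                    pooled_charges = c(2L, 3L)) {
  stopifnot(is.data.frame(pairs))
  if (!is.null(mod_masses)) pairs <- compute_deltas(pairs, mod_masses)
  if (!"delta_ccs_rel" %in% names(pairs))
    stop("pairs must carry delta fields; run compute_deltas() first")
  mods <- sort(unique(pairs$modification_name))
  rows <- lapply(mods, function(m) {
    pm <- pairs[pairs$modification_name == m, , drop = FALSE]
    pooled <- pm[pm$charge %in% pooled_charges, , drop = FALSE]
    if (nrow(pooled) == 0L) {
      warning("modification '", m, "' has no pairs in pooled charges; omitted")
      return(NULL)
    }
    data.frame(
      modification_name = m,
      n_pairs_total = nrow(pm),
      n_pairs_z2 = sum(pm$charge == 2L),
      n_pairs_z3 = sum(pm$charge == 3L),
      med_pct = 100 * stats::median(pooled$delta_ccs_rel),
      p_value = suppressWarnings(wilcoxon_one_sample(pooled$delta_ccs_rel)),
      delta_mass = if ("delta_mass" %in% names(pm)) pm$delta_mass[1L]
                   else NA_real_,
      median_delta_rt = stats::median(pooled$delta_rt))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no modifications to summarize")
  out$q_value <- benjamini_hochberg(out$p_value)
  out <- out[, c("modification_name", "n_pairs_total", "n_pairs_z2",
                 "n_pairs_z3", "med_pct", "p_value", "q_value",
                 "delta_mass", "median_delta_rt")]
  rownames(out) <- NULL
  out
}

has_internal_residue <- function(sequence, residues) {
  core <- substr(sequence, 2L, nchar(sequence) - 1L)
  grepl(paste0("[", paste(residues, collapse = ""), "]"), core)
}

#' Charge-state profile per modification
#'
#' Counts (or intensity-weights) records per charge state within each
#' modification, computed on data before the charge filter so all
#' observed charges appear. Fractions sum to one within a modification;
#' the predominant charge is the argmax, ties broken toward the lower
#' charge for deterministic reports.
#'
#' @param records Peptide-record data.frame (all charges).
#' @param internal_residue_filter Optional character vector of residues;
#'   keeps only sequences with at least one internal (non-terminal)
#'   occurrence — used for lysine/arginine pools where terminal basic
#'   residues are ubiquitous by construction.
#' @param intensity_weighted If TRUE, fractions weight records by
#'   `intensity_max` instead of counting them.
#' @return data.frame with `modification_name`, `charge`, `n`,
#'   `fraction`, `predominant_charge`.
#' @export
charge_state_profile <- function(records, internal_residue_filter = NULL,
                                 intensity_weighted = FALSE) {
  stopifnot(is.data.frame(records))
  if (!is.null(internal_residue_filter))
    records <- records[has_internal_residue(records$sequence,
                                            internal_residue_filter), ,
                       drop = FALSE]
  mods <- sort(unique(records$modification_name))
  rows <- lapply(mods, function(m) {
    rm_ <- records[records$modification_name == m, , drop = FALSE]
    w <- if (intensity_weighted) rm_$intensity_max else rep(1, nrow(rm_))
    tab <- tapply(w, rm_$charge, sum)
    charges <- as.integer(names(tab))
    n <- as.numeric(tab)
    counts <- as.numeric(tapply(rep(1, nrow(rm_)), rm_$charge, sum))
    pred <- charges[order(-n, charges)][1L]
    data.frame(modification_name = m, charge = charges, n = counts,
               fraction = n / sum(n), predominant_charge = pred)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the per-charge CCS versus m/z ion cloud
#'
#' Ordinary least-squares fit of mean CCS on m/z over the unmodified
#' peptides of one charge state. The residual of each peptide — observed
#' minus fitted CCS — separates extended (positive) from compact
#' (negative) gas-phase structures and is the predictor of the
#' delta-CCS gradient analysis.
#'
#' @param unmodified Peptide-record data.frame of unmodified peptides.
#' @param charge Charge state to fit.
#' @return Object of class `cloud_fit`: list with `charge`, `slope`
#'   (A^2/Th), `intercept` (A^2), `n`, and `residuals` (data.frame
#'   `sequence`, `mz`, `ccs`, `residual`).
#' @export
fit_ion_cloud <- function(unmodified, charge) {
  stopifnot(is.data.frame(unmodified))
  u <- unmodified[unmodified$charge == charge, , drop = FALSE]
  if (nrow(u) < 3L)
    stop("ion-cloud fit requires >= 3 unmodified records at charge ",
         charge, ", got ", nrow(u))
  fit <- stats::lm(ccs_mean ~ mz, data = u)
  structure(list(
    charge = charge,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n = nrow(u),
    residuals = data.frame(sequence = u$sequence, mz = u$mz,
                           ccs = u$ccs_mean,
                           residual = unname(stats::residuals(fit)))),
    class = "cloud_fit")
}

#' @export
print.cloud_fit <- function(x, ...) {
  cat(sprintf("Ion cloud z=%d: CCS = %.4g + %.4g * m/z (n = %d)\n",
              x$charge, x$intercept, x$slope, x$n))
  invisible(x)
}

#' Delta-CCS gradient within an ion cloud
#'
#' Regresses each pair's CCS shift on the ion-cloud residual of its
#' unmodified member, per modification, at the cloud's charge state. A
#' negative slope means peptides with extended unmodified conformers
#' (positive residual) compact upon modification. By default the
#' ABSOLUTE shift (A^2) is regressed on the residual (A^2), making the
#' slope dimensionless; `mode = "relative"` regresses the fractional
#' shift instead.
#'
#' @param pairs Matched-pair data.frame with delta fields; only pairs at
#'   `cloud$charge` are used.
#' @param cloud A `cloud_fit` for the matching charge state.
#' @param mode `"absolute"` (default) or `"relative"`.
#' @param min_pairs Minimum pairs per modification for a reported slope
#'   (default 3).
#' @return data.frame with `modification_name`, `charge`,
#'   `gradient_slope`, `intercept`, `n_pairs`, `standard_error`.
#'   Modifications with fewer than `min_pairs` matched residuals are
#'   omitted with a warning.
#' @export
deltaccs_gradient <- function(pairs, cloud, mode = c("absolute", "relative"),
                              min_pairs = 3L) {
  stopifnot(is.data.frame(pairs), inherits(cloud, "cloud_fit"))
  mode <- match.arg(mode)
  p <- pairs[pairs$charge == cloud$charge, , drop = FALSE]
  p$residual_unmodified <-
    cloud$residuals$residual[match(p$sequence, cloud$residuals$sequence)]
  p <- p[!is.na(p$residual_unmodified), , drop = FALSE]
  y_all <- if (mode == "absolute") p$delta_ccs_abs else p$delta_ccs_rel
  rows <- lapply(sort(unique(p$modification_name)), function(m) {
    sel <- p$modification_name == m
    if (sum(sel) < min_pairs) {
      warning("modification '", m, "' has ", sum(sel),
              " pair(s) with residuals at charge ", cloud$charge,
              "; gradient omitted")
      return(NULL)
    }
    fit <- stats::lm(y ~ x, data = data.frame(
      y = y_all[sel], x = p$residual_unmodified[sel]))
    sm <- summary(fit)$coefficients
    data.frame(modification_name = m, charge = cloud$charge,
               gradient_slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               n_pairs = sum(sel),
               standard_error = unname(sm["x", "Std. Error"]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(modification_name = character(), charge = integer(),
                      gradient_slope = numeric(), intercept = numeric(),
                      n_pairs = integer(), standard_error = numeric()))
  rownames(out) <- NULL
  out
}

#' Correlation of median CCS shifts with modification mass or RT shift
#'
#' Squared Pearson correlation (identical to the OLS r^2 of a simple
#' regression) between per-modification MED values and either the
#' modification mass shift or the median RT shift, optionally excluding
#' named modifications (e.g. the largest mass outliers).
#'
#' @param summaries Output of [summarize_modifications()].
#' @param x Predictor: `"delta_mass"` or `"median_delta_rt"`.
#' @param exclude Character vector of modification names to drop first.
#' @return List: `x_name`, `r_squared`, `n_modifications`, `exclusions`.
#' @export
deltaccs_mass_correlation <- function(summaries,
                                      x = c("delta_mass", "median_delta_rt"),
                                      exclude = character()) {
  stopifnot(is.data.frame(summaries))
  x <- match.arg(x)
  s <- summaries[!summaries$modification_name %in% exclude, , drop = FALSE]
  if (nrow(s) < 3L)
    stop("correlation requires >= 3 modifications after exclusion, got ",
         nrow(s))
  r <- stats::cor(s$med_pct, s[[x]])
  list(x_name = x, r_squared = r^2, n_modifications = nrow(s),
       exclusions = exclude)
}

#' Rank concordance of CCS shifts between two modifications
#'
#' Spearman rank correlation of the per-sequence absolute CCS shifts of
#' two modifications on their shared sequences (one charge state) —
#' quantifies whether a homologous series preserves the sequence rank
#' order of shifts.
#'
#' @param pairs_a,pairs_b Matched-pair data.frames for one modification
#'   and charge each.
#' @return Spearman rho, or NA (with a warning) when fewer than 3
#'   sequences are shared.
#' @export
rank_concordance <- function(pairs_a, pairs_b) {
  stopifnot(is.data.frame(pairs_a), is.data.frame(pairs_b))
  shared <- intersect(pairs_a$sequence, pairs_b$sequence)
  if (length(shared) < 3L) {
    warning("only ", length(shared),
            " shared sequence(s); rank concordance not computed")
    return(NA_real_)
  }
  a <- pairs_a$delta_ccs_abs[match(shared, pairs_a$sequence)]
  b <- pairs_b$delta_ccs_abs[match(shared, pairs_b$sequence)]
  stats::cor(a, b, method = "spearman")
}
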