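# Shared fixtures and independent oracles for the test suite.

# one evidence feature row with sensible defaults, overridable per field
feature_row <- function(run_id = "run_01", sequence = "ACDEFKGSLR",
                        modification_name = "Unmodified",
                        mod_position = NA_integer_, charge = 2L,
                        mz = 550, inv_k0 = 1.0, rt = 30,
                        intensity = 1e5, ccs = NA_real_,
                        n_mod_sites = NULL, modified_sequence = NULL,
                        tag = "xx") {
  if (is.null(n_mod_sites))
    n_mod_sites <- if (modification_name == "Unmodified") 0L else 1L
  if (is.null(modified_sequence)) {
    modified_sequence <- if (modification_name == "Unmodified" ||
                             is.na(mod_position))
      paste0("_", sequence, "_")
    else
      paste0("_", substr(sequence, 1, mod_position), "(", tag, ")",
             substr(sequence, mod_position + 1, nchar(sequence)), "_")
  }
  data.frame(run_id = run_id, sequence = sequence,
             modified_sequence = modified_sequence,
             modification_name = modification_name,
             mod_position = mod_position, charge = charge, mz = mz,
             inv_k0 = inv_k0, rt = rt, intensity = intensity, ccs = ccs,
             n_mod_sites = n_mod_sites)
}

feature_table <- function(...) {
  do.call(rbind, list(...))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

# --- independent oracles -------------------------------------------------

# full 2^n sign-flip enumeration of the two-sided signed-rank p-value
wilcox_exact_oracle <- function(x, mu0 = 0) {
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# naive sort / adjust / cummin step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# closed-form simple OLS on (x, y)
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# canonical six-row filter fixture: two survivors, one drop per rule
six_row_filter_fixture <- function() {
  rbind(
    feature_row(sequence = "ACDKFGHR", modification_name = "Acetyl (K)",
                mod_position = 4L, charge = 2L, intensity = 10),  # keep
    feature_row(sequence = "ACDKFGHR", modification_name = "Acetyl (K)",
                mod_position = 4L, charge = 4L, intensity = 20),  # charge
    feature_row(sequence = "ACDFGHKK", modification_name = "Acetyl (K)",
                mod_position = 8L, charge = 2L, intensity = 30),  # cterm
    feature_row(sequence = "ACDKFGKR", modification_name = "Acetyl (K)",
                mod_position = 4L, charge = 2L, intensity = 40,
                n_mod_sites = 2L,
                modified_sequence = "_ACDK(ac)FGK(ac)R_"),         # multisite
    feature_row(sequence = "ACDKFMHR", modification_name =
                  "Acetyl (K),Oxidation (M)", mod_position = 4L,
                charge = 2L, intensity = 50,
                modified_sequence = "_ACDK(ac)FM(ox)HR_",
                n_mod_sites = 2L),                                 # oxidized
    feature_row(sequence = "ACDEFGHR", modification_name = "Unmodified",
                charge = 3L, intensity = 60))                      # keep
}

# small noise-free synthetic configuration for closed-loop tests
noise_free_config <- function(seed = 3L, n_sequences = 20L, n_runs = 2L,
                              shift_pct = 4, gradient = 0) {
  mods <- data.frame(
    modification_name = c("Unmodified", "Test (K)"),
    tag = c("", "te"),
    target_residue = c("", "K"),
    delta_mass = c(0, 42.01057),
    shift_pct = c(0, shift_pct),
    gradient = c(0, gradient),
    shift_sd_pct = c(0, 0),
    extra_noise_sd = c(0, 0),
    rt_shift = c(0, 2),
    p_charge2 = c(1, 1),
    p_charge3 = c(0, 0))
  # gentle cloud keeps every species inside the acquisition window so
  # row counts are exactly predictable from the configuration
  synthetic_config(seed = seed, n_sequences = n_sequences,
                   n_runs = n_runs, modifications = mods,
                   cloud = list(`2` = list(slope = 0.3, intercept = 200,
                                           residual_sd = 5)),
                   drift_sd_inv_k0 = 0, drift_sd_rt = 0, noise_cv = 0,
                   rt_noise_sd = 0, missing_prob = 0)
}
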