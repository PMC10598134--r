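# Synthetic evidence-table generator with known ground truth.
#
# The generative model mirrors the structures the pipeline assumes:
#  - per-charge linear CCS-vs-m/z ion clouds with per-sequence residuals
#    drawn once and shared across modifications (creating rank-concordance
#    structure across a homologous series by construction),
#  - modification-specific median shifts plus residual-correlated
#    gradients: CCS_mod = CCS_unmod * (1 + shift + eps_rel) + g * residual
#    + eps_abs,
#  - additive per-run drift on the 1/K0 and RT scales (the alignment
#    model, exactly — recovery is an identifiability test),
#  - multiplicative (CV-style) measurement noise on CCS,
#  - replicate missingness, log-normal intensities, and spiked reference
#    peptides emitted in every run.

# monoisotopic residue masses (Da)
.residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.water <- 18.0105646863
.proton <- 1.00727646688

peptide_mass <- function(sequence) {
  vapply(strsplit(sequence, ""), function(aa) sum(.residue_mass[aa]),
         numeric(1)) + .water
}

# the 11 public iRT reference sequences (doubly protonated standard)
.irt_sequences <- c(
  "LGGNEQVTR", "GAGSSEPVTGLDAK", "VEATFGVDESNAK", "YILAGVENSK",
  "TPVISGGPYEYR", "TPVITGAPYEYR", "DGLDAASYYAPVR", "ADVTPADFSEWSK",
  "GTFIIDPGGVIR", "GTFIIDPAAVIR", "LFLQFGAQGSPFLK")

#' Default per-modification ground truth for the synthetic generator
#'
#' Four modifications spanning the observed shift range: a small negative
#' shift with a negative gradient (formylation-like), a null shift
#' (methylation-like), and two large positive shifts
#' (biotinylation-like, O-GlcNAcylation-like). Shifts are percent of the
#' unmodified CCS; gradients are dimensionless (A^2 per A^2 of residual);
#' `shift_sd_pct` is the per-pair relative scatter and `extra_noise_sd`
#' an additional absolute scatter in A^2. `p_charge2`/`p_charge3` are
#' the probabilities that a peptide is observed in each charge state.
#' The `Unmodified` row carries the base-pool charge probabilities.
#'
#' @return data.frame of modification truth parameters.
#' @export
default_modification_truth <- function() {
  data.frame(
    modification_name = c("Unmodified", "Formyl (K)", "Methyl (K)",
                          "Biotinyl (K)", "O-GlcNAc (S)"),
    tag = c("", "fo", "me", "bi", "og"),
    target_residue = c("", "K", "K", "K", "S"),
    delta_mass = c(0, 28.0106, 14.01565, 226.07759, 203.07937),
    shift_pct = c(0, -1.2, 0, 4.3, 4.5),
    gradient = c(0, -0.3, 0, -0.15, 0),
    shift_sd_pct = c(0, 1, 1, 1, 1),
    extra_noise_sd = c(0, 0, 0, 0, 0),
    rt_shift = c(0, 3, 1, 25, 2),
    p_charge2 = c(0.85, 0.9, 0.8, 0.9, 0.85),
    p_charge3 = c(0.5, 0.25, 0.6, 0.25, 0.5))
}

#' Configuration of the synthetic evidence generator
#'
#' All stochastic structure of the generated dataset is fixed here; given
#' the same configuration (including `seed`) the generator is
#' deterministic down to the byte.
#'
#' @param seed Integer RNG seed.
#' @param n_sequences Number of base peptide sequences in the pool.
#' @param n_runs Number of replicate LC-MS runs.
#' @param modifications Modification truth table; see
#'   [default_modification_truth()].
#' @param cloud Per-charge cloud parameters: named list (`"2"`, `"3"`)
#'   of lists with `slope` (A^2/Th), `intercept` (A^2), `residual_sd`
#'   (A^2).
#' @param drift_sd_inv_k0 SD of the per-run additive 1/K0 drift,
#'   Vs cm^-2.
#' @param drift_sd_rt SD of the per-run additive RT drift, minutes.
#' @param noise_cv Multiplicative measurement noise on CCS (SD as a
#'   fraction; 0.0025 = 0.25% CV).
#' @param rt_noise_sd Per-observation RT noise, minutes.
#' @param missing_prob Probability that a peptide is missing from a run.
#' @param min_length_z3 Minimum sequence length for observation as a
#'   triply charged species (short peptides lack the backbone to carry
#'   three protons, and their 3+ ions would fall below the 0.6 Vs cm^-2
#'   acquisition window edge). Default 12.
#' @param constants `ccs_constants` used to emit raw-scale 1/K0.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_sequences = 300L,
                             n_runs = 20L,
                             modifications = default_modification_truth(),
                             cloud = list(
                               `2` = list(slope = 0.40, intercept = 160,
                                          residual_sd = 15),
                               `3` = list(slope = 0.50, intercept = 220,
                                          residual_sd = 18)),
                             drift_sd_inv_k0 = 0.01,
                             drift_sd_rt = 0.2,
                             noise_cv = 0.0025,
                             rt_noise_sd = 0.05,
                             missing_prob = 0.1,
                             min_length_z3 = 12L,
                             constants = physical_constants()) {
  cfg <- list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
              n_runs = as.integer(n_runs), modifications = modifications,
              cloud = cloud, drift_sd_inv_k0 = drift_sd_inv_k0,
              drift_sd_rt = drift_sd_rt, noise_cv = noise_cv,
              rt_noise_sd = rt_noise_sd, missing_prob = missing_prob,
              min_length_z3 = as.integer(min_length_z3),
              constants = constants)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid synthetic config: ", field, " ", what)
  }
  chk(cfg$n_sequences >= 1L, "n_sequences", "must be >= 1")
  chk(cfg$n_runs >= 1L, "n_runs", "must be >= 1")
  chk(cfg$drift_sd_inv_k0 >= 0, "drift_sd_inv_k0", "must be >= 0")
  chk(cfg$drift_sd_rt >= 0, "drift_sd_rt", "must be >= 0")
  chk(cfg$noise_cv >= 0, "noise_cv", "must be >= 0")
  chk(cfg$rt_noise_sd >= 0, "rt_noise_sd", "must be >= 0")
  chk(cfg$missing_prob >= 0 && cfg$missing_prob < 1, "missing_prob",
      "must be in [0, 1)")
  m <- cfg$modifications
  chk(all(c("modification_name", "tag", "target_residue", "delta_mass",
            "shift_pct", "gradient", "shift_sd_pct", "extra_noise_sd",
            "rt_shift", "p_charge2", "p_charge3") %in% names(m)),
      "modifications", "is missing required columns")
  chk("Unmodified" %in% m$modification_name, "modifications",
      "must contain an 'Unmodified' row")
  chk(all(m$p_charge2 >= 0 & m$p_charge2 <= 1 &
            m$p_charge3 >= 0 & m$p_charge3 <= 1),
      "p_charge2/p_charge3", "must lie in [0, 1]")
  chk(all(m$shift_sd_pct >= 0) && all(m$extra_noise_sd >= 0),
      "shift_sd_pct/extra_noise_sd", "must be >= 0")
  for (z in names(cfg$cloud))
    chk(cfg$cloud[[z]]$residual_sd >= 0, paste0("cloud$", z, "$residual_sd"),
        "must be >= 0")
  invisible(cfg)
}

# random tryptic-like sequences with one internal K and one internal S
# planted (modification targets), terminating in K or R
generate_sequences <- function(n) {
  body_alphabet <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P",
                     "Q", "T", "V", "Y")
  seqs <- character(0)
  pos_k <- integer(0)
  pos_s <- integer(0)
  while (length(seqs) < n) {
    len <- sample(8:16, 1L)
    aa <- sample(body_alphabet, len, replace = TRUE)
    aa[len] <- sample(c("K", "R"), 1L)
    internal <- 2:(len - 2L)
    pk <- sample(internal, 1L)
    ps <- sample(setdiff(internal, pk), 1L)
    aa[pk] <- "K"
    aa[ps] <- "S"
    s <- paste(aa, collapse = "")
    if (!s %in% seqs) {
      seqs <- c(seqs, s)
      pos_k <- c(pos_k, pk)
      pos_s <- c(pos_s, ps)
    }
  }
  data.frame(sequence = seqs, pos_K = pos_k, pos_S = pos_s)
}

annotate_sequence <- function(sequence, mod_position, tag) {
  ifelse(tag == "" | is.na(mod_position),
         paste0("_", sequence, "_"),
         paste0("_", substr(sequence, 1, mod_position), "(", tag, ")",
                substr(sequence, mod_position + 1L, nchar(sequence)), "_"))
}

#' Generate a synthetic evidence table with known ground truth
#'
#' Draws a pool of peptide sequences, assigns true CCS values from the
#' configured per-charge clouds and modification truths, and emits a
#' raw-scale evidence table (1/K0, RT, intensity per run) that passes
#' [read_evidence_table()] unchanged, together with a reference-peptide
#' table and the full latent ground truth. Generated 1/K0 values must lie
#' within the acquisition window [0.6, 1.5] Vs cm^-2; values outside it
#' are an error (the configuration is rejected, never clipped).
#'
#' @param config A `synthetic_config`.
#' @return List of class `synthetic_pools`: `features` (evidence
#'   data.frame, all runs, with `run_id`), `reference_table` (for
#'   [compute_run_corrections()]), and `truth` (list: `run_drifts`,
#'   `sequence_residuals`, `modification_truth`, `true_ccs`,
#'   `reference`).
#' @export
generate_pools <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  mods <- config$modifications
  charges <- as.integer(names(config$cloud))

  ## --- latent truth -------------------------------------------------
  seqs <- generate_sequences(config$n_sequences)
  seqs$mass <- peptide_mass(seqs$sequence)
  seqs$rt_base <- stats::runif(nrow(seqs), 5, 115)

  # per-sequence, per-charge cloud residual (shared across modifications)
  resid <- do.call(rbind, lapply(charges, function(z) {
    data.frame(sequence = seqs$sequence, charge = z,
               residual = stats::rnorm(nrow(seqs), 0,
                                       config$cloud[[as.character(z)]]$residual_sd))
  }))

  # truth rows: sequence x modification x charge
  truth <- do.call(rbind, lapply(seq_len(nrow(mods)), function(i) {
    m <- mods[i, ]
    do.call(rbind, lapply(charges, function(z) {
      cl <- config$cloud[[as.character(z)]]
      mz_un <- (seqs$mass + z * .proton) / z
      mz <- (seqs$mass + m$delta_mass + z * .proton) / z
      rs <- resid$residual[resid$charge == z][match(seqs$sequence,
              resid$sequence[resid$charge == z])]
      ccs_un <- cl$intercept + cl$slope * mz_un + rs
      if (m$modification_name == "Unmodified") {
        ccs <- ccs_un
        mp <- NA_integer_
      } else {
        eps_rel <- stats::rnorm(nrow(seqs), 0, m$shift_sd_pct / 100)
        eps_abs <- stats::rnorm(nrow(seqs), 0, m$extra_noise_sd)
        ccs <- ccs_un * (1 + m$shift_pct / 100 + eps_rel) +
          m$gradient * rs + eps_abs
        mp <- if (m$target_residue == "K") seqs$pos_K else seqs$pos_S
      }
      observed <- stats::runif(nrow(seqs)) <
        (if (z == 2L) m$p_charge2 else m$p_charge3)
      if (z == 3L)
        observed <- observed & nchar(seqs$sequence) >= config$min_length_z3
      # acquisition window: ions whose true mobility falls within 0.05
      # Vs cm^-2 of the ramp edges are not acquired (unobserved, never
      # clipped); the margin keeps drift + noise inside [0.6, 1.5]
      ik_true <- inv_k0_from_ccs(pmax(ccs, 1), z, mz, config$constants)
      observed <- observed & ccs > 0 &
        ik_true >= 0.65 & ik_true <= 1.45
      rt_true <- seqs$rt_base + m$rt_shift +
        if (m$modification_name == "Unmodified") 0 else
          stats::rnorm(nrow(seqs), 0, 0.3)
      data.frame(sequence = seqs$sequence,
                 modification_name = m$modification_name,
                 tag = m$tag, mod_position = mp, charge = z, mz = mz,
                 ccs_true = ccs, rt_true = rt_true, observed = observed)
    }))
  }))
  truth$intensity_base <- stats::rlnorm(nrow(truth), log(1e5), 1)

  ## --- reference peptides -------------------------------------------
  ref_mass <- peptide_mass(.irt_sequences)
  ord <- order(ref_mass)
  ref <- data.frame(sequence = .irt_sequences[ord],
                    charge = 2L,
                    mz = (ref_mass[ord] + 2 * .proton) / 2,
                    ccs_true = seq(320, 430, length.out = 11L),
                    rt_true = seq(10, 110, length.out = 11L))
  ref$ref_inv_k0 <- inv_k0_from_ccs(ref$ccs_true, ref$charge, ref$mz,
                                    config$constants)

  ## --- per-run observations -----------------------------------------
  run_ids <- sprintf("run_%02d", seq_len(config$n_runs))
  drifts <- data.frame(run_id = run_ids,
                       delta_inv_k0 = stats::rnorm(config$n_runs, 0,
                                                   config$drift_sd_inv_k0),
                       delta_rt = stats::rnorm(config$n_runs, 0,
                                               config$drift_sd_rt))

  obs_truth <- truth[truth$observed, , drop = FALSE]
  n_obs <- nrow(obs_truth)
  full <- obs_truth[rep(seq_len(n_obs), times = config$n_runs), ,
                    drop = FALSE]
  full$run_id <- rep(run_ids, each = n_obs)
  keep <- stats::runif(nrow(full)) >= config$missing_prob
  meas_eps <- stats::rnorm(nrow(full), 0, config$noise_cv)
  rt_eps <- stats::rnorm(nrow(full), 0, config$rt_noise_sd)
  int_eps <- stats::rlnorm(nrow(full), 0, 0.2)
  full <- full[keep, , drop = FALSE]
  ccs_obs <- full$ccs_true * (1 + meas_eps[keep])
  di <- match(full$run_id, drifts$run_id)
  full$inv_k0 <- inv_k0_from_ccs(ccs_obs, full$charge, full$mz,
                                 config$constants) +
    drifts$delta_inv_k0[di]
  full$rt <- full$rt_true + drifts$delta_rt[di] + rt_eps[keep]
  full$intensity <- full$intensity_base * int_eps[keep]

  # reference peptides in every run
  nref <- nrow(ref)
  rfull <- ref[rep(seq_len(nref), times = config$n_runs), , drop = FALSE]
  rfull$run_id <- rep(run_ids, each = nref)
  r_eps <- stats::rnorm(nrow(rfull), 0, config$noise_cv)
  rdi <- match(rfull$run_id, drifts$run_id)
  rfull$inv_k0 <- inv_k0_from_ccs(rfull$ccs_true * (1 + r_eps),
                                  rfull$charge, rfull$mz,
                                  config$constants) +
    drifts$delta_inv_k0[rdi]
  rfull$rt <- rfull$rt_true + drifts$delta_rt[rdi] +
    stats::rnorm(nrow(rfull), 0, config$rt_noise_sd)
  rfull$intensity <- stats::rlnorm(nrow(rfull), log(5e5), 0.2)

  features <- rbind(
    data.frame(run_id = full$run_id, sequence = full$sequence,
               modified_sequence = annotate_sequence(full$sequence,
                                                     full$mod_position,
                                                     full$tag),
               modification_name = full$modification_name,
               mod_position = full$mod_position, charge = full$charge,
               mz = full$mz, inv_k0 = full$inv_k0, rt = full$rt,
               intensity = full$intensity, ccs = NA_real_),
    data.frame(run_id = rfull$run_id, sequence = rfull$sequence,
               modified_sequence = paste0("_", rfull$sequence, "_"),
               modification_name = "Unmodified",
               mod_position = NA_integer_, charge = rfull$charge,
               mz = rfull$mz, inv_k0 = rfull$inv_k0, rt = rfull$rt,
               intensity = rfull$intensity, ccs = NA_real_))
  features <- features[order(features$run_id, features$rt), , drop = FALSE]
  rownames(features) <- NULL
  features$n_mod_sites <- ifelse(features$modification_name == "Unmodified",
                                 0L, 1L)

  out_of_window <- features$inv_k0 < 0.6 | features$inv_k0 > 1.5
  if (any(out_of_window))
    stop("configuration produces ", sum(out_of_window),
         " 1/K0 value(s) outside the acquisition window [0.6, 1.5] ",
         "Vs cm^-2; adjust cloud or drift parameters (values are never ",
         "clipped)")

  reference_table <- data.frame(sequence = ref$sequence,
                                ref_inv_k0 = ref$ref_inv_k0,
                                ref_rt = ref$rt_true,
                                charge = ref$charge)

  structure(list(
    features = features,
    reference_table = reference_table,
    truth = list(run_drifts = drifts,
                 sequence_residuals = resid,
                 modification_truth = mods,
                 true_ccs = truth[, c("sequence", "modification_name",
                                      "charge", "mz", "ccs_true",
                                      "rt_true", "observed")],
                 reference = ref)),
    class = "synthetic_pools")
}

#' Ground truth of a synthetic configuration
#'
#' Returns every latent quantity [generate_pools()] uses for the same
#' configuration and seed (the generator is re-run deterministically).
#'
#' @param config A `synthetic_config`.
#' @return The `truth` list of [generate_pools()].
#' @export
ground_truth <- function(config) {
  generate_pools(config)$truth
}
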