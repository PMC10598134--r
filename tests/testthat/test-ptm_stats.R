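# Wilcoxon, BH, modification summaries, charge profiles, ion clouds,
# delta-CCS gradients, correlations, rank concordance

test_that("exact Wilcoxon matches hand-derived extreme cases", {
  expect_equal(wilcoxon_one_sample(c(1, 2, 3, 4, 5)), 2 / 32)
  # perfectly symmetric sample: p capped at 1 (verified against the
  # 2^4 enumeration oracle)
  x <- c(-1, 1, -2, 2)
  expect_equal(wilcoxon_one_sample(x), wilcox_exact_oracle(x))
  expect_equal(wilcoxon_one_sample(x), 1)
  expect_warning(p <- wilcoxon_one_sample(c(0, 0, 0)), "equal mu0")
  expect_equal(p, 1)
})

test_that("exact Wilcoxon equals sign-flip enumeration with and without ties", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    # half-integer values force ties in |x| frequently
    x <- sample(c(-3, -2, -1.5, -1, 1, 1.5, 2, 3), n, replace = TRUE)
    x <- x[x != 0]
    if (length(x) == 0) next
    expect_equal(wilcoxon_one_sample(x), wilcox_exact_oracle(x),
                 info = paste(x, collapse = ","))
  }
})

test_that("normal approximation tracks the exact tail at moderate n", {
  set.seed(14)
  x <- rnorm(26, mean = 0.3)
  exact <- wilcoxon_one_sample(x, exact_max_n = 30L)
  approx <- wilcoxon_one_sample(x, exact_max_n = 25L)
  expect_lt(abs(exact - approx), 0.015)
})

test_that("Benjamini-Hochberg step-up with monotonicity", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.04, 6)), rep(0.04, 6))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # order preservation
  p <- c(0.04, 0.001, 0.9)
  q <- benjamini_hochberg(p)
  expect_equal(order(q), order(p))
})

test_that("BH equals the naive sort/cummin oracle on random vectors", {
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
})

make_pairs <- function(mod, deltas, charge = 2L, ccs_un = 400,
                       drt = 0, dmass = 42) {
  n <- length(deltas)
  data.frame(sequence = sprintf("%sPEP%03dK", substr(mod, 1, 2), seq_len(n)),
             modification_name = mod, mod_position = 3L, charge = charge,
             ccs_modified = ccs_un * (1 + deltas), ccs_unmodified = ccs_un,
             rt_modified = 30 + drt, rt_unmodified = 30,
             mz_unmodified = 500, delta_ccs_abs = ccs_un * deltas,
             delta_ccs_rel = deltas, delta_rt = rep(drt, n),
             delta_mass = dmass)
}

test_that("summarize_modifications: degenerate and ranking behavior", {
  null_pairs <- make_pairs("Null (K)", rep(0, 10))
  s <- suppressWarnings(summarize_modifications(null_pairs))
  expect_equal(s$med_pct, 0)
  expect_equal(s$p_value, 1)
  # shifted modification ranks ahead of the null after BH
  set.seed(16)
  both <- rbind(make_pairs("Shifted (K)", rnorm(30, 0.04, 0.01)),
                make_pairs("Null (K)", rnorm(30, 0, 0.01)))
  s2 <- summarize_modifications(both)
  qs <- setNames(s2$q_value, s2$modification_name)
  expect_lt(qs["Shifted (K)"], qs["Null (K)"])
  expect_true(all(s2$q_value >= s2$p_value))
  # MED lies within the delta range
  expect_true(all(s2$med_pct >= 100 * tapply(both$delta_ccs_rel,
                                             both$modification_name,
                                             min)[s2$modification_name]))
})

test_that("MED pools charges 2 and 3 and counts per charge", {
  pairs <- rbind(make_pairs("Ac (K)", c(0.01, 0.02), charge = 2L),
                 make_pairs("Ac (K)", c(0.04, 0.05), charge = 3L))
  s <- summarize_modifications(pairs)
  expect_equal(s$n_pairs_z2, 2L)
  expect_equal(s$n_pairs_z3, 2L)
  expect_equal(s$med_pct, 100 * median(c(0.01, 0.02, 0.04, 0.05)))
})

test_that("charge profile fractions, predominance and internal filter", {
  recs <- rbind(
    do.call(rbind, lapply(1:74, function(i)
      data.frame(sequence = sprintf("AK%03dPEPR", i),
                 modification_name = "Unmodified", charge = 2L,
                 intensity_max = 10))),
    do.call(rbind, lapply(1:26, function(i)
      data.frame(sequence = sprintf("AK%03dPEPR", i),
                 modification_name = "Unmodified", charge = 3L,
                 intensity_max = 10))))
  prof <- charge_state_profile(recs)
  expect_equal(prof$fraction, c(0.74, 0.26))
  expect_equal(unique(prof$predominant_charge), 2L)
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
  # tie broken toward the lower charge
  tie <- recs[c(1:10, 75:84), ]
  expect_equal(unique(charge_state_profile(tie)$predominant_charge), 2L)
  # duplication leaves predominance unchanged
  dup <- charge_state_profile(rbind(recs, recs))
  expect_equal(unique(dup$predominant_charge), 2L)
  expect_equal(dup$fraction, prof$fraction)
  # internal residue boundary
  internal <- data.frame(sequence = c("PEPTKIDE", "PEPTIDEK"),
                         modification_name = "Unmodified", charge = 2L,
                         intensity_max = 1)
  filt <- charge_state_profile(internal, internal_residue_filter = "K")
  expect_equal(sum(filt$n), 1)
})

unmod_cloud_records <- function(n = 40, slope = 0.5, intercept = 180,
                                resid_sd = 10, charge = 2L, seed = 17) {
  set.seed(seed)
  mz <- seq(400, 900, length.out = n)
  resid <- rnorm(n, 0, resid_sd)
  data.frame(sequence = sprintf("CLOUD%03dK", seq_len(n)),
             modified_sequence = sprintf("_CLOUD%03dK_", seq_len(n)),
             modification_name = "Unmodified",
             mod_position = NA_integer_, charge = charge, mz = mz,
             ccs_mean = intercept + slope * mz + resid, rt_mean = 30,
             intensity_max = 1e5, n_replicates = 3L)
}

test_that("ion-cloud fit: exact on collinear data, residuals sum to zero", {
  col <- unmod_cloud_records(resid_sd = 0)
  fit <- fit_ion_cloud(col, 2L)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals$residual)), 0, tolerance = 1e-9)
  noisy <- unmod_cloud_records(resid_sd = 12)
  fitn <- fit_ion_cloud(noisy, 2L)
  expect_lt(abs(sum(fitn$residuals$residual)), 1e-9)
  expect_error(fit_ion_cloud(noisy[1:2, ], 2L), ">= 3")
})

test_that("ion-cloud fit recovers a generator slope of 0.55", {
  cfg <- synthetic_config(seed = 19, n_sequences = 150, n_runs = 1,
                          cloud = list(`2` = list(slope = 0.55,
                                                  intercept = 100,
                                                  residual_sd = 5)),
                          drift_sd_inv_k0 = 0, noise_cv = 0,
                          missing_prob = 0)
  pools <- generate_pools(cfg)
  feats <- convert_features_to_ccs(pools$features)
  recs <- aggregate_replicates(select_top_evidence(feats))
  unmod <- recs[recs$modification_name == "Unmodified" &
                  !recs$sequence %in% pools$reference_table$sequence, ]
  fit <- fit_ion_cloud(unmod, 2L)
  expect_lt(abs(fit$slope - 0.55), 0.02)
})

test_that("gradient regression: constant and exactly linear cases", {
  cloud <- fit_ion_cloud(unmod_cloud_records(resid_sd = 10), 2L)
  res <- cloud$residuals
  # constant delta across residuals -> slope 0
  flat <- data.frame(sequence = res$sequence,
                     modification_name = "Flat (K)", charge = 2L,
                     delta_ccs_abs = 7, delta_ccs_rel = 7 / res$ccs)
  g0 <- suppressWarnings(deltaccs_gradient(flat, cloud))
  expect_equal(g0$gradient_slope, 0, tolerance = 1e-12)
  # exact linear relation -0.3 * residual + 5
  lin <- flat
  lin$modification_name <- "Lin (K)"
  lin$delta_ccs_abs <- -0.3 * res$residual + 5
  g1 <- suppressWarnings(deltaccs_gradient(lin, cloud))
  expect_equal(g1$gradient_slope, -0.3, tolerance = 1e-10)
  expect_equal(g1$intercept, 5, tolerance = 1e-10)
  expect_equal(g1$standard_error, 0, tolerance = 1e-8)
  expect_equal(g1$n_pairs, nrow(res))
})

test_that("gradient slope is invariant under constant offsets", {
  cloud <- fit_ion_cloud(unmod_cloud_records(resid_sd = 10, seed = 23), 2L)
  res <- cloud$residuals
  set.seed(24)
  pairs <- data.frame(sequence = res$sequence,
                      modification_name = "G (K)", charge = 2L,
                      delta_ccs_abs = -0.2 * res$residual + rnorm(nrow(res)),
                      delta_ccs_rel = 0)
  base <- deltaccs_gradient(pairs, cloud)$gradient_slope
  shifted <- pairs
  shifted$delta_ccs_abs <- shifted$delta_ccs_abs + 11
  expect_equal(deltaccs_gradient(shifted, cloud)$gradient_slope, base,
               tolerance = 1e-10)
  cloud2 <- cloud
  cloud2$residuals$residual <- cloud2$residuals$residual + 4
  expect_equal(deltaccs_gradient(pairs, cloud2)$gradient_slope, base,
               tolerance = 1e-10)
})

test_that("gradients below min_pairs are omitted with a warning", {
  cloud <- fit_ion_cloud(unmod_cloud_records(n = 5), 2L)
  res <- cloud$residuals[1:2, ]
  tiny <- data.frame(sequence = res$sequence,
                     modification_name = "Tiny (K)", charge = 2L,
                     delta_ccs_abs = 1, delta_ccs_rel = 0.01)
  expect_warning(g <- deltaccs_gradient(tiny, cloud), "omitted")
  expect_equal(nrow(g), 0L)
})

test_that("MED-mass correlation: exact, null and heavy-tail exclusion", {
  s <- data.frame(modification_name = sprintf("M%02d (K)", 1:10),
                  med_pct = 0.02 * (1:10), delta_mass = 10 * (1:10),
                  median_delta_rt = rnorm(10))
  expect_equal(deltaccs_mass_correlation(s)$r_squared, 1, tolerance = 1e-12)
  # permuted MED vs mass -> near-zero r^2 at larger m
  set.seed(25)
  s2 <- data.frame(modification_name = sprintf("M%02d (K)", 1:30),
                   med_pct = sample(0.02 * (1:30)),
                   delta_mass = 10 * (1:30), median_delta_rt = 0)
  expect_lt(deltaccs_mass_correlation(s2)$r_squared, 0.2)
  # two heavy-tail points dominate; excluding them drops r^2
  s3 <- data.frame(modification_name = sprintf("M%02d (K)", 1:10),
                   med_pct = c(rnorm(8, 0, 0.5), 4.3, 4.5),
                   delta_mass = c(rnorm(8, 50, 15), 226, 203),
                   median_delta_rt = 0)
  full <- deltaccs_mass_correlation(s3)$r_squared
  excl <- deltaccs_mass_correlation(
    s3, exclude = c("M09 (K)", "M10 (K)"))
  expect_lt(excl$r_squared, full)
  expect_equal(excl$exclusions, c("M09 (K)", "M10 (K)"))
  expect_error(deltaccs_mass_correlation(s3[1:2, ]), ">= 3")
})

test_that("rank concordance: shifts, reversals and noise monotonicity", {
  a <- make_pairs("A (K)", seq(-0.05, 0.05, length.out = 12))
  b <- a
  b$modification_name <- "B (K)"
  b$delta_ccs_abs <- a$delta_ccs_abs + 8   # constant shift per sequence
  expect_equal(rank_concordance(a, b), 1)
  rev_b <- b
  rev_b$delta_ccs_abs <- rev(b$delta_ccs_abs)
  expect_equal(rank_concordance(a, rev_b), -1)
  expect_warning(r <- rank_concordance(a[1:2, ], b[1:2, ]), "shared")
  expect_true(is.na(r))
  # shared signal with increasing independent noise -> decreasing rho
  set.seed(26)
  shared <- rnorm(60, 0, 10)
  rho <- sapply(c(1, 10, 40), function(sd_noise) {
    mean(replicate(10, {
      pa <- make_pairs("A (K)", numeric(60))
      pb <- make_pairs("B (K)", numeric(60))
      pb$sequence <- pa$sequence
      pa$delta_ccs_abs <- shared + rnorm(60, 0, sd_noise)
      pb$delta_ccs_abs <- shared + rnorm(60, 0, sd_noise)
      rank_concordance(pa, pb)
    }))
  })
  expect_true(all(diff(rho) < 0))
  expect_gt(rho[1], 0.9)
})
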