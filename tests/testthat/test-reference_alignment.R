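# run-wise median-deviation alignment and CV precision metrics

ref_set <- function(n = 5, inv_k0 = seq(0.8, 1.1, length.out = n)) {
  data.frame(sequence = sprintf("REFPEP%02dK", seq_len(n)),
             ref_inv_k0 = inv_k0,
             ref_rt = seq(10, 100, length.out = n),
             charge = 2L)
}

run_with_devs <- function(devs, refs, run_id = "run_01", rt_dev = 0) {
  do.call(rbind, lapply(seq_along(devs), function(i) {
    feature_row(run_id = run_id, sequence = refs$sequence[i],
                charge = refs$charge[i],
                inv_k0 = refs$ref_inv_k0[i] + devs[i],
                rt = refs$ref_rt[i] + rt_dev)
  }))
}

test_that("exact reference match gives zero correction", {
  refs <- ref_set()
  feats <- run_with_devs(rep(0, 5), refs)
  corr <- compute_run_correction(feats, refs)
  expect_equal(corr$delta_inv_k0, 0)
  expect_equal(corr$delta_rt, 0)
  expect_equal(corr$n_refs_used, 5L)
  expect_true(corr$alignable)
})

test_that("median deviation is robust to a single outlier", {
  refs <- ref_set()
  devs <- c(0.010, 0.012, 0.011, 0.009, 0.050)
  corr <- compute_run_correction(run_with_devs(devs, refs), refs)
  expect_equal(corr$delta_inv_k0, 0.011)   # brute-force median
  expect_equal(corr$delta_inv_k0, median(devs))
})

test_that("runs below min_refs are flagged unalignable", {
  refs <- ref_set()
  feats <- run_with_devs(c(0.01, 0.01), refs[1:2, ])
  expect_warning(corr <- compute_run_correction(feats, refs, min_refs = 3),
                 "unalignable")
  expect_false(corr$alignable)
  expect_true(is.na(corr$delta_inv_k0))
})

test_that("duplicate reference occurrences resolve to the most intense", {
  refs <- ref_set(3)
  feats <- run_with_devs(c(0.01, 0.01, 0.01), refs)
  extra <- feats[1, ]
  extra$inv_k0 <- refs$ref_inv_k0[1] + 0.5   # wild duplicate, low intensity
  extra$intensity <- 1
  corr <- compute_run_correction(rbind(feats, extra), refs, min_refs = 3)
  expect_equal(corr$delta_inv_k0, 0.01)
})

test_that("apply_corrections subtracts per-run offsets and self-corrects to zero", {
  refs <- ref_set()
  f1 <- run_with_devs(rep(0.01, 5), refs, "run_01", rt_dev = 0.5)
  f2 <- run_with_devs(rep(-0.02, 5), refs, "run_02", rt_dev = -1)
  feats <- rbind(f1, f2)
  corr <- compute_run_corrections(feats, refs)
  aligned <- apply_corrections(feats, corr)
  # single-run check: every inv_k0 reduced by exactly the correction
  expect_equal(aligned$inv_k0[aligned$run_id == "run_01"],
               f1$inv_k0 - 0.01, tolerance = 1e-12)
  # post-condition: recomputing corrections on aligned data returns 0
  corr2 <- compute_run_corrections(aligned, refs)
  expect_equal(corr2$delta_inv_k0, c(0, 0), tolerance = 1e-12)
  expect_equal(corr2$delta_rt, c(0, 0), tolerance = 1e-12)
  # idempotence: a second pass changes nothing
  aligned2 <- apply_corrections(aligned, corr2)
  expect_equal(aligned2$inv_k0, aligned$inv_k0, tolerance = 1e-12)
  # zero corrections leave input untouched
  zero <- corr; zero$delta_inv_k0 <- 0; zero$delta_rt <- 0
  expect_equal(apply_corrections(feats, zero)$inv_k0, feats$inv_k0)
})

test_that("alignment preserves intensity, m/z, charge and feature count", {
  refs <- ref_set()
  feats <- rbind(run_with_devs(rep(0.01, 5), refs, "run_01"),
                 feature_row(run_id = "run_01", sequence = "OTHERPEPK",
                             mz = 777, intensity = 42))
  corr <- compute_run_corrections(feats, refs)
  aligned <- apply_corrections(feats, corr)
  expect_equal(nrow(aligned), nrow(feats))
  expect_equal(aligned$intensity, feats$intensity)
  expect_equal(aligned$mz, feats$mz)
  expect_equal(aligned$charge, feats$charge)
  expect_equal(order(aligned$rt), order(feats$rt))
})

test_that("features from unalignable runs are dropped and counted", {
  refs <- ref_set()
  good <- run_with_devs(rep(0.01, 5), refs, "run_01")
  bad <- feature_row(run_id = "run_02", sequence = "NOREFPEPK")
  feats <- rbind(good, bad)
  corr <- suppressWarnings(compute_run_corrections(feats, refs))
  expect_warning(aligned <- apply_corrections(feats, corr), "dropping 1")
  expect_equal(attr(aligned, "n_dropped_unalignable"), 1L)
  expect_false("run_02" %in% aligned$run_id)
})

test_that("per-peptide CV matches hand computation", {
  feats <- do.call(rbind, lapply(1:3, function(r) {
    f <- feature_row(run_id = sprintf("run_%02d", r))
    f$ccs <- c(500, 505, 495)[r]
    f
  }))
  pm <- precision_summary(feats)
  expect_equal(pm$median_cv, 100 * sd(c(500, 505, 495)) / 500)
  expect_equal(pm$completeness_fraction, 1)
  # identical values give CV exactly 0
  feats$ccs <- 500
  expect_equal(precision_summary(feats)$median_cv, 0)
})

test_that("precision_summary errors without usable peptides or runs", {
  f <- feature_row(); f$ccs <- 500
  expect_error(precision_summary(f), "2 runs")
  f2 <- rbind(f, feature_row(run_id = "run_02", sequence = "OTHERPEPK"))
  f2$ccs <- c(500, 510)
  expect_error(precision_summary(f2), "no peptides")
})

test_that("alignment reduces median CV under run-wise additive drift", {
  cfg <- synthetic_config(seed = 21, n_sequences = 80, n_runs = 5,
                          missing_prob = 0)
  pools <- generate_pools(cfg)
  refs <- pools$reference_table
  feats <- pools$features
  before <- precision_summary(convert_features_to_ccs(feats))
  corr <- compute_run_corrections(feats, refs)
  after <- precision_summary(
    convert_features_to_ccs(apply_corrections(feats, corr)))
  expect_lt(after$median_cv, before$median_cv)
  # after alignment the CV sits near the injected noise floor (0.25%)
  expect_lt(abs(after$median_cv - 0.25) / 0.25, 0.2)
})
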