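# Closed-form M+1/M0 ratio from elemental counts (independent oracle:
# first-order expansion of the product of per-element binomials).
m1_ratio_oracle <- function(counts) {
  p <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
            N = c(0.99636, 0.00364), O = c(0.99757, 0.00038),
            S = c(0.9499, 0.0075))
  sum(vapply(names(counts), function(el)
    counts[[el]] * p[[el]][2] / p[[el]][1], 0))
}

test_that("theoretical envelopes are normalized and match the M+1 oracle", {
  for (s in c("G", "GVQGPPGPAGPR", "DGEAGAQGPPGPAGPAGER")) {
    env <- theoretical_envelope(s, 0, 0, 6)
    expect_equal(sum(env$relative_abundances), 1, tolerance = 1e-12)
    expect_true(all(env$relative_abundances >= 0))
  }
  # free glycine: C2 H5 N O2
  env <- theoretical_envelope("G", 0, 0, 6)
  ratio <- m1_ratio_oracle(c(C = 2, H = 5, N = 1, O = 2))
  expect_equal(env$relative_abundances[2] / env$relative_abundances[1],
               ratio, tolerance = 0.002)
  # deamidation: +0.984016 exact offset, first-order same shape
  eQ <- theoretical_envelope("GVQGPPGPAGPR", 1, 0, 5)
  eD <- theoretical_envelope("GVQGPPGPAGPR", 1, 1, 5)
  expect_equal(eD$base_mz - eQ$base_mz, 0.984016, tolerance = 1e-9)
  expect_equal(eD$relative_abundances, eQ$relative_abundances,
               tolerance = 0.005)
})

envelope_peaks <- function(q, peptide = "COL1a1 508-519", amp = 1000,
                           n_iso = 5L) {
  info <- paleozooms:::DEAMIDATION_PEPTIDES[[peptide]]
  eQ <- theoretical_envelope(info$sequence, info$n_hyd, 0L, n_iso)
  grid <- eQ$base_mz + (0:n_iso) * paleozooms:::ISOTOPE_SPACING
  eD <- theoretical_envelope(info$sequence, info$n_hyd, 1L, n_iso)
  y <- q * c(eQ$relative_abundances, 0) +
    (1 - q) * c(0, eD$relative_abundances)
  data.frame(mz = grid[y > 0], intensity = amp * y[y > 0])
}

test_that("pure and mixed envelopes recover the stated deamidation scale", {
  expect_equal(estimate_deamidation(envelope_peaks(1))$value, 1,
               tolerance = 1e-9)
  expect_equal(estimate_deamidation(envelope_peaks(0))$value, 0,
               tolerance = 1e-9)
  est <- estimate_deamidation(envelope_peaks(0.5))
  expect_equal(est$value, 0.5, tolerance = 0.01)
  expect_lt(est$fit_residual, 1e-12)
  # second peptide too
  expect_equal(estimate_deamidation(
    envelope_peaks(0.3, "COL1a1 435-453"),
    peptide = "COL1a1 435-453")$value, 0.3, tolerance = 0.01)
  # scale invariance
  pk <- envelope_peaks(0.37)
  v1 <- estimate_deamidation(pk)$value
  pk$intensity <- pk$intensity * 1e4
  expect_equal(estimate_deamidation(pk)$value, v1, tolerance = 1e-10)
  # absent peptide
  expect_message(
    out <- estimate_deamidation(data.frame(mz = 900, intensity = 5)),
    "not detected")
  expect_null(out)
})

test_that("deamidation recovery under 5% intensity noise has MAE <= 0.03", {
  set.seed(404)
  qs <- seq(0, 1, by = 0.1)
  errs <- vapply(1:10, function(rep) {
    est <- vapply(qs, function(q) {
      pk <- envelope_peaks(q)
      pk$intensity <- pk$intensity * exp(stats::rnorm(nrow(pk), 0, 0.05))
      estimate_deamidation(pk)$value
    }, 0)
    mean(abs(est - qs))
  }, 0)
  expect_lte(mean(errs), 0.03)
})

test_that("layer summaries give percentile intervals around the mean", {
  est <- data.frame(specimen_id = "a", peptide = "COL1a1 508-519",
                    value = 0.4)
  lm <- c(a = "L1")
  s <- summarize_by_layer(est, lm, n_boot = 200)
  expect_equal(s$mean, 0.4)
  expect_equal(s$lo_68, 0.4)
  expect_equal(s$hi_68, 0.4)
  # constant values: degenerate interval
  est2 <- data.frame(specimen_id = sprintf("s%d", 1:100),
                     peptide = "COL1a1 508-519", value = 0.5)
  lm2 <- stats::setNames(rep("L1", 100), est2$specimen_id)
  s2 <- summarize_by_layer(est2, lm2, n_boot = 200)
  expect_equal(c(s2$mean, s2$lo_68, s2$hi_68), rep(0.5, 3))
  # CLT check: interval width ~ 2 * sd/sqrt(n)
  set.seed(7)
  est3 <- data.frame(specimen_id = sprintf("s%d", 1:50),
                     peptide = "COL1a1 508-519",
                     value = stats::rnorm(50, 0.4, 0.05))
  lm3 <- stats::setNames(rep("L1", 50), est3$specimen_id)
  s3 <- summarize_by_layer(est3, lm3, n_boot = 2000, seed = 11)
  width <- s3$hi_68 - s3$lo_68
  expect_lt(abs(width - 2 * stats::sd(est3$value) / sqrt(50)) /
              (2 * stats::sd(est3$value) / sqrt(50)), 0.3)
  # estimates without a layer are dropped with a warning
  expect_warning(summarize_by_layer(
    rbind(est3, data.frame(specimen_id = "zz",
                           peptide = "COL1a1 508-519", value = 1)),
    lm3, n_boot = 100), "dropped")
})

test_that("layer-graded deamidation is monotone in the synthetic world", {
  cfg <- sim_config(seed = 15, n_specimens_per_layer = 4,
                    mz_noise_sd = 0, dropout = 0,
                    noise_peaks_per_spectrum = 0)
  sim <- simulate_col1_taxa(cfg)
  db <- predict_markers(sim$sequences, sim$taxonomy)
  sp <- simulate_spectra(cfg, db)
  cons <- lapply(sp$spectra, merge_replicates)
  est <- Filter(Negate(is.null), lapply(cons, estimate_deamidation))
  lmap <- stats::setNames(sp$truth$layer, sp$truth$specimen_id)
  s <- summarize_by_layer(est, lmap, n_boot = 200, seed = 1)
  s <- s[match(cfg$layers, s$layer), ]
  expect_equal(stats::cor(s$mean, cfg$deamidation_by_layer[s$layer],
                          method = "spearman"), 1)
  # deeper layers more deamidated -> non-increasing mean value
  expect_true(all(diff(s$mean) <= 0))
})
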