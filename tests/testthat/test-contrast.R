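test_that("contrast decomposition matches the hand-evaluated example", {
  # one window, one frame: <I> = 100 ADU, sigma^2 = 150 ADU^2, G = 0.5,
  # <sigma2_dark> = 4 ADU^2, Ksp^2 = 1e-4
  ws <- structure(list(
    mean = matrix(100, 1, 1), var = matrix(150, 1, 1),
    timestamps = 0, source_ids = 1L, window_size = 7,
    grid = list(nwr = 1, nwc = 1, n_win = 1), sources = 1L,
    mi_mean = matrix(100, 1, 1), mi_var = matrix(1, 1, 1),  # Ksp^2 = 1e-4
    exposure_s = 4e-3, camera = camera_spec()), class = "window_stats")
  dark <- structure(list(mean_dark = matrix(25, 7, 7),
                         windowed_dark_tvar = 4, window_size = 7,
                         grid = list(nwr = 1, nwc = 1, n_win = 1)),
                    class = "dark_stats")
  cc <- contrast_components(ws, dark, camera_spec(gain = 0.5))
  expect_equal(cc$k_raw2[1, 1], 1.5e-2)
  expect_equal(cc$k_s2[1, 1], 5.0e-3)
  expect_equal(cc$k_r2[1, 1], (4 - 1 / 12) / 1e4)
  expect_equal(cc$k_r2[1, 1], 3.9167e-4, tolerance = 1e-4)
  expect_equal(cc$k_q2[1, 1], (1 / 12) / 1e4)
  expect_equal(cc$k_sp2[1, 1], 1e-4)
  expect_equal(cc$k_f2_window[1, 1], 9.4999e-3, tolerance = 1e-4)
  # decomposition identity is exact
  expect_identical(cc$k_f2_window,
                   cc$k_raw2 - cc$k_s2 - cc$k_r2 - cc$k_q2 - cc$k_sp2)
  # non-positive window mean is flagged invalid
  ws$mean[1, 1] <- -3
  cc2 <- contrast_components(ws, dark, camera_spec())
  expect_false(cc2$valid[1, 1])
})

test_that("intensity weighting follows the squared-mean rule", {
  mk <- function(means, kf2_shift) {
    # two-window frame with prescribed window means; k_f2 set via var
    structure(list(
      mean = matrix(means, 1), var = matrix(kf2_shift * means^2, 1),
      timestamps = 0, source_ids = 1L, window_size = 7,
      grid = list(nwr = 1, nwc = 2, n_win = 2), sources = 1L,
      mi_mean = matrix(means, 1), mi_var = matrix(0, 1, length(means)),
      exposure_s = 4e-3, camera = camera_spec()), class = "window_stats")
  }
  dark <- structure(list(mean_dark = NULL, windowed_dark_tvar = c(1 / 12, 1 / 12),
                         window_size = 7,
                         grid = list(nwr = 1, nwc = 2, n_win = 2)),
                    class = "dark_stats")
  cam_noiseless <- camera_spec(gain = 1e-9, read_noise_e = 0)
  # K^2_f,window ~= {0.01, 0.03} at intensities {100, 200} -> 0.026
  ws <- mk(c(100, 200), c(0.01, 0.03))
  cc <- contrast_components(ws, dark, cam_noiseless)
  expect_equal(cc$k_f2_window[1, ], c(0.01, 0.03), tolerance = 1e-3)
  wk <- weighted_kf2(cc, ws)
  # the squared-intensity weighting rule, exact on the computed components
  expect_equal(wk$kf2,
               (1e4 * cc$k_f2_window[1, 1] + 4e4 * cc$k_f2_window[1, 2]) / 5e4,
               tolerance = 1e-12)
  expect_equal(wk$kf2, 0.026, tolerance = 1e-3)
  # equal intensities -> unweighted mean (exact)
  wse <- mk(c(100, 100), c(0.01, 0.03))
  cce <- contrast_components(wse, dark, cam_noiseless)
  expect_equal(weighted_kf2(cce, wse)$kf2, mean(cce$k_f2_window[1, ]),
               tolerance = 1e-12)
  # single window -> its own value
  ws1 <- mk(150, 0.02)
  ws1$grid <- list(nwr = 1, nwc = 1, n_win = 1)
  dark1 <- dark
  dark1$windowed_dark_tvar <- 1 / 12
  dark1$grid <- list(nwr = 1, nwc = 1, n_win = 1)
  cc1 <- contrast_components(ws1, dark1, cam_noiseless)
  expect_equal(weighted_kf2(cc1, ws1)$kf2, cc1$k_f2_window[1, 1],
               tolerance = 1e-12)
  # all windows invalid -> missing
  wsn <- mk(c(-5, -5), c(0.01, 0.01))
  ccn <- contrast_components(wsn, dark, cam_noiseless)
  expect_true(is.na(weighted_kf2(ccn, wsn)$kf2))
  # per-frame weighting agrees with mean-image weighting here (identical
  # intensities) — both interpretations of the normalization are available
  expect_equal(weighted_kf2(cc, ws, weights = "perframe")$kf2,
               weighted_kf2(cc, ws, weights = "meanimage")$kf2)
})

test_that("delta OD uses the natural log of the baseline-normalized intensity", {
  tt <- seq(0, 9.9, by = 0.1)
  i0 <- 80
  v <- rep(i0, length(tt))
  v[51] <- i0 * exp(-0.017)
  v[61] <- i0 / 2
  ser <- channel_series(tt, v, kind = "intensity")
  # I0 from the whole measurement period shifts all samples slightly
  od <- delta_od(ser, baseline = c(0, 4))
  expect_equal(unname(od$values[1, 1]), 0)
  expect_equal(unname(od$values[51, 1]), 1.7e-2, tolerance = 1e-9)
  expect_equal(unname(od$values[61, 1]), log(2), tolerance = 1e-12)
})

test_that("rDB-1 is the baseline-normalized reciprocal contrast minus one", {
  tt <- seq(0, 9.9, by = 0.1)
  kf2 <- rep(0.09, length(tt))
  ser <- channel_series(tt, kf2, kind = "kf2")
  expect_lt(max(abs(rdb_minus_one(ser)$values)), 1e-12)
  # halving the contrast doubles the flow index
  kf2[60:70] <- 0.045
  r <- rdb_minus_one(channel_series(tt, kf2, "kf2"), baseline = c(0, 3))
  expect_equal(unname(r$values[65, 1]), 1.0, tolerance = 1e-12)
  # non-positive contrast samples become missing
  kf2[5] <- 0
  r2 <- rdb_minus_one(channel_series(tt, kf2, "kf2"), baseline = c(1, 3))
  expect_true(is.na(r2$values[5, 1]))
})

test_that("photon transfer curve recovers gain and read noise", {
  set.seed(21)
  cam <- camera_spec(gain = 0.5, read_noise_e = 2.1, bit_depth = 10)
  dark <- make_dark(cam, 400, c(21, 21), seed = 31)
  fluxes <- round(exp(seq(log(5), log(1500), length.out = 8)))
  mk_level <- function(flux, camera, seed) {
    tr <- speckle_truth(beta = 0.16, tau_c = 1e-7, mean_flux = flux)
    simulate_frames(sim_scenario(tr, seed = seed),
                    multiplex_schedule(n_sources = 1), camera,
                    shape = c(21, 21), duration = 2)
  }
  stacks <- lapply(seq_along(fluxes), function(i)
    suppressWarnings(mk_level(fluxes[i], cam, 100 + i)))
  fit <- estimate_gain_ptc(stacks, dark)
  expect_equal(fit$gain, 0.5, tolerance = 0.02)
  expect_equal(fit$intercept_adu2, (0.5 * 2.1)^2 + 1 / 12, tolerance = 0.15)
  # the top level (mean 25 + 750 ADU, speckle tail beyond 1023) is the only
  # candidate for clipping here; adding a fully saturated level must not
  # disturb the fit
  sat <- suppressWarnings(mk_level(4000, cam, 200))
  fit2 <- estimate_gain_ptc(c(stacks, list(sat)), dark)
  expect_false(fit2$levels$used[9])
  expect_equal(fit2$gain, fit$gain, tolerance = 1e-6)
  # pure Poisson camera: slope 1, intercept = quantization only
  cam1 <- camera_spec(gain = 1, read_noise_e = 0, bit_depth = 12)
  dark1 <- make_dark(cam1, 400, c(21, 21), seed = 32)
  stacks1 <- lapply(1:6, function(i)
    mk_level(round(10 * 3^ (i - 1)), cam1, 300 + i))
  fit1 <- estimate_gain_ptc(stacks1, dark1)
  expect_equal(fit1$gain, 1, tolerance = 0.02)
  expect_equal(fit1$intercept_adu2, 1 / 12, tolerance = 0.5)
  # fewer than 3 usable levels is a calibration error
  expect_error(estimate_gain_ptc(stacks[1:2], dark), "3 usable")
})

test_that("static-scene contrast recovers beta and closes the s/p calibration", {
  # frozen speckle: the independent samples are windows of independent
  # static patterns, so pool several patterns
  static_kf2 <- function(n_patterns, frames, seed0) {
    vals <- c()
    for (s in seq_len(n_patterns)) {
      tr <- speckle_truth(sp_ratio = 0.69, tau_c = Inf, mean_flux = 400)
      p <- pipeline_kf2(tr, seed = seed0 + s, shape = c(70, 70),
                        frames = frames, method = "field")
      vals <- c(vals, colMeans(matrix(p$values, nrow = frames)))
    }
    vals
  }
  vals <- static_kf2(6, 8, 400)
  se <- sd(vals) / sqrt(length(vals))
  expect_equal(mean(vals), beta_from_sp(0.69), tolerance = 3 * se / 0.16)
  # calibration closure at higher precision: the measured contrast maps back
  # to the calibrated s/p within 2% (the remaining offset is the documented
  # O(1/49) windowed-estimator bias, ~ -1.3% on s/p)
  vals2 <- c(vals, static_kf2(80, 4, 500))
  expect_equal(sp_from_contrast(mean(vals2)), 0.69, tolerance = 0.02)
})

test_that("gamma and field generators agree on corrected contrast", {
  tr <- speckle_truth(beta = 0.16, tau_c = 4e-3, mean_flux = 50)
  pf <- pipeline_kf2(tr, seed = 51, frames = 30, method = "field")
  pg <- pipeline_kf2(tr, seed = 52, frames = 30, method = "gamma")
  se <- sqrt(sd(pf$values)^2 / length(pf$values) +
               sd(pg$values)^2 / length(pg$values))
  expect_lt(abs(mean(pf$values) - mean(pg$values)), 3 * se)
})

test_that("doubling the flux leaves corrected contrast unchanged", {
  mk <- function(flux, seed) {
    tr <- speckle_truth(beta = 0.16, tau_c = 4e-3, mean_flux = flux)
    pipeline_kf2(tr, seed = seed, frames = 30, method = "field")
  }
  a <- mk(40, 61); b <- mk(80, 61)   # same seed: identical field dynamics
  se <- sqrt(sd(a$values)^2 / length(a$values) +
               sd(b$values)^2 / length(b$values))
  expect_lt(abs(mean(a$values) - mean(b$values)), 3 * se)
  # negative control: the uncorrected raw contrast shifts by the shot-noise
  # term, far outside the same band
  raw_a <- mean(a$cc$k_raw2[a$cc$valid])
  raw_b <- mean(b$cc$k_raw2[b$cc$valid])
  expect_gt(abs(raw_a - raw_b), 10 * se)
})
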