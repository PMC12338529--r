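fs_array <- 100 / 7   # full-array rate of the 7-source schedule

test_that("low-flux channel pruning reports the retained fraction", {
  # cohort-scale fixture: 1500 channel-runs, 58 constructed below 4 ADU
  set.seed(3)
  n <- 1500
  means <- runif(n, 6, 400)
  low <- sample(n, 58)
  means[low] <- runif(58, 0.2, 3.9)
  tt <- seq(0, 9, by = 1 / fs_array)
  v <- matrix(rep(means, each = length(tt)), length(tt))
  ser <- channel_series(tt, v, kind = "intensity")
  pr <- prune_low_flux(ser, threshold = 4)
  expect_equal(sum(pr$keep), 1442)
  expect_equal(round(100 * pr$retained_fraction, 1), 96.1)
  # all channels bright / zero threshold: nothing excluded
  expect_equal(length(prune_low_flux(ser, threshold = 0)$excluded), 0)
  bright <- channel_series(tt, v[, -low], kind = "intensity")
  expect_equal(length(prune_low_flux(bright)$excluded), 0)
})

test_that("motion-contaminated blocks are masked and heavy subjects flagged", {
  set.seed(8)
  tt <- seq(0, 199, by = 1 / fs_array)
  des <- block_design(onsets = seq(20, 180, by = 40), durations = 18,
                      epoch_window = c(-2, 20))
  clean <- matrix(0.002 * sin(2 * pi * 0.05 * tt) +
                    rnorm(length(tt), sd = 5e-4), ncol = 1)
  ser <- channel_series(tt, clean, kind = "delta_od")
  d0 <- detect_motion_blocks(ser, des)
  expect_true(all(d0$valid))
  expect_false(d0$subject_excluded)
  # a 0.5-OD spike inside block 3 masks exactly that block
  spiked <- clean
  i <- which.min(abs(tt - (des$onsets[3] + 5)))
  spiked[i + 0:1, 1] <- spiked[i + 0:1, 1] + 0.5
  d1 <- detect_motion_blocks(channel_series(tt, spiked, "delta_od"), des)
  expect_equal(which(!d1$valid), 3L)
  # manual mask overrides detection
  d2 <- detect_motion_blocks(channel_series(tt, spiked, "delta_od"), des,
                             manual_mask = rep(TRUE, 5))
  expect_true(all(d2$valid))
  # >50% contaminated blocks -> subject excluded
  heavy <- clean
  for (b in c(1, 2, 4)) {
    j <- which.min(abs(tt - (des$onsets[b] + 5)))
    heavy[j + 0:1, 1] <- heavy[j + 0:1, 1] + 0.5
  }
  d3 <- detect_motion_blocks(channel_series(tt, heavy, "delta_od"), des)
  expect_true(d3$subject_excluded)
})

test_that("short-separation regression leaves residuals orthogonal to the regressor", {
  set.seed(4)
  tt <- seq(0, (4000 - 1)) / fs_array
  short <- sin(2 * pi * 0.1 * tt) + 0.3 * rnorm(4000)
  brain <- 0.5 * sin(2 * pi * 0.03 * tt + 1)
  y <- 0.6 * short + brain
  ser <- channel_series(tt, cbind(y, short), kind = "delta_od",
                        channels = c("far", "short"))
  res <- short_sep_regress(channel_series(tt, y, "delta_od"), short)
  # residual recovers the planted independent signal
  expect_gt(cor(res$values[, 1], brain), 0.99)
  # orthogonality to 1e-10 relative, on random inputs too
  for (k in 1:5) {
    yk <- rnorm(4000); sk <- rnorm(4000)
    rk <- short_sep_regress(channel_series(tt, yk, "delta_od"), sk)
    expect_lt(abs(cov(rk$values[, 1], sk)) / (sd(yk) * sd(sk)), 1e-10)
  }
  # target identical to the short channel: residual vanishes
  r0 <- short_sep_regress(channel_series(tt, short, "delta_od"), short)
  expect_lt(max(abs(r0$values)), 1e-10)
  # constant regressor degenerates to mean removal
  rc <- short_sep_regress(channel_series(tt, y, "delta_od"),
                          rep(2, 4000))
  expect_equal(rc$values[, 1], y - mean(y), tolerance = 1e-12)
})

test_that("PCA common-mode regression removes shared drifts only", {
  set.seed(5)
  nt <- 2000
  tt <- seq_len(nt) / fs_array
  own <- sapply(1:4, function(k)
    (0.5 + 0.6 * k) * sin(2 * pi * (0.02 + 0.013 * k) * tt + k))
  drift <- 5 * sin(2 * pi * 0.005 * tt) + 2 * tt / max(tt)
  contaminated <- own + drift
  ser <- channel_series(tt, contaminated, kind = "rdb_minus_one")
  cleaned <- pca_common_mode_regress(ser, groups = list(1:4))
  resid_drift <- function(v) {
    d <- drift - mean(drift)
    sum((apply(v, 2, function(c) sum((c - mean(c)) * d) / sum(d^2)))^2)
  }
  # planted common drift variance reduced by > 95%
  expect_lt(resid_drift(cleaned$values) / resid_drift(contaminated), 0.05)
  # channel-specific signals alone are untouched (no qualifying component)
  ser2 <- channel_series(tt, own, kind = "rdb_minus_one")
  cleaned2 <- pca_common_mode_regress(ser2, groups = list(1:4))
  expect_equal(cleaned2$values, ser2$values, tolerance = 1e-6)
  # single-channel group is a no-op
  ser3 <- channel_series(tt, contaminated[, 1], kind = "rdb_minus_one")
  expect_equal(pca_common_mode_regress(ser3, groups = list(1))$values,
               ser3$values)
})

test_that("the 0.2 Hz fifth-order low-pass has the specified transfer", {
  tt <- seq(0, 600, by = 1 / fs_array)
  mid <- tt > 100 & tt < 500
  # DC passes untouched
  dc <- channel_series(tt, rep(2.5, length(tt)), "rdb_minus_one")
  expect_equal(lowpass(dc)$values, dc$values, tolerance = 1e-6)
  # 1 Hz is suppressed below 1% residual amplitude (> 40 dB)
  s1 <- channel_series(tt, sin(2 * pi * 1 * tt), "rdb_minus_one")
  expect_lt(max(abs(lowpass(s1)$values[mid, 1])), 0.01)
  # 0.02 Hz passes within 1% of unit amplitude
  s2 <- channel_series(tt, sin(2 * pi * 0.02 * tt), "rdb_minus_one")
  ratio <- max(abs(lowpass(s2)$values[mid, 1])) / max(abs(s2$values[mid, 1]))
  expect_equal(ratio, 1, tolerance = 0.01)
  # linearity
  a <- lowpass(channel_series(tt, s1$values + 2 * s2$values, "rdb_minus_one"))
  expect_equal(a$values, lowpass(s1)$values + 2 * lowpass(s2)$values,
               tolerance = 1e-10)
})

test_that("block averaging baseline-shifts, masks and recovers planted responses", {
  fs <- fs_array
  tt <- seq(0, 260 - 1 / fs, by = 1 / fs)
  # onsets on the sampling grid so noise-free recovery is exact
  des <- block_design(onsets = tt[seq(290, by = 570, length.out = 6)],
                      durations = 10, epoch_window = c(-2, 38))
  # constant series -> all-zero epochs after baseline shift
  cser <- channel_series(tt, rep(3, length(tt)), "rdb_minus_one")
  ep0 <- block_average(cser, des)
  expect_true(all(abs(ep0$data[, ep0$valid, ]) < 1e-12))
  # canonical response at every onset, noise-free -> recovered exactly
  resp <- function(t) ifelse(t > 0 & t < 15, sin(pi * t / 15)^2, 0)
  v <- rowSums(sapply(des$onsets, function(o) resp(tt - o)))
  ep1 <- block_average(channel_series(tt, v, "rdb_minus_one"), des)
  expect_equal(ep1$average$task[, 1], resp(ep1$time), tolerance = 1e-9)
  # a constant offset commutes through (baseline shift removes it exactly)
  ep2 <- block_average(channel_series(tt, v + 7, "rdb_minus_one"), des)
  expect_equal(ep2$average$task, ep1$average$task, tolerance = 1e-12)
  # masking one of 6 blocks averages the remaining 5
  mask <- rep(TRUE, 6); mask[2] <- FALSE
  ep3 <- block_average(channel_series(tt, v, "rdb_minus_one"), des, mask)
  expect_equal(ep3$n_valid[["task"]], 5L)
  expect_equal(ep3$average$task[, 1],
               apply(ep3$data[, mask, , drop = FALSE], 1, mean),
               tolerance = 1e-12)
})

test_that("group statistics weight subjects by valid blocks and flag by 1.96 SE", {
  set.seed(6)
  nt <- 30; nch <- 3; ns <- 8
  time <- seq(-2, 27, length.out = nt)
  # identical subjects: SE is zero and any nonzero activation is significant
  base <- array(rep(1.5, ns * nt * nch), c(ns, nt, nch))
  g0 <- group_stats(base, rep(18, ns), time, window = c(10, 15))
  expect_true(all(g0$table$se == 0))
  expect_true(all(g0$table$significant))
  # equal weights reduce to the plain mean and the t-test path agrees
  x <- array(rnorm(ns * nt * nch), c(ns, nt, nch))
  g1 <- group_stats(x, rep(10, ns), time, window = c(10, 15))
  xw <- apply(x[, time >= 10 & time <= 15, ], c(1, 3), mean)
  expect_equal(g1$table$window_mean, colMeans(xw), tolerance = 1e-12)
  for (ch in 1:nch) {
    tt_ref <- t.test(xw[, ch])
    expect_equal(g1$table$t[ch], unname(tt_ref$statistic), tolerance = 1e-10)
    expect_equal(g1$table$p[ch], tt_ref$p.value, tolerance = 1e-10)
  }
  expect_equal(g1$table$significant, g1$table$t > 1.96)
  # unequal weights follow the valid-block rule
  nv <- c(18, 9, 18, 3, 12, 18, 6, 18)
  g2 <- group_stats(x, nv, time, window = c(10, 15))
  w <- nv / sum(nv)
  expect_equal(g2$table$window_mean, colSums(xw * w), tolerance = 1e-12)
})
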