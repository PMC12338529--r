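# shared fixture builders (all synthetic, generated at test time)

default_cam <- function(...) camera_spec(...)

# dark statistics from a simulated dark stack
make_dark <- function(camera = default_cam(), n = 300, shape = c(49, 49),
                      seed = 5, window = 7) {
  compute_dark_stats(simulate_dark_frames(camera, n, shape, seed = seed),
                     window = window)
}

# full single-source pipeline: simulate -> dark-subtract -> window stats ->
# corrected per-window contrast values; returns the pieces recovery tests need
pipeline_kf2 <- function(truth, seed, shape = c(49, 49), frames = 35,
                         method = "field", camera = default_cam(),
                         ksp = "none", exposure_ms = 4) {
  sched <- multiplex_schedule(n_sources = 1, exposure_ms = exposure_ms)
  scen <- sim_scenario(truth, seed = seed, method = method)
  st <- simulate_frames(scen, sched, camera, shape,
                        duration = frames / sched$camera_rate_hz)
  dark <- make_dark(camera, 300, shape, seed = seed + 1000)
  ws <- window_statistics(subtract_dark(st, dark))
  cc <- contrast_components(ws, dark, camera, ksp = ksp)
  list(values = cc$k_f2_window[cc$valid], cc = cc, ws = ws, dark = dark,
       wkf2 = weighted_kf2(cc, ws))
}

# independent oracle: expectation (and SE) of the windowed var/mean^2
# statistic on pure noiseless speckle fields at 7x7 = 49 pixels
windowed_speckle_expectation <- function(beta, sp_ratio, x, n_windows = 3000,
                                         seed = 99) {
  set.seed(seed)
  v <- scosr:::field_speckle(49 * n_windows, beta, sp_ratio, x)
  w <- matrix(v, 49)
  k <- apply(w, 2, stats::var) / colMeans(w)^2
  list(mean = mean(k), se = stats::sd(k) / sqrt(n_windows))
}

# brute-force window statistics oracle (double loop, two-pass)
brute_window_stats <- function(frame, w = 7) {
  nwr <- nrow(frame) %/% w; nwc <- ncol(frame) %/% w
  m <- v <- matrix(0, nwr, nwc)
  for (i in seq_len(nwr)) for (j in seq_len(nwc)) {
    px <- frame[(i - 1) * w + seq_len(w), (j - 1) * w + seq_len(w)]
    m[i, j] <- mean(px); v[i, j] <- stats::var(as.vector(px))
  }
  list(mean = as.vector(m), var = as.vector(v))
}
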