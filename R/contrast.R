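#' Noise-decomposed contrast components
#'
#' Decomposes the raw windowed contrast of dark-subtracted frames into its
#' noise constituents so they can be subtracted, window by window and frame
#' by frame:
#' \deqn{K_{raw}^2 = \sigma^2_{window} / \langle I_{window}\rangle^2}
#' \deqn{K_s^2 = G / \langle I_{window}\rangle \quad \textrm{(shot noise)}}
#' \deqn{K_r^2 = (\langle\sigma^2_{dark,window}\rangle - 1/12) / \langle I_{window}\rangle^2 \quad \textrm{(read noise)}}
#' \deqn{K_q^2 = (1/12) / \langle I_{window}\rangle^2 \quad \textrm{(quantization)}}
#' \deqn{K_{sp}^2 = \sigma^2_{meanimage} / \langle I_{meanimage}\rangle^2 \quad \textrm{(spatial heterogeneity)}}
#' \deqn{K_{f,window}^2 = K_{raw}^2 - K_s^2 - K_r^2 - K_q^2 - K_{sp}^2}
#' where G is the camera gain in ADU per photoelectron. The decomposition
#' identity holds exactly by construction.
#'
#' `ksp = "none"` skips the heterogeneity subtraction — appropriate for
#' static scenes, where the temporal mean image is the speckle pattern
#' itself, and for simulations with uniform illumination.
#'
#' @param ws [window_statistics()] of a dark-subtracted stack.
#' @param dark the matching [compute_dark_stats()] result.
#' @param camera a [camera_spec()]; supplies G.
#' @param ksp `"meanimage"` (default) or `"none"`.
#' @return an object of class `contrast_components`: matrices (frames x
#'   windows) `k_raw2`, `k_s2`, `k_r2`, `k_q2`, `k_sp2`, `k_f2_window`, and
#'   `valid` (windows with positive mean intensity).
#' @export
contrast_components <- function(ws, dark, camera,
                                ksp = c("meanimage", "none")) {
  ksp <- match.arg(ksp)
  if (!is.null(dark$grid) && dark$grid$n_win != ws$grid$n_win)
    stop("dark statistics computed on a different window grid")
  m <- ws$mean
  valid <- is.finite(m) & m > 0
  m2 <- m^2
  k_raw2 <- ws$var / m2
  k_s2 <- camera$gain / m
  k_r2 <- sweep(1 / m2, 2, dark$windowed_dark_tvar - 1 / 12, "*")
  k_q2 <- (1 / 12) / m2
  if (ksp == "meanimage") {
    sp_by_src <- ws$mi_var / ws$mi_mean^2          # sources x windows
    k_sp2 <- sp_by_src[match(ws$source_ids, ws$sources), , drop = FALSE]
  } else {
    k_sp2 <- matrix(0, nrow(m), ncol(m))
  }
  k_f2 <- k_raw2 - k_s2 - k_r2 - k_q2 - k_sp2
  structure(list(k_raw2 = k_raw2, k_s2 = k_s2, k_r2 = k_r2, k_q2 = k_q2,
                 k_sp2 = k_sp2, k_f2_window = k_f2, valid = valid),
            class = "contrast_components")
}

#' Intensity-weighted fundamental contrast per frame
#'
#' Combines the per-window corrected contrasts into one value per frame,
#' weighting each window by its squared mean intensity, normalized over the
#' valid windows, so windows receiving more photons dominate:
#' \deqn{w = \langle I\rangle^2 / \sum \langle I\rangle^2, \qquad
#'       K_f^2 = \sum w\, K_{f,window}^2}
#' By default the weights come from the per-source temporal mean image
#' (stable against frame-to-frame noise); `weights = "perframe"` uses each
#' frame's own window intensities instead. Windows with negative corrected
#' contrast are retained (unbiased under zero-mean noise); a frame is marked
#' missing only when no window is valid or the aggregate is non-positive.
#'
#' @param components a [contrast_components()] result.
#' @param ws the matching [window_statistics()].
#' @param weights `"meanimage"` or `"perframe"`.
#' @return data.frame with one row per frame: `time`, `source`, `kf2`,
#'   `intensity` (plain mean of window intensities, ADU).
#' @export
weighted_kf2 <- function(components, ws,
                         weights = c("meanimage", "perframe")) {
  weights <- match.arg(weights)
  nf <- nrow(ws$mean)
  kf2 <- rep(NA_real_, nf)
  intensity <- rep(NA_real_, nf)
  wmat <- if (weights == "meanimage")
    ws$mi_mean[match(ws$source_ids, ws$sources), , drop = FALSE]^2
  else ws$mean^2
  for (i in seq_len(nf)) {
    ok <- components$valid[i, ] & is.finite(wmat[i, ])
    if (!any(ok)) next
    w <- wmat[i, ok] / sum(wmat[i, ok])
    v <- sum(w * components$k_f2_window[i, ok])
    kf2[i] <- if (v > 0) v else NA_real_
    intensity[i] <- mean(ws$mean[i, ok])
  }
  data.frame(time = ws$timestamps, source = ws$source_ids,
             kf2 = kf2, intensity = intensity)
}

#' Split a multiplexed per-frame table into per-source channel series
#'
#' @param kf2_df the data.frame returned by [weighted_kf2()].
#' @param what `"kf2"` or `"intensity"`.
#' @param detector optional detector label used in the channel names
#'   (`"S<s>D<detector>"`).
#' @return a [channel_series()] with one channel per source, sampled at the
#'   full-array rate.
#' @export
per_source_series <- function(kf2_df, what = c("kf2", "intensity"),
                              detector = NULL) {
  what <- match.arg(what)
  srcs <- sort(unique(kf2_df$source))
  rows <- lapply(srcs, function(s) which(kf2_df$source == s))
  nt <- min(lengths(rows))
  v <- vapply(rows, function(r) kf2_df[[what]][r[seq_len(nt)]], numeric(nt))
  tt <- kf2_df$time[rows[[1]][seq_len(nt)]]
  nm <- if (is.null(detector)) paste0("S", srcs)
        else paste0("S", srcs, "D", detector)
  channel_series(tt, v, kind = if (what == "kf2") "kf2" else "intensity",
                 channels = nm)
}

#' Change in optical density
#'
#' \eqn{\Delta OD = -\ln(I / I_0)} per channel, with \eqn{I_0} the mean
#' intensity over the baseline interval (the whole series when `baseline`
#' is NULL, matching the convention of normalizing by the mean intensity
#' over the measurement period).
#'
#' @param series an intensity [channel_series()].
#' @param baseline `c(t0, t1)` seconds, or NULL for the whole series.
#' @return a `delta_od` [channel_series()].
#' @export
delta_od <- function(series, baseline = NULL) {
  stopifnot(series$kind == "intensity")
  i0 <- baseline_mean(series, baseline)
  v <- -log(sweep(series$values, 2, i0, "/"))
  channel_series(series$time, v, kind = "delta_od",
                 channels = series$channels)
}

#' Fractional blood-flow-index change
#'
#' \deqn{rD_B - 1 = \frac{1/K_f^2}{1/K_{f,0}^2} - 1 = \frac{K_{f,0}^2}{K_f^2} - 1}
#' where \eqn{K_{f,0}^2} is the temporal mean of the fundamental contrast
#' over the baseline interval. A doubling of the scatterer diffusion (e.g. a
#' halving of the decorrelation time, in the long-exposure regime) gives
#' +1.0. Samples with non-positive contrast become `NA`.
#'
#' @param series a kf2 [channel_series()].
#' @param baseline `c(t0, t1)` seconds, or NULL for the whole series.
#' @return an `rdb_minus_one` [channel_series()].
#' @export
rdb_minus_one <- function(series, baseline = NULL) {
  stopifnot(series$kind == "kf2")
  vals <- series$values
  vals[vals <= 0] <- NA
  kf0 <- baseline_mean(channel_series(series$time, vals, "kf2",
                                      series$channels), baseline)
  v <- sweep(1 / vals, 2, kf0, "*") - 1
  channel_series(series$time, v, kind = "rdb_minus_one",
                 channels = series$channels)
}

#' Photon-transfer-curve gain and read-noise estimation
#'
#' Fits the camera's variance-versus-mean relation from a ladder of flat
#' illumination levels: after dark subtraction, the per-level temporal
#' variance is linear in the mean signal with slope G (ADU per
#' photoelectron) and intercept equal to the read + quantization noise
#' power in ADU^2. The fit is inverse-variance weighted least squares;
#' levels with more than `max_clip_frac` clipped pixels are excluded
#' automatically.
#'
#' @param stacks list of raw [frame_stack()]s at increasing flux, ideally
#'   >= 8 levels logarithmically spanning the dynamic range.
#' @param dark a [compute_dark_stats()] result.
#' @param max_clip_frac maximum tolerated fraction of clipped pixels per
#'   level (default 0.01).
#' @return list with `gain`, `intercept_adu2`, `read_var_adu2`
#'   (= intercept - 1/12), `levels` (per-level data.frame with `mean`,
#'   `var`, `clip_frac`, `used`).
#' @export
estimate_gain_ptc <- function(stacks, dark, max_clip_frac = 0.01) {
  lev <- lapply(stacks, function(st) {
    sat <- st$camera$saturation
    clip <- mean(apply(st$frames >= sat, c(2, 3), any))
    ds <- subtract_dark(st, dark)
    pm <- apply(ds$frames, c(2, 3), mean)
    pv <- apply(ds$frames, c(2, 3), stats::var)
    c(mean = mean(pm), var = mean(pv), clip_frac = clip)
  })
  lev <- as.data.frame(do.call(rbind, lev))
  lev$used <- lev$clip_frac <= max_clip_frac & lev$mean > 0
  if (sum(lev$used) < 3)
    stop("fewer than 3 usable flux levels; cannot calibrate gain")
  fit <- stats::lm(var ~ mean, data = lev[lev$used, ],
                   weights = 1 / lev$var[lev$used]^2)
  co <- stats::coef(fit)
  list(gain = unname(co[2]), intercept_adu2 = unname(co[1]),
       read_var_adu2 = unname(co[1]) - 1 / 12, levels = lev)
}
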