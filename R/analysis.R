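#' Stimulus block design
#'
#' @param onsets stimulus onsets, seconds, increasing.
#' @param durations stimulus durations, seconds (scalar recycled).
#' @param conditions condition label per block (e.g. congruent /
#'   incongruent).
#' @param epoch_window `c(t0, t1)` seconds relative to onset over which
#'   blocks are epoched (default -2 to 38 s).
#' @return an object of class `block_design`.
#' @export
block_design <- function(onsets, durations, conditions = "task",
                         epoch_window = c(-2, 38)) {
  if (any(diff(onsets) <= 0)) stop("onsets must be increasing")
  n <- length(onsets)
  structure(list(onsets = onsets, durations = rep_len(durations, n),
                 conditions = rep_len(as.character(conditions), n),
                 epoch_window = epoch_window),
            class = "block_design")
}

#' Read / write a block design as 3-column TSV (onset, duration, condition)
#' @param design a [block_design()].
#' @param path TSV path.
#' @param epoch_window epoch window passed to [block_design()] when reading.
#' @return `path` (write) or a [block_design()] (read).
#' @export
write_block_design <- function(design, path) {
  utils::write.table(
    data.frame(onset = design$onsets, duration = design$durations,
               condition = design$conditions),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_block_design
#' @export
read_block_design <- function(path, epoch_window = c(-2, 38)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  block_design(df$onset, df$duration, df$condition, epoch_window)
}

#' Exclude channels with insufficient photon flux
#'
#' At low photon counts the photon-transfer curve turns nonlinear and the
#' contrast correction degrades, so channels whose mean dark-subtracted
#' camera counts fall below a threshold (default 4 ADU) are excluded.
#'
#' @param series an intensity [channel_series()] (one column per
#'   channel-run).
#' @param threshold ADU threshold.
#' @return list with `keep` (logical per channel), `retained_fraction`,
#'   `excluded` (channel names), and a per-channel `report` data.frame.
#' @export
prune_low_flux <- function(series, threshold = 4) {
  stopifnot(series$kind == "intensity")
  m <- colMeans(series$values, na.rm = TRUE)
  keep <- m >= threshold
  list(keep = keep, retained_fraction = mean(keep),
       excluded = series$channels[!keep],
       report = data.frame(channel = series$channels, mean_adu = m,
                           kept = keep))
}

# zero-phase Butterworth helper; NA samples are bridged by linear
# interpolation for filtering and restored afterwards. The series is
# extended by odd-symmetric reflection before filtering so the
# forward-backward pass carries no startup transient into the data.
butter_filtfilt <- function(v, fs, cutoff, order, type) {
  na <- is.na(v)
  if (all(na)) return(v)
  if (any(na)) {
    idx <- seq_along(v)
    v[na] <- stats::approx(idx[!na], v[!na], idx[na], rule = 2)$y
  }
  n <- length(v)
  pad <- min(n - 1, ceiling(15 * fs / cutoff))
  ext <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  out <- signal::filtfilt(bf, ext)[pad + seq_len(n)]
  out[na] <- NA
  out
}

#' Automated motion-artifact block detection
#'
#' Motion artifacts appear as high-amplitude, high-frequency spikes,
#' readily distinguishable from the slower, smaller physiological signals.
#' This automated stand-in for manual block review high-pass filters each
#' channel (> `hp_cutoff` Hz), converts absolute amplitudes to robust z
#' scores (median/MAD), and masks any block in which any channel exceeds
#' `z_threshold`. A manually supplied mask always takes precedence. A
#' subject with more than `max_bad_frac` of blocks masked is flagged for
#' exclusion.
#'
#' @param series a dOD [channel_series()].
#' @param design a [block_design()].
#' @param z_threshold robust z threshold (default 5 MAD).
#' @param hp_cutoff high-pass cutoff in Hz (default 0.5).
#' @param manual_mask optional logical vector (TRUE = block valid) that
#'   overrides detection.
#' @param max_bad_frac subject-exclusion fraction (default 0.5).
#' @return list with `valid` (logical per block), `n_masked`,
#'   `subject_excluded`, and `max_z` per block.
#' @export
detect_motion_blocks <- function(series, design, z_threshold = 5,
                                 hp_cutoff = 0.5, manual_mask = NULL,
                                 max_bad_frac = 0.5) {
  nb <- length(design$onsets)
  if (!is.null(manual_mask)) {
    stopifnot(length(manual_mask) == nb)
    valid <- as.logical(manual_mask)
    return(list(valid = valid, n_masked = sum(!valid),
                subject_excluded = mean(!valid) > max_bad_frac,
                max_z = rep(NA_real_, nb)))
  }
  fs <- series_fs(series)
  z <- apply(series$values, 2, function(v) {
    hp <- butter_filtfilt(v, fs, hp_cutoff, 2, "high")
    s <- stats::mad(hp, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(hp)))
    abs(hp - stats::median(hp, na.rm = TRUE)) / s
  })
  zmax_t <- apply(z, 1, max, na.rm = TRUE)
  max_z <- vapply(seq_len(nb), function(b) {
    sel <- series$time >= design$onsets[b] + design$epoch_window[1] &
           series$time <= design$onsets[b] + design$epoch_window[2]
    if (!any(sel)) return(NA_real_)
    max(zmax_t[sel], na.rm = TRUE)
  }, numeric(1))
  valid <- !is.na(max_z) & max_z <= z_threshold
  list(valid = valid, n_masked = sum(!valid),
       subject_excluded = mean(!valid) > max_bad_frac, max_z = max_z)
}

#' Short-separation regression
#'
#' Removes scalp-dominated physiology by ordinary least squares: for each
#' target channel, the short-separation (~8 mm) signal is regressed out,
#' leaving the residual \eqn{y - \hat a - \hat b\, s}. The residual has
#' exactly zero sample covariance with the regressor. A constant regressor
#' degenerates to mean removal.
#'
#' @param target a [channel_series()] (19 / 33 mm channels).
#' @param short the short-separation signal: a one-channel
#'   [channel_series()] or a numeric vector on the same time axis.
#' @return a [channel_series()] of residuals, same kind as `target`.
#' @export
short_sep_regress <- function(target, short) {
  s <- if (inherits(short, "channel_series")) short$values[, 1] else short
  stopifnot(length(s) == nrow(target$values))
  out <- target$values
  for (k in seq_len(ncol(out))) {
    y <- out[, k]
    ok <- is.finite(y) & is.finite(s)
    if (sum(ok) < 3) next
    if (stats::var(s[ok]) == 0) {
      out[ok, k] <- y[ok] - mean(y[ok])
    } else {
      b <- stats::cov(s[ok], y[ok]) / stats::var(s[ok])
      a <- mean(y[ok]) - b * mean(s[ok])
      out[ok, k] <- y[ok] - a - b * s[ok]
    }
  }
  channel_series(target$time, out, kind = target$kind,
                 channels = target$channels)
}

#' Common-mode removal by principal components within source groups
#'
#' For channels sharing one source optode, fluctuations extraneous to the
#' medium (laser/coupling drifts) load nearly equally on every channel.
#' Principal components of the time x channel matrix whose loading
#' coefficients have a coefficient of variation across channels below
#' `cv_threshold` (default 1) are projected out of every channel in the
#' group. Channel-specific components have sign-mixed, high-CV loadings and
#' are untouched; single-channel groups are a no-op.
#'
#' @param series a [channel_series()].
#' @param groups list of channel-index (or name) vectors, one per source
#'   group.
#' @param cv_threshold CV threshold below which a component counts as
#'   common mode.
#' @return a cleaned [channel_series()].
#' @export
pca_common_mode_regress <- function(series, groups, cv_threshold = 1) {
  vals <- series$values
  for (g in groups) {
    if (is.character(g)) g <- match(g, series$channels)
    if (length(g) < 2) next
    X <- vals[, g, drop = FALSE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc)
    for (k in seq_along(sv$d)) {
      ld <- sv$v[, k]
      m <- mean(ld)
      cv <- if (abs(m) < .Machine$double.eps) Inf else stats::sd(ld) / abs(m)
      if (cv < cv_threshold)
        Xc <- Xc - sv$u[, k, drop = FALSE] %*%
          (sv$d[k] * t(sv$v[, k, drop = FALSE]))
    }
    vals[, g] <- sweep(Xc, 2, mu, "+")
  }
  channel_series(series$time, vals, kind = series$kind,
                 channels = series$channels)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fifth-order (by default) Butterworth low-pass applied forward and
#' backward (zero phase, so block-average timing is preserved), cutoff
#' 0.2 Hz — the hemodynamic band.
#'
#' @param series a [channel_series()].
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return a filtered [channel_series()].
#' @export
lowpass <- function(series, cutoff = 0.2, order = 5) {
  fs <- series_fs(series)
  if (cutoff >= fs / 2) stop("cutoff at or above Nyquist")
  v <- apply(series$values, 2, butter_filtfilt, fs = fs, cutoff = cutoff,
             order = order, type = "low")
  channel_series(series$time, v, kind = series$kind,
                 channels = series$channels)
}

#' Block averaging
#'
#' Extracts one epoch per stimulus onset over the design's epoch window
#' (default -2 to 38 s relative to onset), shifts each epoch by its own
#' pre-stimulus baseline mean (default the -2..0 s interval), drops masked
#' blocks, and averages the valid blocks of each condition.
#'
#' @param series a [channel_series()].
#' @param design a [block_design()].
#' @param valid logical per block (e.g. from [detect_motion_blocks()]);
#'   NULL keeps all.
#' @param baseline `c(t0, t1)` seconds relative to onset.
#' @return an object of class `epoched_data`: `time` (relative seconds),
#'   `data` (time x block x channel array), `condition` and `valid` per
#'   block, `channels`, plus `average` — a list per condition of
#'   time x channel matrices averaged over valid blocks — and
#'   `n_valid` per condition.
#' @export
block_average <- function(series, design, valid = NULL,
                          baseline = c(-2, 0)) {
  fs <- series_fs(series)
  nb <- length(design$onsets)
  if (is.null(valid)) valid <- rep(TRUE, nb)
  rel_idx <- seq(ceiling(design$epoch_window[1] * fs),
                 floor(design$epoch_window[2] * fs))
  rel_t <- rel_idx / fs
  nch <- ncol(series$values)
  dat <- array(NA_real_, c(length(rel_idx), nb, nch))
  for (b in seq_len(nb)) {
    i0 <- which.min(abs(series$time - design$onsets[b]))
    idx <- i0 + rel_idx
    if (idx[1] < 1 || idx[length(idx)] > length(series$time)) {
      valid[b] <- FALSE
      next
    }
    ep <- series$values[idx, , drop = FALSE]
    bl <- rel_t >= baseline[1] & rel_t <= baseline[2]
    ep <- sweep(ep, 2, colMeans(ep[bl, , drop = FALSE], na.rm = TRUE))
    dat[, b, ] <- ep
  }
  conds <- unique(design$conditions)
  avg <- lapply(conds, function(cc) {
    sel <- which(design$conditions == cc & valid)
    if (!length(sel)) return(matrix(NA_real_, length(rel_t), nch))
    apply(dat[, sel, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
  })
  names(avg) <- conds
  n_valid <- vapply(conds, function(cc)
    sum(design$conditions == cc & valid), integer(1))
  structure(list(time = rel_t, data = dat, condition = design$conditions,
                 valid = valid, channels = series$channels, average = avg,
                 n_valid = n_valid),
            class = "epoched_data")
}

#' Group-level statistics across subjects
#'
#' Combines per-subject block-averaged time courses into a group mean
#' weighted by each subject's number of valid blocks, with the standard
#' error taken across subjects. A channel is flagged significant when its
#' mean activation over the `window` interval (default 10-15 s after
#' onset) exceeds 1.96 times the standard error (95% confidence); a
#' two-tailed one-sample t-test p-value over subjects is reported as well.
#'
#' The weighted standard error is
#' \eqn{\sqrt{\tfrac{n}{n-1}\sum_i w_i^2 (x_i - \bar x_w)^2}}, which
#' reduces exactly to \eqn{sd/\sqrt{n}} under equal weights, so the 1.96
#' flag then coincides with the classic t-statistic threshold.
#'
#' @param subject_means array subjects x time x channels of block-averaged
#'   responses (one condition).
#' @param n_valid_blocks valid-block count per subject (the weights).
#' @param time epoch time axis, seconds relative to onset.
#' @param window `c(t0, t1)` activation window, seconds.
#' @param z significance multiple of the standard error (1.96 = 95%).
#' @return list with `mean` and `se` time courses (time x channel), and a
#'   per-channel data.frame `table` (`window_mean`, `se`, `t`, `p`,
#'   `significant`), plus `weights`.
#' @export
group_stats <- function(subject_means, n_valid_blocks, time,
                        window = c(10, 15), z = 1.96) {
  ns <- dim(subject_means)[1]
  stopifnot(length(n_valid_blocks) == ns, dim(subject_means)[2] == length(time))
  w <- n_valid_blocks / sum(n_valid_blocks)
  gm <- apply(subject_means * w, c(2, 3), sum)
  dev <- sweep(subject_means, c(2, 3), gm)
  gse <- sqrt(ns / (ns - 1) * apply(dev^2 * w^2, c(2, 3), sum))
  win <- time >= window[1] & time <= window[2]
  xw <- apply(subject_means[, win, , drop = FALSE], c(1, 3), mean)  # subj x ch
  m <- colSums(xw * w)
  se <- sqrt(ns / (ns - 1) * colSums(sweep(xw, 2, m)^2 * w^2))
  tstat <- m / se
  p <- 2 * stats::pt(-abs(tstat), df = ns - 1)
  nch <- dim(subject_means)[3]
  ch <- dimnames(subject_means)[[3]]
  if (is.null(ch)) ch <- paste0("ch", seq_len(nch))
  list(mean = gm, se = gse, weights = w,
       table = data.frame(channel = ch, window_mean = m, se = se,
                          t = tstat, p = p, significant = m > z * se))
}
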