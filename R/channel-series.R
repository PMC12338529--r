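#' Channel time-series container
#'
#' Per-channel time courses at the full-array rate. `values` is a
#' time x channel matrix; `kind` records what the values are: `"kf2"`
#' (fundamental contrast squared), `"intensity"` (mean dark-subtracted ADU),
#' `"delta_od"` (change in optical density, natural-log units) or
#' `"rdb_minus_one"` (fractional blood-flow-index change). Missing samples
#' are `NA`.
#'
#' @param time sample times, seconds, uniformly spaced.
#' @param values numeric matrix, time x channel (a vector is treated as one
#'   channel).
#' @param kind one of `"kf2"`, `"intensity"`, `"delta_od"`,
#'   `"rdb_minus_one"`.
#' @param channels optional channel names.
#' @return an object of class `channel_series`.
#' @export
channel_series <- function(time, values,
                           kind = c("kf2", "intensity", "delta_od",
                                    "rdb_minus_one"),
                           channels = NULL) {
  kind <- match.arg(kind)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  stopifnot(nrow(values) == length(time))
  if (length(time) > 2) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("time axis must be uniformly spaced")
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  colnames(values) <- channels
  structure(list(time = as.numeric(time), values = values, kind = kind,
                 channels = channels),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> kind '%s': %d samples x %d channels at %.4g Hz\n",
              x$kind, nrow(x$values), ncol(x$values), series_fs(x)))
  invisible(x)
}

#' Sampling rate of a channel series
#' @param series a [channel_series()].
#' @return rate in Hz.
#' @export
series_fs <- function(series) {
  if (length(series$time) < 2) return(NA_real_)
  1 / mean(diff(series$time))
}

# mean over a [t0, t1] interval per channel (NULL interval = whole series)
baseline_mean <- function(series, baseline = NULL) {
  sel <- if (is.null(baseline)) rep(TRUE, length(series$time))
         else series$time >= baseline[1] & series$time <= baseline[2]
  if (!any(sel)) stop("baseline interval contains no samples")
  colMeans(series$values[sel, , drop = FALSE], na.rm = TRUE)
}

#' Write / read a channel series as tidy CSV
#'
#' Long format: `time, channel, kind, value`.
#'
#' @param series a [channel_series()].
#' @param path CSV path.
#' @return `path` (write) or a [channel_series()] (read).
#' @export
write_channel_series <- function(series, path) {
  df <- data.frame(time = rep(series$time, ncol(series$values)),
                   channel = rep(series$channels, each = nrow(series$values)),
                   kind = series$kind, value = as.vector(series$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_channel_series
#' @export
read_channel_series <- function(path) {
  df <- utils::read.csv(path)
  chans <- unique(df$channel)
  tt <- sort(unique(df$time))
  v <- matrix(NA_real_, length(tt), length(chans))
  for (k in seq_along(chans)) {
    sub <- df[df$channel == chans[k], ]
    v[match(sub$time, tt), k] <- sub$value
  }
  channel_series(tt, v, kind = df$kind[1], channels = as.character(chans))
}
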