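# window grid helpers: pixels beyond the largest window-divisible region are
# discarded (partial windows would carry different noise statistics)
win_grid <- function(rows, cols, w) {
  nwr <- rows %/% w; nwc <- cols %/% w
  if (nwr < 1 || nwc < 1) stop("sensor smaller than one window")
  idx <- matrix(0L, nwr * w, nwc * w)
  for (c in seq_len(nwc * w))
    idx[, c] <- (seq_len(nwr * w) - 1L) %/% w + ((c - 1L) %/% w) * nwr + 1L
  list(nwr = nwr, nwc = nwc, n_win = nwr * nwc, id = as.vector(idx))
}

# frames [nf x rows x cols] -> pixel matrix [n_trunc_px x nf]
px_matrix <- function(frames, g, w) {
  nf <- dim(frames)[1]
  sub <- frames[, seq_len(g$nwr * w), seq_len(g$nwc * w), drop = FALSE]
  matrix(aperm(sub, c(2, 3, 1)), ncol = nf)
}

#' Repair missed frames against the nominal schedule grid
#'
#' Uses the timestamps to detect frames the camera dropped: each recorded
#' frame is snapped to its nominal slot on the `1/camera_rate_hz` grid and
#' empty slots are filled with all-`NA` marker frames (never interpolated).
#' Source indices are re-synchronized to the schedule cycle so every slot is
#' attributed to the source that was actually illuminated. The operation is
#' idempotent.
#'
#' @param stack a [frame_stack()].
#' @param schedule the [multiplex_schedule()] the stack was acquired under.
#' @return a repaired [frame_stack()] with attribute `repair_report`, a list
#'   with `inserted_slots` (1-based slot indices) and `n_inserted`.
#'   More than 10% missing frames is a hard error.
#' @export
repair_frames <- function(stack, schedule) {
  dt <- 1 / schedule$camera_rate_hz
  tt <- stack$timestamps
  if (any(diff(tt) <= 0)) stop("timestamps are not strictly increasing")
  slot <- round((tt - tt[1]) / dt)
  if (anyDuplicated(slot)) stop("two frames map to the same schedule slot")
  n_slot <- slot[length(slot)] + 1
  missing <- setdiff(seq_len(n_slot) - 1, slot)
  if (length(missing) / n_slot > 0.1)
    stop(sprintf("%.1f%% of frames missing; stack unusable",
                 100 * length(missing) / n_slot))
  d <- dim(stack$frames)
  frames <- array(NA_real_, c(n_slot, d[2], d[3]))
  frames[slot + 1, , ] <- stack$frames
  s0 <- stack$source_ids[1]
  ns <- schedule$n_sources
  src <- ((s0 - 1 + seq_len(n_slot) - 1) %% ns) + 1
  out <- frame_stack(frames, tt[1] + (seq_len(n_slot) - 1) * dt, src,
                     stack$exposure_s, stack$camera,
                     dark_subtracted = stack$dark_subtracted,
                     saturated = stack$saturated)
  attr(out, "repair_report") <- list(inserted_slots = missing + 1,
                                     n_inserted = length(missing))
  out
}

#' Dark statistics
#'
#' Reduces a dark stack (laser off) to the two quantities the corrections
#' need: the per-pixel temporal mean image (subtracted from every signal
#' frame) and the per-window spatial mean of the per-pixel temporal
#' variance, which carries the read + quantization noise power in ADU^2.
#'
#' @param dark_stack a [frame_stack()] of dark frames.
#' @param window window edge length in pixels (default 7).
#' @return an object of class `dark_stats` with fields `mean_dark` (matrix),
#'   `windowed_dark_tvar` (vector, one per window), `window_size`, `grid`.
#' @export
compute_dark_stats <- function(dark_stack, window = 7) {
  d <- dim(dark_stack$frames)
  g <- win_grid(d[2], d[3], window)
  mean_dark <- apply(dark_stack$frames, c(2, 3), mean)
  tvar <- apply(dark_stack$frames, c(2, 3), stats::var)
  tv <- as.vector(tvar[seq_len(g$nwr * window), seq_len(g$nwc * window)])
  wtv <- as.vector(rowsum(tv, g$id)) / window^2
  structure(list(mean_dark = mean_dark, windowed_dark_tvar = wtv,
                 window_size = window, grid = g[c("nwr", "nwc", "n_win")]),
            class = "dark_stats")
}

#' Subtract the temporal mean dark image from every frame
#'
#' @param stack a raw [frame_stack()].
#' @param dark a [compute_dark_stats()] result (its `mean_dark` must match
#'   the stack's frame shape).
#' @return a signed, dark-subtracted [frame_stack()].
#' @export
subtract_dark <- function(stack, dark) {
  d <- dim(stack$frames)
  if (!all(dim(dark$mean_dark) == d[2:3]))
    stop("dark image shape does not match the stack")
  frames <- stack$frames -
    aperm(array(dark$mean_dark, c(d[2], d[3], d[1])), c(3, 1, 2))
  out <- stack
  out$frames <- frames
  out$dark_subtracted <- TRUE
  out
}

#' Windowed spatial statistics
#'
#' The reduced representation all downstream contrast math consumes: per
#' frame and per window (default 7 x 7 pixels), the spatial mean and the
#' unbiased (n-1) spatial variance over the window's pixels. Edge pixels
#' beyond the largest window-divisible region are discarded. Per-source
#' temporal-mean-image window statistics (needed by the spatial
#' heterogeneity correction) are computed alongside. Storing 2 values per
#' 49-pixel window reduces the data volume 24.5-fold.
#'
#' Marker (all-`NA`) frames propagate as `NA` rows.
#'
#' @param stack a (normally dark-subtracted) [frame_stack()].
#' @param window window edge length in pixels.
#' @return an object of class `window_stats`: matrices `mean` and `var`
#'   (frames x windows), `timestamps`, `source_ids`, `window_size`, `grid`,
#'   `sources`, and mean-image statistics `mi_mean` / `mi_var`
#'   (sources x windows).
#' @export
window_statistics <- function(stack, window = 7) {
  d <- dim(stack$frames)
  g <- win_grid(d[2], d[3], window)
  P <- px_matrix(stack$frames, g, window)
  n <- window^2
  s1 <- rowsum(P, g$id)                      # n_win x nf
  s2 <- rowsum(P^2, g$id)
  m <- t(s1) / n
  v <- t((s2 - s1^2 / n) / (n - 1))
  dimnames(m) <- dimnames(v) <- NULL
  bi <- per_source_baseline_images(stack, window)
  structure(list(mean = m, var = v, timestamps = stack$timestamps,
                 source_ids = stack$source_ids, window_size = window,
                 grid = g[c("nwr", "nwc", "n_win")], sources = bi$sources,
                 mi_mean = bi$mi_mean, mi_var = bi$mi_var,
                 exposure_s = stack$exposure_s, camera = stack$camera),
            class = "window_stats")
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("<window_stats> %d frames x %d windows (%dx%d px), %d source(s)\n",
              nrow(x$mean), ncol(x$mean), x$window_size, x$window_size,
              length(x$sources)))
  invisible(x)
}

#' Per-source baseline (temporal mean) images and their window statistics
#'
#' For each source index present in the stack, averages all its (non-marker)
#' frames into a temporal mean image, and computes the per-window spatial
#' mean and unbiased variance of that image — the ingredients of the spatial
#' heterogeneity contrast term.
#'
#' @param stack a (normally dark-subtracted) [frame_stack()].
#' @param window window edge length in pixels.
#' @return list with `sources`, `images` (one truncated-region matrix per
#'   source), `mi_mean` and `mi_var` (sources x windows).
#' @export
per_source_baseline_images <- function(stack, window = 7) {
  d <- dim(stack$frames)
  g <- win_grid(d[2], d[3], window)
  P <- px_matrix(stack$frames, g, window)
  srcs <- sort(unique(stack$source_ids))
  n <- window^2
  images <- vector("list", length(srcs))
  mi_mean <- matrix(NA_real_, length(srcs), g$n_win)
  mi_var <- matrix(NA_real_, length(srcs), g$n_win)
  for (k in seq_along(srcs)) {
    cols <- which(stack$source_ids == srcs[k])
    mi <- rowMeans(P[, cols, drop = FALSE], na.rm = TRUE)
    images[[k]] <- matrix(mi, g$nwr * window, g$nwc * window)
    s1 <- as.vector(rowsum(mi, g$id))
    s2 <- as.vector(rowsum(mi^2, g$id))
    mi_mean[k, ] <- s1 / n
    mi_var[k, ] <- (s2 - s1^2 / n) / (n - 1)
  }
  list(sources = srcs, images = images, mi_mean = mi_mean, mi_var = mi_var)
}

#' Data reduction factor of the windowed representation
#'
#' Raw pixels per window divided by stored values per window (mean and
#' variance): `window^2 / 2`, i.e. 24.5-fold for 7 x 7 windows.
#'
#' @param window window edge length in pixels.
#' @return the reduction factor.
#' @export
reduction_factor <- function(window = 7) window^2 / 2

#' Persist / load window statistics as TSV
#'
#' Long-format table (frame, window, timestamp, source, mean, var) plus a
#' JSON sidecar with the grid and acquisition metadata.
#'
#' @param ws a [window_statistics()] result.
#' @param path TSV path.
#' @return `path` (write) or a `window_stats` (read).
#' @export
write_window_stats <- function(ws, path) {
  nf <- nrow(ws$mean); nw <- ncol(ws$mean)
  df <- data.frame(frame = rep(seq_len(nf), nw),
                   window = rep(seq_len(nw), each = nf),
                   mean = as.vector(ws$mean), var = as.vector(ws$var))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(timestamps = ws$timestamps, source_ids = ws$source_ids,
               window_size = ws$window_size, grid = ws$grid,
               sources = ws$sources, mi_mean = ws$mi_mean,
               mi_var = ws$mi_var, exposure_s = ws$exposure_s,
               camera = unclass(ws$camera))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nf <- max(df$frame); nw <- max(df$window)
  structure(list(mean = matrix(df$mean, nf, nw),
                 var = matrix(df$var, nf, nw),
                 timestamps = meta$timestamps,
                 source_ids = as.integer(meta$source_ids),
                 window_size = meta$window_size,
                 grid = as.list(meta$grid), sources = meta$sources,
                 mi_mean = matrix(meta$mi_mean, nrow = length(meta$sources)),
                 mi_var = matrix(meta$mi_var, nrow = length(meta$sources)),
                 exposure_s = meta$exposure_s,
                 camera = do.call(camera_spec,
                   meta$camera[c("gain", "black_level", "bit_depth",
                                 "read_noise_e", "saturation")])),
            class = "window_stats")
}
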