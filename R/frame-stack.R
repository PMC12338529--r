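#' Frame stack container
#'
#' A stack of camera frames in ADU with acquisition metadata: per-frame
#' timestamps, the source index illuminated during each frame, the exposure
#' time, and the camera specification. Frames are stored as a 3-D array
#' (frame x row x column). Raw stacks are integer-valued in
#' `[0, 2^bit_depth - 1]`; dark-subtracted stacks are signed and flagged via
#' the `dark_subtracted` attribute. A frame whose values are all `NA` marks a
#' slot where the camera dropped a frame (see [repair_frames()]).
#'
#' @param frames 3-D numeric array, frame x row x column, in ADU.
#' @param timestamps seconds per frame, strictly increasing.
#' @param source_ids integer source index per frame.
#' @param exposure_s exposure time in seconds.
#' @param camera a [camera_spec()].
#' @param dark_subtracted logical; signed values allowed when TRUE.
#' @param saturated logical flag set by the simulator when the commanded flux
#'   drove the mean signal beyond full scale.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps, source_ids, exposure_s, camera,
                        dark_subtracted = FALSE, saturated = FALSE) {
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[1]
  if (length(timestamps) != n || length(source_ids) != n)
    stop("timestamps and source_ids must have one entry per frame")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!dark_subtracted) {
    v <- frames[!is.na(frames)]
    if (length(v) && (min(v) < 0 || max(v) > 2^camera$bit_depth - 1))
      stop("raw frames must lie within [0, 2^bit_depth - 1]")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 source_ids = as.integer(source_ids),
                 exposure_s = exposure_s, camera = camera,
                 dark_subtracted = isTRUE(dark_subtracted),
                 saturated = isTRUE(saturated)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %d source(s), exposure %.3g ms%s%s\n",
    d[1], d[2], d[3], length(unique(x$source_ids)), 1000 * x$exposure_s,
    if (x$dark_subtracted) ", dark-subtracted" else "",
    if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[1]

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Frames go into a 16-bit multi-page TIFF; timestamps, source indices,
#' exposure and the camera specification go into `<path>.json`. Dropped
#' frames (all-NA) are stored as zero pages and recorded in the sidecar.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  if (stack$dark_subtracted)
    stop("only raw (non-negative) stacks can be written to TIFF")
  miss <- apply(is.na(stack$frames), 1, all)
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    m <- stack$frames[i, , ]
    m[is.na(m)] <- 0
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- list(timestamps = stack$timestamps, source_ids = stack$source_ids,
               exposure_s = stack$exposure_s,
               camera = unclass(stack$camera),
               missing_frames = which(miss),
               saturated = stack$saturated)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 65535)
  if (length(side$missing_frames)) frames[side$missing_frames, , ] <- NA
  cam <- do.call(camera_spec, side$camera[c("gain", "black_level", "bit_depth",
                                            "read_noise_e", "saturation")])
  frame_stack(frames, side$timestamps, side$source_ids, side$exposure_s, cam,
              saturated = isTRUE(side$saturated))
}
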