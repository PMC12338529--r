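#' Camera specification
#'
#' Photometric model of the detection camera: conversion gain in ADU per
#' photoelectron, black-level offset, bit depth, and RMS read noise in
#' electrons. The defaults describe a 10-bit CMOS sensor with a black level
#' of 25 ADU and 2.1 e- read noise, with a conversion gain of 0.5 ADU/e-.
#'
#' @param gain conversion gain G, ADU per photoelectron (> 0).
#' @param black_level black-level offset in ADU (>= 0).
#' @param bit_depth one of 8, 10, 12, 16.
#' @param read_noise_e RMS read noise in electrons (scalar, >= 0).
#' @param saturation full-scale ADU; defaults to `2^bit_depth - 1`.
#' @return an object of class `camera_spec`.
#' @export
#' @examples
#' camera_spec() # the default 10-bit instrument camera
camera_spec <- function(gain = 0.5, black_level = 25, bit_depth = 10,
                        read_noise_e = 2.1, saturation = NULL) {
  stopifnot(gain > 0, black_level >= 0, read_noise_e >= 0)
  if (!bit_depth %in% c(8L, 10L, 12L, 16L))
    stop("`bit_depth` must be one of 8, 10, 12, 16")
  if (is.null(saturation)) saturation <- 2^bit_depth - 1
  structure(list(gain = gain, black_level = black_level,
                 bit_depth = as.integer(bit_depth),
                 read_noise_e = read_noise_e, saturation = saturation),
            class = "camera_spec")
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf(
    "<camera_spec> %d-bit, gain %.3g ADU/e-, black level %.3g ADU, read noise %.3g e-, saturation %g ADU\n",
    x$bit_depth, x$gain, x$black_level, x$read_noise_e, x$saturation))
  invisible(x)
}

#' Temporal multiplexing schedule
#'
#' One laser is steered sequentially across `n_sources` fiber positions; each
#' source owns one camera-frame slot, is illuminated for `on_ms` within its
#' slot, and the camera exposes for `exposure_ms` inside the illuminated
#' interval. The defaults reproduce the instrument schedule: 7 sources, 10 ms
#' slots, 5.2 ms illumination, 100 Hz camera, so each source repeats every
#' 70 ms.
#'
#' @param n_sources number of multiplexed source positions.
#' @param slot_ms milliseconds per source slot.
#' @param on_ms illumination milliseconds within a slot (<= slot_ms).
#' @param exposure_ms camera exposure milliseconds (<= on_ms).
#' @param camera_rate_hz per-frame camera rate; defaults to `1000 / slot_ms`.
#' @return an object of class `multiplex_schedule`.
#' @export
multiplex_schedule <- function(n_sources = 7, slot_ms = 10, on_ms = 5.2,
                               exposure_ms = 4, camera_rate_hz = NULL) {
  stopifnot(n_sources >= 1, slot_ms > 0)
  if (on_ms > slot_ms) stop("`on_ms` must not exceed `slot_ms`")
  if (exposure_ms > on_ms) stop("`exposure_ms` must not exceed `on_ms`")
  if (is.null(camera_rate_hz)) camera_rate_hz <- 1000 / slot_ms
  structure(list(n_sources = as.integer(n_sources), slot_ms = slot_ms,
                 on_ms = on_ms, exposure_ms = exposure_ms,
                 camera_rate_hz = camera_rate_hz),
            class = "multiplex_schedule")
}

#' Per-source duty cycle of a multiplexing schedule
#'
#' Fraction of time each source is illuminated: `on_ms / (n_sources *
#' slot_ms)`. For the instrument schedule this is 5.2 / 70 = 7.4%.
#'
#' @param schedule a [multiplex_schedule()].
#' @return duty cycle as a fraction in (0, 1].
#' @export
duty_cycle <- function(schedule) {
  schedule$on_ms / (schedule$n_sources * schedule$slot_ms)
}

#' Full-array sampling rate
#'
#' Rate at which the complete source set is cycled:
#' `camera_rate_hz / n_sources`. 100 Hz over 7 sources gives 14.3 Hz.
#'
#' @param schedule a [multiplex_schedule()].
#' @return rate in Hz.
#' @export
full_array_rate <- function(schedule) {
  schedule$camera_rate_hz / schedule$n_sources
}

#' Time-averaged source power under a multiplexing schedule
#'
#' Peak power delivered during the illuminated interval times the duty
#' cycle; used to confirm that pulsed multiplexing keeps the average skin
#' exposure low (270 mW peak at a 7.4% duty cycle averages to ~20 mW).
#'
#' @param peak_mw peak optical power in mW.
#' @param schedule a [multiplex_schedule()].
#' @return average power in mW.
#' @export
average_power <- function(peak_mw, schedule) {
  peak_mw * duty_cycle(schedule)
}

#' @export
print.multiplex_schedule <- function(x, ...) {
  cat(sprintf(
    "<multiplex_schedule> %d sources, %.3g ms slots (%.3g ms on, %.3g ms exposure), camera %.4g Hz, full array %.4g Hz, duty cycle %.2f%%\n",
    x$n_sources, x$slot_ms, x$on_ms, x$exposure_ms, x$camera_rate_hz,
    full_array_rate(x), 100 * duty_cycle(x)))
  invisible(x)
}
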