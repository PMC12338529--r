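#' Simulation scenario
#'
#' Describes a synthetic measurement: the per-source speckle ground truth,
#' optional multiplicative modulations of the decorrelation time (flow; what
#' rDB-1 should recover) and of the photon flux (absorption; what dOD should
#' recover), which sources the modulations apply to, an optional block
#' design, the speckle generation method, and the seed that fully determines
#' the output.
#'
#' Two speckle generators are available. `"gamma"` draws per-pixel
#' intensities from a Gamma law whose relative variance equals
#' [expected_contrast()] exactly; it is fast and is the default. `"field"`
#' synthesizes two polarization speckle fields as first-order autoregressive
#' complex Gaussian processes integrated over the exposure in sub-steps, and
#' is the physical gold standard used by the recovery tests. Both must agree
#' on the corrected contrast within Monte Carlo error.
#'
#' @param truth a [speckle_truth()], or a list of one per source.
#' @param flow_timecourse function of time (s) returning a positive
#'   multiplicative factor applied to tau_c; NULL means constant 1.
#' @param absorption_timecourse function of time (s) returning a positive
#'   multiplicative factor applied to the mean flux; NULL means constant 1.
#' @param active_sources integer vector of sources the modulations apply to;
#'   NULL means all.
#' @param block_design optional [block_design()] carried along for analysis.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param method `"gamma"` or `"field"`.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(truth, flow_timecourse = NULL,
                         absorption_timecourse = NULL, active_sources = NULL,
                         block_design = NULL, seed = 1,
                         method = c("gamma", "field")) {
  method <- match.arg(method)
  if (inherits(truth, "speckle_truth")) truth <- list(truth)
  stopifnot(all(vapply(truth, inherits, logical(1), "speckle_truth")))
  structure(list(truth = truth, flow_timecourse = flow_timecourse,
                 absorption_timecourse = absorption_timecourse,
                 active_sources = active_sources, block_design = block_design,
                 seed = as.integer(seed), method = method),
            class = "sim_scenario")
}

# number of exposure sub-steps for which the discrete AR(1) intensity sum
# matches the continuous single-exponential contrast model to < 0.1%
n_substeps <- function(x, rtol = 1e-3) {
  h <- (exp(-2 * x) - 1 + 2 * x) / (2 * x^2)
  for (n in c(20L, 40L, 80L, 160L, 320L, 640L)) {
    q <- exp(-2 * x / n)
    d <- seq_len(n - 1)
    k2d <- (n + 2 * sum((n - d) * q^d)) / n^2
    if (abs(k2d - h) / h < rtol) return(n)
  }
  640L
}

# one frame of normalized speckle intensity (mean 1, relative spatial
# variance expected_contrast(beta, x)); field method: two AR(1) complex
# polarization components mixed with a static background so arbitrary
# beta < 0.5 is reached exactly
field_speckle <- function(npx, beta, sp_ratio, x) {
  r <- sp_ratio^2
  p <- c(r, 1) / (1 + r)             # component powers, sum 1
  k20 <- sum(p^2)
  a <- sqrt(beta / k20)
  ints <- matrix(0, npx, 2)
  if (x <= 0) {
    for (c in 1:2) {
      e <- complex(real = stats::rnorm(npx), imaginary = stats::rnorm(npx)) /
        sqrt(2)
      ints[, c] <- p[c] * Mod(e)^2
    }
  } else {
    n <- n_substeps(x)
    rho <- exp(-x / n)
    sig <- sqrt(1 - rho^2)
    for (c in 1:2) {
      e <- complex(real = stats::rnorm(npx), imaginary = stats::rnorm(npx)) /
        sqrt(2)
      acc <- Mod(e)^2
      for (k in seq_len(n - 1)) {
        e <- rho * e + sig *
          complex(real = stats::rnorm(npx), imaginary = stats::rnorm(npx)) /
          sqrt(2)
        acc <- acc + Mod(e)^2
      }
      ints[, c] <- p[c] * acc / n
    }
  }
  a * (ints[, 1] + ints[, 2]) + (1 - a)
}

gamma_speckle <- function(npx, k2) {
  if (k2 <= 0) return(rep(1, npx))
  stats::rgamma(npx, shape = 1 / k2, rate = 1 / k2)
}

#' Simulate a multiplexed speckle frame stack
#'
#' Generates raw camera frames for a scenario under a multiplexing schedule:
#' per frame, the active source's speckle pattern (with contrast set by beta
#' and the exposure-to-decorrelation-time ratio, optionally modulated in
#' time) scales the mean photoelectron flux and the illumination
#' heterogeneity map; photoelectrons are drawn as Poisson counts, converted
#' to ADU through the camera gain, offset by the black level, perturbed by
#' Gaussian read noise, rounded to integers and clipped to the bit depth.
#'
#' The scenario seed drives two separate random streams, one for the speckle
#' fields and one for the detection noise, so two runs with the same seed
#' but different flux share identical field dynamics.
#'
#' @param scenario a [sim_scenario()].
#' @param schedule a [multiplex_schedule()].
#' @param camera a [camera_spec()].
#' @param shape `c(rows, cols)` sensor size in pixels.
#' @param duration seconds of acquisition.
#' @return a [frame_stack()]; its `saturated` flag is set (with a warning)
#'   when the commanded mean signal exceeds full scale.
#' @export
simulate_frames <- function(scenario, schedule = multiplex_schedule(),
                            camera = camera_spec(), shape = c(28, 28),
                            duration = 10) {
  rows <- shape[1]; cols <- shape[2]; npx <- rows * cols
  ns <- schedule$n_sources
  truth <- scenario$truth
  if (length(truth) == 1) truth <- rep(truth, ns)
  if (length(truth) != ns)
    stop("scenario truth must have 1 or n_sources entries")
  nf <- floor(duration * schedule$camera_rate_hz)
  tt <- (seq_len(nf) - 1) / schedule$camera_rate_hz
  src <- rep_len(seq_len(ns), nf)
  expo <- schedule$exposure_ms / 1000
  fmod <- scenario$flow_timecourse
  amod <- scenario$absorption_timecourse
  act <- scenario$active_sources
  if (is.null(act)) act <- seq_len(ns)

  het <- lapply(truth, function(tr) {
    if (is.null(tr$heterogeneity)) rep(1, npx)
    else {
      if (!all(dim(tr$heterogeneity) == c(rows, cols)))
        stop("heterogeneity map does not match the sensor shape")
      as.vector(tr$heterogeneity)
    }
  })

  # pass 1: speckle fields (own stream, flux-independent)
  set.seed(scenario$seed)
  sf <- matrix(0, nf, npx)
  frozen <- vector("list", ns)
  for (i in seq_len(nf)) {
    s <- src[i]; tr <- truth[[s]]
    f <- if (s %in% act && !is.null(fmod)) fmod(tt[i]) else 1
    if (any(f <= 0)) stop("flow modulation must be positive")
    tau <- tr$tau_c * f
    x <- if (is.finite(tau)) expo / tau else 0
    if (x == 0) {                      # static scene: frozen pattern
      if (is.null(frozen[[s]]))
        frozen[[s]] <- if (scenario$method == "field")
          field_speckle(npx, tr$beta, tr$sp_ratio, 0)
        else gamma_speckle(npx, tr$beta)
      sf[i, ] <- frozen[[s]]
    } else if (scenario$method == "field") {
      sf[i, ] <- field_speckle(npx, tr$beta, tr$sp_ratio, x)
    } else {
      sf[i, ] <- gamma_speckle(npx, expected_contrast(tr$beta, x))
    }
  }

  # pass 2: detection noise
  set.seed(scenario$seed + 1L)
  frames <- array(0, c(nf, rows, cols))
  sat_hit <- FALSE
  g <- camera$gain; bl <- camera$black_level
  rn_adu <- camera$read_noise_e * g
  for (i in seq_len(nf)) {
    s <- src[i]; tr <- truth[[s]]
    a <- if (s %in% act && !is.null(amod)) amod(tt[i]) else 1
    if (any(a <= 0)) stop("absorption modulation must be positive")
    lam <- tr$mean_flux * a * het[[s]] * sf[i, ]
    adu <- g * stats::rpois(npx, lam) + bl
    if (rn_adu > 0) adu <- adu + stats::rnorm(npx, sd = rn_adu)
    if (bl + g * tr$mean_flux * a > camera$saturation) sat_hit <- TRUE
    adu <- pmin(pmax(round(adu), 0), camera$saturation)
    frames[i, , ] <- adu
  }
  if (sat_hit)
    warning("commanded mean signal exceeds camera full scale; stack flagged saturated")
  frame_stack(frames, tt, src, expo, camera, saturated = sat_hit)
}

#' Simulate dark frames
#'
#' Frames with the laser off: black level plus Gaussian read noise, rounded
#' and clipped. Per pixel the temporal mean is the black level and the
#' temporal variance is `(gain * read_noise_e)^2 + 1/12` (the 1/12 ADU^2
#' term from rounding to integer ADU).
#'
#' @param camera a [camera_spec()].
#' @param n number of frames.
#' @param shape `c(rows, cols)`.
#' @param quantize round to integer ADU (TRUE, the physical camera) or keep
#'   continuous values (useful to isolate the quantization term).
#' @param seed optional seed.
#' @return a [frame_stack()] with source id 0 throughout.
#' @export
simulate_dark_frames <- function(camera = camera_spec(), n = 500,
                                 shape = c(28, 28), quantize = TRUE,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- shape[1]; cols <- shape[2]; npx <- rows * cols
  rn_adu <- camera$read_noise_e * camera$gain
  frames <- array(0, c(n, rows, cols))
  for (i in seq_len(n)) {
    adu <- rep(camera$black_level, npx)
    if (rn_adu > 0) adu <- adu + stats::rnorm(npx, sd = rn_adu)
    if (quantize) adu <- pmin(pmax(round(adu), 0), camera$saturation)
    frames[i, , ] <- adu
  }
  frame_stack(frames, (seq_len(n) - 1) * 1e-2, rep(0L, n),
              1e-3, camera)
}
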