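#' Expected speckle contrast squared for a finite exposure
#'
#' Closed-form fundamental contrast squared K^2 for fully developed speckle
#' whose field decorrelates with a single-exponential correlation
#' \eqn{g_1(\tau) = e^{-\tau/\tau_c}}, integrated over an exposure time
#' \eqn{T = x \tau_c}:
#' \deqn{K^2(\beta, x) = \beta \frac{e^{-2x} - 1 + 2x}{2x^2}}
#' This is the ground truth the synthetic frame generator targets and the
#' reference curve used by the recovery tests. It decreases monotonically in
#' x, tends to \eqn{\beta} as \eqn{x \to 0} (frozen speckle), and behaves as
#' \eqn{\beta/x} for \eqn{x \gg 1}.
#'
#' @param beta coherence parameter (maximum attainable contrast squared),
#'   0 < beta <= 0.5.
#' @param x ratio exposure / decorrelation time, > 0. `x = 0` is accepted and
#'   returns the frozen-speckle limit `beta`.
#' @return contrast squared (dimensionless), same length as `x`.
#' @export
#' @examples
#' expected_contrast(0.16, 1)    # 0.0908268
#' expected_contrast(0.16, 1e-9) # ~0.16
expected_contrast <- function(beta, x) {
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop("`beta` must be positive and finite")
  if (any(is.na(x)) || any(x < 0))
    stop("`x` must be non-negative")
  out <- numeric(length(x))
  small <- x < 1e-6
  # series: (e^{-2x} - 1 + 2x)/(2x^2) = 1 - 2x/3 + x^2/3 - ...
  out[small] <- beta * (1 - 2 * x[small] / 3 + x[small]^2 / 3)
  xl <- x[!small]
  out[!small] <- beta * (exp(-2 * xl) - 1 + 2 * xl) / (2 * xl^2)
  out
}

#' Coherence parameter from the polarization amplitude ratio
#'
#' For unpolarized detection with two partially mixed polarization speckle
#' fields of amplitude ratio s/p, the coherence parameter is
#' \deqn{\beta = \frac{(s/p)^2}{2\,(1 + (s/p)^2)}}
#' so a fully polarized channel pair (s/p = 1) gives beta = 0.25 and
#' beta < 0.5 always.
#'
#' @param sp_ratio amplitude ratio of the two detected polarization fields,
#'   >= 0.
#' @return beta in [0, 0.5).
#' @seealso [sp_from_contrast()] for the exact inverse.
#' @export
#' @examples
#' beta_from_sp(0.69) # ~0.16
beta_from_sp <- function(sp_ratio) {
  if (any(is.na(sp_ratio)) || any(sp_ratio < 0))
    stop("`sp_ratio` must be non-negative")
  sp_ratio^2 / (2 * (1 + sp_ratio^2))
}

#' Polarization amplitude ratio from a static-scene contrast
#'
#' Inverts [beta_from_sp()]: for a static scene measured at high flux the
#' noise-corrected contrast squared equals beta, and
#' \deqn{s/p = \sqrt{\frac{2 K_f^2}{1 - 2 K_f^2}}}
#'
#' @param kf2_static noise-corrected contrast squared of a static scene,
#'   in [0, 0.5).
#' @return s/p amplitude ratio.
#' @export
#' @examples
#' sp_from_contrast(beta_from_sp(0.69)) # 0.69
sp_from_contrast <- function(kf2_static) {
  if (any(is.na(kf2_static)) || any(kf2_static < 0))
    stop("`kf2_static` must be non-negative")
  if (any(kf2_static >= 0.5))
    stop("`kf2_static` >= 0.5 is unphysical for unpolarized light")
  sqrt(2 * kf2_static / (1 - 2 * kf2_static))
}

#' Speckle ground truth for the synthetic frame generator
#'
#' Bundles the dynamic and photometric truth of a simulated scene: the
#' coherence parameter beta (equivalently the s/p ratio, via the unpolarized
#' relation), the field decorrelation time tau_c, the mean photoelectron flux
#' per pixel per exposure, and an optional multiplicative illumination
#' heterogeneity map (mean 1).
#'
#' Exactly one of `beta`/`sp_ratio` may be given (the other is derived); if
#' both are given they must satisfy the unpolarized relation to 1e-9.
#'
#' @param beta coherence parameter in (0, 0.5].
#' @param sp_ratio polarization amplitude ratio (alternative to `beta`).
#' @param tau_c field decorrelation time in seconds; `Inf` for a static scene.
#' @param mean_flux mean photoelectrons per pixel per exposure.
#' @param heterogeneity optional multiplicative illumination map (matrix,
#'   mean 1) or NULL for uniform illumination.
#' @return an object of class `speckle_truth`.
#' @export
speckle_truth <- function(beta = NULL, sp_ratio = NULL, tau_c, mean_flux,
                          heterogeneity = NULL) {
  if (is.null(beta) && is.null(sp_ratio))
    stop("give `beta` or `sp_ratio`")
  if (!is.null(beta) && !is.null(sp_ratio)) {
    if (abs(beta - beta_from_sp(sp_ratio)) > 1e-9)
      stop("`beta` and `sp_ratio` violate the unpolarized relation")
  } else if (is.null(beta)) {
    beta <- beta_from_sp(sp_ratio)
  } else {
    sp_ratio <- sp_from_contrast(beta)
  }
  stopifnot(beta > 0, beta <= 0.5, tau_c > 0, mean_flux > 0)
  if (!is.null(heterogeneity)) {
    if (any(heterogeneity <= 0)) stop("heterogeneity map must be positive")
    heterogeneity <- heterogeneity / mean(heterogeneity)
  }
  structure(list(beta = beta, sp_ratio = sp_ratio, tau_c = tau_c,
                 mean_flux = mean_flux, heterogeneity = heterogeneity),
            class = "speckle_truth")
}

#' Smooth low-order polynomial illumination heterogeneity map
#'
#' Emulates the residual non-uniformity of defocused fiber-bundle
#' illumination: a random quadratic surface over the sensor, rescaled to a
#' target RMS relative amplitude about a mean of 1.
#'
#' @param rows,cols sensor dimensions in pixels.
#' @param rms_relative target RMS of the map about 1 (default 0.05).
#' @param seed optional integer seed for the random polynomial coefficients.
#' @return a rows x cols matrix with mean 1.
#' @export
heterogeneity_map <- function(rows, cols, rms_relative = 0.05, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  u <- seq(-1, 1, length.out = rows)
  v <- seq(-1, 1, length.out = cols)
  co <- stats::rnorm(6)
  m <- outer(u, v, function(a, b)
    co[1] * a + co[2] * b + co[3] * a * b + co[4] * a^2 + co[5] * b^2 +
      co[6] * a^2 * b^2)
  m <- m - mean(m)
  s <- stats::sd(as.vector(m))
  if (s > 0) m <- m * (rms_relative / s)
  1 + m
}
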