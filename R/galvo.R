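#' Galvanometer fiber-coupling coordinate search
#'
#' Reproduces the staged coupling-optimization procedure used to locate each
#' fiber of the source array: the beam spirals outward from the starting
#' coordinate until the measured power reaches a threshold; from there,
#' alternating line scans of +/- 20 um along each axis move to the best
#' coordinate until neither axis improves; finally a ~40 x 40 um grid
#' centered on the best point is scanned and its peak returned.
#'
#' All stages sample on a fixed `step` grid (default 5 um); ties are broken
#' toward the earlier-scanned coordinate. The spiral is bounded at
#' `max_radius` (default 500 um); if the threshold is never reached inside
#' the bound the search reports failure.
#'
#' @param landscape function `(x, y) -> power` (vectorized over x/y).
#' @param start numeric `c(x, y)` starting coordinate, um.
#' @param threshold power level that ends the spiral stage.
#' @param step scan grid step, um.
#' @param line_reach half-length of each line scan, um.
#' @param grid_reach half-size of the final refinement grid, um.
#' @param max_radius spiral bound, um.
#' @return list with `coord` (the located coordinate), `power` at that
#'   coordinate, `success`, and `n_evaluations`.
#' @export
galvo_search <- function(landscape, start, threshold, step = 5,
                         line_reach = 20, grid_reach = 20, max_radius = 500) {
  nev <- 0L
  f <- function(x, y) {
    nev <<- nev + length(x)
    landscape(x, y)
  }

  # stage 1: spiral until threshold
  found <- NULL
  if (f(start[1], start[2]) >= threshold) {
    found <- start
  } else {
    r <- step
    while (r <= max_radius && is.null(found)) {
      npts <- max(8L, ceiling(2 * pi * r / step))
      ang <- 2 * pi * (seq_len(npts) - 1) / npts
      px <- start[1] + r * cos(ang)
      py <- start[2] + r * sin(ang)
      pw <- f(px, py)
      hit <- which(pw >= threshold)
      if (length(hit)) found <- c(px[hit[1]], py[hit[1]])
      r <- r + step
    }
  }
  if (is.null(found))
    return(list(coord = NULL, power = NA_real_, success = FALSE,
                n_evaluations = nev))

  # stage 2: alternating line scans until no improvement
  best <- found
  best_pw <- f(best[1], best[2])
  repeat {
    improved <- FALSE
    for (axis in 1:2) {
      off <- seq(-line_reach, line_reach, by = step)
      px <- if (axis == 1) best[1] + off else rep(best[1], length(off))
      py <- if (axis == 2) best[2] + off else rep(best[2], length(off))
      pw <- f(px, py)
      k <- which.max(pw)                 # ties -> earlier-scanned point
      if (pw[k] > best_pw) {
        best <- c(px[k], py[k]); best_pw <- pw[k]; improved <- TRUE
      }
    }
    if (!improved) break
  }

  # stage 3: square grid refinement
  off <- seq(-grid_reach, grid_reach, by = step)
  gx <- rep(best[1] + off, times = length(off))
  gy <- rep(best[2] + off, each = length(off))
  pw <- f(gx, gy)
  k <- which.max(pw)
  if (pw[k] > best_pw) {
    best <- c(gx[k], gy[k]); best_pw <- pw[k]
  }
  list(coord = best, power = best_pw, success = TRUE, n_evaluations = nev)
}
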