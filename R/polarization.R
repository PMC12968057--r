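#' Particle-motion polarization analysis of a three-component window
#'
#' Band-passes the three seismic components, forms the 3x3 zero-lag
#' covariance matrix of (N, E, Z) over the window, and eigen-decomposes it.
#' The vertical-to-horizontal energy ratio `vh_ratio = E[Z^2] / (E[N^2] +
#' E[E^2])` separates Rayleigh-wave-like motion (dominantly vertical,
#' elliptical in the vertical plane) from Love-wave-like motion (transverse
#' horizontal): under isotropic noise with equal per-component power the
#' ratio is 1/2.
#'
#' @param trace_n,trace_e,trace_z Co-registered component [trace()]s (equal
#'   length, sampling rate and start time).
#' @param band Frequency band `c(f_lo, f_hi)`, Hz.
#' @param thresholds Named numeric `c(love = ..., rayleigh = ...)`:
#'   classification is `"rayleigh_like"` when `vh_ratio >= rayleigh`,
#'   `"love_like"` when `vh_ratio <= love`, else `"mixed"`. Defaults (0.25,
#'   2) sit a factor 2 below and 4 above the isotropic expectation of 0.5.
#' @return An object of class `polarization_result`: `band`, `vh_ratio`,
#'   `incidence_angle` (degrees of the dominant eigenvector from the
#'   horizontal plane), `rectilinearity` in `[0, 1]`, and `classification`.
#' @export
particle_motion <- function(trace_n, trace_e, trace_z, band = c(16, 20),
                            thresholds = c(love = 0.25, rayleigh = 2)) {
  trs <- list(trace_n, trace_e, trace_z)
  stopifnot(all(vapply(trs, inherits, TRUE, "trace")),
            length(unique(vapply(trs, function(x) length(x$samples), 0L))) == 1,
            band[1] < band[2])
  comps <- lapply(trs, function(tr)
    bandpass_filter(tr, band[1], band[2])$samples)
  M <- do.call(cbind, comps)  # columns N, E, Z
  if (all(abs(M) < 1e-14)) stop("zero-energy window")
  C <- crossprod(M) / nrow(M)
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1]
  vh <- C[3, 3] / (C[1, 1] + C[2, 2])
  incidence <- asin(pmin(1, abs(v[3]))) * 180 / pi
  lam <- pmax(eg$values, 0)
  rect <- 1 - (lam[2] + lam[3]) / (2 * lam[1])
  cls <- if (vh >= thresholds[["rayleigh"]]) "rayleigh_like"
         else if (vh <= thresholds[["love"]]) "love_like" else "mixed"
  structure(list(band = band, vh_ratio = vh, incidence_angle = incidence,
                 rectilinearity = rect, classification = cls),
            class = "polarization_result")
}

#' @export
print.polarization_result <- function(x, ...) {
  cat(sprintf(
    "<polarization> band %g-%g Hz: V/H = %.3g, incidence %.1f deg, rectilinearity %.2f -> %s\n",
    x$band[1], x$band[2], x$vh_ratio, x$incidence_angle, x$rectilinearity,
    x$classification))
  invisible(x)
}

#' Classify particle motion per frequency band
#'
#' Runs [particle_motion()] on each band of a three-component snippet. The
#' bands default to the fundamental (16-20 Hz) and first-harmonic (30-40 Hz)
#' ranges used to contrast Rayleigh-like and Love-like coupling of rumble
#' energy into the ground.
#'
#' @param trace_n,trace_e,trace_z Co-registered component [trace()]s.
#' @param bands List of frequency bands, Hz.
#' @param thresholds See [particle_motion()].
#' @return A data.frame with one row per band: `f_lo`, `f_hi`, `vh_ratio`,
#'   `incidence_angle`, `rectilinearity`, `classification`.
#' @export
classify_band_polarization <- function(trace_n, trace_e, trace_z,
                                       bands = list(c(16, 20), c(30, 40)),
                                       thresholds = c(love = 0.25,
                                                      rayleigh = 2)) {
  rows <- lapply(bands, function(b) {
    pm <- particle_motion(trace_n, trace_e, trace_z, b, thresholds)
    data.frame(f_lo = b[1], f_hi = b[2], vh_ratio = pm$vh_ratio,
               incidence_angle = pm$incidence_angle,
               rectilinearity = pm$rectilinearity,
               classification = pm$classification)
  })
  do.call(rbind, rows)
}
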