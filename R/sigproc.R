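#' Zero-phase band-pass filter
#'
#' Zero-phase (two-pass, forward-backward) Butterworth band-pass built as a
#' cascade of a 4th-order high-pass at `f_lo` and an 8th-order low-pass at
#' `f_hi`, so pick times are not shifted and in-band amplitudes are
#' preserved. The steeper upper section matters at a 200-Hz sampling rate,
#' where the 80-Hz analysis corner sits close to the Nyquist frequency: it
#' narrows the upper transition band enough that repeated filtering leaves
#' the signal essentially unchanged (idempotence), which a 4-pole upper
#' edge does not achieve. The analysis band for all downstream processing
#' is 1-80 Hz.
#'
#' @param x A [trace()].
#' @param f_lo,f_hi Corner frequencies, Hz (`0 < f_lo < f_hi < ` Nyquist).
#' @return A filtered `trace` with unchanged metadata.
#' @export
bandpass_filter <- function(x, f_lo = 1, f_hi = 80) {
  stopifnot(inherits(x, "trace"))
  nyq <- x$sampling_rate / 2
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  if (f_hi >= nyq)
    stop(sprintf("f_hi = %g Hz must be below the Nyquist frequency %g Hz",
                 f_hi, nyq))
  y <- signal::filtfilt(signal::butter(4, f_lo / nyq, type = "high"),
                        x$samples)
  y <- signal::filtfilt(signal::butter(8, f_hi / nyq, type = "low"), y)
  out <- x
  out$samples <- as.numeric(y)
  out
}

# Periodic Hann window (constant-overlap-add friendly).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Compute a short-time power spectrogram
#'
#' Hann-windowed short-time Fourier transform, returned as a one-sided power
#' spectral density (units^2/Hz) on a linear scale. Frequency resolution is
#' `1/window_length`; frames are processed in blocks so long records do not
#' materialize large intermediate matrices. The scaling is such that the total
#' map energy `sum(power) * df * dt_hop` matches the signal energy
#' `sum(x^2)/fs` (Parseval) for interior-supported signals.
#'
#' @param x A [trace()].
#' @param window_length STFT window, seconds (default 1 s: 1-Hz resolution
#'   resolves 10-25 Hz fundamentals).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.75:
#'   0.25-s hop resolves 1-s calls).
#' @return An object of class `tfmap`: `power` (time bins x frequency bins),
#'   `time_axis` (frame centres, s), `freq_axis` (Hz), `scale = "linear"`.
#' @export
compute_spectrogram <- function(x, window_length = 1, overlap = 0.75) {
  stopifnot(inherits(x, "trace"), overlap >= 0, overlap < 1)
  fs <- x$sampling_rate
  nfft <- round(window_length * fs)
  if (nfft < 8) stop("window_length too short: needs >= 8 samples")
  if (nfft > length(x$samples)) stop("window longer than trace")
  hop <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, length(x$samples) - nfft + 1L, by = hop)
  w <- hann_window(nfft)
  w2 <- sum(w^2)
  nfreq <- nfft %/% 2L + 1L
  power <- matrix(0, nrow = length(starts), ncol = nfreq)
  block <- 2048L
  for (b0 in seq(1L, length(starts), by = block)) {
    bi <- b0:min(length(starts), b0 + block - 1L)
    seg <- vapply(starts[bi],
                  function(s) x$samples[s:(s + nfft - 1L)] * w,
                  numeric(nfft))
    X <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    p <- Mod(X)^2 / (fs * w2)
    p[c(-1L, -nfreq), ] <- 2 * p[c(-1L, -nfreq), ]
    power[bi, ] <- t(p)
  }
  structure(list(power = power,
                 time_axis = x$start_time + (starts - 1L + nfft / 2) / fs,
                 freq_axis = (seq_len(nfreq) - 1L) * fs / nfft,
                 scale = "linear",
                 window_length = window_length,
                 hop = hop / fs),
            class = "tfmap")
}

#' Average three component spectrograms
#'
#' Cell-wise arithmetic mean of the N, E and Z seismic component spectrograms
#' on the linear power scale; averaging raises the ridge-to-background ratio
#' of tonal signals against component-independent noise.
#'
#' @param map_n,map_e,map_z `tfmap`s with identical axes.
#' @return A `tfmap` of the same shape.
#' @export
average_component_maps <- function(map_n, map_e, map_z) {
  maps <- list(map_n, map_e, map_z)
  stopifnot(all(vapply(maps, inherits, TRUE, "tfmap")))
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(m$time_axis, maps[[1]]$time_axis)) ||
        !isTRUE(all.equal(m$freq_axis, maps[[1]]$freq_axis)))
      stop("component maps have mismatched axes")
    if (m$scale != "linear" || maps[[1]]$scale != "linear")
      stop("component maps must be on the linear power scale")
  }
  out <- maps[[1]]
  out$power <- (map_n$power + map_e$power + map_z$power) / 3
  out
}

#' Extract a fixed-length snippet centred on a pick
#'
#' Cuts exactly `length * sampling_rate` samples with the picked timestamp at
#' the temporal centre. Picks whose window would exceed the trace bounds are
#' rejected (no padding).
#'
#' @param x A [trace()].
#' @param t_pick Pick time (same time base as the trace), seconds.
#' @param length Snippet length, seconds (default 12).
#' @return A `trace` covering `[t_pick - length/2, t_pick + length/2)`.
#' @export
extract_snippet <- function(x, t_pick, length = 12) {
  stopifnot(inherits(x, "trace"))
  fs <- x$sampling_rate
  n <- round(length * fs)
  i0 <- round((t_pick - length / 2 - x$start_time) * fs) + 1L
  if (i0 < 1L || i0 + n - 1L > base::length(x$samples))
    stop(sprintf("snippet [%g, %g) s exceeds trace bounds",
                 t_pick - length / 2, t_pick + length / 2))
  out <- x
  out$samples <- x$samples[i0:(i0 + n - 1L)]
  out$start_time <- x$start_time + (i0 - 1L) / fs
  out
}

# Fixed perceptually-uniform colour lookup table (256 RGB rows, 0-255).
snippet_palette <- function() {
  hex <- grDevices::hcl.colors(256, "viridis")
  t(grDevices::col2rgb(hex))
}

#' Render a spectrogram snippet as a fixed-size RGB image
#'
#' dB-scales the map over the analysis frequency band, clips the dynamic
#' range to fixed percentile anchors computed per snippet (2nd/98th), maps
#' through a fixed perceptually-uniform colour table, and resamples to
#' exactly `width x height` pixels. The rendering is a pure function of the
#' map and the anchors.
#'
#' @param map A `tfmap` on the linear scale.
#' @param freq_range Frequency band to render, Hz (default `c(1, 80)`).
#' @param width,height Output image size in pixels (default 232 x 115).
#' @param anchors Percentile anchors for the dB dynamic range.
#' @param label Class label to attach: `"rumble"`, `"noise"` or
#'   `"unlabeled"`.
#' @param domain `"seismic"` or `"infrasound"`.
#' @return An object of class `snippet_image`: integer `pixels` array of
#'   dimension `height x width x 3` with values 0-255, plus `label` and
#'   `domain`.
#' @export
render_snippet_image <- function(map, freq_range = c(1, 80), width = 232,
                                 height = 115, anchors = c(0.02, 0.98),
                                 label = c("unlabeled", "rumble", "noise"),
                                 domain = c("seismic", "infrasound")) {
  label <- match.arg(label)
  domain <- match.arg(domain)
  stopifnot(inherits(map, "tfmap"), map$scale == "linear")
  sel <- which(map$freq_axis >= freq_range[1] & map$freq_axis <= freq_range[2])
  if (length(sel) < 2L || nrow(map$power) < 2L)
    stop("map too small to render (needs >= 2 bins per axis in range)")
  p <- map$power[, sel, drop = FALSE]
  db <- 10 * log10(p + 1e-30)
  # columns ordered so row 1 of the image is the highest frequency
  a <- db[, rev(seq_along(sel)), drop = FALSE]
  img <- EBImage::resize(EBImage::Image(a), w = width, h = height)
  m <- EBImage::imageData(img)
  qs <- stats::quantile(m, anchors, names = FALSE)
  rng <- qs[2] - qs[1]
  norm <- if (rng > 0) pmin(1, pmax(0, (m - qs[1]) / rng)) else
    matrix(0, nrow(m), ncol(m))
  idx <- pmin(255L, as.integer(floor(norm * 256))) + 1L
  pal <- snippet_palette()
  px <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3)
    px[, , ch] <- t(matrix(pal[idx, ch], nrow = width, ncol = height))
  structure(list(pixels = px, label = label, domain = domain),
            class = "snippet_image")
}

#' Write a snippet image as PNG
#' @param img A `snippet_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snippet_png <- function(img, path) {
  stopifnot(inherits(img, "snippet_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Partition a trace into fixed scanning windows
#'
#' Contiguous, non-overlapping windows (default 200 s, the interval used for
#' visual record scanning) covering the whole trace; a final partial window is
#' included and flagged.
#'
#' @param x A [trace()].
#' @param window Window length, seconds.
#' @return A data.frame with columns `start`, `end` (seconds, same time base
#'   as the trace) and logical `partial`.
#' @export
scan_windows <- function(x, window = 200) {
  stopifnot(inherits(x, "trace"), window > 0)
  dur <- trace_duration(x)
  if (dur < window) stop("trace shorter than one window")
  n_full <- floor(dur / window + 1e-9)
  n_win <- n_full + as.integer(dur - n_full * window > 1e-9)
  starts <- (seq_len(n_win) - 1) * window
  ends <- pmin(starts + window, dur)
  data.frame(start = x$start_time + starts,
             end = x$start_time + ends,
             partial = (ends - starts) < window - 1e-9)
}
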