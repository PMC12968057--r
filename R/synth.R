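#' Specification of a single synthetic rumble
#'
#' A rumble is a tonal call with a fundamental frequency contour that rises to
#' its apex at the temporal centre of the call and falls by a fractional
#' `contour_depth` at the edges, plus `n_harmonics` integer harmonics whose
#' amplitudes decay geometrically by `harmonic_decay` per order. Rumbles are
#' radiated both as seismic ground velocity (peak `peak_ground_velocity`,
#' um/s) and as infrasound pressure (peak `peak_pressure`, Pa).
#'
#' @param onset_time Onset in seconds from scene start.
#' @param apex_frequency Fundamental apex frequency, Hz.
#' @param duration Call duration, seconds.
#' @param n_harmonics Number of harmonics above the fundamental (>= 0).
#' @param harmonic_decay Amplitude ratio per harmonic order, in (0, 1].
#' @param peak_ground_velocity Peak seismic amplitude, um/s (vector magnitude
#'   across N/E/Z).
#' @param peak_pressure Peak infrasound amplitude, Pa.
#' @param contour_depth Fractional frequency drop at the call edges, in
#'   \[0, 0.5).
#' @return An object of class `rumble_spec`.
#' @export
rumble_spec <- function(onset_time = 0, apex_frequency = 18, duration = 4,
                        n_harmonics = 2, harmonic_decay = 0.55,
                        peak_ground_velocity = 5, peak_pressure = 0.5,
                        contour_depth = 0.15) {
  stopifnot(apex_frequency > 0, duration > 0, n_harmonics >= 0,
            harmonic_decay > 0, harmonic_decay <= 1,
            peak_ground_velocity >= 0, peak_pressure >= 0,
            contour_depth >= 0, contour_depth < 0.5)
  structure(list(onset_time = onset_time, apex_frequency = apex_frequency,
                 duration = duration, n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 peak_ground_velocity = peak_ground_velocity,
                 peak_pressure = peak_pressure, contour_depth = contour_depth),
            class = "rumble_spec")
}

#' Specification of a single footfall transient
#'
#' Footfalls are broadband impulsive seismic signals from locomotion or
#' trampling. They couple into the ground only: rendered scenes never place
#' footfall energy on the infrasound channel.
#'
#' @param onset_time Onset in seconds from scene start.
#' @param impulse_duration Impulse duration, seconds (typically 0.05-0.3).
#' @param peak_ground_velocity Peak amplitude, um/s.
#' @param spectral_corner High-pass corner of the impulse spectrum, Hz.
#' @return An object of class `footfall_spec`.
#' @export
footfall_spec <- function(onset_time = 0, impulse_duration = 0.15,
                          peak_ground_velocity = 5, spectral_corner = 10) {
  stopifnot(impulse_duration > 0, peak_ground_velocity >= 0,
            spectral_corner > 0)
  structure(list(onset_time = onset_time, impulse_duration = impulse_duration,
                 peak_ground_velocity = peak_ground_velocity,
                 spectral_corner = spectral_corner),
            class = "footfall_spec")
}

#' Diurnal background-noise model
#'
#' Background noise is Gaussian and broadband at a night-time RMS, multiplied
#' by a day factor during zoo opening hours (a hard step at the configured
#' hours). Seismic noise additionally carries monochromatic machine lines and
#' Poisson-scheduled short broadband bursts during the day; the infrasound
#' channel has a smaller day factor and neither lines nor bursts.
#'
#' Defaults emulate a noisy zoo installation: daytime seismic noise elevated
#' by a factor 7 (within the observed 5-10 range), machine lines at 12, 25 and
#' 30 Hz, opening hours 07:00-17:00 UTC.
#'
#' @param night_rms_seismic Night seismic RMS, um/s.
#' @param day_factor_seismic Daytime multiplier for seismic noise, in \[5, 10\]
#'   for realistic scenes.
#' @param machine_line_freqs Frequencies of daytime monochromatic lines, Hz.
#' @param machine_line_rms RMS of each machine line, um/s.
#' @param night_rms_infrasound Night infrasound RMS, Pa.
#' @param day_factor_infrasound Daytime multiplier for infrasound noise; must
#'   be smaller than `day_factor_seismic` and at least 1.
#' @param burst_rate_day Daytime broadband-burst rate, events per hour
#'   (seismic only).
#' @param opening_hours Numeric length-2: opening hours `[start, end)` in UTC
#'   hours of day.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(night_rms_seismic = 0.1, day_factor_seismic = 7,
                        machine_line_freqs = c(12, 25, 30),
                        machine_line_rms = 0.15,
                        night_rms_infrasound = 0.01,
                        day_factor_infrasound = 1.5,
                        burst_rate_day = 20,
                        opening_hours = c(7, 17)) {
  stopifnot(night_rms_seismic > 0, night_rms_infrasound > 0,
            day_factor_infrasound >= 1,
            day_factor_seismic > day_factor_infrasound,
            length(opening_hours) == 2, opening_hours[1] < opening_hours[2])
  structure(list(night_rms_seismic = night_rms_seismic,
                 day_factor_seismic = day_factor_seismic,
                 machine_line_freqs = machine_line_freqs,
                 machine_line_rms = machine_line_rms,
                 night_rms_infrasound = night_rms_infrasound,
                 day_factor_infrasound = day_factor_infrasound,
                 burst_rate_day = burst_rate_day,
                 opening_hours = opening_hours),
            class = "noise_model")
}

#' Priors for randomly drawn rumble specifications
#'
#' Ranges reflect the observed call population: fundamental apex between 10
#' and 25 Hz, durations 1-8 s, seismic peak ground velocities 1-10 um/s.
#' Infrasound peak pressures (not reported as numbers in the field data) use a
#' 0.1-1 Pa range so that night-time SNR is comparable across domains.
#'
#' @param apex Range of apex frequencies, Hz.
#' @param duration Range of durations, s.
#' @param peak_ground_velocity Range of seismic peaks, um/s.
#' @param peak_pressure Range of infrasound peaks, Pa.
#' @param n_harmonics Number of harmonics (fixed).
#' @param harmonic_decay Range of per-order amplitude decay.
#' @param contour_depth Range of fractional contour depth.
#' @return A list of prior ranges.
#' @export
rumble_priors <- function(apex = c(10, 25), duration = c(1, 8),
                          peak_ground_velocity = c(1, 10),
                          peak_pressure = c(0.1, 1),
                          n_harmonics = 2L,
                          harmonic_decay = c(0.4, 0.7),
                          contour_depth = c(0.05, 0.25)) {
  list(apex = apex, duration = duration,
       peak_ground_velocity = peak_ground_velocity,
       peak_pressure = peak_pressure, n_harmonics = as.integer(n_harmonics),
       harmonic_decay = harmonic_decay, contour_depth = contour_depth)
}

#' Draw random rumble specifications from the default priors
#'
#' @param n Number of rumbles.
#' @param onset_times Optional fixed onset times (seconds). If `NULL`, onsets
#'   are drawn uniformly over `[margin, t_max - margin]` with a minimum
#'   separation.
#' @param t_max Scene duration, seconds (required when onsets are drawn).
#' @param priors Prior ranges from [rumble_priors()].
#' @param margin Keep-out margin at scene edges, seconds.
#' @param min_separation Minimum onset separation, seconds. Injected calls are
#'   kept resolvable at the 12-s analysis scale by default.
#' @param seed Optional RNG seed for reproducible draws.
#' @return A list of `rumble_spec` objects sorted by onset time.
#' @export
draw_rumble_specs <- function(n, onset_times = NULL, t_max = NULL,
                              priors = rumble_priors(), margin = 30,
                              min_separation = 12, seed = NULL) {
  draw <- function() {
    if (is.null(onset_times)) {
      stopifnot(!is.null(t_max), t_max > 2 * margin)
      lo <- margin
      hi <- t_max - margin
      ons <- sort(stats::runif(n, lo, hi))
      for (tries in seq_len(200)) {
        if (n < 2 || all(diff(ons) >= min_separation)) break
        bad <- which(diff(ons) < min_separation) + 1L
        ons[bad] <- stats::runif(length(bad), lo, hi)
        ons <- sort(ons)
      }
    } else {
      stopifnot(length(onset_times) == n)
      ons <- sort(onset_times)
    }
    lapply(seq_len(n), function(i) {
      rumble_spec(
        onset_time = ons[i],
        apex_frequency = stats::runif(1, priors$apex[1], priors$apex[2]),
        duration = stats::runif(1, priors$duration[1], priors$duration[2]),
        n_harmonics = priors$n_harmonics,
        harmonic_decay = stats::runif(1, priors$harmonic_decay[1],
                                      priors$harmonic_decay[2]),
        peak_ground_velocity = stats::runif(1, priors$peak_ground_velocity[1],
                                            priors$peak_ground_velocity[2]),
        peak_pressure = stats::runif(1, priors$peak_pressure[1],
                                     priors$peak_pressure[2]),
        contour_depth = stats::runif(1, priors$contour_depth[1],
                                     priors$contour_depth[2]))
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Contour weight: half-sine rise over the first quarter of the call, a
# plateau at the apex over the central half, half-sine fall over the last
# quarter. The plateau concentrates spectral energy at a single well-defined
# apex frequency (the only stationary region of the contour), which is what
# makes the apex recoverable from band-power maxima.
rumble_contour <- function(n, apex, depth) {
  u <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  rise <- u < 0.25
  fall <- u > 0.75
  w[rise] <- sin(2 * pi * u[rise])
  w[fall] <- sin(2 * pi * (1 - u[fall]))
  apex * (1 - depth * (1 - w))
}

# Cosine on/off ramps covering `frac` of each end of the segment.
taper_envelope <- function(n, frac = 0.1) {
  env <- rep(1, n)
  m <- max(2L, floor(n * frac))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / (m - 1)))
  env[seq_len(m)] <- ramp
  env[(n - m + 1L):n] <- rev(ramp)
  env
}

#' Synthesize a rumble waveform segment
#'
#' Sums `n_harmonics + 1` harmonic orders of the integrated instantaneous
#' frequency contour (half-sine weighted rise to the apex at the temporal
#' centre), applies cosine on/off ramps, and scales the peak amplitude to the
#' domain's peak value.
#'
#' @param spec A [rumble_spec()].
#' @param sampling_rate Sampling rate, Hz.
#' @param domain `"seismic"` (peak = `peak_ground_velocity`) or `"infrasound"`
#'   (peak = `peak_pressure`).
#' @return Numeric waveform segment of `round(duration * sampling_rate)`
#'   samples.
#' @export
synth_rumble <- function(spec, sampling_rate = 200,
                         domain = c("seismic", "infrasound")) {
  domain <- match.arg(domain)
  stopifnot(inherits(spec, "rumble_spec"))
  f_top <- spec$apex_frequency * (spec$n_harmonics + 1L)
  if (sampling_rate < 2 * f_top)
    stop(sprintf(
      "aliasing: highest harmonic %.1f Hz exceeds Nyquist %.1f Hz",
      f_top, sampling_rate / 2))
  n <- max(4L, round(spec$duration * sampling_rate))
  f <- rumble_contour(n, spec$apex_frequency, spec$contour_depth)
  phase <- 2 * pi * cumsum(f) / sampling_rate
  seg <- numeric(n)
  for (k in seq_len(spec$n_harmonics + 1L))
    seg <- seg + spec$harmonic_decay^(k - 1) * sin(k * phase)
  seg <- seg * taper_envelope(n)
  peak <- if (domain == "seismic") spec$peak_ground_velocity else
    spec$peak_pressure
  if (peak == 0 || max(abs(seg)) == 0) return(numeric(n))
  seg / max(abs(seg)) * peak
}

#' Synthesize a polarized three-component rumble
#'
#' Renders the fundamental as vertically polarized motion (on Z, Rayleigh
#' wave-like) and the harmonics as transverse horizontal motion at a fixed
#' azimuth (on N/E, Love wave-like). Used to emulate the band-dependent
#' particle-motion character of ground-coupled rumbles.
#'
#' @param spec A [rumble_spec()] with `n_harmonics >= 1`.
#' @param sampling_rate Sampling rate, Hz.
#' @param azimuth Horizontal polarization azimuth of the harmonic, degrees
#'   clockwise from North.
#' @return A list with numeric components `N`, `E`, `Z`.
#' @export
synth_rumble_polarized <- function(spec, sampling_rate = 200, azimuth = 60) {
  stopifnot(inherits(spec, "rumble_spec"), spec$n_harmonics >= 1L)
  f_top <- spec$apex_frequency * (spec$n_harmonics + 1L)
  if (sampling_rate < 2 * f_top)
    stop("aliasing: highest harmonic exceeds Nyquist")
  n <- max(4L, round(spec$duration * sampling_rate))
  f <- rumble_contour(n, spec$apex_frequency, spec$contour_depth)
  phase <- 2 * pi * cumsum(f) / sampling_rate
  env <- taper_envelope(n)
  fund <- sin(phase) * env
  harm <- numeric(n)
  for (k in 1L + seq_len(spec$n_harmonics))
    harm <- harm + spec$harmonic_decay^(k - 1) * sin(k * phase)
  harm <- harm * env
  pk <- spec$peak_ground_velocity
  z <- if (max(abs(fund)) > 0) fund / max(abs(fund)) * pk else fund
  h <- if (max(abs(harm)) > 0)
    harm / max(abs(harm)) * pk * spec$harmonic_decay else harm
  az <- azimuth * pi / 180
  list(N = h * cos(az), E = h * sin(az), Z = z)
}

#' Synthesize a footfall waveform segment
#'
#' An exponentially damped, high-passed Gaussian noise burst: broadband with a
#' sharp onset, matching the impulsive character of locomotion signals.
#'
#' @param spec A [footfall_spec()].
#' @param sampling_rate Sampling rate, Hz.
#' @param seed Optional RNG seed; identical spec and seed give identical
#'   segments.
#' @return Numeric waveform segment.
#' @export
synth_footfall <- function(spec, sampling_rate = 200, seed = NULL) {
  stopifnot(inherits(spec, "footfall_spec"))
  if (spec$impulse_duration <= 0) stop("impulse_duration must be positive")
  n <- round(spec$impulse_duration * sampling_rate)
  if (n < 4L) stop("impulse_duration too short: needs >= 4 samples")
  gen <- function() {
    x <- stats::rnorm(n)
    bf <- signal::butter(2, min(0.95, spec$spectral_corner / (sampling_rate / 2)),
                         type = "high")
    x <- as.numeric(signal::filter(bf, x))
    tau <- spec$impulse_duration / 3
    x <- x * exp(-(seq_len(n) - 1) / sampling_rate / tau)
    if (spec$peak_ground_velocity == 0 || max(abs(x)) == 0) return(numeric(n))
    x / max(abs(x)) * spec$peak_ground_velocity
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Hour of day (0-24) for scene times `t` (seconds), given the clock hour at
# scene t = 0.
scene_hour <- function(t, clock_start_hour) {
  (clock_start_hour + t / 3600) %% 24
}

is_daytime <- function(t, clock_start_hour, opening_hours) {
  h <- scene_hour(t, clock_start_hour)
  h >= opening_hours[1] & h < opening_hours[2]
}

#' Synthesize diurnal background noise
#'
#' Gaussian broadband noise at the domain's night RMS, multiplied by the day
#' factor inside opening hours (hard step). Seismic noise additionally carries
#' daytime monochromatic machine lines and Poisson-scheduled broadband bursts.
#'
#' @param model A [noise_model()].
#' @param domain `"seismic"` or `"infrasound"`.
#' @param t_start,t_end Segment bounds in scene seconds (`t_end > t_start`).
#' @param sampling_rate Sampling rate, Hz.
#' @param clock_start_hour Hour of day at scene time 0 (UTC).
#' @param seed Optional RNG seed.
#' @return Numeric waveform segment of `round((t_end - t_start) *
#'   sampling_rate)` samples.
#' @export
synth_noise <- function(model, domain = c("seismic", "infrasound"),
                        t_start = 0, t_end = 3600, sampling_rate = 200,
                        clock_start_hour = 0, seed = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(model, "noise_model"), t_end > t_start)
  gen <- function() {
    n <- round((t_end - t_start) * sampling_rate)
    t <- t_start + (seq_len(n) - 1) / sampling_rate
    day <- is_daytime(t, clock_start_hour, model$opening_hours)
    rms_night <- if (domain == "seismic") model$night_rms_seismic else
      model$night_rms_infrasound
    fac <- if (domain == "seismic") model$day_factor_seismic else
      model$day_factor_infrasound
    x <- stats::rnorm(n, sd = rms_night)
    x[day] <- x[day] * fac
    if (domain == "seismic" && any(day)) {
      for (f0 in model$machine_line_freqs) {
        ph <- stats::runif(1, 0, 2 * pi)
        x <- x + (model$machine_line_rms * sqrt(2)) *
          sin(2 * pi * f0 * t + ph) * day
      }
      day_seconds <- sum(day) / sampling_rate
      n_burst <- stats::rpois(1, model$burst_rate_day * day_seconds / 3600)
      if (n_burst > 0) {
        day_idx <- which(day)
        for (b in seq_len(n_burst)) {
          i0 <- sample(day_idx, 1L)
          dur <- stats::runif(1, 0.3, 1.0)
          fs_spec <- footfall_spec(
            impulse_duration = dur,
            peak_ground_velocity = 2.5 * fac * rms_night,
            spectral_corner = 5)
          seg <- synth_footfall(fs_spec, sampling_rate)
          idx <- i0:min(n, i0 + length(seg) - 1L)
          x[idx] <- x[idx] + seg[seq_along(idx)]
        }
      }
    }
    x
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Configuration of a synthetic seismo-acoustic scene
#'
#' @param duration Scene duration, seconds.
#' @param seed Integer RNG seed (mandatory; the scene is a pure function of
#'   its configuration and seed).
#' @param sampling_rate Sampling rate, Hz. Must exceed twice the highest
#'   synthesized frequency.
#' @param clock_start_hour Hour of day (UTC) at scene time 0.
#' @param noise A [noise_model()].
#' @param rumbles Optional list of [rumble_spec()]; if `NULL`, `n_rumbles`
#'   specs are drawn from `priors`.
#' @param n_rumbles Number of rumbles to draw when `rumbles` is `NULL`.
#' @param footfalls Optional list of [footfall_spec()]; if `NULL`, footfalls
#'   are coupled to rumbles with probability `footfall_prob` (locomotion
#'   accompanying calls) plus `n_extra_footfalls` independent ones.
#' @param footfall_prob Probability that a rumble is accompanied by footfalls
#'   within +/-45 s.
#' @param n_extra_footfalls Number of additional rumble-independent footfalls.
#' @param priors Prior ranges from [rumble_priors()].
#' @param margin Scene-edge keep-out for drawn onsets, seconds.
#' @param min_separation Minimum drawn rumble separation, seconds.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(duration, seed, sampling_rate = 200,
                         clock_start_hour = 0, noise = noise_model(),
                         rumbles = NULL, n_rumbles = 0L,
                         footfalls = NULL, footfall_prob = 2 / 3,
                         n_extra_footfalls = 0L,
                         priors = rumble_priors(), margin = 30,
                         min_separation = 12) {
  stopifnot(duration > 0, is.numeric(seed), length(seed) == 1)
  f_max <- if (!is.null(rumbles) && length(rumbles) > 0) {
    max(vapply(rumbles, function(s)
      s$apex_frequency * (s$n_harmonics + 1L), 0))
  } else {
    priors$apex[2] * (priors$n_harmonics + 1L)
  }
  if (sampling_rate <= 2 * f_max)
    stop(sprintf("sampling_rate %g Hz must exceed twice the highest synthesized frequency (%g Hz)",
                 sampling_rate, f_max))
  structure(list(duration = duration, seed = as.integer(seed),
                 sampling_rate = sampling_rate,
                 clock_start_hour = clock_start_hour, noise = noise,
                 rumbles = rumbles, n_rumbles = as.integer(n_rumbles),
                 footfalls = footfalls, footfall_prob = footfall_prob,
                 n_extra_footfalls = as.integer(n_extra_footfalls),
                 priors = priors, margin = margin,
                 min_separation = min_separation),
            class = "scene_config")
}

# Uniformly distributed unit direction vector (N, E, Z).
random_direction <- function() {
  z <- stats::runif(1, -1, 1)
  az <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(N = r * cos(az), E = r * sin(az), Z = z)
}

#' Render a synthetic seismo-acoustic scene
#'
#' Mixes background noise with injected rumbles and footfalls. Rumbles appear
#' on all four channels: the seismic waveform is partitioned across N/E/Z by
#' per-rumble direction cosines (so the peak vector ground velocity equals the
#' spec's peak), and the same call shape is rendered on the infrasound channel
#' scaled to its peak pressure. Footfalls are rendered on seismic channels
#' only. The result is a pure function of the configuration (including its
#' seed).
#'
#' @param config A [scene_config()].
#' @return An object of class `scene_bundle`: traces `seismic_N`, `seismic_E`,
#'   `seismic_Z`, `infrasound`, the ground-truth catalog `truth` (a
#'   data.frame sorted by onset with columns `type`, `onset_time`,
#'   `apex_frequency`, `duration`, `peak_amplitude`), and the `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)

  rumbles <- config$rumbles
  if (is.null(rumbles) && config$n_rumbles > 0L) {
    rumbles <- draw_rumble_specs(
      config$n_rumbles, t_max = config$duration, priors = config$priors,
      margin = config$margin, min_separation = config$min_separation,
      seed = child_seed(config$seed, 1L))
  }
  if (is.null(rumbles)) rumbles <- list()

  footfalls <- config$footfalls
  if (is.null(footfalls)) {
    footfalls <- with_seed(child_seed(config$seed, 2L), {
      ff <- list()
      for (rs in rumbles) {
        if (stats::runif(1) < config$footfall_prob) {
          for (j in seq_len(1L + stats::rpois(1, 2))) {
            t_ff <- rs$onset_time + stats::runif(1, -45, 45)
            if (t_ff > 0.5 && t_ff < config$duration - 0.5)
              ff[[length(ff) + 1L]] <- footfall_spec(
                onset_time = t_ff,
                impulse_duration = stats::runif(1, 0.05, 0.3),
                peak_ground_velocity = stats::runif(1, 2, 8),
                spectral_corner = 10)
          }
        }
      }
      for (j in seq_len(config$n_extra_footfalls)) {
        ff[[length(ff) + 1L]] <- footfall_spec(
          onset_time = stats::runif(1, 0.5, config$duration - 0.5),
          impulse_duration = stats::runif(1, 0.05, 0.3),
          peak_ground_velocity = stats::runif(1, 2, 8),
          spectral_corner = 10)
      }
      ff
    })
  }

  ch_N <- synth_noise(config$noise, "seismic", 0, config$duration, fs,
                      config$clock_start_hour, seed = child_seed(config$seed, 3L))
  ch_E <- synth_noise(config$noise, "seismic", 0, config$duration, fs,
                      config$clock_start_hour, seed = child_seed(config$seed, 4L))
  ch_Z <- synth_noise(config$noise, "seismic", 0, config$duration, fs,
                      config$clock_start_hour, seed = child_seed(config$seed, 5L))
  ch_P <- synth_noise(config$noise, "infrasound", 0, config$duration, fs,
                      config$clock_start_hour, seed = child_seed(config$seed, 6L))

  if (length(rumbles) >= 2L) {
    ons <- vapply(rumbles, `[[`, 0, "onset_time")
    dur <- vapply(rumbles, `[[`, 0, "duration")
    o <- order(ons)
    ons <- ons[o]; dur <- dur[o]
    if (any(ons[-1] < (ons + dur)[-length(ons)]))
      warning("overlapping rumbles in scene; mixed additively")
  }

  with_seed(child_seed(config$seed, 7L), {
    for (rs in rumbles) {
      seg_s <- synth_rumble(rs, fs, "seismic")
      seg_p <- synth_rumble(rs, fs, "infrasound")
      u <- random_direction()
      i0 <- round(rs$onset_time * fs) + 1L
      idx <- i0:min(n, i0 + length(seg_s) - 1L)
      k <- seq_along(idx)
      ch_N[idx] <- ch_N[idx] + u["N"] * seg_s[k]
      ch_E[idx] <- ch_E[idx] + u["E"] * seg_s[k]
      ch_Z[idx] <- ch_Z[idx] + u["Z"] * seg_s[k]
      ch_P[idx] <- ch_P[idx] + seg_p[k]
    }
    for (fs_spec in footfalls) {
      seg <- synth_footfall(fs_spec, fs)
      u <- abs(random_direction())
      u <- u / max(u)
      i0 <- round(fs_spec$onset_time * fs) + 1L
      idx <- i0:min(n, i0 + length(seg) - 1L)
      k <- seq_along(idx)
      ch_N[idx] <- ch_N[idx] + u["N"] * seg[k]
      ch_E[idx] <- ch_E[idx] + u["E"] * seg[k]
      ch_Z[idx] <- ch_Z[idx] + u["Z"] * seg[k]
    }
  })

  truth <- rbind(
    if (length(rumbles))
      data.frame(type = "rumble",
                 onset_time = vapply(rumbles, `[[`, 0, "onset_time"),
                 apex_frequency = vapply(rumbles, `[[`, 0, "apex_frequency"),
                 duration = vapply(rumbles, `[[`, 0, "duration"),
                 peak_amplitude = vapply(rumbles, `[[`, 0, "peak_ground_velocity")),
    if (length(footfalls))
      data.frame(type = "footfall",
                 onset_time = vapply(footfalls, `[[`, 0, "onset_time"),
                 apex_frequency = NA_real_,
                 duration = vapply(footfalls, `[[`, 0, "impulse_duration"),
                 peak_amplitude = vapply(footfalls, `[[`, 0, "peak_ground_velocity")))
  if (is.null(truth))
    truth <- data.frame(type = character(), onset_time = numeric(),
                        apex_frequency = numeric(), duration = numeric(),
                        peak_amplitude = numeric())
  truth <- truth[order(truth$onset_time), , drop = FALSE]
  rownames(truth) <- NULL

  structure(
    list(seismic_N = trace(ch_N, fs, 0, "N", "seismic"),
         seismic_E = trace(ch_E, fs, 0, "E", "seismic"),
         seismic_Z = trace(ch_Z, fs, 0, "Z", "seismic"),
         infrasound = trace(ch_P, fs, 0, "P", "infrasound"),
         truth = truth, config = config),
    class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> %g s @ %g Hz; %d rumbles, %d footfalls\n",
              x$config$duration, x$config$sampling_rate,
              sum(x$truth$type == "rumble"), sum(x$truth$type == "footfall")))
  invisible(x)
}

#' Write a ground-truth catalog to CSV
#' @param truth Truth data.frame from a [render_scene()] bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Read a scene configuration from YAML or JSON
#'
#' The file must provide `duration` and `seed`; all other fields are optional
#' and fall back to package defaults. A `noise` block maps to
#' [noise_model()] arguments; a `rumbles` list of records with `rumble_spec`
#' fields maps to explicit [rumble_spec()]s.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext))
  if (is.null(raw$seed)) stop("scene config must declare a seed")
  if (is.null(raw$duration)) stop("scene config must declare a duration")
  noise <- if (!is.null(raw$noise)) do.call(noise_model, raw$noise) else
    noise_model()
  rumbles <- if (!is.null(raw$rumbles)) {
    lapply(seq_len(NROW(raw$rumbles)), function(i) {
      rec <- if (is.data.frame(raw$rumbles)) as.list(raw$rumbles[i, ]) else
        raw$rumbles[[i]]
      do.call(rumble_spec, rec)
    })
  }
  args <- raw[intersect(names(raw),
                        c("duration", "seed", "sampling_rate",
                          "clock_start_hour", "n_rumbles", "footfall_prob",
                          "n_extra_footfalls", "margin", "min_separation"))]
  args$noise <- noise
  args$rumbles <- rumbles
  do.call(scene_config, args)
}

#' Sample rumble onset times with a diurnal/housing activity schedule
#'
#' Piecewise-constant Poisson arrivals: the base hourly rate is multiplied,
#' during closed (night) hours, by a per-night factor that alternates between
#' nights, emulating an alternating indoor-housing schedule in which one
#' sub-group of animals vocalizes substantially more.
#'
#' @param duration Scene duration, seconds.
#' @param base_rate Base rumble rate, events per hour.
#' @param clock_start_hour Hour of day at scene time 0.
#' @param night_multipliers Numeric vector of per-night rate multipliers,
#'   recycled over successive nights (default alternating 1 and 4).
#' @param opening_hours Daytime hours `[start, end)`.
#' @param seed Optional RNG seed.
#' @return Sorted numeric vector of onset times in seconds.
#' @export
sample_rumble_onsets <- function(duration, base_rate = 4,
                                 clock_start_hour = 0,
                                 night_multipliers = c(1, 4),
                                 opening_hours = c(7, 17), seed = NULL) {
  gen <- function() {
    edges <- seq(0, duration, by = 3600)
    if (utils::tail(edges, 1) < duration) edges <- c(edges, duration)
    ons <- numeric(0)
    for (i in seq_len(length(edges) - 1L)) {
      t0 <- edges[i]
      h <- scene_hour(t0, clock_start_hour)
      day <- h >= opening_hours[1] && h < opening_hours[2]
      # Night index: nights are anchored at the preceding closing time.
      abs_h <- clock_start_hour + t0 / 3600
      night_idx <- floor((abs_h - opening_hours[2]) / 24)
      mult <- if (day) 1 else
        night_multipliers[(night_idx %% length(night_multipliers)) + 1L]
      rate <- base_rate * mult * (edges[i + 1L] - t0) / 3600
      k <- stats::rpois(1, rate)
      if (k > 0) ons <- c(ons, stats::runif(k, t0, edges[i + 1L]))
    }
    sort(ons)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
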