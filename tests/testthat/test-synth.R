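test_that("rumble synthesis places band energy at the fundamental and first harmonic", {
  sp <- rumble_spec(apex_frequency = 18, duration = 4, n_harmonics = 1,
                    peak_ground_velocity = 5)
  seg <- synth_rumble(sp, 200)
  expect_length(seg, 4 * 200)
  expect_equal(max(abs(seg)), 5, tolerance = 1e-12)
  n <- length(seg)
  p <- (Mod(stats::fft(seg))^2)[seq_len(n %/% 2 + 1)]
  f <- (seq_len(n %/% 2 + 1) - 1) * 200 / n
  band <- function(lo, hi) sum(p[f >= lo & f <= hi])
  # fundamental band dominates, and the harmonic band holds the rest
  expect_gt(band(10, 25), band(25, 45))
  expect_gt(band(25, 45), band(45, 80))
  # within each band the maximum sits at the expected line
  expect_lt(abs(f[f >= 10 & f <= 25][which.max(p[f >= 10 & f <= 25])] - 18), 1)
  expect_lt(abs(f[f >= 25 & f <= 45][which.max(p[f >= 25 & f <= 45])] - 36), 2)
})

test_that("rumble edge cases: zero amplitude, aliasing rejection, inst-frequency apex", {
  sp0 <- rumble_spec(peak_ground_velocity = 0)
  expect_true(all(synth_rumble(sp0, 200) == 0))

  sp_alias <- rumble_spec(apex_frequency = 24, n_harmonics = 4)  # 120 Hz top
  expect_error(synth_rumble(sp_alias, 200), "aliasing")

  # instantaneous-frequency oracle on the isolated fundamental
  sp <- rumble_spec(apex_frequency = 20, duration = 4, n_harmonics = 0,
                    contour_depth = 0.1)
  seg <- synth_rumble(sp, 200)
  fi <- instantaneous_frequency(seg, 200)
  interior <- fi[100:(length(fi) - 100)]
  expect_lt(abs(max(interior) - 20), 0.5)
})

test_that("fundamental band-power maximum recovers the apex for random specs", {
  specs <- draw_rumble_specs(100, t_max = 1e6, seed = 77)
  hits <- vapply(specs, function(sp) {
    sp$n_harmonics <- 0L
    seg <- synth_rumble(sp, 200)
    fpk <- periodogram_peak(seg, 200, f_range = c(5, 30))
    bin <- 200 / length(seg)  # one spectral bin of the periodogram
    abs(fpk - sp$apex_frequency) <= bin + 1e-9
  }, TRUE)
  expect_gte(sum(hits), 99)
  # prior invariants
  apex <- vapply(specs, `[[`, 0, "apex_frequency")
  dur <- vapply(specs, `[[`, 0, "duration")
  pgv <- vapply(specs, `[[`, 0, "peak_ground_velocity")
  expect_true(all(apex >= 10 & apex <= 25))
  expect_true(all(dur >= 1 & dur <= 8))
  expect_true(all(pgv >= 1 & pgv <= 10))
})

test_that("footfalls are broadband, deterministic under seed, and validate input", {
  sp <- footfall_spec(impulse_duration = 0.1, peak_ground_velocity = 8)
  seg1 <- synth_footfall(sp, 200, seed = 3)
  seg2 <- synth_footfall(sp, 200, seed = 3)
  expect_identical(seg1, seg2)
  expect_equal(max(abs(seg1)), 8, tolerance = 1e-12)
  expect_gte(energy_fraction_above(seg1, 200, 20), 0.5)

  expect_true(all(synth_footfall(
    footfall_spec(impulse_duration = 0.1, peak_ground_velocity = 0), 200,
    seed = 1) == 0))
  expect_error(synth_footfall(footfall_spec(impulse_duration = 0.01), 200),
               "4 samples")
})

test_that("noise model reproduces night RMS, day factor and machine lines", {
  nm <- noise_model()
  night <- synth_noise(nm, "seismic", 0, 3600, 200, clock_start_hour = 1,
                       seed = 5)
  expect_equal(sqrt(mean(night^2)), nm$night_rms_seismic, tolerance = 0.05)

  nm7 <- noise_model(day_factor_seismic = 7, machine_line_rms = 0,
                     burst_rate_day = 0)
  day <- synth_noise(nm7, "seismic", 0, 3600, 200, clock_start_hour = 11,
                     seed = 5)
  ratio <- sqrt(mean(day^2)) / sqrt(mean(night^2))
  expect_equal(ratio, 7, tolerance = 0.10)

  # machine lines: fine-resolution daytime spectrum shows >= 10 dB peaks at
  # 12, 25 and 30 Hz relative to neighbouring bins
  day_full <- synth_noise(noise_model(), "seismic", 0, 1200, 200,
                          clock_start_hour = 11, seed = 6)
  m <- compute_spectrogram(trace(day_full, 200), window_length = 4,
                           overlap = 0.5)
  spec <- colMeans(m$power)
  for (f0 in c(12, 25, 30)) {
    i0 <- which.min(abs(m$freq_axis - f0))
    neigh <- mean(spec[c(i0 - 4, i0 - 3, i0 + 3, i0 + 4)])
    expect_gte(10 * log10(spec[i0] / neigh), 10)
  }
})

test_that("rendered scenes keep exact source bookkeeping and seed determinism", {
  cfg <- scene_config(duration = 240, seed = 21, n_rumbles = 5L,
                      n_extra_footfalls = 3L, margin = 20,
                      clock_start_hour = 3)
  sc1 <- render_scene(cfg)
  expect_equal(sum(sc1$truth$type == "rumble"), 5)
  expect_gte(sum(sc1$truth$type == "footfall"), 3)
  expect_false(is.unsorted(sc1$truth$onset_time))

  sc2 <- render_scene(cfg)
  expect_identical(sc1$seismic_Z$samples, sc2$seismic_Z$samples)
  expect_identical(sc1$infrasound$samples, sc2$infrasound$samples)
  expect_identical(sc1$truth, sc2$truth)

  cfg3 <- scene_config(duration = 240, seed = 22, n_rumbles = 5L,
                       n_extra_footfalls = 3L, margin = 20,
                       clock_start_hour = 3)
  sc3 <- render_scene(cfg3)
  expect_false(identical(sc1$seismic_Z$samples, sc3$seismic_Z$samples))
  expect_equal(sum(sc3$truth$type == "rumble"), 5)
})

test_that("an isolated rumble's peak vector ground velocity matches its spec", {
  for (seed in 1:5) {
    sp <- draw_rumble_specs(1, onset_times = 10, seed = seed)[[1]]
    cfg <- scene_config(duration = 40, seed = seed,
                        noise = noise_model(night_rms_seismic = 1e-6,
                                            night_rms_infrasound = 1e-7),
                        rumbles = list(sp), footfalls = list(),
                        clock_start_hour = 2)
    sc <- render_scene(cfg)
    vmag <- sqrt(sc$seismic_N$samples^2 + sc$seismic_E$samples^2 +
                   sc$seismic_Z$samples^2)
    expect_equal(max(vmag), sp$peak_ground_velocity, tolerance = 0.02)
    expect_equal(max(abs(sc$infrasound$samples)), sp$peak_pressure,
                 tolerance = 0.02)
  }
})

test_that("footfalls leave the infrasound channel untouched", {
  base <- list(duration = 180, seed = 31, clock_start_hour = 2,
               rumbles = list())
  cfg_ff <- do.call(scene_config, c(base, list(
    footfalls = lapply(seq(20, 160, by = 20), function(t0)
      footfall_spec(onset_time = t0, peak_ground_velocity = 8)))))
  cfg_quiet <- do.call(scene_config, c(base, list(footfalls = list())))
  sc_ff <- render_scene(cfg_ff)
  sc_quiet <- render_scene(cfg_quiet)
  # identical noise seed: the infrasound channel is bit-identical
  expect_identical(sc_ff$infrasound$samples, sc_quiet$infrasound$samples)
  # ... while the seismic channel is not
  expect_false(identical(sc_ff$seismic_Z$samples, sc_quiet$seismic_Z$samples))
  # cross-correlation of infrasound with the footfall-only component is zero
  ff_comp <- sc_ff$seismic_Z$samples - sc_quiet$seismic_Z$samples
  r <- stats::cor(ff_comp, sc_ff$infrasound$samples)
  expect_lt(abs(r), 0.02)
})

test_that("scene configs load from YAML and JSON with a mandatory seed", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("duration: 120", "seed: 7", "n_rumbles: 2",
               "clock_start_hour: 3",
               "noise:", "  day_factor_seismic: 6"), y)
  cfg <- read_scene_config(y)
  expect_s3_class(cfg, "scene_config")
  expect_equal(cfg$noise$day_factor_seismic, 6)
  expect_identical(render_scene(cfg)$truth,
                   render_scene(cfg)$truth)

  j <- tempfile(fileext = ".json")
  writeLines('{"duration": 60, "n_rumbles": 1}', j)
  expect_error(read_scene_config(j), "seed")
})

test_that("housing-schedule onsets alternate between active and quiet nights", {
  # two full nights: start at 17:00, 48 h; nights are 17:00-07:00
  ons <- sample_rumble_onsets(48 * 3600, base_rate = 6,
                              clock_start_hour = 17,
                              night_multipliers = c(4, 1), seed = 13)
  night1 <- sum(ons < 14 * 3600)
  night2 <- sum(ons >= 24 * 3600 & ons < 38 * 3600)
  expect_gt(night1, 2 * night2)
})
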