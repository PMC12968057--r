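test_that("band-pass preserves in-band tones and rejects out-of-band energy", {
  t <- (0:3999) / 200
  tr40 <- trace(sin(2 * pi * 40 * t), 200)
  y40 <- bandpass_filter(tr40)
  mid <- 1000:3000
  expect_equal(max(abs(y40$samples[mid])), 1, tolerance = 0.05)

  tr02 <- trace(sin(2 * pi * 0.2 * t), 200)
  y02 <- bandpass_filter(tr02)
  atten_db <- 20 * log10(max(abs(y02$samples[mid])))
  expect_lt(atten_db, -20)

  expect_error(bandpass_filter(tr40, 1, 120), "Nyquist")
  expect_error(bandpass_filter(tr40, 0, 80))
  expect_silent(bandpass_filter(tr40, 1, 80))

  # idempotence: a second application changes the RMS by < 1%
  y1 <- bandpass_filter(trace(rnorm(4000), 200))
  y2 <- bandpass_filter(y1)
  expect_lt(abs(sqrt(mean(y2$samples[mid]^2)) /
                  sqrt(mean(y1$samples[mid]^2)) - 1), 0.01)
})

test_that("spectrograms have correct resolution, ridge and energy accounting", {
  fs <- 200
  x <- c(rep(0, 2 * fs), sin(2 * pi * 30 * (0:(4 * fs - 1)) / fs),
         rep(0, 2 * fs))
  m <- compute_spectrogram(trace(x, fs), window_length = 1, overlap = 0.75)
  expect_equal(m$freq_axis[2] - m$freq_axis[1], 1)  # 1/window_length

  ridge <- m$freq_axis[apply(m$power, 1, which.max)]
  on_frames <- m$time_axis > 2.5 & m$time_axis < 5.5
  expect_true(all(ridge[on_frames] == 30))
  # ridge duration ~ tone duration within one time bin's slack
  expect_equal(sum(ridge == 30 & apply(m$power, 1, max) >
                     10 * stats::median(m$power)) * m$hop,
               4, tolerance = 0.3)

  # Parseval: map energy matches signal energy within 1%
  E_map <- sum(m$power) * (m$freq_axis[2] - m$freq_axis[1]) * m$hop
  expect_equal(E_map, sum(x^2) / fs, tolerance = 0.01)

  z <- compute_spectrogram(trace(rep(0, 800), fs))
  expect_true(all(z$power == 0))
  expect_error(compute_spectrogram(trace(rnorm(100), fs), window_length = 1),
               "longer than trace")
})

test_that("component averaging is a cell-wise mean with strict axis checks", {
  tr <- trace(rnorm(2000), 200)
  m <- compute_spectrogram(tr)
  avg_same <- average_component_maps(m, m, m)
  expect_equal(avg_same$power, m$power)

  m1 <- m; m2 <- m; m3 <- m
  m1$power[] <- 1; m2$power[] <- 2; m3$power[] <- 6
  expect_true(all(average_component_maps(m1, m2, m3)$power == 3))
  expect_equal(average_component_maps(m1, m2, m3)$power,
               average_component_maps(m3, m1, m2)$power)

  m_bad <- compute_spectrogram(trace(rnorm(2400), 200))
  expect_error(average_component_maps(m, m, m_bad), "mismatch")
})

test_that("averaging N/E/Z raises the ridge-to-background ratio over one component", {
  fs <- 200
  wins <- 0L
  for (rep_i in 1:10) {
    set.seed(300 + rep_i)
    tone <- 2 * sin(2 * pi * 20 * (0:(12 * fs - 1)) / fs)
    mk <- function(sig) compute_spectrogram(trace(sig + rnorm(12 * fs), fs))
    mN <- mk(0); mE <- mk(0); mZ <- mk(tone)
    avg <- average_component_maps(mN, mE, mZ)
    rr <- function(m) {
      i20 <- which(m$freq_axis == 20)
      mean(m$power[, i20]) / stats::median(m$power)
    }
    if (rr(avg) > rr(mN)) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})

test_that("snippet extraction is centred, exact-length and bounds-checked", {
  tr <- trace(seq_len(200 * 200), 200)  # 200 s ramp
  sn <- extract_snippet(tr, t_pick = 100, length = 12)
  expect_length(sn$samples, 2400)
  expect_equal(sn$start_time, 94)
  expect_equal(sn$samples[1], 94 * 200 + 1)  # sample at t = 94 s
  expect_error(extract_snippet(tr, t_pick = 3), "bounds")
  expect_error(extract_snippet(tr, t_pick = 199), "bounds")
})

test_that("snippet images are exactly 232x115x3, deterministic, single-colour when constant", {
  m <- compute_spectrogram(trace(rnorm(2400), 200))
  img <- render_snippet_image(m)
  expect_identical(dim(img$pixels), c(115L, 232L, 3L))
  img2 <- render_snippet_image(m)
  expect_identical(img$pixels, img2$pixels)

  mc <- m; mc$power[] <- 3.7
  imgc <- render_snippet_image(mc)
  expect_equal(length(unique(as.vector(
    apply(imgc$pixels, 3, function(ch) unique(as.vector(ch)))))), 3)
})

test_that("record scanning windows tile the trace and flag the partial tail", {
  w1000 <- scan_windows(trace(rnorm(1000 * 200), 200))
  expect_equal(nrow(w1000), 5)
  expect_true(all(!w1000$partial))

  w200 <- scan_windows(trace(rnorm(200 * 200), 200))
  expect_equal(nrow(w200), 1)

  w450 <- scan_windows(trace(rnorm(450 * 200), 200))
  expect_equal(w450$start, c(0, 200, 400))
  expect_equal(w450$end, c(200, 400, 450))
  expect_identical(w450$partial, c(FALSE, FALSE, TRUE))
})
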