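test_that("harmonic stacks merge into one rumble; separated events stay apart", {
  ev <- event_table(timestamp = c(0, 0, 0),
                    apex_frequency = c(15, 30, 45), duration = c(4, 4, 4))
  cat1 <- group_events_to_rumbles(ev)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$n_events, 3)
  expect_equal(cat1$fundamental_frequency, 15)

  single <- group_events_to_rumbles(
    event_table(10, 18, 3))
  expect_equal(nrow(single), 1)
  expect_equal(single$fundamental_frequency, 18)

  apart <- group_events_to_rumbles(
    event_table(c(0, 300), c(15, 15), c(4, 4)))
  expect_equal(nrow(apart), 2)

  # same frequencies, overlapping, but a non-integer ratio: not merged
  odd <- group_events_to_rumbles(
    event_table(c(0, 0.5), c(15, 22), c(4, 4)))
  expect_equal(nrow(odd), 2)
})

test_that("interval histogram follows the half-open binning rule", {
  mk <- function(starts) {
    d <- data.frame(start_time = starts, duration = rep(1, length(starts)))
    class(d) <- c("rumble_catalog", "data.frame")
    d
  }
  expect_equal(as.integer(interval_histogram(mk(c(0, 3)))),
               c(1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(as.integer(interval_histogram(mk(c(0, 7)))),
               c(0L, 1L, 0L, 0L, 0L, 1L))
  expect_equal(as.integer(interval_histogram(mk(numeric()))), rep(0L, 6))
  # boundary values land in the right-open bin
  expect_equal(as.integer(interval_histogram(mk(c(0, 5)))),
               c(0L, 1L, 0L, 0L, 0L, 1L))
  # counts always partition the catalog
  for (seed in 1:20) {
    set.seed(seed)
    cat_i <- mk(sort(runif(sample(1:40, 1), 0, 2000)))
    expect_equal(sum(interval_histogram(cat_i)), nrow(cat_i))
  }
})

test_that("motion labeling matches the +/-50 s rule and is order-invariant", {
  mk <- function(starts, durs) {
    d <- data.frame(start_time = starts, duration = durs,
                    motion_label = "unlabeled")
    class(d) <- c("rumble_catalog", "data.frame")
    d
  }
  one <- label_motion(mk(100, 4), footfall_times = 130)
  expect_equal(one$motion_label, "yes")
  far <- label_motion(mk(100, 4), footfall_times = 160)
  expect_equal(far$motion_label, "no")
  # boundary: footfall exactly at start - 50
  expect_equal(label_motion(mk(100, 4), 50)$motion_label, "yes")

  set.seed(99)
  ct <- mk(sort(runif(50, 0, 5000)), runif(50, 1, 8))
  ff <- runif(30, 0, 5000)
  a <- label_motion(ct, ff)
  b <- label_motion(ct, sample(ff))
  expect_identical(a$motion_label, b$motion_label)
})

test_that("activity series conserves counts and aggregates by clock hour", {
  d <- data.frame(start_time = c(100, 500, 3000, 50000),
                  duration = rep(2, 4))
  class(d) <- c("rumble_catalog", "data.frame")
  ser <- activity_series(d, bin_width = 7200, t_range = c(0, 86400))
  expect_equal(sum(ser$count), 4)
  expect_equal(ser$count[1], 3)

  empty <- d[0, ]
  expect_true(all(activity_series(empty, 7200,
                                  t_range = c(0, 86400))$count == 0))

  hod <- activity_series(d, mode = "hour_of_day", clock_start_hour = 0,
                         t_range = c(0, 86400))
  expect_equal(nrow(hod), 24)
  expect_equal(sum(hod$mean_count), 4)  # one day of data
})

test_that("noise profile recovers closed-form RMS values", {
  t <- (0:(7200 * 200 - 1)) / 200
  tone <- trace(sin(2 * pi * 30 * t), 200)
  np <- noise_profile(tone, window = 3600)
  expect_equal(np$rms, rep(1 / sqrt(2), 2), tolerance = 0.01)

  z <- noise_profile(trace(rep(0, 3600 * 200), 200), window = 3600)
  expect_equal(z$rms, 0)
})

test_that("cross-domain matching is exact on degenerate cases and symmetric", {
  mk <- function(ts, fs_) {
    d <- data.frame(start_time = ts, fundamental_frequency = fs_)
    class(d) <- c("rumble_catalog", "data.frame")
    d
  }
  a <- mk(c(10, 50, 90), c(15, 18, 22))
  expect_equal(match_cross_domain(a, a)$n_matched, 3)
  b <- mk(c(1000, 2000), c(15, 18))
  expect_equal(match_cross_domain(a, b)$n_matched, 0)

  set.seed(5)
  for (i in 1:25) {
    x <- mk(sort(runif(8, 0, 300)), runif(8, 10, 25))
    y <- mk(sort(runif(6, 0, 300)), runif(6, 10, 25))
    expect_equal(match_cross_domain(x, y)$n_matched,
                 match_cross_domain(y, x)$n_matched)
  }
})

test_that("greedy matching count agrees with optimal bipartite matching on random catalogs", {
  skip_if_not_installed("igraph")
  mk <- function(ts, fs_) {
    d <- data.frame(start_time = ts, fundamental_frequency = fs_)
    class(d) <- c("rumble_catalog", "data.frame")
    d
  }
  optimal_count <- function(x, y, t_tol = 2, f_tol = 2) {
    ok <- abs(outer(x$start_time, y$start_time, "-")) <= t_tol &
      abs(outer(x$fundamental_frequency, y$fundamental_frequency,
                "-")) <= f_tol
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) == 0) return(0L)
    g <- igraph::graph_from_biadjacency_matrix(ok)
    igraph::max_bipartite_match(g)$matching_size
  }
  set.seed(41)
  agree <- 0L
  for (i in 1:200) {
    ns <- sample(2:12, 1)
    ni <- sample(2:12, 1)
    ts <- sort(runif(ns, 0, 40 * ns))
    x <- mk(ts, runif(ns, 10, 25))
    keep <- sort(sample(ns, ni, replace = ni > ns))
    y <- mk(ts[keep] + runif(ni, -1.5, 1.5),
            x$fundamental_frequency[keep] + runif(ni, -1, 1))
    if (match_cross_domain(x, y)$n_matched == optimal_count(x, y))
      agree <- agree + 1L
  }
  expect_equal(agree, 200L)
})

test_that("histogram intersection behaves on identical, disjoint and mixed inputs", {
  expect_equal(histogram_similarity(c(4, 6, 0), c(4, 6, 0)), 1)
  expect_equal(histogram_similarity(c(1, 0, 0), c(0, 0, 5)), 0)
  expect_equal(histogram_similarity(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 0.5)
  expect_error(histogram_similarity(c(1, 2), c(1, 2, 3)), "bins")
  h1 <- interval_histogram(structure(
    data.frame(start_time = c(0, 3), duration = c(1, 1)),
    class = c("rumble_catalog", "data.frame")))
  expect_equal(histogram_similarity(h1, h1), 1)
})

test_that("event features recover apex, duration and onset from clean spectrograms", {
  fs <- 200
  ok_apex <- ok_dur <- 0L
  for (i in 1:8) {
    sp <- draw_rumble_specs(1, onset_times = 13, seed = 500 + i)[[1]]
    sp$peak_ground_velocity <- max(sp$peak_ground_velocity, 2)  # SNR >= 5
    cfg <- scene_config(duration = 30, seed = 500 + i, rumbles = list(sp),
                        footfalls = list(), clock_start_hour = 2)
    sc <- render_scene(cfg)
    m <- average_component_maps(compute_spectrogram(sc$seismic_N),
                                compute_spectrogram(sc$seismic_E),
                                compute_spectrogram(sc$seismic_Z))
    est <- estimate_event_features(m, 8, 28)
    expect_false(is.null(est))
    if (abs(est$apex_frequency - sp$apex_frequency) <= 1) ok_apex <- ok_apex + 1L
    if (abs(est$duration - sp$duration) <= 0.75) ok_dur <- ok_dur + 1L
  }
  expect_gte(ok_apex, 7)
  expect_gte(ok_dur, 7)

  # pure noise window: no event
  cfg0 <- scene_config(duration = 30, seed = 1234, rumbles = list(),
                       footfalls = list(), clock_start_hour = 2)
  sc0 <- render_scene(cfg0)
  m0 <- compute_spectrogram(sc0$seismic_Z)
  expect_null(estimate_event_features(m0, 8, 28, margin = 8))
})

test_that("catalog CSV round trip preserves values and manual labels", {
  d <- data.frame(start_time = c(10, 60), fundamental_frequency = c(15, 20),
                  duration = c(4, 3), n_events = c(2L, 1L),
                  domain = "seismic", motion_label = c("yes", "not_sure"))
  class(d) <- c("rumble_catalog", "data.frame")
  p <- tempfile(fileext = ".csv")
  write_catalog_csv(d, p)
  d2 <- read_catalog_csv(p)
  expect_equal(d2$start_time, d$start_time)
  expect_equal(d2$motion_label, c("yes", "not_sure"))
})
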