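test_that("trace CSV round trip preserves samples and metadata", {
  tr <- trace(rnorm(400), 200, start_time = 10, channel = "E",
              domain = "seismic")
  p <- tempfile(fileext = ".csv")
  write_trace_csv(tr, p)
  tr2 <- read_trace_csv(p)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-8)
  expect_equal(tr2$sampling_rate, 200)
  expect_equal(tr2$channel, "E")
  expect_equal(tr2$start_time, 10)
})

test_that("waveform reading enforces the sampling-rate contract", {
  p <- tempfile(fileext = ".csv")
  write_trace_csv(trace(rnorm(500), 100, channel = "Z"), p)
  expect_error(read_waveforms(p, expected_fs = 200), "does not match")
  rs <- read_waveforms(p, expected_fs = 200, on_mismatch = "resample")
  expect_equal(rs[[1]]$sampling_rate, 200)
  expect_error(read_waveforms(tempfile(), 200), "not found")

  p2 <- tempfile(fileext = ".csv")
  write_trace_csv(trace(rnorm(400), 200, channel = "P",
                        domain = "infrasound"), p2)
  tl <- read_waveforms(c(p, p2), expected_fs = 200,
                       on_mismatch = "resample")
  expect_length(tl, 2)
  expect_equal(tl[[2]]$domain, "infrasound")
})

test_that("the shipped example scene config loads and validates", {
  p <- system.file("extdata", "example_scene.yaml", package = "rumbleR")
  cfg <- read_scene_config(p)
  expect_s3_class(cfg, "scene_config")
  expect_equal(cfg$duration, 600)
  expect_equal(cfg$noise$opening_hours, c(7, 17))
  expect_equal(cfg$n_rumbles, 6L)
})

test_that("pipeline pre-flight rejects unsatisfiable stage selections", {
  cfg <- pipeline_config(tempfile(), seed = 1,
                         stages = c("simulate", "train"))
  expect_error(run_pipeline(cfg), "pre-flight")
  cfg2 <- pipeline_config(tempfile(), seed = 1,
                          stages = c("simulate", "snippets", "train"),
                          snippet_sizes = c(rumble = 4, noise = 4))
  expect_error(run_pipeline(cfg2), "pre-flight")
  expect_error(pipeline_config(tempfile(), seed = 1, stages = "foo"),
               "unknown stage")
})

test_that("simulate+stats+polarize pipeline writes coherent artifacts and a manifest", {
  out <- file.path(tempfile(), "run1")
  cfg <- pipeline_config(out, seed = 77,
                         stages = c("simulate", "stats", "polarize"),
                         scene = scene_config(duration = 300, seed = 78,
                                              n_rumbles = 4L,
                                              clock_start_hour = 3,
                                              margin = 20),
                         noise_window = 100)
  mf <- suppressMessages(run_pipeline(cfg))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(c("truth_catalog.csv", "interval_histogram.csv",
                    "catalog.csv", "noise_profile.csv",
                    "polarization.csv") %in% names(mf$outputs)))
  truth <- utils::read.csv(file.path(out, "truth_catalog.csv"))
  expect_equal(sum(truth$type == "rumble"), 4)
  ih <- utils::read.csv(file.path(out, "interval_histogram.csv"))
  expect_equal(sum(ih$count), 4)
  pol <- utils::read.csv(file.path(out, "polarization.csv"))
  expect_equal(pol$classification, c("rayleigh_like", "love_like"))
})
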