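test_that("the model matches the prescribed layer sequence and parameter count", {
  m <- build_model(seed = 1)
  layers <- model_layers(m)
  expect_equal(layers$layer,
               c("conv2d", "conv2d", "maxpool", "dropout",
                 "conv2d", "conv2d", "maxpool", "dropout",
                 "conv2d", "conv2d", "maxpool", "dropout",
                 "flatten", "dense", "dropout", "dense_softmax"))
  expect_equal(layers$filters[layers$layer == "conv2d"],
               c(32, 32, 64, 64, 128, 128))
  expect_equal(layers$kernel[layers$layer == "conv2d"], c(5, 5, 3, 3, 5, 5))
  expect_equal(layers$rate[!is.na(layers$rate)], c(0.25, 0.25, 0.25, 0.4))
  expect_equal(n_parameters(m), closed_form_n_params())
})

test_that("initialization is seed-deterministic and probabilities normalize", {
  m1 <- build_model(seed = 9)
  m2 <- build_model(seed = 9)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_model(seed = 10)
  expect_false(identical(m1$weights$dense2_w, m3$weights$dense2_w))

  set.seed(4)
  img <- fake_image("unlabeled", fill = 0L)
  img$pixels[] <- sample(0:255, length(img$pixels), replace = TRUE)
  p <- predict_cnn(m1, list(img))
  expect_equal(dim(p), c(1L, 2L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("backpropagation matches numerical gradients on a reduced input", {
  h <- 24L; w <- 32L
  m <- build_model(seed = 3, input_shape = c(h, w, 3L))
  set.seed(12)
  n <- 3L
  X <- as.raw(sample(0:255, h * w * 3 * n, replace = TRUE))
  y <- c(0L, 1L, 0L)
  sizes <- c(vapply(m$weights$conv_w, length, 0),
             vapply(m$weights$conv_b, length, 0),
             length(m$weights$dense1_w), length(m$weights$dense1_b),
             length(m$weights$dense2_w), length(m$weights$dense2_b))
  tensors <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 9L, 12L, 13L, 14L, 15L)
  idx <- vapply(tensors, function(t) sample(sizes[t + 1], 1) - 1L, 0L)
  gc <- rumbleR:::cpp_cnn_gradcheck(m$weights, X, y, n, h, w, tensors, idx,
                                    1e-5)
  rel <- abs(gc$analytic - gc$numeric) /
    pmax(pmax(abs(gc$analytic), abs(gc$numeric)), 1e-7)
  expect_lt(max(rel), 1e-4)
})

test_that("stratified splits honour the 70/10/20 fractions and the seed", {
  imgs <- c(lapply(1:500, function(i) fake_image("rumble")),
            lapply(1:500, function(i) fake_image("noise")))
  cfg <- train_config(seed = 5)
  sp <- split_dataset(imgs, cfg)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 700L, val = 100L, test = 200L))
  labs <- vapply(sp$test, `[[`, "", "label")
  expect_equal(sum(labs == "rumble"), 100L)

  ten <- c(lapply(1:5, function(i) fake_image("rumble")),
           lapply(1:5, function(i) fake_image("noise")))
  # 10 images: 7 train, 1 val, 2 test after per-class flooring
  sp10 <- split_dataset(c(ten, ten[1:10]), cfg)  # 20 images -> 14/2/4
  expect_equal(lengths(sp10[c("train", "val", "test")]),
               c(train = 14L, val = 2L, test = 4L))

  sp_a <- split_dataset(imgs, cfg)
  expect_identical(sp_a, sp)
  expect_error(split_dataset(lapply(1:20, function(i) fake_image("noise")),
                             cfg), "classes")
})

test_that("evaluation reports are arithmetically consistent", {
  h <- 24L; w <- 32L
  m <- build_model(seed = 6, input_shape = c(h, w, 3L))
  set.seed(21)
  imgs <- lapply(1:20, function(i) {
    im <- fake_image(if (i %% 2) "rumble" else "noise",
                     shape = c(h, w, 3L))
    im$pixels[] <- sample(0:255, h * w * 3, replace = TRUE)
    im
  })
  rep <- evaluate_cnn(m, imgs, "seismic", "seismic")
  expect_equal(sum(rep$confusion_matrix), 20)
  expect_equal(rep$n_test, 20)
  expect_equal(rep$accuracy, sum(diag(rep$confusion_matrix)) / 20)
  expect_error(evaluate_cnn(m, list(fake_image("unlabeled",
                                               shape = c(h, w, 3L)))),
               "unlabeled")
})

test_that("a small synthetic set is learned to high validation accuracy", {
  fit <- small_trained_model()
  m <- fit$model
  expect_lte(nrow(m$history), 30)
  expect_gte(max(m$history$val_acc), 0.95)
  rep <- evaluate_cnn(m, fit$split$test)
  expect_gte(rep$accuracy, 0.85)
})

test_that("continuous scanning respects thresholds, short traces and monotonicity", {
  fit <- small_trained_model()
  m <- fit$model
  sc <- render_scene(scene_config(duration = 120, seed = 55, n_rumbles = 2L,
                                  margin = 20, clock_start_hour = 2))
  traces <- list(sc$seismic_N, sc$seismic_E, sc$seismic_Z)
  det5 <- scan_continuous(traces, m, hop = 4, threshold = 0.5)
  det8 <- scan_continuous(traces, m, hop = 4, threshold = 0.8)
  det10 <- scan_continuous(traces, m, hop = 4, threshold = 1.0)
  expect_gte(nrow(det5), nrow(det8))
  expect_gte(nrow(det8), nrow(det10))
  expect_equal(nrow(det10), 0)
  # the two injected rumbles are found at threshold 0.5
  s <- score_detections(det5, sc$truth$onset_time[sc$truth$type == "rumble"])
  expect_equal(s$recall, 1)

  short <- trace(rnorm(200 * 5), 200)
  expect_warning(d0 <- scan_continuous(short, m), "shorter")
  expect_equal(nrow(d0), 0)
})

test_that("checkpoints round-trip through JSON", {
  m <- build_model(seed = 2, input_shape = c(16L, 16L, 3L))
  p <- tempfile(fileext = ".json")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_equal(m2$input_shape, m$input_shape)
  expect_equal(m2$weights$dense2_w, m$weights$dense2_w, tolerance = 1e-12)
  img <- fake_image("unlabeled", shape = c(16L, 16L, 3L))
  expect_equal(predict_cnn(m, list(img)), predict_cnn(m2, list(img)),
               tolerance = 1e-6)
})
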