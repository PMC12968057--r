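#' Training configuration for the rumble/noise CNN
#'
#' Defaults follow the study protocol: RMSprop with learning rate 0.0005 and
#' epsilon 1e-8, batch size 8, at most 30 epochs with validation-loss early
#' stopping, sparse categorical cross-entropy, and a stratified 70/10/20
#' train/validation/test split.
#'
#' @param learning_rate RMSprop learning rate.
#' @param rho RMSprop moving-average decay.
#' @param epsilon RMSprop numerical-stability constant.
#' @param batch_size Minibatch size.
#' @param max_epochs Hard cap on training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); best weights are restored.
#' @param converge_loss Additional convergence stop: training halts once
#'   validation accuracy is 1 and validation loss falls below this value
#'   (nothing left to learn on separable synthetic sets; without this stop
#'   the patience rule would spend further epochs confirming it).
#' @param split Train/validation/test fractions (must sum to 1).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, rho = 0.9, epsilon = 1e-8,
                         batch_size = 8, max_epochs = 30, patience = 3,
                         converge_loss = 0.05,
                         split = c(train = 0.7, val = 0.1, test = 0.2),
                         seed = 1) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3)
  structure(list(learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 converge_loss = converge_loss, split = split,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build the rumble/noise convolutional network
#'
#' Three convolutional blocks (two 32-filter 5x5 layers; two 64-filter 3x3
#' layers; two 128-filter 5x5 layers), each followed by 2x2 max-pooling and
#' 25% dropout; a dense 128-unit ReLU layer with 40% dropout; and a 2-class
#' softmax output. Convolutions use "same" padding. Initialization is
#' Glorot-uniform, deterministic under the seed.
#'
#' @param seed Integer seed for weight initialization.
#' @param input_shape Image shape `c(height, width, channels)`; default
#'   `c(115, 232, 3)`.
#' @return An object of class `rumble_cnn`.
#' @export
build_model <- function(seed = 1, input_shape = c(115L, 232L, 3L)) {
  stopifnot(length(input_shape) == 3, input_shape[3] == 3)
  if (any(input_shape[1:2] < 8))
    stop("input spatial dimensions too small for three pooling stages")
  weights <- cpp_cnn_init(input_shape[1], input_shape[2], input_shape[3],
                          as.integer(seed))
  structure(list(weights = weights,
                 input_shape = as.integer(input_shape),
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "rumble_cnn")
}

#' Number of trainable parameters of a model
#' @param model A `rumble_cnn`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "rumble_cnn"))
  sum(vapply(rapply(model$weights, length, how = "unlist"), identity, 0))
}

#' Layer summary of the model architecture
#'
#' @param model A `rumble_cnn`.
#' @return A data.frame with one row per layer (type, filters/units, kernel,
#'   dropout rate where applicable).
#' @export
model_layers <- function(model) {
  stopifnot(inherits(model, "rumble_cnn"))
  data.frame(
    layer = c("conv2d", "conv2d", "maxpool", "dropout",
              "conv2d", "conv2d", "maxpool", "dropout",
              "conv2d", "conv2d", "maxpool", "dropout",
              "flatten", "dense", "dropout", "dense_softmax"),
    filters = c(32, 32, NA, NA, 64, 64, NA, NA, 128, 128, NA, NA, NA, 128,
                NA, 2),
    kernel = c(5, 5, 2, NA, 3, 3, 2, NA, 5, 5, 2, NA, NA, NA, NA, NA),
    rate = c(NA, NA, NA, 0.25, NA, NA, NA, 0.25, NA, NA, NA, 0.25, NA, NA,
             0.4, NA))
}

#' @export
print.rumble_cnn <- function(x, ...) {
  cat(sprintf("<rumble_cnn> input %dx%dx%d, %d parameters, %s\n",
              x$input_shape[1], x$input_shape[2], x$input_shape[3],
              n_parameters(x),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# Pack a list of snippet_images into a raw vector for the C++ engine and
# extract integer labels (0 = noise, 1 = rumble).
pack_images <- function(images, input_shape, need_labels = FALSE) {
  stopifnot(length(images) > 0)
  for (im in images) {
    stopifnot(inherits(im, "snippet_image"))
    if (!identical(dim(im$pixels), as.integer(input_shape)))
      stop("image dimensions do not match the model input shape")
  }
  labels <- vapply(images, `[[`, "", "label")
  if (need_labels && any(labels == "unlabeled"))
    stop("unlabeled images in a labeled operation")
  x <- do.call(c, lapply(images, function(im) as.raw(im$pixels)))
  list(x = x, n = length(images),
       y = as.integer(labels == "rumble"))
}

#' Stratified train/validation/test split
#'
#' Splits labeled snippet images per class at the configured fractions
#' (rounded down per class and subset, remainder to train), with seeded
#' shuffling; the three subsets are disjoint.
#'
#' @param images List of labeled `snippet_image`s (both classes present,
#'   at least 10 images per class).
#' @param config A [train_config()].
#' @return A list with elements `train`, `val`, `test` (lists of images).
#' @export
split_dataset <- function(images, config = train_config()) {
  labels <- vapply(images, `[[`, "", "label")
  if (!all(c("rumble", "noise") %in% labels))
    stop("both classes must be present")
  if (min(table(labels)) < 10) stop("need >= 10 images per class")
  out <- list(train = integer(), val = integer(), test = integer())
  with_seed(config$seed, {
    for (cl in c("noise", "rumble")) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_val <- floor(config$split[["val"]] * n)
      n_te <- floor(config$split[["test"]] * n)
      n_tr <- n - n_val - n_te
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$val <- c(out$val, idx[n_tr + seq_len(n_val)])
      out$test <- c(out$test, idx[n_tr + n_val + seq_len(n_te)])
    }
  })
  lapply(out, function(i) images[sort(i)])
}

#' Train the CNN
#'
#' Minibatch RMSprop on the sparse categorical cross-entropy, capped at
#' `max_epochs` with validation-loss early stopping (best weights restored).
#' Deterministic under the config seed.
#'
#' @param model A `rumble_cnn` from [build_model()].
#' @param train_images,val_images Non-empty lists of labeled
#'   `snippet_image`s.
#' @param config A [train_config()].
#' @return The fitted model; `$history` holds per-epoch train/validation loss
#'   and accuracy.
#' @export
train_cnn <- function(model, train_images, val_images,
                      config = train_config()) {
  stopifnot(inherits(model, "rumble_cnn"), length(train_images) > 0,
            length(val_images) > 0)
  tr <- pack_images(train_images, model$input_shape, need_labels = TRUE)
  va <- pack_images(val_images, model$input_shape, need_labels = TRUE)
  fit <- cpp_cnn_train(model$weights, tr$x, tr$y, tr$n, va$x, va$y, va$n,
                       model$input_shape[1], model$input_shape[2],
                       config$learning_rate, config$rho, config$epsilon,
                       config$batch_size, config$max_epochs, config$patience,
                       config$converge_loss, config$seed, FALSE)
  model$weights <- fit$weights
  model$history <- as.data.frame(fit$history)
  model$trained <- TRUE
  model
}

#' Classify snippet images
#'
#' @param model A `rumble_cnn`.
#' @param images List of `snippet_image`s.
#' @return Numeric matrix `n x 2` of class probabilities with columns
#'   `noise` and `rumble` (rows sum to 1).
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "rumble_cnn"))
  pk <- pack_images(images, model$input_shape)
  probs <- cpp_cnn_predict(model$weights, pk$x, pk$n,
                           model$input_shape[1], model$input_shape[2])
  colnames(probs) <- c("noise", "rumble")
  probs
}

#' Evaluate the CNN on a labeled test set
#'
#' @param model A trained `rumble_cnn`.
#' @param test_images Non-empty list of labeled `snippet_image`s.
#' @param train_domain,test_domain Optional domain labels recorded in the
#'   report (for cross-domain bookkeeping).
#' @return An `eval_report`: 2x2 confusion matrix (true class x predicted
#'   class), overall and per-class accuracy, and `n_test`.
#' @export
evaluate_cnn <- function(model, test_images, train_domain = NA_character_,
                         test_domain = NA_character_) {
  stopifnot(length(test_images) > 0)
  pk <- pack_images(test_images, model$input_shape, need_labels = TRUE)
  probs <- predict_cnn(model, test_images)
  pred <- as.integer(probs[, "rumble"] > probs[, "noise"])
  cm <- matrix(0L, 2, 2, dimnames = list(true = c("noise", "rumble"),
                                         predicted = c("noise", "rumble")))
  for (i in seq_along(pred))
    cm[pk$y[i] + 1L, pred[i] + 1L] <- cm[pk$y[i] + 1L, pred[i] + 1L] + 1L
  per_class <- diag(cm) / pmax(1L, rowSums(cm))
  structure(list(confusion_matrix = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 per_class_accuracy = per_class,
                 n_test = sum(cm),
                 train_domain = train_domain, test_domain = test_domain),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s-CNN on %s test (n = %d): accuracy %.3f\n",
              toupper(substr(ifelse(is.na(x$train_domain), "?",
                                    x$train_domain), 1, 1)),
              ifelse(is.na(x$test_domain), "?", x$test_domain), x$n_test,
              x$accuracy))
  print(x$confusion_matrix)
  invisible(x)
}

#' Run the within- and cross-domain training protocol
#'
#' Trains three networks — one on seismic snippets (S-CNN), one on
#' infrasound snippets (I-CNN), and one on the union of both training splits
#' (C-CNN) — and evaluates each on both the seismic and the infrasound test
#' split, yielding six evaluation reports.
#'
#' @param seismic_images,infrasound_images Labeled `snippet_image` lists.
#' @param config A [train_config()]; per-model seeds are derived from its
#'   seed.
#' @return A list of class `protocol_result` with six `eval_report`s named
#'   `S_seismic`, `S_infrasound`, `I_seismic`, `I_infrasound`, `C_seismic`,
#'   `C_infrasound`, plus `train_sizes` and the fitted `models`.
#' @export
run_protocol <- function(seismic_images, infrasound_images,
                         config = train_config()) {
  sp_s <- split_dataset(seismic_images, config)
  sp_i <- split_dataset(infrasound_images,
                        `[[<-`(config, "seed", child_seed(config$seed, 2L)))
  sets <- list(
    S = list(train = sp_s$train, val = sp_s$val),
    I = list(train = sp_i$train, val = sp_i$val),
    C = list(train = c(sp_s$train, sp_i$train), val = c(sp_s$val, sp_i$val)))
  reports <- list()
  models <- list()
  for (nm in names(sets)) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, match(nm, names(sets)) + 10L)
    m <- build_model(seed = cfg$seed)
    m <- train_cnn(m, sets[[nm]]$train, sets[[nm]]$val, cfg)
    models[[nm]] <- m
    dom <- c(S = "seismic", I = "infrasound", C = "combined")[[nm]]
    reports[[paste0(nm, "_seismic")]] <-
      evaluate_cnn(m, sp_s$test, train_domain = dom, test_domain = "seismic")
    reports[[paste0(nm, "_infrasound")]] <-
      evaluate_cnn(m, sp_i$test, train_domain = dom,
                   test_domain = "infrasound")
  }
  structure(c(reports,
              list(train_sizes = c(S = length(sets$S$train),
                                   I = length(sets$I$train),
                                   C = length(sets$C$train)),
                   models = models)),
            class = "protocol_result")
}

#' Scan a continuous record for rumbles
#'
#' Slides 12-s windows along the record at the given hop, renders each
#' window's spectrogram image exactly as in training, classifies it, and
#' merges runs of consecutive above-threshold windows into single detections
#' at the run's peak-score window centre.
#'
#' @param x A single [trace()] (infrasound or one seismic component) or a
#'   list of the three seismic component traces, whose spectrograms are then
#'   averaged before rendering.
#' @param model A trained `rumble_cnn`.
#' @param hop Window hop, seconds.
#' @param threshold Rumble-probability detection threshold in `[0, 1]`.
#' @param snippet_length Window length, seconds (default 12).
#' @param window_length,overlap Spectrogram parameters (must match
#'   training).
#' @return A data.frame of detections with columns `time` (window centre,
#'   seconds) and `score`; attribute `"window_scores"` holds the per-window
#'   score series.
#' @export
scan_continuous <- function(x, model, hop = 4, threshold = 0.5,
                            snippet_length = 12, window_length = 1,
                            overlap = 0.75) {
  stopifnot(inherits(model, "rumble_cnn"), hop > 0)
  traces <- if (inherits(x, "trace")) list(x) else x
  stopifnot(length(traces) %in% c(1L, 3L),
            all(vapply(traces, inherits, TRUE, "trace")))
  domain <- traces[[1]]$domain
  dur <- trace_duration(traces[[1]])
  if (dur < snippet_length) {
    warning("trace shorter than one scan window; no detections")
    return(data.frame(time = numeric(), score = numeric()))
  }
  t0 <- traces[[1]]$start_time
  centers <- seq(t0 + snippet_length / 2, t0 + dur - snippet_length / 2,
                 by = hop)
  images <- lapply(centers, function(tc) {
    maps <- lapply(traces, function(tr)
      compute_spectrogram(extract_snippet(tr, tc, snippet_length),
                          window_length, overlap))
    map <- if (length(maps) == 3L)
      average_component_maps(maps[[1]], maps[[2]], maps[[3]]) else maps[[1]]
    render_snippet_image(map, domain = domain)
  })
  scores <- numeric(length(centers))
  chunk <- 256L
  for (b0 in seq(1L, length(images), by = chunk)) {
    bi <- b0:min(length(images), b0 + chunk - 1L)
    scores[bi] <- predict_cnn(model, images[bi])[, "rumble"]
  }
  above <- scores > threshold
  det_time <- numeric()
  det_score <- numeric()
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    run <- starts[j]:ends[j]
    k <- run[which.max(scores[run])]
    det_time <- c(det_time, centers[k])
    det_score <- c(det_score, scores[k])
  }
  out <- data.frame(time = det_time, score = det_score)
  attr(out, "window_scores") <- data.frame(time = centers, score = scores)
  out
}

#' Synthesize a labeled snippet-image training set
#'
#' Generates 12-s mini-scenes with known content: rumble snippets place a
#' call drawn from the priors at the temporal centre over background noise;
#' noise snippets contain background only, with a fraction of the seismic
#' ones carrying footfall transients (the noise class deliberately includes
#' motion-induced signals). Day and night conditions are mixed so the
#' classifier sees the diurnal noise variability. Seismic snippets are
#' rendered from the average of the three component spectrograms.
#'
#' @param n_rumble,n_noise Number of snippets per class.
#' @param domain `"seismic"` or `"infrasound"`.
#' @param noise A [noise_model()].
#' @param priors Call priors from [rumble_priors()].
#' @param day_fraction Fraction of snippets drawn under daytime noise.
#' @param footfall_frac Fraction of seismic noise snippets containing
#'   footfalls.
#' @param center_jitter Half-range (s) of the uniform offset applied to the
#'   call centre within the window. Sliding-window scanning presents calls
#'   up to half a hop off-centre, so training with matching jitter keeps the
#'   classifier's operating conditions aligned with deployment.
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate, Hz.
#' @return A list of labeled `snippet_image`s (rumbles first).
#' @export
synth_snippet_set <- function(n_rumble, n_noise,
                              domain = c("seismic", "infrasound"),
                              noise = noise_model(), priors = rumble_priors(),
                              day_fraction = 0.5, footfall_frac = 1 / 2,
                              center_jitter = 2, seed = 1,
                              sampling_rate = 200) {
  domain <- match.arg(domain)
  make_one <- function(i, label) {
    sd_i <- child_seed(seed, i + 1000L * (label == "noise"))
    with_seed(sd_i, {
      day <- stats::runif(1) < day_fraction
      clock <- if (day) 12 else 2
      rumbles <- NULL
      footfalls <- list()
      if (label == "rumble") {
        sp <- draw_rumble_specs(1, onset_times = 0, priors = priors)[[1]]
        jit <- stats::runif(1, -center_jitter, center_jitter)
        sp$onset_time <- max(0.25, min(11.75 - sp$duration,
                                       6 - sp$duration / 2 + jit))
        rumbles <- list(sp)
      } else if (domain == "seismic" && stats::runif(1) < footfall_frac) {
        for (k in seq_len(sample(1:3, 1)))
          footfalls[[k]] <- footfall_spec(
            onset_time = stats::runif(1, 0.5, 11),
            impulse_duration = stats::runif(1, 0.05, 0.3),
            peak_ground_velocity = stats::runif(1, 2, 8))
      }
      cfg <- scene_config(duration = 12, seed = child_seed(sd_i, 3L),
                          sampling_rate = sampling_rate,
                          clock_start_hour = clock, noise = noise,
                          rumbles = if (is.null(rumbles)) list() else rumbles,
                          footfalls = footfalls)
      sc <- render_scene(cfg)
      map <- if (domain == "seismic") {
        average_component_maps(compute_spectrogram(sc$seismic_N),
                               compute_spectrogram(sc$seismic_E),
                               compute_spectrogram(sc$seismic_Z))
      } else {
        compute_spectrogram(sc$infrasound)
      }
      render_snippet_image(map, label = label, domain = domain)
    })
  }
  c(lapply(seq_len(n_rumble), make_one, label = "rumble"),
    lapply(seq_len(n_noise), make_one, label = "noise"))
}

#' Save / load model weights as a portable checkpoint
#'
#' Weights are written as a plain JSON checkpoint (portable, text-only).
#'
#' @param model A `rumble_cnn`.
#' @param path Checkpoint file path (`.json`).
#' @return `path` invisibly, or the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rumble_cnn"))
  jsonlite::write_json(
    list(input_shape = model$input_shape, seed = model$seed,
         trained = model$trained, weights = model$weights),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- raw$weights
  w$conv_w <- lapply(w$conv_w, as.matrix)
  w$conv_b <- lapply(w$conv_b, as.numeric)
  w$dense1_w <- as.matrix(w$dense1_w)
  w$dense2_w <- as.matrix(w$dense2_w)
  w$dense1_b <- as.numeric(w$dense1_b)
  w$dense2_b <- as.numeric(w$dense2_b)
  structure(list(weights = w, input_shape = as.integer(raw$input_shape),
                 seed = as.integer(raw$seed),
                 trained = isTRUE(raw$trained), history = NULL),
            class = "rumble_cnn")
}
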