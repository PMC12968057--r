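# Independent oracles and small fixture builders shared across tests.

# Periodogram peak frequency of a segment (oracle for spectral placement):
# returns the frequency of the maximum |FFT|^2 bin within f_range.
periodogram_peak <- function(x, fs, f_range = c(5, 95)) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= f_range[1] & f <= f_range[2] & f <= fs / 2
  f[sel][which.max(p[sel])]
}

# Fraction of signal energy above f0 (band-energy oracle).
energy_fraction_above <- function(x, fs, f0) {
  n <- length(x)
  p <- (Mod(stats::fft(x))^2)[seq_len(n %/% 2 + 1)]
  f <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  sum(p[f > f0]) / sum(p)
}

# Instantaneous frequency via the analytic-signal phase derivative.
instantaneous_frequency <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  h[1] <- 1
  h[2:(n %/% 2)] <- 2
  if (n %% 2 == 0) h[n %/% 2 + 1] <- 1
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- atan2(sin(diff(ph)), cos(diff(ph)))
  dph * fs / (2 * pi)
}

# Brute-force O(n) interval histogram following the stated binning rule.
brute_interval_histogram <- function(starts) {
  counts <- integer(6)
  breaks <- c(0, 5, 10, 30, 60, 120, Inf)
  n <- length(starts)
  if (n == 0) return(counts)
  for (i in seq_len(n)) {
    if (i == n) {
      counts[6] <- counts[6] + 1L
    } else {
      gap <- starts[i + 1] - starts[i]
      for (b in 1:6) {
        if (gap >= breaks[b] && gap < breaks[b + 1]) {
          counts[b] <- counts[b] + 1L
          break
        }
      }
    }
  }
  counts
}

# Brute-force double-loop motion labeling.
brute_label_motion <- function(starts, durations, footfalls, half_window = 50) {
  out <- character(length(starts))
  for (i in seq_along(starts)) {
    hit <- FALSE
    for (f in footfalls) {
      if (f >= starts[i] - half_window &&
          f <= starts[i] + durations[i] + half_window) {
        hit <- TRUE
        break
      }
    }
    out[i] <- if (hit) "yes" else "no"
  }
  out
}

# Brute-force greedy nearest-in-time one-to-one matching (naive loops).
brute_match_count <- function(ts, fs_, ti, fi, t_tol = 2, f_tol = 2) {
  used_s <- logical(length(ts))
  used_i <- logical(length(ti))
  n <- 0L
  repeat {
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_along(ts)) {
      if (used_s[i]) next
      for (j in seq_along(ti)) {
        if (used_i[j]) next
        dt <- abs(ts[i] - ti[j])
        if (dt <= t_tol && abs(fs_[i] - fi[j]) <= f_tol && dt < best) {
          best <- dt
          bi <- i
          bj <- j
        }
      }
    }
    if (!is.finite(best)) break
    used_s[bi] <- TRUE
    used_i[bj] <- TRUE
    n <- n + 1L
  }
  n
}

# Closed-form parameter count of the fixed architecture (computed from the
# layer hyper-parameters and the pooling arithmetic, independent of the
# implementation).
closed_form_n_params <- function(height = 115, width = 232) {
  k <- c(5, 5, 3, 3, 5, 5)
  cin <- c(3, 32, 32, 64, 64, 128)
  cout <- c(32, 32, 64, 64, 128, 128)
  conv <- sum(k^2 * cin * cout + cout)
  h <- height %/% 2 %/% 2 %/% 2
  w <- width %/% 2 %/% 2 %/% 2
  flat <- h * w * 128
  conv + (flat * 128 + 128) + (128 * 2 + 2)
}

# Minimal fake snippet image (for split/evaluate plumbing tests).
fake_image <- function(label, domain = "seismic",
                       shape = c(115L, 232L, 3L), fill = 0L) {
  structure(list(pixels = array(fill, dim = shape), label = label,
                 domain = domain),
            class = "snippet_image")
}

# A small trained model cache shared between classifier tests and the
# acceptance suite (trained once per test run on a small separable set).
.rumbleR_test_env <- new.env(parent = emptyenv())

small_trained_model <- function() {
  if (is.null(.rumbleR_test_env$model)) {
    imgs <- synth_snippet_set(60, 60, "seismic", seed = 11)
    cfg <- train_config(seed = 42)
    sp <- split_dataset(imgs, cfg)
    m <- train_cnn(build_model(seed = 42), sp$train, sp$val, cfg)
    .rumbleR_test_env$model <- m
    .rumbleR_test_env$split <- sp
  }
  list(model = .rumbleR_test_env$model, split = .rumbleR_test_env$split)
}
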