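#' Construct an event-pick table
#'
#' An event is one (frequency, duration) detection: a rumble detectable by
#' its fundamental and two harmonics consists of three events. Event picks
#' carry a timestamp, the frequency at the apex of the event shape, the
#' duration, the sensing domain and the pick source.
#'
#' @param timestamp Numeric vector of event times, seconds.
#' @param apex_frequency Apex frequencies, Hz (within the 1-80 Hz analysis
#'   band).
#' @param duration Durations, s (> 0).
#' @param domain `"seismic"` or `"infrasound"` (recycled).
#' @param source `"manual"`, `"cnn"` or `"truth"` (recycled).
#' @return A data.frame of class `event_table`, sorted by timestamp.
#' @export
event_table <- function(timestamp, apex_frequency, duration,
                        domain = "seismic", source = "truth") {
  stopifnot(all(duration > 0), all(apex_frequency >= 1 & apex_frequency <= 80))
  d <- data.frame(timestamp = timestamp, apex_frequency = apex_frequency,
                  duration = duration, domain = domain, source = source)
  d <- d[order(d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  if (anyDuplicated(d[c("timestamp", "apex_frequency", "domain")]))
    stop("duplicate (timestamp, frequency, domain) event triples")
  class(d) <- c("event_table", "data.frame")
  d
}

#' Group event picks into rumbles
#'
#' A single call radiates its fundamental and harmonics as separate picks.
#' Time-sorted events are merged into one rumble when their time intervals
#' overlap the group's common window and their frequency ratio to the
#' group's lowest frequency is within `freq_ratio_tol` of an integer; all
#' other events form singleton rumbles.
#'
#' @param events An [event_table()] (time-sorted).
#' @param freq_ratio_tol Tolerance on the harmonic (integer) frequency
#'   ratio.
#' @param time_overlap_required Require time overlap for merging (default
#'   TRUE).
#' @return A data.frame of class `rumble_catalog` sorted by `start_time`,
#'   with columns `start_time`, `fundamental_frequency` (lowest member),
#'   `duration` (longest member), `n_events`, `domain`, `motion_label`
#'   (initialized `"unlabeled"`); attribute `"members"` lists member event
#'   row indices.
#' @export
group_events_to_rumbles <- function(events, freq_ratio_tol = 0.15,
                                    time_overlap_required = TRUE) {
  stopifnot(is.data.frame(events))
  n <- nrow(events)
  groups <- list()
  # running state per group: member rows, fundamental, intersection window
  for (i in seq_len(n)) {
    t0 <- events$timestamp[i]
    t1 <- t0 + events$duration[i]
    f <- events$apex_frequency[i]
    joined <- FALSE
    for (g in seq_along(groups)) {
      gr <- groups[[g]]
      overlap <- t0 < gr$win_end && t1 > gr$win_start
      if (time_overlap_required && !overlap) next
      fund <- min(gr$fund, f)
      ratios <- c(events$apex_frequency[gr$members], f) / fund
      ok <- all(abs(ratios - round(ratios)) <= freq_ratio_tol * round(ratios) &
                  round(ratios) >= 1)
      if (ok) {
        gr$members <- c(gr$members, i)
        gr$fund <- fund
        gr$win_start <- max(gr$win_start, t0)
        gr$win_end <- min(gr$win_end, t1)
        groups[[g]] <- gr
        joined <- TRUE
        break
      }
    }
    if (!joined)
      groups[[length(groups) + 1L]] <- list(members = i, fund = f,
                                            win_start = t0, win_end = t1)
  }
  cat_df <- do.call(rbind, lapply(groups, function(gr) {
    m <- gr$members
    data.frame(start_time = min(events$timestamp[m]),
               fundamental_frequency = gr$fund,
               duration = max(events$duration[m]),
               n_events = length(m),
               domain = events$domain[m[1]],
               motion_label = "unlabeled")
  }))
  if (is.null(cat_df))
    cat_df <- data.frame(start_time = numeric(),
                         fundamental_frequency = numeric(),
                         duration = numeric(), n_events = integer(),
                         domain = character(), motion_label = character())
  o <- order(cat_df$start_time)
  cat_df <- cat_df[o, , drop = FALSE]
  rownames(cat_df) <- NULL
  attr(cat_df, "members") <- lapply(groups, `[[`, "members")[o]
  class(cat_df) <- c("rumble_catalog", "data.frame")
  cat_df
}

interval_bin_labels <- c("<5s", "5-10s", "10-30s", "30-60s", "60-120s",
                         ">120s")

#' Inter-rumble interval histogram
#'
#' For each rumble, the gap to the next rumble (start-to-start) is assigned
#' to one of six half-open bins `[0,5)`, `[5,10)`, `[10,30)`, `[30,60)`,
#' `[60,120)`, `[120,Inf)` seconds; the final rumble, having no successor,
#' counts in the `>120 s` bin, so counts always sum to the catalog size.
#'
#' @param catalog A `rumble_catalog` (or any data.frame with sorted
#'   `start_time`).
#' @param anchor `"start"` (default, start-to-start gaps) or `"end"`
#'   (end-to-start).
#' @return An object of class `interval_histogram`: a named integer vector
#'   of six counts.
#' @export
interval_histogram <- function(catalog, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  breaks <- c(0, 5, 10, 30, 60, 120, Inf)
  counts <- integer(6)
  n <- nrow(catalog)
  if (n > 0) {
    if (n > 1) {
      from <- catalog$start_time[-n] +
        if (anchor == "end") catalog$duration[-n] else 0
      gaps <- pmax(0, catalog$start_time[-1] - from)
      counts <- as.integer(table(cut(gaps, breaks, right = FALSE,
                                     labels = interval_bin_labels)))
    }
    counts[6] <- counts[6] + 1L  # final rumble: no successor within 120 s
  }
  structure(stats::setNames(counts, interval_bin_labels),
            breaks = breaks, class = "interval_histogram")
}

#' Label rumbles by coincident locomotion signals
#'
#' A rumble is labeled `"yes"` when at least one footfall time falls within
#' `half_window` seconds before its start or after its end, `"no"`
#' otherwise. (`"not_sure"` encodes human uncertainty and is only preserved
#' when reading pre-existing manual labels from file; the automated labeler
#' is binary.)
#'
#' @param catalog A `rumble_catalog`.
#' @param footfall_times Sorted numeric vector of footfall times, seconds.
#' @param half_window Coincidence half-window, seconds (default 50).
#' @return The catalog with `motion_label` filled in.
#' @export
label_motion <- function(catalog, footfall_times, half_window = 50) {
  ft <- sort(footfall_times)
  if (nrow(catalog) == 0) return(catalog)
  lo <- catalog$start_time - half_window
  hi <- catalog$start_time + catalog$duration + half_window
  has <- if (length(ft) == 0) rep(FALSE, nrow(catalog)) else
    findInterval(hi, ft) > findInterval(lo, ft, left.open = TRUE)
  catalog$motion_label <- ifelse(has, "yes", "no")
  catalog
}

#' Rumble activity time series
#'
#' Counts rumble starts per contiguous time bin; optionally aggregates to a
#' mean hour-of-day profile across days.
#'
#' @param catalog A `rumble_catalog`.
#' @param bin_width Bin width, seconds (e.g. 7200 for two-hour windows).
#' @param t_range Time range `c(t0, t1)` covered (defaults to the catalog
#'   span, snapped to whole bins from `t0`).
#' @param mode `"series"` (counts per bin) or `"hour_of_day"` (mean count
#'   per clock hour across days).
#' @param clock_start_hour Hour of day at time 0 (for `"hour_of_day"`).
#' @return A data.frame: `start`, `count` for `"series"`; `hour`,
#'   `mean_count` for `"hour_of_day"`.
#' @export
activity_series <- function(catalog, bin_width = 7200, t_range = NULL,
                            mode = c("series", "hour_of_day"),
                            clock_start_hour = 0) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0)
  ts <- catalog$start_time
  if (is.null(t_range))
    t_range <- if (length(ts) == 0) c(0, bin_width) else
      c(min(ts), max(ts) + 1e-9)
  if (mode == "series") {
    edges <- seq(t_range[1], t_range[2] + bin_width, by = bin_width)
    counts <- as.integer(table(cut(ts, edges, right = FALSE)))
    return(data.frame(start = edges[-length(edges)], count = counts))
  }
  hours <- floor(scene_hour(ts, clock_start_hour))
  day_idx <- floor((clock_start_hour + ts / 3600) / 24)
  n_days <- max(1, floor((clock_start_hour * 3600 + t_range[2] - 1e-9) / 86400) -
                  floor((clock_start_hour * 3600 + t_range[1]) / 86400) + 1)
  tab <- table(factor(hours, levels = 0:23))
  data.frame(hour = 0:23, mean_count = as.numeric(tab) / n_days)
}

#' Band-limited RMS noise profile
#'
#' Band-passes the trace to the analysis band and computes the RMS amplitude
#' per consecutive window — the noise metric used to track the diurnal noise
#' level.
#'
#' @param x A [trace()].
#' @param window Window length, seconds (default 3600).
#' @param f_lo,f_hi Band corners, Hz.
#' @return A data.frame with columns `start` (window start, s) and `rms`.
#' @export
noise_profile <- function(x, window = 3600, f_lo = 1, f_hi = 80) {
  stopifnot(inherits(x, "trace"))
  if (trace_duration(x) < window) stop("trace shorter than one window")
  y <- bandpass_filter(x, f_lo, f_hi)
  fs <- x$sampling_rate
  n_win <- floor(length(y$samples) / (window * fs))
  starts <- (seq_len(n_win) - 1L) * window
  rms <- vapply(starts, function(s) {
    idx <- (s * fs + 1L):((s + window) * fs)
    sqrt(mean(y$samples[idx]^2))
  }, 0)
  data.frame(start = x$start_time + starts, rms = rms)
}

#' Match rumbles across the seismic and infrasound catalogs
#'
#' Greedy one-to-one matching: among all cross-domain pairs within both the
#' time and frequency tolerances, repeatedly accept the pair with the
#' smallest time difference (ties broken by catalog order) until no
#' compatible pair remains. Symmetric in the matched count under argument
#' swap.
#'
#' @param catalog_seismic,catalog_infrasound `rumble_catalog`s (sorted).
#' @param t_tol Time tolerance on start times, seconds.
#' @param f_tol Frequency tolerance on fundamentals, Hz.
#' @return A list: `pairs` (data.frame of matched row indices `seismic`,
#'   `infrasound` and `dt`), `n_matched`, `n_seismic_only`,
#'   `n_infrasound_only`.
#' @export
match_cross_domain <- function(catalog_seismic, catalog_infrasound,
                               t_tol = 2, f_tol = 2) {
  ns <- nrow(catalog_seismic)
  ni <- nrow(catalog_infrasound)
  if (ns == 0 || ni == 0) {
    return(list(pairs = data.frame(seismic = integer(),
                                   infrasound = integer(), dt = numeric()),
                n_matched = 0L, n_seismic_only = ns, n_infrasound_only = ni))
  }
  dt <- abs(outer(catalog_seismic$start_time,
                  catalog_infrasound$start_time, "-"))
  df <- abs(outer(catalog_seismic$fundamental_frequency,
                  catalog_infrasound$fundamental_frequency, "-"))
  ok <- dt <= t_tol & df <= f_tol
  cand <- which(ok, arr.ind = TRUE)
  o <- order(dt[ok], cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  used_s <- logical(ns)
  used_i <- logical(ni)
  pairs <- matrix(0L, 0, 2)
  dts <- numeric()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_s[i] && !used_i[j]) {
      used_s[i] <- TRUE
      used_i[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
      dts <- c(dts, dt[i, j])
    }
  }
  list(pairs = data.frame(seismic = pairs[, 1], infrasound = pairs[, 2],
                          dt = dts),
       n_matched = nrow(pairs),
       n_seismic_only = ns - nrow(pairs),
       n_infrasound_only = ni - nrow(pairs))
}

#' Histogram intersection similarity
#'
#' Normalizes both histograms to unit mass and sums the bin-wise minima:
#' 1 for identical distributions, 0 for disjoint supports.
#'
#' @param h1,h2 Numeric count vectors over identical bins (e.g. two
#'   [interval_histogram()]s, or binned duration/frequency counts from the
#'   two domains).
#' @return Similarity score in `[0, 1]`.
#' @export
histogram_similarity <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("histograms have different numbers of bins")
  b1 <- attr(h1, "breaks")
  b2 <- attr(h2, "breaks")
  if (!is.null(b1) && !is.null(b2) && !isTRUE(all.equal(b1, b2)))
    stop("histograms have different bin edges")
  s1 <- sum(h1); s2 <- sum(h2)
  if (s1 == 0 || s2 == 0) return(0)
  sum(pmin(h1 / s1, h2 / s2))
}

#' Estimate event features from a spectrogram window
#'
#' Tracks the per-frame band-power ridge inside a detection window: the apex
#' frequency is the ridge frequency at the ridge-power maximum; the duration
#' is the contiguous span around the maximum where the ridge exceeds both
#' the per-frequency background (median over the window) by a margin and a
#' fixed fraction of the ridge's peak power (so the measured duration stays
#' anchored to the call envelope rather than growing with SNR); the
#' timestamp is the ridge-power centroid of that span.
#'
#' @param map A `tfmap` (linear scale).
#' @param t_start,t_end Detection window bounds, seconds.
#' @param freq_range Search band, Hz.
#' @param margin Ridge-to-background power factor required for signal
#'   presence (default 5).
#' @param min_duration Minimum tonal duration, seconds (default 0.75):
#'   shorter above-margin runs are treated as noise excursions, which
#'   single frames in pure noise readily produce.
#' @param peak_fraction Fraction of the ridge's peak power a frame must
#'   exceed to count toward the duration (default 0.1, i.e. within 10 dB
#'   of the peak).
#' @return A one-row data.frame (`timestamp`, `apex_frequency`, `duration`)
#'   or `NULL` when no sufficiently long ridge exceeds the margin (no
#'   event).
#' @export
estimate_event_features <- function(map, t_start, t_end,
                                    freq_range = c(1, 80), margin = 5,
                                    min_duration = 0.75,
                                    peak_fraction = 0.1) {
  stopifnot(inherits(map, "tfmap"), map$scale == "linear")
  fr <- which(map$freq_axis >= freq_range[1] & map$freq_axis <= freq_range[2])
  tf <- which(map$time_axis >= t_start & map$time_axis <= t_end)
  if (length(tf) < 2 || length(fr) < 2)
    stop("detection window outside map")
  p <- map$power[tf, fr, drop = FALSE]
  bg <- apply(p, 2, stats::median)
  ridge_bin <- apply(p, 1, which.max)
  ridge_pow <- p[cbind(seq_len(nrow(p)), ridge_bin)]
  present <- ridge_pow > margin * pmax(bg[ridge_bin], 1e-30)
  if (!any(present)) return(NULL)
  k_max <- which.max(ifelse(present, ridge_pow, -Inf))
  present <- present & ridge_pow > peak_fraction * ridge_pow[k_max]
  run_lo <- k_max
  while (run_lo > 1 && present[run_lo - 1]) run_lo <- run_lo - 1
  run_hi <- k_max
  while (run_hi < length(present) && present[run_hi + 1]) run_hi <- run_hi + 1
  run <- run_lo:run_hi
  tt <- map$time_axis[tf]
  hop <- if (length(tt) > 1) tt[2] - tt[1] else map$hop
  if ((run_hi - run_lo) * hop + hop < min_duration) return(NULL)
  data.frame(
    timestamp = sum(tt[run] * ridge_pow[run]) / sum(ridge_pow[run]),
    apex_frequency = map$freq_axis[fr][ridge_bin[k_max]],
    duration = (run_hi - run_lo) * hop + hop)
}

#' Score continuous-scan detections against a truth catalog
#'
#' A truth rumble is recovered when any detection lies within `tol` seconds
#' of its onset; a detection is a true positive when it lies within `tol`
#' seconds of any truth onset.
#'
#' @param detections Data.frame from [scan_continuous()].
#' @param truth_onsets Numeric vector of true rumble onset times, seconds.
#' @param tol Matching tolerance, seconds (default 6, half a scan window).
#' @return A list: `recall`, `precision`, `n_truth`, `n_detections`,
#'   `n_recovered`, `n_true_positive`.
#' @export
score_detections <- function(detections, truth_onsets, tol = 6) {
  n_truth <- length(truth_onsets)
  n_det <- nrow(detections)
  recovered <- vapply(truth_onsets, function(t0)
    any(abs(detections$time - t0) <= tol), TRUE)
  tp <- if (n_det == 0) logical(0) else
    vapply(detections$time, function(td)
      any(abs(truth_onsets - td) <= tol), TRUE)
  list(recall = if (n_truth) mean(recovered) else NA_real_,
       precision = if (n_det) mean(tp) else NA_real_,
       n_truth = n_truth, n_detections = n_det,
       n_recovered = sum(recovered), n_true_positive = sum(tp))
}

#' Write / read a rumble catalog as CSV
#'
#' Columns: `start_time` (s), `fundamental_frequency_hz`, `duration_s`,
#' `n_events`, `domain`, `motion_label`. Manual `"not_sure"` motion labels
#' in a file are preserved on reading.
#'
#' @param catalog A `rumble_catalog`.
#' @param path CSV path.
#' @return `path` invisibly / the catalog.
#' @export
write_catalog_csv <- function(catalog, path) {
  d <- data.frame(start_time = catalog$start_time,
                  fundamental_frequency_hz = catalog$fundamental_frequency,
                  duration_s = catalog$duration,
                  n_events = catalog$n_events,
                  domain = catalog$domain,
                  motion_label = catalog$motion_label)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_csv
#' @export
read_catalog_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(d$motion_label %in% c("yes", "no", "not_sure", "unlabeled")))
  out <- data.frame(start_time = d$start_time,
                    fundamental_frequency = d$fundamental_frequency_hz,
                    duration = d$duration_s, n_events = d$n_events,
                    domain = d$domain, motion_label = d$motion_label)
  class(out) <- c("rumble_catalog", "data.frame")
  out
}
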