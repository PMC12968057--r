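#' Construct a uniformly sampled waveform trace
#'
#' A `trace` is the carrier of all raw signal in the package: a uniformly
#' sampled amplitude series with channel and domain metadata. Seismic traces
#' carry ground velocity in micrometres per second (um/s); infrasound traces
#' carry pressure in pascal (Pa).
#'
#' @param samples Numeric vector of amplitudes (um/s for seismic, Pa for
#'   infrasound).
#' @param sampling_rate Sampling rate in Hz (default 200, the deployment rate
#'   of both sensors).
#' @param start_time Start time of the first sample, in seconds. Scene-relative
#'   time starts at 0; absolute (UTC epoch) seconds are equally valid.
#' @param channel One of `"N"`, `"E"`, `"Z"` (seismic components) or `"P"`
#'   (pressure).
#' @param domain `"seismic"` or `"infrasound"`.
#' @return An object of class `trace`.
#' @export
trace <- function(samples, sampling_rate = 200, start_time = 0,
                  channel = c("Z", "N", "E", "P"),
                  domain = c("seismic", "infrasound")) {
  channel <- match.arg(channel)
  domain <- match.arg(domain)
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sampling_rate), sampling_rate > 0)
  if (domain == "infrasound" && channel != "P")
    stop("infrasound traces use channel 'P'")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time),
         channel = channel,
         domain = domain),
    class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s/%s: %d samples @ %g Hz, t = [%g, %g) s, units %s\n",
              x$domain, x$channel, length(x$samples), x$sampling_rate,
              x$start_time, x$start_time + trace_duration(x),
              trace_units(x)))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param x A `trace`.
#' @return Numeric scalar, seconds.
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "trace"))
  length(x$samples) / x$sampling_rate
}

trace_units <- function(x) if (x$domain == "seismic") "um/s" else "Pa"

#' Time axis of a trace
#' @param x A `trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$start_time + (seq_along(x$samples) - 1L) / x$sampling_rate
}

#' Write a trace to CSV (time, amplitude)
#'
#' Plain-text waveform interchange. The header row records channel, domain and
#' sampling rate as a comment-style first line so a round trip preserves
#' metadata.
#'
#' @param x A `trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#channel=%s,domain=%s,sampling_rate=%.10g,start_time=%.10g",
                     x$channel, x$domain, x$sampling_rate, x$start_time), con)
  writeLines("time,amplitude", con)
  tt <- trace_times(x)
  writeLines(paste(sprintf("%.6f", tt), sprintf("%.9g", x$samples), sep = ","),
             con)
  invisible(path)
}

#' Read a trace from CSV written by [write_trace_csv()]
#' @param path CSV file path.
#' @return A `trace`.
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    stop("not a trace CSV (missing metadata header): ", path)
  kv <- strsplit(sub("^#", "", hdr), ",")[[1]]
  meta <- stats::setNames(
    vapply(strsplit(kv, "="), `[`, "", 2L),
    vapply(strsplit(kv, "="), `[`, "", 1L))
  d <- utils::read.csv(path, skip = 1L)
  trace(d$amplitude,
        sampling_rate = as.numeric(meta[["sampling_rate"]]),
        start_time = as.numeric(meta[["start_time"]]),
        channel = meta[["channel"]],
        domain = meta[["domain"]])
}

#' Read waveform files with a sampling-rate contract
#'
#' Reads one or more trace CSV files and verifies the sampling rate matches
#' the expected deployment rate. Mismatches are rejected or resampled (by
#' linear interpolation) according to `on_mismatch`.
#'
#' @param paths Character vector of file paths.
#' @param expected_fs Expected sampling rate in Hz (default 200).
#' @param on_mismatch `"reject"` (default) or `"resample"`.
#' @return A list of `trace` objects.
#' @export
read_waveforms <- function(paths, expected_fs = 200,
                           on_mismatch = c("reject", "resample")) {
  on_mismatch <- match.arg(on_mismatch)
  lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    tr <- read_trace_csv(p)
    if (!isTRUE(all.equal(tr$sampling_rate, expected_fs))) {
      if (on_mismatch == "reject")
        stop(sprintf("sampling rate %g Hz in %s does not match expected %g Hz",
                     tr$sampling_rate, p, expected_fs))
      tt <- trace_times(tr)
      n_new <- max(2L, floor((utils::tail(tt, 1) - tr$start_time) * expected_fs) + 1L)
      t_new <- tr$start_time + (seq_len(n_new) - 1L) / expected_fs
      tr <- trace(stats::approx(tt, tr$samples, xout = t_new, rule = 2)$y,
                  sampling_rate = expected_fs, start_time = tr$start_time,
                  channel = tr$channel, domain = tr$domain)
    }
    tr
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a base seed (kept within 32-bit
# signed range).
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}
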