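# Synchronization and preprocessing: detect the three-clap pattern, estimate
# the true sampling rate from the inter-burst sample count and the video
# duration, and resample streams to a uniform 200 Hz axis.

#' Detect the three-clap synchronization bursts
#'
#' A rule-based detector for the characteristic synchronization movement: the
#' sensor rod clapped to the ground three times in a row, producing three
#' clearly visible peaks in all accelerometer axes. A burst qualifies only if
#' three peaks above `threshold` occur within `span` seconds on *all three*
#' accelerometer axes (peak times coincide across axes up to `axis_tol`
#' samples).
#'
#' @param stream A [sensor_stream()] in physical units (g).
#' @param threshold Clap amplitude threshold in g.
#' @param span Maximum burst duration in seconds.
#' @param axis_tol Cross-axis peak alignment tolerance in samples.
#' @return A list of class `sync_result`: `start_index` / `end_index` (first
#'   clap sample of the leading and trailing burst, 1-based) and
#'   `n_samples_between`.
#' @export
detect_sync_claps <- function(stream, threshold = 8, span = 2, axis_tol = 5) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (stream$scaled)
    stop("detect_sync_claps expects a stream in physical units", call. = FALSE)
  rate <- stream$rate
  acc <- accel_data(stream)
  min_sep <- round(0.1 * rate) # claps are >= 0.1 s apart
  peaks_per_axis <- lapply(1:3, function(k)
    .local_maxima(abs(acc[, k]), threshold, min_sep))
  # a clap must appear on all three axes at (nearly) the same sample
  base <- peaks_per_axis[[1]]
  on_all <- base[vapply(base, function(p)
    all(vapply(peaks_per_axis[2:3], function(q)
      any(abs(q - p) <= axis_tol), logical(1))), logical(1))]
  bursts <- .group_bursts(on_all, span * rate)
  if (length(bursts) < 2)
    stop("sync failed: fewer than 2 qualifying three-peak bursts found", call. = FALSE)
  first <- bursts[[1]]
  last <- bursts[[length(bursts)]]
  structure(list(start_index = first[1], end_index = last[1],
                 n_samples_between = last[1] - first[1]),
            class = "sync_result")
}

# indices of local maxima of x above `thr`, thinned to >= min_sep apart
.local_maxima <- function(x, thr, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- integer(0)
  for (i in cand[order(-x[cand], cand)]) {
    if (all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# group sorted peak indices into runs of >= 3 peaks spanning <= span samples;
# returns list of index vectors (one per qualifying burst)
.group_bursts <- function(peaks, span) {
  if (length(peaks) < 3) return(list())
  bursts <- list()
  i <- 1
  while (i <= length(peaks) - 2) {
    j <- i
    while (j < length(peaks) && peaks[j + 1] - peaks[i] <= span) j <- j + 1
    if (j - i + 1 >= 3) {
      bursts[[length(bursts) + 1]] <- peaks[i:j]
      i <- j + 1
    } else i <- i + 1
  }
  bursts
}

#' Estimate the true sampling rate
#'
#' The nominal sensor rate drifts; the realised rate is estimated as the
#' number of samples between the detected synchronization claps divided by
#' the recording duration between the same claps extracted from the video.
#'
#' @param n_samples_between Samples between the first claps of the two bursts.
#' @param video_duration_s Elapsed video time between the same claps, seconds.
#' @return Estimated rate in Hz.
#' @export
estimate_sampling_rate <- function(n_samples_between, video_duration_s) {
  if (!is.numeric(n_samples_between) || n_samples_between <= 0)
    stop("n_samples_between must be positive", call. = FALSE)
  if (!is.numeric(video_duration_s) || video_duration_s <= 0)
    stop("video_duration_s must be positive", call. = FALSE)
  n_samples_between / video_duration_s
}

#' Resample a stream to a uniform target rate
#'
#' Rebuilds the true time axis from the estimated sampling rate (sample `i`
#' occurred at `(i-1)/estimated_rate` seconds) and linearly interpolates each
#' channel onto a uniform grid at `target_rate`. Duration is preserved within
#' one sample period.
#'
#' @param stream A [sensor_stream()].
#' @param estimated_rate Realised rate in Hz (from [estimate_sampling_rate()]).
#' @param target_rate Target rate in Hz (default 200).
#' @param band Plausibility band: `estimated_rate` must lie within
#'   `band` x 100 percent of `target_rate` (default 5 percent).
#' @return The resampled [sensor_stream()] at `target_rate`.
#' @export
resample_to_uniform <- function(stream, estimated_rate, target_rate = 200,
                                band = 0.05) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (abs(estimated_rate - target_rate) > band * target_rate)
    stop(sprintf("estimated rate %.2f Hz outside +-%.0f%% band around %g Hz",
                 estimated_rate, 100 * band, target_rate), call. = FALSE)
  n <- n_samples(stream)
  true_times <- (seq_len(n) - 1) / estimated_rate
  dur <- true_times[n]
  new_times <- seq(0, dur, by = 1 / target_rate)
  out <- matrix(0, length(new_times), 6)
  for (k in 1:6) {
    out[, k] <- stats::approx(true_times, stream$data[, k], xout = new_times,
                              rule = 2)$y
  }
  sensor_stream(new_times, out, rate = target_rate, scaled = stream$scaled)
}
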