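# Candidate selection: moving-window segmentation of the continuous stream,
# Butterworth high-pass + signal-magnitude-vector peak detection, and
# ground-truth label assignment for the resulting 2 s candidate windows.

WINDOW_LEN <- 400L   # 2 s at 200 Hz
LABEL_HALF <- 0.5    # label window: 1 s around the peak

#' High-pass filter the gyroscope channels
#'
#' Butterworth high-pass (default order 2, cutoff 20 Hz) applied causally to
#' each gyroscope channel. The causal (forward-only) filter mirrors what a
#' deployable on-line pipeline sees; set `zero_phase = TRUE` for
#' forward-backward filtering when phase distortion matters.
#'
#' @param stream A [sensor_stream()] at a uniform rate.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order.
#' @param zero_phase Use forward-backward filtering instead of causal.
#' @return n x 3 matrix of filtered gyroscope channels.
#' @export
highpass_gyro <- function(stream, cutoff = 20, order = 2, zero_phase = FALSE) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- n_samples(stream)
  warmup <- 3 * (order + 1)
  if (n <= 3 * warmup)
    stop("stream too short for filter warm-up (", n, " samples)", call. = FALSE)
  bf <- signal::butter(order, cutoff / (stream$rate / 2), type = "high")
  g <- gyro_data(stream)
  out <- matrix(0, n, 3)
  for (k in 1:3) {
    out[, k] <- if (zero_phase) signal::filtfilt(bf, g[, k])
                else as.numeric(signal::filter(bf, g[, k]))
  }
  colnames(out) <- c("gx", "gy", "gz")
  out
}

#' Signal magnitude vector
#'
#' Per-sample Euclidean norm across the three (filtered) gyroscope axes.
#'
#' @param g n x 3 matrix of gyroscope channels.
#' @return Numeric vector of length n.
#' @export
smv <- function(g) {
  g <- as.matrix(g)
  if (ncol(g) != 3)
    stop("smv expects 3 equal-length channels (got ", ncol(g), ")", call. = FALSE)
  sqrt(rowSums(g^2))
}

#' Moving-window start indices
#'
#' Fixed-length moving windows (default 2 s) with fractional overlap (default
#' 25 percent), i.e. a stride of `length * (1 - overlap)` samples. The last
#' partial window is dropped.
#'
#' @param n Stream length in samples (or a [sensor_stream()]).
#' @param length Window length in samples.
#' @param overlap Fractional overlap in \[0, 1).
#' @return Integer vector of 1-based window start indices (possibly empty).
#' @export
moving_windows <- function(n, length = WINDOW_LEN, overlap = 0.25) {
  if (inherits(n, "sensor_stream")) n <- n_samples(n)
  stride <- as.integer(round(length * (1 - overlap)))
  if (n < length) return(integer(0))
  seq.int(1L, n - length + 1L, by = stride)
}

#' Detect super-threshold peaks in an SMV window
#'
#' Local maxima above `threshold_frac` times the window maximum, greedily
#' thinned so that kept peaks are at least `min_distance` samples apart
#' (higher peak wins; ties break to the earlier index). An all-zero window
#' yields no peaks (the relative threshold would otherwise fire everywhere).
#'
#' @param x Numeric SMV values of one window.
#' @param threshold_frac Peak threshold as a fraction of `max(x)`.
#' @param min_distance Minimum distance between kept peaks, samples.
#' @return Integer vector of 1-based peak indices within the window.
#' @export
detect_peaks <- function(x, threshold_frac = 0.3, min_distance = 300) {
  n <- length(x)
  mx <- max(x)
  if (n < 3 || mx <= 0) return(integer(0))
  thr <- threshold_frac * mx
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (x[1] > x[2] && x[1] > thr) cand <- c(1L, cand)
  if (x[n] > x[n - 1] && x[n] > thr) cand <- c(cand, n)
  if (length(cand) <= 1) return(cand)
  keep <- integer(0)
  for (i in cand[order(-x[cand], cand)]) {
    if (all(abs(keep - i) >= min_distance)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Default candidate-selection parameters
#'
#' Cutoff 20 Hz / order 2 for the gyroscope high-pass, relative peak threshold
#' 0.3, minimum peak distance 300 samples (1.5 s), 2 s windows with 25 percent
#' overlap, cross-window peak merge radius 100 samples (0.5 s, the closest
#' detectable contact spacing), and an absolute minimum SMV peak height of
#' 100 deg/s that rejects low-activity windows whose only peaks are noise.
#'
#' @return Named list of parameters.
#' @export
candidate_params <- function() {
  list(cutoff = 20, order = 2, threshold_frac = 0.3, min_distance = 300,
       window_len = WINDOW_LEN, overlap = 0.25, merge_radius = 100,
       min_peak_height = 100)
}

#' Select candidate windows from a session
#'
#' The moving-window candidate-selection pre-filter: per foot, the gyroscope
#' is high-pass filtered, the SMV is computed, each 2 s moving window is
#' scanned for super-threshold peaks ([detect_peaks()]), peaks below the
#' absolute activity floor (`min_peak_height`) are discarded, and duplicate
#' peaks from overlapping windows within `merge_radius` samples are merged
#' keeping the larger SMV. For each surviving peak a 2 s block centered on the
#' peak is cut from the scaled stream (zero-padded and flagged if it overruns
#' an edge) and labelled from the ball contacts inside the 1 s window around
#' the peak: precedence shot > pass > null; a window whose only contacts are
#' `unknown` is marked `excluded`; a window with no labelled contact is a
#' `none`/null candidate.
#'
#' @param x A [session()].
#' @param params Parameter list from [candidate_params()].
#' @return A `candidate_set`: list with `windows` (a [window_set()]),
#'   `stats` (windows total / rejected / candidates per foot) and `params`.
#' @export
select_candidates <- function(x, params = candidate_params()) {
  stopifnot(inherits(x, "session"))
  blocks <- list(); labels <- character(0); fines <- character(0)
  feet <- character(0); centers <- integer(0); heights <- numeric(0)
  padded <- logical(0)
  windows_total <- 0L; n_cand <- 0L
  floor_scaled <- params$min_peak_height / IMU_FULL_SCALE[["gyro"]]
  for (foot in names(x$streams)) {
    st <- scale_stream(x$streams[[foot]])
    g <- highpass_gyro(st, cutoff = params$cutoff, order = params$order)
    v <- smv(g)
    starts <- moving_windows(length(v), params$window_len, params$overlap)
    windows_total <- windows_total + length(starts)
    peaks <- integer(0)
    for (s0 in starts) {
      w <- v[s0:(s0 + params$window_len - 1)]
      p <- detect_peaks(w, params$threshold_frac, params$min_distance)
      p <- p[w[p] >= floor_scaled]
      peaks <- c(peaks, p + s0 - 1L)
    }
    peaks <- .merge_peaks(unique(peaks), v, params$merge_radius)
    ev <- x$events[x$events$foot == foot, , drop = FALSE]
    for (p in peaks) {
      blk <- .cut_block(st$data, p, params$window_len)
      t_peak <- st$times[p]
      lab <- .label_window(ev, t_peak)
      blocks[[length(blocks) + 1]] <- blk$block
      labels <- c(labels, lab$class)
      fines <- c(fines, lab$fine_type)
      feet <- c(feet, foot)
      centers <- c(centers, p)
      heights <- c(heights, v[p])
      padded <- c(padded, blk$padded)
      n_cand <- n_cand + 1L
    }
  }
  ws <- window_set(blocks, labels, fines,
                   session_ids = rep(x$session_id, length(labels)),
                   meta = data.frame(foot = feet, center = centers,
                                     smv = heights, padded = padded))
  structure(list(windows = ws,
                 stats = list(windows_total = windows_total,
                              rejected = windows_total - n_cand,
                              candidates = n_cand),
                 session_id = x$session_id, params = params),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<candidate_set> %s: %d moving windows, %d rejected, %d candidates\n",
              x$session_id, s$windows_total, s$rejected, s$candidates))
  invisible(x)
}

# merge peak indices closer than `radius`, keeping the larger SMV value
.merge_peaks <- function(peaks, v, radius) {
  if (length(peaks) <= 1) return(peaks)
  peaks <- sort(peaks)
  keep <- integer(0)
  for (p in peaks[order(-v[peaks], peaks)]) {
    if (all(abs(keep - p) > radius)) keep <- c(keep, p)
  }
  sort(keep)
}

# cut a window_len block centered on index p; zero-pad symmetric overruns
.cut_block <- function(data, p, window_len) {
  half <- window_len %/% 2
  lo <- p - half + 1L
  hi <- p + half
  n <- nrow(data)
  block <- matrix(0, window_len, ncol(data))
  src <- max(1L, lo):min(n, hi)
  block[src - lo + 1L, ] <- data[src, ]
  colnames(block) <- colnames(data)
  list(block = block, padded = (lo < 1L || hi > n))
}

# label a window from events within +-LABEL_HALF of the peak time:
# shot > pass > null precedence; unknown-only => excluded; none => null
.label_window <- function(ev, t_peak) {
  hit <- ev[abs(ev$time - t_peak) <= LABEL_HALF, , drop = FALSE]
  if (nrow(hit) == 0)
    return(list(class = "null", fine_type = "none"))
  for (cl in c("shot", "pass", "null")) {
    sub <- hit[hit$class == cl, , drop = FALSE]
    if (nrow(sub) > 0) {
      i <- which.min(abs(sub$time - t_peak))
      return(list(class = cl, fine_type = sub$fine_type[i]))
    }
  }
  list(class = "excluded", fine_type = "unknown")
}

#' Tune candidate-selection parameters on labelled sessions
#'
#' Grid search over filter and peak-detection parameters maximizing the
#' rejection rate (specificity proxy) subject to 100 percent sensitivity for
#' labelled shots and passes — the tuning rule used to fix the package
#' defaults. Provided as a utility for synthetic data.
#'
#' @param sessions List of labelled [session()] objects.
#' @param grid Data frame of parameter combinations; columns may include
#'   `cutoff`, `order`, `threshold_frac`, `min_peak_height`.
#' @return The grid with `sensitivity` and `rejection` columns, sorted best
#'   first (full-sensitivity rows ranked by rejection).
#' @export
tune_candidate_params <- function(sessions, grid = expand.grid(
                                    cutoff = c(10, 20, 30),
                                    threshold_frac = c(0.2, 0.3, 0.5),
                                    min_peak_height = c(50, 100, 200))) {
  res <- grid
  res$sensitivity <- NA_real_
  res$rejection <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- candidate_params()
    for (nm in intersect(names(grid), names(p))) p[[nm]] <- grid[[nm]][i]
    hits <- 0L; total <- 0L; wins <- 0L; cands <- 0L
    for (s in sessions) {
      cs <- select_candidates(s, p)
      rec <- candidate_recall(s, cs)
      hits <- hits + rec$found; total <- total + rec$events
      wins <- wins + cs$stats$windows_total; cands <- cands + cs$stats$candidates
    }
    res$sensitivity[i] <- if (total > 0) hits / total else NA_real_
    res$rejection[i] <- if (wins > 0) 1 - cands / wins else NA_real_
  }
  res[order(res$sensitivity < 1, -res$rejection), , drop = FALSE]
}

#' Recall of labelled shots and passes among candidates
#'
#' @param x The source [session()].
#' @param cands A `candidate_set` from [select_candidates()].
#' @return List with `events` (labelled shots+passes), `found` (covered by at
#'   least one candidate within the 1 s label window) and `recall`.
#' @export
candidate_recall <- function(x, cands) {
  ev <- x$events[x$events$class %in% c("shot", "pass"), , drop = FALSE]
  if (nrow(ev) == 0) return(list(events = 0L, found = 0L, recall = NA_real_))
  meta <- cands$windows$meta
  found <- 0L
  for (i in seq_len(nrow(ev))) {
    idx <- which(meta$foot == ev$foot[i])
    if (length(idx) == 0) next
    tt <- vapply(idx, function(j)
      x$streams[[meta$foot[j]]]$times[meta$center[j]], numeric(1))
    if (any(abs(tt - ev$time[i]) <= LABEL_HALF)) found <- found + 1L
  }
  list(events = nrow(ev), found = found, recall = found / nrow(ev))
}
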