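# Core domain types: sensor streams, ball-contact events, sessions, and the
# fixed label taxonomy of the three-class shot/pass/null problem.

#' Channel order of a sensor stream
#'
#' All six-channel signal blocks in the package use this fixed column order:
#' tri-axial accelerometer (g) followed by tri-axial gyroscope (deg/s). `gx`
#' carries the sagittal-plane angular velocity of the foot (the forward swing
#' of the leg), which drives kick-phase segmentation.
#'
#' @format Character vector of length 6.
#' @export
IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Sensor full-scale values
#'
#' Full-scale range of the accelerometer (+-16 g) and gyroscope (+-2000 deg/s).
#' Signals are scaled to \[-1, 1\] by dividing by these values, so that
#' accelerometer saturation (a class cue for shots) maps to exactly +-1
#' independent of the session.
#'
#' @format Named numeric vector with elements `accel` and `gyro`.
#' @export
IMU_FULL_SCALE <- c(accel = 16, gyro = 2000)

#' Fine-grained ball-contact types
#'
#' The eight fine-grained ball-contact annotations and the order used for
#' confusion-matrix columns. `unknown` marks contacts where the player was not
#' visible on the labelling video; such windows are excluded from evaluation.
#'
#' @format Character vector of length 8.
#' @export
CONTACT_TYPES <- c("none", "light contact", "strong contact",
                   "short pass medial", "short pass other", "long pass",
                   "shot", "unknown")

#' Class labels of the classification problem
#' @format Character vector: the three classes plus the `excluded` marker.
#' @export
CLASS_LABELS <- c("shot", "pass", "null", "excluded")

.CONTACT_CLASS_MAP <- c(
  "none"              = "null",
  "light contact"     = "null",
  "strong contact"    = "null",
  "short pass medial" = "pass",
  "short pass other"  = "pass",
  "long pass"         = "pass",
  "shot"              = "shot",
  "unknown"           = "excluded"
)

#' Map a fine-grained ball-contact type to its class label
#'
#' Deterministic, total mapping from the eight fine-grained contact types to
#' the class labels of the three-class problem: the three dribbling/no-contact
#' types map to `null`, the three pass types to `pass`, `shot` to `shot`, and
#' `unknown` (player not visible in the video) to `excluded`.
#'
#' @param fine_type Character vector of contact types (see [CONTACT_TYPES]).
#' @return Character vector of class labels (`shot`, `pass`, `null`,
#'   `excluded`), same length as `fine_type`.
#' @examples
#' map_contact_to_class("short pass medial")  # "pass"
#' map_contact_to_class(c("shot", "light contact", "unknown"))
#' @export
map_contact_to_class <- function(fine_type) {
  bad <- setdiff(unique(fine_type), names(.CONTACT_CLASS_MAP))
  if (length(bad) > 0) {
    stop("unrecognized ball-contact type(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  unname(.CONTACT_CLASS_MAP[fine_type])
}

#' Construct a sensor stream
#'
#' A `sensor_stream` is one foot's uniformly sampled six-channel IMU recording:
#' sample times in seconds and an n x 6 signal matrix in the [IMU_CHANNELS]
#' order, accelerometer in g and gyroscope in deg/s (or both scaled to
#' \[-1, 1\], tracked by the `scaled` flag).
#'
#' @param times Numeric vector of sample times in seconds, strictly increasing.
#' @param data Numeric n x 6 matrix, columns in [IMU_CHANNELS] order.
#' @param rate Nominal sampling rate in Hz.
#' @param scaled Logical; `TRUE` if the channels are already divided by the
#'   sensor full-scale values.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(times, data, rate = 200, scaled = FALSE) {
  data <- as.matrix(data)
  if (ncol(data) != 6) {
    have <- if (!is.null(colnames(data))) colnames(data) else as.character(seq_len(ncol(data)))
    missing_ch <- setdiff(IMU_CHANNELS, have)
    stop("sensor stream must have 6 channels (", paste(IMU_CHANNELS, collapse = ","),
         "); missing: ", paste(missing_ch, collapse = ","), call. = FALSE)
  }
  if (length(times) != nrow(data))
    stop("length(times) must equal nrow(data)", call. = FALSE)
  if (nrow(data) > 1 && any(diff(times) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  colnames(data) <- IMU_CHANNELS
  structure(list(times = as.numeric(times), data = data,
                 rate = rate, scaled = isTRUE(scaled)),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples @ %g Hz (%.1f s), %s units\n",
              nrow(x$data), x$rate, diff(range(x$times)),
              if (x$scaled) "scaled [-1,1]" else "physical"))
  invisible(x)
}

#' Number of samples in a stream
#' @param stream A [sensor_stream()].
#' @return Integer sample count.
#' @export
n_samples <- function(stream) nrow(stream$data)

#' Accelerometer / gyroscope block of a stream
#' @param stream A [sensor_stream()].
#' @return n x 3 matrix of the accelerometer (`accel_data`) or gyroscope
#'   (`gyro_data`) channels.
#' @export
accel_data <- function(stream) stream$data[, 1:3, drop = FALSE]

#' @rdname accel_data
#' @export
gyro_data <- function(stream) stream$data[, 4:6, drop = FALSE]

#' Scale a stream to \[-1, 1\] by the sensor full-scale values
#'
#' Divides accelerometer channels by 16 g and gyroscope channels by
#' 2000 deg/s. Scaling by the fixed full scale (rather than per-session
#' min-max) keeps saturation semantics: a saturated accelerometer sample maps
#' to exactly +-1 in every session.
#'
#' @param stream A [sensor_stream()] in physical units.
#' @param tol Clipping tolerance: values up to `(1 + tol)` x full scale are
#'   clipped to full scale; values beyond that raise an error.
#' @return The scaled stream (`scaled = TRUE`).
#' @seealso [unscale_stream()]
#' @export
scale_stream <- function(stream, tol = 1e-6) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (stream$scaled) return(stream)
  fs <- rep(IMU_FULL_SCALE[c("accel", "gyro")], each = 3)
  d <- sweep(stream$data, 2, fs, "/")
  over <- max(abs(d))
  if (over > 1 + tol)
    stop(sprintf("channel value exceeds sensor full scale by %.3g%%; not a raw stream?",
                 100 * (over - 1)), call. = FALSE)
  d[d > 1] <- 1
  d[d < -1] <- -1
  sensor_stream(stream$times, d, rate = stream$rate, scaled = TRUE)
}

#' Undo full-scale scaling
#' @param stream A scaled [sensor_stream()].
#' @return The stream in physical units (g, deg/s).
#' @export
unscale_stream <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!stream$scaled) return(stream)
  fs <- rep(IMU_FULL_SCALE[c("accel", "gyro")], each = 3)
  sensor_stream(stream$times, sweep(stream$data, 2, fs, "*"),
                rate = stream$rate, scaled = FALSE)
}

#' Construct a ball-contact event table
#'
#' @param time Numeric vector of event times (seconds).
#' @param foot Character vector, `"left"` or `"right"`.
#' @param fine_type Character vector of fine-grained contact types.
#' @return A data.frame with columns `time`, `foot`, `fine_type` and the
#'   derived `class`, sorted by time.
#' @export
contact_events <- function(time = numeric(), foot = character(),
                           fine_type = character()) {
  stopifnot(length(time) == length(foot), length(time) == length(fine_type))
  cls <- map_contact_to_class(fine_type)
  bad_foot <- setdiff(unique(foot), c("left", "right"))
  if (length(bad_foot) > 0)
    stop("foot must be 'left' or 'right'", call. = FALSE)
  ev <- data.frame(time = as.numeric(time), foot = as.character(foot),
                   fine_type = as.character(fine_type), class = cls,
                   stringsAsFactors = FALSE)
  ev[order(ev$time), , drop = FALSE]
}

#' Construct a recording session
#'
#' A session bundles one or two per-foot sensor streams with the labelled
#' ball-contact events of one recording, plus a `setting` flag distinguishing
#' controlled laboratory protocols from real-world training/game recordings.
#'
#' @param session_id Character scalar identifier.
#' @param streams Named list of [sensor_stream()] objects, names in
#'   `c("left","right")`.
#' @param events Event table from [contact_events()].
#' @param setting `"lab"` or `"field"`.
#' @param extra Optional list of generator ground truth / provenance.
#' @return An object of class `session`.
#' @export
session <- function(session_id, streams, events, setting = c("lab", "field"),
                    extra = list()) {
  setting <- match.arg(setting)
  stopifnot(is.list(streams), length(streams) >= 1)
  if (is.null(names(streams)) || !all(names(streams) %in% c("left", "right")))
    stop("streams must be a named list with names in c('left','right')", call. = FALSE)
  for (s in streams) stopifnot(inherits(s, "sensor_stream"))
  if (nrow(events) > 0) {
    rng <- range(unlist(lapply(streams, function(s) range(s$times))))
    if (any(events$time < rng[1] - 1e-9 | events$time > rng[2] + 1e-9))
      stop("event times must fall inside the stream time range", call. = FALSE)
    if (is.unsorted(events$time)) events <- events[order(events$time), ]
  }
  structure(list(session_id = as.character(session_id), setting = setting,
                 streams = streams, events = events, extra = extra),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cls <- table(factor(x$events$class, levels = CLASS_LABELS))
  cat(sprintf("<session> %s [%s], %d foot stream(s), %d events (shot %d / pass %d / null %d / excluded %d)\n",
              x$session_id, x$setting, length(x$streams), nrow(x$events),
              cls["shot"], cls["pass"], cls["null"], cls["excluded"]))
  invisible(x)
}

#' Session duration in seconds
#' @param x A [session()].
#' @return Duration of the longest stream, seconds.
#' @export
session_duration <- function(x) {
  max(vapply(x$streams, function(s) diff(range(s$times)), numeric(1)))
}

# --- session directory I/O -------------------------------------------------
# Layout: <dir>/meta.yaml, <dir>/<foot>.csv (t,ax,ay,az,gx,gy,gz),
# <dir>/labels.csv (time_s,foot,contact_type).

#' Write a session to a directory
#'
#' Stores one directory per session: a per-foot sensor CSV with header
#' `t,ax,ay,az,gx,gy,gz` (seconds, g, deg/s), a label CSV
#' `time_s,foot,contact_type` with contact types spelled as in
#' [CONTACT_TYPES], and a `meta.yaml` with session id, setting and nominal
#' rate.
#'
#' @param x A [session()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (foot in names(x$streams)) {
    s <- x$streams[[foot]]
    df <- data.frame(t = s$times, unscale_stream(s)$data, check.names = FALSE)
    utils::write.csv(df, file.path(path, paste0(foot, ".csv")), row.names = FALSE)
  }
  lab <- data.frame(time_s = x$events$time, foot = x$events$foot,
                    contact_type = x$events$fine_type)
  utils::write.csv(lab, file.path(path, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(session_id = x$session_id, setting = x$setting,
                        nominal_rate = x$streams[[1]]$rate),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]: the round trip is the identity on the
#' documented fields. Malformed inputs (missing channels, non-monotone time,
#' unknown contact types) raise labelled parse errors.
#'
#' @param path Session directory.
#' @return A [session()].
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path))
    stop("not a session directory (no meta.yaml): ", path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  streams <- list()
  for (foot in c("left", "right")) {
    f <- file.path(path, paste0(foot, ".csv"))
    if (!file.exists(f)) next
    df <- utils::read.csv(f, check.names = FALSE)
    missing_ch <- setdiff(c("t", IMU_CHANNELS), names(df))
    if (length(missing_ch) > 0)
      stop("sensor file ", f, " missing channel(s): ",
           paste(missing_ch, collapse = ","), call. = FALSE)
    if (nrow(df) > 1 && any(diff(df$t) <= 0))
      stop("sensor file ", f, ": non-monotone time axis", call. = FALSE)
    streams[[foot]] <- sensor_stream(df$t, as.matrix(df[IMU_CHANNELS]),
                                     rate = meta$nominal_rate %||% 200)
  }
  if (length(streams) == 0)
    stop("no per-foot sensor CSV found in ", path, call. = FALSE)
  lab_path <- file.path(path, "labels.csv")
  if (file.exists(lab_path)) {
    lab <- utils::read.csv(lab_path, check.names = FALSE,
                           colClasses = c("numeric", "character", "character"))
    need <- c("time_s", "foot", "contact_type")
    if (!all(need %in% names(lab)))
      stop("labels.csv must have columns ", paste(need, collapse = ","), call. = FALSE)
    events <- contact_events(lab$time_s, lab$foot, lab$contact_type)
  } else {
    events <- contact_events()
  }
  session(meta$session_id, streams, events, setting = meta$setting)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
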