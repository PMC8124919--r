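# Synthetic labelled session generator. Emulates the statistical structure the
# detection pipeline assumes: gait/running background, high-impact shot
# signatures reaching accelerometer saturation, medium-impact pass signatures,
# low-amplitude dribble contacts, agile no-contact bursts, the three-clap
# synchronization pattern, and session-level class imbalance (null >> pass >>
# shot).

#' Synthetic-session configuration
#'
#' Bundles every knob of the generator. Defaults are the package's reference
#' conditions: a 180 s single-foot recording at 200 Hz with a
#' standing/walking/running background and an event mix whose class imbalance
#' runs null > pass > shot.
#'
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @param duration_s Session length in seconds.
#' @param counts Named integer vector of events per fine-grained contact type
#'   (names from [CONTACT_TYPES]). Omitted types default to 0.
#' @param n_events,class_ratio Alternative to `counts`: total event count plus
#'   a named `c(shot=,pass=,null=)` ratio; counts per class are rounded from
#'   the ratio and split across the fine types of each class by fixed weights.
#' @param setting `"lab"` (tight controlled amplitude ranges) or `"field"`
#'   (wider technique/amplitude variation, more running and agile movement).
#' @param regime Template difficulty: `"default"`, `"separable"` (disjoint
#'   class amplitude ranges) or `"confusable"` (long passes overlap weak shots
#'   in amplitude; classes differ mainly in waveform shape).
#' @param background Fractions of standing/walking/running time, summing to 1.
#' @param cadence Stride frequencies in Hz, named `walking`/`running`.
#' @param noise_accel_sd,noise_gyro_sd Broadband sensor noise, g and deg/s.
#' @param min_spacing Minimum spacing between any two event times in seconds
#'   (>= 0.3 s, the closest observed dribble-contact spacing).
#' @param kick_spacing Minimum spacing between two kicks (shot or pass), in
#'   seconds. A player cannot kick twice in quick succession — the ball is
#'   gone — so kick-to-kick gaps are kept above the peak detector's 1.5 s
#'   within-window resolution; dribble contacts may still crowd kicks at
#'   `min_spacing`.
#' @param sync Logical: inject the three-clap synchronization pattern at both
#'   ends of the stream.
#' @param feet Which feet to synthesize (`"left"`, `"right"` or both).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         duration_s = 180,
                         counts = NULL,
                         n_events = NULL,
                         class_ratio = NULL,
                         setting = c("lab", "field"),
                         regime = c("default", "separable", "confusable"),
                         background = c(standing = 0.4, walking = 0.35, running = 0.25),
                         cadence = c(walking = 1.8, running = 2.8),
                         noise_accel_sd = 0.05,
                         noise_gyro_sd = 8,
                         min_spacing = 1.2,
                         kick_spacing = NULL,
                         sync = TRUE,
                         feet = "left") {
  setting <- match.arg(setting)
  regime <- match.arg(regime)
  if (min_spacing < 0.3)
    stop("min_spacing must be >= 0.3 s", call. = FALSE)
  if (is.null(kick_spacing)) kick_spacing <- max(2, min_spacing)
  if (kick_spacing < min_spacing)
    stop("kick_spacing must be >= min_spacing", call. = FALSE)
  if (is.null(counts)) {
    if (!is.null(n_events)) {
      counts <- .counts_from_ratio(n_events, class_ratio)
    } else {
      counts <- c("shot" = 4, "long pass" = 3, "short pass medial" = 6,
                  "short pass other" = 5, "light contact" = 12,
                  "strong contact" = 8, "none" = 8, "unknown" = 1)
    }
  }
  bad <- setdiff(names(counts), CONTACT_TYPES)
  if (length(bad) > 0)
    stop("unknown contact type(s) in counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  full <- stats::setNames(integer(length(CONTACT_TYPES)), CONTACT_TYPES)
  full[names(counts)] <- as.integer(counts)
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 counts = full, setting = setting, regime = regime,
                 background = background, cadence = cadence,
                 noise_accel_sd = noise_accel_sd, noise_gyro_sd = noise_gyro_sd,
                 min_spacing = min_spacing, kick_spacing = kick_spacing,
                 sync = sync, feet = feet),
            class = "synth_config")
}

# Split a total event budget into per-fine-type counts following a
# shot/pass/null class ratio; fine types within a class use fixed weights.
.counts_from_ratio <- function(n_events, class_ratio) {
  if (is.null(class_ratio))
    class_ratio <- c(shot = 8424, pass = 24254, null = 61168)
  class_ratio <- class_ratio / sum(class_ratio)
  per_class <- round(n_events * class_ratio)
  weights <- list(
    shot = c("shot" = 1),
    pass = c("long pass" = 0.2, "short pass medial" = 0.45, "short pass other" = 0.35),
    null = c("light contact" = 0.4, "strong contact" = 0.3, "none" = 0.3)
  )
  counts <- integer(0)
  for (cl in names(per_class)) {
    w <- weights[[cl]]
    k <- floor(per_class[[cl]] * w)
    rem <- per_class[[cl]] - sum(k)
    if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
    counts <- c(counts, k)
  }
  counts
}

#' Event waveform templates
#'
#' Per-contact-type parameter ranges for the injected signatures: peak
#' accelerometer amplitude (g, pre-clipping — shots draw above 16 g so the
#' stored signal saturates at exactly +-16 g), peak gyroscope ring amplitude
#' (deg/s), forward-swing amplitude and duration of the sagittal gyroscope
#' half-sine ending at contact, and the ring frequency of the contact
#' impulse. `"field"` settings widen every range about its midpoint to emulate
#' the larger technique variation of uncontrolled play.
#'
#' @param regime Template difficulty (see [synth_config()]).
#' @param setting `"lab"` or `"field"`.
#' @return Named list of per-type parameter lists.
#' @export
event_templates <- function(regime = c("default", "separable", "confusable"),
                            setting = c("lab", "field")) {
  regime <- match.arg(regime)
  setting <- match.arg(setting)
  tpl <- function(accel, gyro, swing, swing_dur, freq, decay = 0.035)
    list(accel_amp = accel, gyro_amp = gyro, swing_amp = swing,
         swing_dur = swing_dur, ring_freq = freq, ring_decay = decay)
  t <- switch(regime,
    default = list(
      "shot"              = tpl(c(18, 26), c(1200, 1800), c(900, 1400), c(0.22, 0.30), 42),
      "long pass"         = tpl(c(7, 11),  c(550, 850),  c(500, 800),  c(0.28, 0.36), 30),
      "short pass medial" = tpl(c(5, 9),   c(420, 700),  c(400, 650),  c(0.25, 0.33), 30),
      "short pass other"  = tpl(c(4.5, 8.5), c(380, 650), c(380, 620), c(0.25, 0.33), 30),
      "strong contact"    = tpl(c(2.5, 4.5), c(260, 450), c(0, 0),     c(0, 0),       36),
      "light contact"     = tpl(c(0.8, 2.2), c(130, 300), c(0, 0),     c(0, 0),       34),
      "none"              = tpl(c(1.0, 3.0), c(150, 380), c(0, 0),     c(0, 0),       30, 0.12),
      "unknown"           = tpl(c(3, 6),   c(300, 500),  c(250, 450),  c(0.22, 0.30), 32)
    ),
    separable = list(
      "shot"              = tpl(c(20, 26), c(1500, 1900), c(1300, 1600), c(0.20, 0.24), 42),
      "long pass"         = tpl(c(6.5, 8), c(480, 620),  c(520, 680),  c(0.30, 0.34), 30),
      "short pass medial" = tpl(c(6, 8),   c(450, 600),  c(500, 650),  c(0.30, 0.34), 30),
      "short pass other"  = tpl(c(6, 8),   c(450, 600),  c(500, 650),  c(0.30, 0.34), 30),
      "strong contact"    = tpl(c(1.8, 2.6), c(200, 300), c(0, 0),     c(0, 0),       36),
      "light contact"     = tpl(c(0.8, 1.6), c(140, 240), c(0, 0),     c(0, 0),       34),
      "none"              = tpl(c(0.8, 1.6), c(140, 260), c(0, 0),     c(0, 0),       30, 0.12),
      "unknown"           = tpl(c(3, 5),   c(300, 450),  c(250, 400),  c(0.24, 0.30), 32)
    ),
    confusable = list(
      "shot"              = tpl(c(17, 24), c(800, 1400), c(700, 1200), c(0.22, 0.34), 45),
      "long pass"         = tpl(c(12, 18), c(750, 1350), c(650, 1150), c(0.22, 0.34), 28),
      "short pass medial" = tpl(c(5, 10),  c(400, 800),  c(400, 800),  c(0.24, 0.34), 28),
      "short pass other"  = tpl(c(5, 10),  c(400, 800),  c(400, 800),  c(0.24, 0.34), 28),
      "strong contact"    = tpl(c(3, 7),   c(300, 600),  c(0, 0),      c(0, 0),       38),
      "light contact"     = tpl(c(0.8, 2.5), c(130, 320), c(0, 0),     c(0, 0),       34),
      "none"              = tpl(c(1.5, 4.0), c(200, 500), c(0, 0),     c(0, 0),       30, 0.12),
      "unknown"           = tpl(c(3, 6),   c(300, 500),  c(250, 450),  c(0.22, 0.30), 32)
    ))
  if (setting == "field") {
    widen <- function(r, f = 1.7) {
      m <- mean(r); h <- diff(r) / 2 * f
      c(max(m - h, 0.1 * m), m + h)
    }
    for (ty in names(t)) {
      t[[ty]]$accel_amp <- widen(t[[ty]]$accel_amp)
      t[[ty]]$gyro_amp <- widen(t[[ty]]$gyro_amp)
      if (diff(t[[ty]]$swing_amp) > 0) t[[ty]]$swing_amp <- widen(t[[ty]]$swing_amp)
    }
  }
  t
}

# Run `expr` with a private RNG stream seeded by `seed`; restores the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

runif1 <- function(r) if (diff(r) <= 0) r[1] else stats::runif(1, r[1], r[2])

#' Generate one labelled synthetic session
#'
#' Builds a gait/standing/running background, injects one waveform per
#' requested ball contact (damped-cosine impact ring on all channels plus, for
#' kicks, a sagittal back-swing/forward-swing on `gx` whose forward half-sine
#' ends at the contact instant, guaranteeing a pre-contact zero crossing),
#' clips the accelerometer at +-16 g (so shots saturate), and optionally
#' injects the three-clap synchronization pattern at both ends. Ground truth
#' (event times, per-event amplitudes, clap times) is stored in
#' `session$extra`.
#'
#' @param config A [synth_config()].
#' @param session_id Identifier for the returned session.
#' @return A [session()] whose event table matches the requested counts per
#'   contact type exactly. Deterministic given `config$seed`.
#' @export
generate_session <- function(config, session_id = sprintf("synth-%03d", config$seed)) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, .generate_session_impl(config, session_id))
}

.generate_session_impl <- function(config, session_id) {
  rate <- 200
  n <- round(config$duration_s * rate)
  times <- (seq_len(n) - 1) / rate
  tpl <- event_templates(config$regime, config$setting)

  margin <- 3 + if (config$sync) 2.5 else 0
  usable <- config$duration_s - 2 * margin
  # feasibility is checked inside .place_events (depends on the kick layout)

  streams <- list()
  all_truth <- list()
  ev_time <- numeric(0); ev_foot <- character(0); ev_type <- character(0)
  for (foot in config$feet) {
    bg <- .make_background(n, rate, config)
    ev <- .place_events(config, margin, usable)
    sig <- bg
    truth <- vector("list", nrow(ev))
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        drawn <- .inject_event(sig, times, rate, ev$time[i], tpl[[ev$fine_type[i]]])
        sig <- drawn$sig
        truth[[i]] <- c(list(time = ev$time[i], fine_type = ev$fine_type[i]),
                        drawn$params)
      }
    }
    # accelerometer clipping at full scale: shots saturate at exactly +-16 g
    acc <- sig[, 1:3]; acc[acc > 16] <- 16; acc[acc < -16] <- -16
    sig[, 1:3] <- acc
    g <- sig[, 4:6]; g[g > 2000] <- 2000; g[g < -2000] <- -2000
    sig[, 4:6] <- g
    st <- sensor_stream(times, sig, rate = rate)
    sync_truth <- NULL
    if (config$sync) {
      st <- inject_sync_pattern(st)
      sync_truth <- attr(st, "sync_truth")
    }
    streams[[foot]] <- st
    all_truth[[foot]] <- list(events = truth, sync = sync_truth)
    ev_time <- c(ev_time, ev$time)
    ev_foot <- c(ev_foot, rep(foot, nrow(ev)))
    ev_type <- c(ev_type, ev$fine_type)
  }
  events <- contact_events(ev_time, ev_foot, ev_type)
  session(session_id, streams, events, setting = config$setting,
          extra = list(truth = all_truth, config = config))
}

# Piecewise standing/walking/running background with harmonic stride pattern.
.make_background <- function(n, rate, config) {
  t <- (seq_len(n) - 1) / rate
  sig <- matrix(0, n, 6)
  # segment the session into ~8 s activity blocks
  n_blocks <- max(1, round(n / rate / 8))
  states <- sample(names(config$background), n_blocks, replace = TRUE,
                   prob = config$background)
  bounds <- round(seq(1, n + 1, length.out = n_blocks + 1))
  for (b in seq_len(n_blocks)) {
    idx <- bounds[b]:(bounds[b + 1] - 1)
    st <- states[b]
    if (st == "standing") next
    f <- config$cadence[[st]] * stats::runif(1, 0.92, 1.08)
    acc_amp <- if (st == "walking") 0.35 else 1.1
    gyr_amp <- if (st == "walking") 35 else 90
    ph <- stats::runif(6, 0, 2 * pi)
    tt <- t[idx]
    sig[idx, 3] <- sig[idx, 3] + acc_amp * sin(2 * pi * f * tt + ph[3]) +
      0.4 * acc_amp * sin(4 * pi * f * tt + ph[1])
    sig[idx, 1] <- sig[idx, 1] + 0.5 * acc_amp * sin(2 * pi * f * tt + ph[2])
    sig[idx, 2] <- sig[idx, 2] + 0.3 * acc_amp * sin(2 * pi * f * tt + ph[6])
    sig[idx, 4] <- sig[idx, 4] + gyr_amp * sin(2 * pi * f * tt + ph[4])
    sig[idx, 5] <- sig[idx, 5] + 0.5 * gyr_amp * sin(2 * pi * f * tt + ph[5])
    sig[idx, 6] <- sig[idx, 6] + 0.3 * gyr_amp * sin(2 * pi * f * tt + ph[5] / 2)
  }
  sig[, 1:3] <- sig[, 1:3] + matrix(stats::rnorm(n * 3, 0, config$noise_accel_sd), n, 3)
  sig[, 4:6] <- sig[, 4:6] + matrix(stats::rnorm(n * 3, 0, config$noise_gyro_sd), n, 3)
  sig
}

# Draw event times inside the usable interval: any two events are at least
# min_spacing apart, and any two kicks (shot/pass) at least kick_spacing
# apart (a player cannot kick again until the ball returns).
.place_events <- function(config, margin, usable) {
  types <- rep(names(config$counts), config$counts)
  n_ev <- length(types)
  if (n_ev == 0) return(data.frame(time = numeric(0), fine_type = character(0)))
  ft <- sample(types)
  kick <- map_contact_to_class(ft) %in% c("shot", "pass")
  # left-to-right walk at minimal gaps: consecutive events >= min_spacing,
  # any two kicks >= kick_spacing
  tt <- numeric(n_ev)
  last_kick <- -Inf
  cur <- 0
  for (i in seq_len(n_ev)) {
    cur <- if (i == 1) 0 else cur + config$min_spacing
    if (kick[i]) {
      cur <- max(cur, last_kick + config$kick_spacing)
      last_kick <- cur
    }
    tt[i] <- cur
  }
  need <- tt[n_ev]
  if (need > usable)
    stop(sprintf("events do not fit: %d events (%d kicks) need %.1f s, only %.1f s usable",
                 n_ev, sum(kick), need, usable), call. = FALSE)
  # spread the remaining slack as random extra gaps
  u <- stats::runif(n_ev + 1)
  extra <- cumsum(u[seq_len(n_ev)]) / sum(u) * (usable - need)
  data.frame(time = margin + tt + extra, fine_type = ft,
             stringsAsFactors = FALSE)
}

# Inject one ball-contact signature at time t0. Kicks get a sagittal
# back-swing + forward half-sine on gx ending at contact; all events get a
# damped-cosine ring on every channel starting at contact.
.inject_event <- function(sig, times, rate, t0, tp) {
  n <- nrow(sig)
  i0 <- round(t0 * rate) + 1
  accel_amp <- runif1(tp$accel_amp)
  gyro_amp <- runif1(tp$gyro_amp)
  swing_amp <- if (diff(tp$swing_amp) > 0 || tp$swing_amp[1] > 0) runif1(tp$swing_amp) else 0
  swing_dur <- if (swing_amp > 0) runif1(tp$swing_dur) else 0
  swing_sign <- sample(c(-1, 1), 1)

  if (swing_amp > 0) {
    # backswing (opposite sign) then forward half-sine ending at contact:
    # gx crosses zero at the swing onset, i.e. before the contact instant
    n_sw <- round(swing_dur * rate)
    i_sw <- (i0 - n_sw):(i0 - 1)
    keep <- i_sw >= 1 & i_sw <= n
    ph <- seq(0, pi, length.out = n_sw)[keep]
    sig[i_sw[keep], 4] <- sig[i_sw[keep], 4] + swing_sign * swing_amp * sin(ph)
    n_bs <- round(0.6 * n_sw)
    i_bs <- (i0 - n_sw - n_bs):(i0 - n_sw - 1)
    keepb <- i_bs >= 1 & i_bs <= n
    phb <- seq(0, pi, length.out = n_bs)[keepb]
    sig[i_bs[keepb], 4] <- sig[i_bs[keepb], 4] - swing_sign * 0.35 * swing_amp * sin(phb)
  }

  # impact ring: damped cosine, value = amplitude at the contact sample
  ring_len <- min(n - i0 + 1, round(6 * tp$ring_decay * rate) + round(0.05 * rate))
  if (ring_len > 0) {
    tt <- (seq_len(ring_len) - 1) / rate
    ring <- exp(-tt / tp$ring_decay) * cos(2 * pi * tp$ring_freq * tt)
    idx <- i0:(i0 + ring_len - 1)
    wa <- c(1, stats::runif(2, 0.3, 0.8)) * sample(c(-1, 1), 3, replace = TRUE)
    wa[1] <- abs(wa[1]) # dominant axis positive => saturation hits +16
    wg <- stats::runif(3, c(0.3, 0.5, 0.5), c(0.7, 1.0, 1.0)) *
      sample(c(-1, 1), 3, replace = TRUE)
    for (k in 1:3) sig[idx, k] <- sig[idx, k] + accel_amp * wa[k] * ring
    for (k in 1:3) sig[idx, 3 + k] <- sig[idx, 3 + k] + gyro_amp * wg[k] * ring
  }
  list(sig = sig, params = list(accel_amp = accel_amp, gyro_amp = gyro_amp,
                                swing_amp = swing_amp, swing_dur = swing_dur))
}

#' Inject the three-clap synchronization pattern
#'
#' Adds two bursts of three high-amplitude accelerometer spikes (one burst
#' near each end of the stream) on all three accelerometer axes, mimicking the
#' rod being clapped to the ground three times before and after a recording.
#' True clap times are recorded in the `sync_truth` attribute of the result.
#'
#' @param stream A [sensor_stream()] in physical units.
#' @param at_start,at_end Logical: inject the leading/trailing burst.
#' @param amp Peak clap amplitude in g (default 12, well above the 8 g
#'   detection threshold).
#' @param spacing Within-burst clap spacing in seconds.
#' @param offset Time of the first clap from the respective stream end.
#' @return The stream with claps added; attribute `sync_truth` holds
#'   `start_times`/`end_times` (seconds, first clap first).
#' @export
inject_sync_pattern <- function(stream, at_start = TRUE, at_end = TRUE,
                                amp = 12, spacing = 0.4, offset = 1.0) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!at_start && !at_end)
    stop("zero-length insertion request: at least one of at_start/at_end", call. = FALSE)
  rate <- stream$rate
  dur <- diff(range(stream$times))
  need <- offset + 2 * spacing + 0.2
  if (dur < (at_start + at_end) * need)
    stop("stream too short for the requested synchronization bursts", call. = FALSE)
  sig <- stream$data
  n <- nrow(sig)
  clap <- function(t_first) {
    tt <- t_first + spacing * (0:2)
    for (tc in tt) {
      i0 <- round(tc * rate) + 1
      len <- min(n - i0 + 1, round(0.08 * rate))
      ts <- (seq_len(len) - 1) / rate
      ring <- amp * exp(-ts / 0.02) * cos(2 * pi * 25 * ts)
      idx <- i0:(i0 + len - 1)
      for (k in 1:3) sig[idx, k] <<- sig[idx, k] + ring
    }
    tt
  }
  truth <- list()
  if (at_start) truth$start_times <- clap(offset)
  if (at_end) truth$end_times <- clap(dur - offset - 2 * spacing)
  acc <- sig[, 1:3]; acc[acc > 16] <- 16; acc[acc < -16] <- -16
  sig[, 1:3] <- acc
  out <- sensor_stream(stream$times, sig, rate = rate, scaled = stream$scaled)
  attr(out, "sync_truth") <- truth
  out
}

#' Generate a train / lab-test / field-test benchmark
#'
#' Generates disjoint session sets mirroring a study design with controlled
#' laboratory recordings and uncontrolled field recordings: training sessions
#' (mixed lab/field), a lab test split, and a field test split. Field-flagged
#' sessions use widened amplitude ranges and more running/agile background
#' than lab-flagged ones.
#'
#' @param config A [synth_config()]; its `seed` seeds the whole benchmark and
#'   per-session seeds are derived from it.
#' @param n_train,n_lab_test,n_field_test Sessions per split.
#' @return List with elements `train`, `lab_test`, `field_test`, each a list
#'   of [session()] objects with disjoint session ids.
#' @export
make_benchmark_split <- function(config, n_train = 6, n_lab_test = 3,
                                 n_field_test = 3) {
  stopifnot(inherits(config, "synth_config"))
  mk <- function(i, setting, split) {
    cfg <- config
    cfg$seed <- config$seed * 1000L + i
    cfg$setting <- setting
    if (setting == "field") {
      cfg$background <- c(standing = 0.2, walking = 0.3, running = 0.5)
      none_extra <- ceiling(cfg$counts[["none"]] * 0.5)
      cfg$counts[["none"]] <- cfg$counts[["none"]] + none_extra
    }
    generate_session(cfg, session_id = sprintf("%s-%02d", split, i))
  }
  n_train_field <- floor(n_train / 3)
  train <- lapply(seq_len(n_train), function(i)
    mk(i, if (i <= n_train - n_train_field) "lab" else "field", "train"))
  lab_test <- lapply(seq_len(n_lab_test), function(i) mk(100L + i, "lab", "lab"))
  field_test <- lapply(seq_len(n_field_test), function(i) mk(200L + i, "field", "field"))
  list(train = train, lab_test = lab_test, field_test = field_test)
}

#' Reference learning benchmark
#'
#' The package's standard desk-scale benchmark for classifier experiments:
#' a [make_benchmark_split()] of 6 training / 3 lab-test / 3 field-test
#' sessions whose per-session event mix doubles the generator defaults
#' (about 560 training windows), together with a session-grouped
#' train/validation split of the segmented training windows (the last
#' training session is held out for validation).
#'
#' @param seed Integer seed.
#' @param regime Template difficulty (see [synth_config()]).
#' @return List: `split` (the session split), `train`, `val` (window sets),
#'   plus `lab_test` / `field_test` session lists.
#' @export
learning_benchmark <- function(seed = 1L, regime = "separable") {
  base <- synth_config(seed = seed, regime = regime,
                       counts = c("shot" = 8, "long pass" = 6,
                                  "short pass medial" = 12,
                                  "short pass other" = 10,
                                  "light contact" = 24, "strong contact" = 16,
                                  "none" = 16, "unknown" = 2))
  split <- make_benchmark_split(base, n_train = 6, n_lab_test = 3,
                                n_field_test = 3)
  ws <- segment_sessions(split$train)
  ids <- unique(ws$session_ids)
  val <- ws$session_ids %in% ids[length(ids)]
  list(split = split,
       train = subset_windows(ws, which(!val)),
       val = subset_windows(ws, which(val)),
       lab_test = split$lab_test, field_test = split$field_test)
}
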