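# High-pass filter, SMV, moving windows, peak detection, candidate selection.

test_that("high-pass filter kills DC and low frequencies, passes 50 Hz", {
  rate <- 200
  t <- (0:1999) / rate
  mk <- function(gyro) {
    d <- matrix(0, length(t), 6); d[, 4:6] <- gyro
    sensor_stream(t, d, rate = rate)
  }
  # constant (DC) input decays to ~0 after the transient
  dc <- highpass_gyro(mk(matrix(5, length(t), 3)))
  expect_lt(max(abs(dc[500:2000, ])), 1e-6)

  # independent oracle for the digital filter's magnitude response
  gain_at <- function(f, cutoff = 20, order = 2) {
    bf <- signal::butter(order, cutoff / (rate / 2), type = "high")
    w <- 2 * pi * f / rate
    z <- exp(-1i * w * (seq_along(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * z))
  }
  steady <- function(f) {
    g <- matrix(sin(2 * pi * f * t), length(t), 3)
    out <- highpass_gyro(mk(g))
    # amplitude from the RMS over whole periods (sampled maxima are biased
    # low when few samples fall per period)
    sqrt(2 * mean(out[1001:2000, 1]^2))
  }
  expect_equal(steady(50), gain_at(50), tolerance = 0.01)
  expect_lt(steady(1), 0.01) # 1 Hz attenuated below 1 % of input
  expect_lt(gain_at(1), 0.01)

  tiny <- sensor_stream((0:9) / 200, matrix(0, 10, 6))
  expect_error(highpass_gyro(tiny), "warm-up")
})

test_that("signal magnitude vector is the per-sample Euclidean norm", {
  g <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1))
  expect_equal(smv(g), c(0, 5, sqrt(3)))
  expect_error(smv(matrix(0, 5, 2)), "3 equal-length channels")
})

test_that("moving windows stride at 75 percent of the window length", {
  expect_equal(moving_windows(1000), c(1L, 301L, 601L))
  expect_equal(moving_windows(400), 1L)
  expect_equal(moving_windows(399), integer(0))
})

test_that("peak detection matches a brute-force oracle", {
  bump <- function(center, amp, width = 30, n = 400) {
    x <- numeric(n)
    idx <- pmax(1, center - width):pmin(n, center + width)
    x[idx] <- amp * exp(-((idx - center) / (width / 3))^2)
    x
  }
  expect_equal(detect_peaks(numeric(400)), integer(0))
  expect_equal(detect_peaks(bump(200, 1.0)), 200L)

  # brute-force oracle: all local maxima above 0.3 * max, then pairwise check
  x <- bump(50, 1.0, 20, 450) + bump(400, 0.5, 20, 450)
  oracle <- which(diff(sign(diff(x))) == -2) + 1L
  oracle <- oracle[x[oracle] > 0.3 * max(x)]
  expect_equal(sort(detect_peaks(x)), sort(oracle))
  expect_length(detect_peaks(x), 2) # 350 apart, both above threshold

  # thinning keeps the higher of two close peaks
  y <- bump(100, 1.0, 20, 400) + bump(250, 0.6, 20, 400)
  expect_equal(detect_peaks(y, min_distance = 300), 100L)
})

test_that("candidate selection finds every labelled kick", {
  s <- default_session()
  cs <- select_candidates(s)
  rec <- candidate_recall(s, cs)
  expect_equal(rec$recall, 1.0)
  expect_equal(cs$stats$windows_total, cs$stats$rejected + cs$stats$candidates)
})

test_that("pure standing sessions yield zero candidates", {
  cs <- select_candidates(quiet_session())
  expect_equal(cs$stats$candidates, 0L)
  expect_equal(cs$stats$rejected, cs$stats$windows_total)
})

test_that("adding an impact to a quiet session only creates candidates", {
  q <- quiet_session()
  base <- select_candidates(q)$stats$candidates
  st <- q$streams$left
  d <- st$data
  i0 <- 5000
  tt <- (0:60) / 200
  ring <- exp(-tt / 0.03) * cos(2 * pi * 40 * tt)
  d[i0:(i0 + 60), 5] <- d[i0:(i0 + 60), 5] + 800 * ring
  d[i0:(i0 + 60), 1] <- d[i0:(i0 + 60), 1] + 5 * ring
  boosted <- session(q$session_id, list(left = sensor_stream(st$times, d)),
                     q$events)
  after <- select_candidates(boosted)
  expect_gt(after$stats$candidates, base)
})

test_that("candidate centers are local SMV maxima and labels use precedence", {
  s <- default_session()
  cs <- select_candidates(s)
  st <- scale_stream(s$streams$left)
  v <- smv(highpass_gyro(st))
  r <- cs$params$merge_radius
  for (i in seq_len(min(10, nrow(cs$windows$meta)))) {
    p <- cs$windows$meta$center[i]
    win <- max(1, p - r):min(length(v), p + r)
    expect_equal(v[p], max(v[win]))
  }
  # windows whose only contact is unknown are excluded
  unk <- s$events$time[s$events$fine_type == "unknown"]
  if (length(unk) > 0) {
    tt <- st$times[cs$windows$meta$center]
    near <- which(abs(tt - unk[1]) <= 0.5)
    if (length(near) > 0)
      expect_true(all(cs$windows$labels[near] == "excluded"))
  }
})

test_that("shot precedence wins when a kick and dribble share a window", {
  # hand-built session: a shot at 10.0 s and a light contact 0.4 s later,
  # inside the same 1 s label window
  n <- 6000
  d <- matrix(0, n, 6)
  ring <- function(i0, amp_a, amp_g, f = 40) {
    tt <- (0:60) / 200
    r <- exp(-tt / 0.03) * cos(2 * pi * f * tt)
    d[i0:(i0 + 60), 1] <<- d[i0:(i0 + 60), 1] + amp_a * r
    d[i0:(i0 + 60), 5] <<- d[i0:(i0 + 60), 5] + amp_g * r
  }
  ring(10.0 * 200 + 1, 16, 1500)
  ring(10.4 * 200 + 1, 1.5, 200)
  st <- sensor_stream((0:(n - 1)) / 200, d)
  ev <- contact_events(c(10.0, 10.4), c("left", "left"),
                       c("shot", "light contact"))
  s <- session("precedence", list(left = st), ev)
  cs <- select_candidates(s)
  tt <- st$times[cs$windows$meta$center]
  near <- which(abs(tt - 10.0) <= 0.5)
  expect_true(length(near) > 0)
  expect_true(all(cs$windows$labels[near] == "shot"))
})

test_that("parameter tuning utility ranks full-sensitivity settings first", {
  s <- fixture("tune_session", function()
    generate_session(synth_config(seed = 41, duration_s = 90,
                                  counts = c("shot" = 2, "short pass medial" = 4,
                                             "light contact" = 6))))
  grid <- expand.grid(threshold_frac = c(0.3), min_peak_height = c(100, 1500))
  res <- tune_candidate_params(list(s), grid)
  expect_equal(res$sensitivity[1], 1.0)
  # an absurdly high floor loses kicks and ranks below
  expect_true(res$min_peak_height[1] == 100)
})
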