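# Generator: event counts by construction, determinism, waveform cues
# (saturation, pre-contact zero crossing), sync pattern, benchmark splits.

test_that("generated sessions match requested counts and are deterministic", {
  cfg <- synth_config(seed = 1, counts = c("shot" = 5, "short pass medial" = 10,
                                           "light contact" = 20))
  s <- generate_session(cfg)
  tab <- table(s$events$fine_type)
  expect_equal(unname(tab[["shot"]]), 5)
  expect_equal(unname(tab[["short pass medial"]]), 10)
  expect_equal(unname(tab[["light contact"]]), 20)
  s2 <- generate_session(cfg)
  expect_identical(s$streams$left$data, s2$streams$left$data)
  expect_identical(s$events, s2$events)
})

test_that("every generated shot reaches accelerometer saturation", {
  s <- default_session()
  st <- s$streams$left
  shots <- s$events[s$events$fine_type == "shot", ]
  expect_gt(nrow(shots), 0)
  for (t0 in shots$time) {
    i0 <- round(t0 * st$rate) + 1
    idx <- max(1, i0 - 100):min(n_samples(st), i0 + 100)
    expect_equal(max(abs(st$data[idx, 1:3])), 16)
  }
  # passes peak below saturation
  passes <- s$events[s$events$class == "pass", ]
  for (t0 in passes$time) {
    i0 <- round(t0 * st$rate) + 1
    idx <- max(1, i0 - 60):min(n_samples(st), i0 + 60)
    expect_lt(max(abs(st$data[idx, 1:3])), 16)
  }
})

test_that("kick events carry a sagittal zero crossing before contact", {
  s <- default_session()
  st <- s$streams$left
  kicks <- s$events[s$events$class %in% c("shot", "pass"), ]
  for (t0 in kicks$time) {
    i0 <- round(t0 * st$rate) + 1
    pre <- st$data[max(1, i0 - 80):(i0 - 1), 4]
    expect_true(any(pre[-1] * pre[-length(pre)] <= 0))
  }
})

test_that("labelled kicks coincide with super-threshold SMV peaks", {
  s <- default_session()
  st <- scale_stream(s$streams$left)
  v <- smv(highpass_gyro(st))
  light_max <- 300 / 2000 # upper light-contact ring amplitude, scaled
  kicks <- s$events[s$events$class %in% c("shot", "pass"), ]
  for (t0 in kicks$time) {
    i0 <- round(t0 * st$rate) + 1
    idx <- max(1, i0 - 100):min(n_samples(st), i0 + 100)
    expect_gt(max(v[idx]), light_max)
  }
})

test_that("sync pattern injects three qualifying peaks per burst", {
  st <- sensor_stream((0:3999) / 200, matrix(0, 4000, 6))
  out <- inject_sync_pattern(st)
  truth <- attr(out, "sync_truth")
  expect_length(truth$start_times, 3)
  expect_length(truth$end_times, 3)
  for (k in 1:3) {
    x <- abs(out$data[, k])
    above <- which(x > 8)
    # claps cluster around the six injected times
    for (tt in c(truth$start_times, truth$end_times)) {
      i0 <- round(tt * 200) + 1
      expect_true(any(abs(above - i0) <= 3))
    }
  }
  expect_error(inject_sync_pattern(st, at_start = FALSE, at_end = FALSE),
               "zero-length")
  short <- sensor_stream((0:199) / 200, matrix(0, 200, 6))
  expect_error(inject_sync_pattern(short), "too short")
})

test_that("benchmark splits are disjoint and field widens pass amplitudes", {
  bench <- fixture("bench_default", function()
    make_benchmark_split(synth_config(seed = 11), n_train = 4,
                         n_lab_test = 2, n_field_test = 2))
  ids <- lapply(bench, function(ss) vapply(ss, function(s) s$session_id, ""))
  expect_length(intersect(ids$train, ids$lab_test), 0)
  expect_length(intersect(ids$train, ids$field_test), 0)
  expect_length(intersect(ids$lab_test, ids$field_test), 0)

  pass_amps <- function(ss) {
    unlist(lapply(ss, function(s) {
      tr <- s$extra$truth$left$events
      cls <- vapply(tr, function(e) map_contact_to_class(e$fine_type), "")
      vapply(tr[cls == "pass"], function(e) e$accel_amp, numeric(1))
    }))
  }
  expect_gt(stats::var(pass_amps(bench$field_test)),
            stats::var(pass_amps(bench$lab_test)))
})

test_that("configured class ratio is reproduced within 1 percent", {
  ratio <- c(shot = 8424, pass = 24254, null = 61168)
  cfg <- synth_config(seed = 2, duration_s = 600, n_events = 300,
                      class_ratio = ratio)
  cls <- map_contact_to_class(rep(names(cfg$counts), cfg$counts))
  emp <- table(factor(cls, levels = c("shot", "pass", "null"))) / length(cls)
  expect_equal(as.numeric(emp), as.numeric(ratio / sum(ratio)),
               tolerance = 0.01)
  # imbalance direction always null > pass > shot under defaults
  d <- table(factor(map_contact_to_class(
    rep(CONTACT_TYPES, synth_config()$counts)), levels = c("shot", "pass", "null")))
  expect_true(d[["null"]] > d[["pass"]] && d[["pass"]] > d[["shot"]])
})

test_that("infeasible event budgets and bad configs are rejected", {
  expect_error(synth_config(min_spacing = 0.2), ">= 0.3")
  cfg <- synth_config(seed = 1, duration_s = 20,
                      counts = c("light contact" = 100))
  expect_error(generate_session(cfg), "do not fit")
})
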