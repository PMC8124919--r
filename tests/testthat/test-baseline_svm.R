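# Kick-phase landmarks, absolute-sum features, linear one-vs-rest SVM.

test_that("ball contact is the maximum sagittal angular acceleration", {
  # brute-force oracle over random windows
  set.seed(5)
  for (rep in 1:20) {
    w <- random_window()
    oracle <- which.max(diff(w[, 4])) + 1L
    expect_equal(find_ball_contact(w), oracle)
  }
  # ramp then flat: contact at the steepest discrete step
  w <- matrix(0, 400, 6)
  w[, 4] <- c(seq(0, 1, length.out = 100)^2, rep(1, 300))
  expect_equal(find_ball_contact(w), which.max(diff(w[, 4])) + 1L)
  # single step discontinuity at i
  w2 <- matrix(0, 400, 6); w2[, 4] <- c(rep(-1, 149), rep(1, 251))
  expect_equal(find_ball_contact(w2), 150L)
  # constant gx is degenerate
  w3 <- matrix(1, 400, 6)
  expect_error(find_ball_contact(w3), "degenerate")
})

test_that("phase start is the last sagittal zero crossing before contact", {
  # brute-force scan oracle
  scan_oracle <- function(gx, contact) {
    for (k in (contact - 1):1) {
      if (gx[k] == 0) return(k)
      if (k >= 2 && gx[k] * gx[k - 1] < 0) return(k)
    }
    1L
  }
  gx <- c(rep(-0.5, 199), sin(pi * (0:99) / 99) + 0.1, rep(2, 101))
  w2 <- matrix(0, 400, 6); w2[, 4] <- gx
  expect_equal(find_phase_start(w2, 350), scan_oracle(gx, 350))
  expect_equal(find_phase_start(w2, 350), 200L) # sign change -0.5 -> +0.1

  # strictly positive before contact: fallback to window start with warning
  w3 <- matrix(0, 400, 6); w3[, 4] <- 1 + (1:400) / 400
  expect_warning(st <- find_phase_start(w3, 300), "zero crossing")
  expect_equal(st, 1L)

  # exact zero at k < contact
  w4 <- matrix(0, 400, 6); w4[, 4] <- 2
  w4[123, 4] <- 0
  expect_equal(find_phase_start(w4, 200), 123L)
})

test_that("features equal a brute-force oracle and scale linearly", {
  set.seed(7)
  for (rep in 1:50) {
    w <- random_window()
    f <- suppressWarnings(extract_features(w))
    # independently coded re-summation
    contact <- which.max(diff(w[, 4])) + 1L
    gx <- w[, 4]
    start <- 1L
    for (k in seq(contact - 1L, 1L)) {
      if (gx[k] == 0) { start <- k; break }
      if (k >= 2 && gx[k] * gx[k - 1] < 0) { start <- k; break }
    }
    oracle <- numeric(6)
    for (ch in 1:6) for (i in start:contact)
      oracle[ch] <- oracle[ch] + abs(w[i, ch])
    expect_equal(unname(f), oracle, tolerance = 1e-12)
    expect_equal(unname(suppressWarnings(extract_features(2 * w))),
                 2 * unname(f), tolerance = 1e-12)
  }
  # all-zero signal inside the phase gives six zeros
  w <- matrix(0, 400, 6); w[, 4] <- c(rep(0, 398), 1, 1)
  f <- suppressWarnings(extract_features(w))
  expect_true(all(f[-4] == 0))
})

test_that("the cost grid spans 2^-10..2^10 and folds never split sessions", {
  grid <- 2^(-10:10)
  expect_length(grid, 21)
  expect_true(32 %in% grid)

  bm <- fixture("bench_sep", function() learning_benchmark(seed = 5))
  ws <- bm$train
  # fold assignment used by the trainer: one fold id per session
  m <- train_svm(ws, c_grid = c(1, 32), seed = 1)
  expect_s3_class(m, "kick_svm")
  expect_true(m$C %in% c(1, 32))

  # under-sampling balances class counts exactly
  b <- undersample_windows(ws, seed = 1)
  tab <- table(b$labels)
  expect_true(all(tab == min(table(ws$labels))))
  # and is reproducible given the seed
  b2 <- undersample_windows(ws, seed = 1)
  expect_identical(b$labels, b2$labels)
  expect_false(identical(undersample_windows(ws, seed = 2)$x, b$x))
})

test_that("the SVM separates the separable benchmark and guards contracts", {
  bm <- fixture("bench_sep", function() learning_benchmark(seed = 5))
  m <- fixture("svm_sep", function() train_svm(bm$train, seed = 1))
  # training windows re-predicted mostly correctly under separable config
  pred <- classify_windows(m, bm$train)
  expect_gt(mean(pred == bm$train$labels), 0.8)

  # all-zero window takes the degenerate path and scores null
  zero_ws <- window_set(list(matrix(0, 400, 6)), "null", "none", "z")
  expect_equal(predict_svm(m, zero_ws), "null")

  # channel order is a hard contract: permuting channels changes predictions
  perm <- bm$train$x[, , c(4, 5, 6, 1, 2, 3)]
  ws_perm <- window_set(perm, bm$train$labels, bm$train$fine_types,
                        bm$train$session_ids)
  expect_false(identical(classify_windows(m, ws_perm), pred))

  # a class absent from training is an error
  idx <- which(bm$train$labels != "shot")
  expect_error(train_svm(subset_windows(bm$train, idx)), "absent")
})
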