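# Metrics against independent oracles; confusion matrix; scenarios.

# independently coded metric oracle: direct evaluation of the definitions
oracle_metrics <- function(truth, pred, classes = c("shot", "pass", "null")) {
  f1s <- numeric(length(classes)); w <- numeric(length(classes))
  sens <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    w[i] <- sum(truth == cl)
    sens[i] <- if (w[i] > 0) tp / (tp + fn) else NA_real_
  }
  list(weighted_f1 = sum(w * f1s) / sum(w), f1 = f1s, sensitivity = sens)
}

test_that("F1 and sensitivity match the oracle on 100 random configurations", {
  set.seed(11)
  classes <- c("shot", "pass", "null")
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    truth <- sample(classes, n, replace = TRUE,
                    prob = stats::runif(3, 0.05, 1))
    pred <- ifelse(stats::runif(n) < stats::runif(1, 0, 1),
                   truth, sample(classes, n, replace = TRUE))
    counts <- class_counts(truth, pred)
    o <- oracle_metrics(truth, pred)
    expect_equal(f1_weighted(counts), o$weighted_f1, tolerance = 1e-12)
    expect_equal(unname(f1_class(counts)), o$f1, tolerance = 1e-12)
    expect_equal(unname(sensitivity_class(counts)), o$sensitivity,
                 tolerance = 1e-12)
  }
})

test_that("metric edge cases follow the stated conventions", {
  truth <- c("shot", "pass", "null", "null")
  expect_equal(weighted_f1(truth, truth), 1.0)
  # class with P = R = 0 scores 0
  counts <- class_counts(c("shot", "pass"), c("pass", "shot"))
  expect_equal(f1_class(counts)[1:2], c(0, 0))
  expect_error(f1_weighted(class_counts(character(0), character(0))),
               "supports")
  # sensitivity arithmetic
  cc <- data.frame(class = "shot", tp = 3, fn = 1, fp = 0, support = 4)
  expect_equal(unname(sensitivity_class(cc)), 0.75)
  cc0 <- data.frame(class = "shot", tp = 0, fn = 0, fp = 2, support = 0)
  expect_true(is.na(sensitivity_class(cc0)))
})

test_that("weighted F1 reproduces a hand-computed three-class toy", {
  # supports (10, 20, 70) with per-class (P, R) of (1.0, 0.5), (0.5, 1.0),
  # (0.9, 0.9); expected value evaluated directly from the definitions
  f1 <- c(2 * 1.0 * 0.5 / 1.5, 2 * 0.5 * 1.0 / 1.5, 2 * 0.9 * 0.9 / 1.8)
  expected <- sum(c(10, 20, 70) * f1) / 100
  counts <- data.frame(class = c("shot", "pass", "null"),
                       tp = c(5, 20, 63), fn = c(5, 0, 7),
                       fp = c(0, 20, 7), support = c(10, 20, 70))
  # check the counts encode the intended precision/recall
  expect_equal(counts$tp / (counts$tp + counts$fp), c(1.0, 0.5, 0.9))
  expect_equal(counts$tp / (counts$tp + counts$fn), c(0.5, 1.0, 0.9))
  expect_equal(f1_weighted(counts), expected, tolerance = 1e-12)
})

test_that("fine-grained confusion matrix is column-normalized and exact", {
  # perfect classifier: 1 where the type's true class meets the prediction
  types <- setdiff(CONTACT_TYPES, "unknown")
  truth_cls <- map_contact_to_class(types)
  m <- fine_grained_confusion(truth_cls, types)
  for (j in seq_along(types)) {
    expect_equal(m[truth_cls[j], types[j]], 1.0)
    expect_equal(sum(m[, types[j]]), 1.0)
  }
  # one shot predicted pass: shot column (0, 1, 0)
  m1 <- fine_grained_confusion("pass", "shot")
  expect_equal(unname(m1[, "shot"]), c(0, 1, 0))
  # mixed 12-sample toy vs hand tabulation
  ft <- c(rep("shot", 3), rep("long pass", 4), rep("light contact", 5))
  pr <- c("shot", "pass", "shot", "pass", "pass", "shot", "null",
          "null", "null", "pass", "null", "null")
  m2 <- fine_grained_confusion(pr, ft)
  expect_equal(unname(m2[, "shot"]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(m2[, "long pass"]), c(1 / 4, 2 / 4, 1 / 4))
  expect_equal(unname(m2[, "light contact"]), c(0, 1 / 5, 4 / 5))
  nonempty <- colSums(m2) > 0
  expect_equal(unname(colSums(m2)[nonempty]), rep(1, sum(nonempty)))
  expect_error(fine_grained_confusion("shot", "bicycle kick"), "unknown fine_type")
})

test_that("segmented scenario evaluates one window per labelled contact", {
  s <- default_session()
  rep_ <- run_segmented_scenario(oracle_classifier(), list(s))
  n_lab <- sum(s$events$class != "excluded")
  expect_equal(rep_$n, n_lab)
  expect_equal(rep_$weighted_f1, 1.0)
  expect_error(run_segmented_scenario(oracle_classifier(),
                                      list(quiet_session())),
               "labelled ball contacts")
})

test_that("window scenario counts rejections and the oracle is perfect", {
  s <- default_session()
  rep_ <- run_window_scenario(oracle_classifier(), list(s), "window_lab")
  cs <- rep_$candidate_stats
  expect_equal(cs$windows_total, cs$rejected + cs$candidates)
  expect_equal(rep_$sensitivity[["shot"]], 1.0)
  expect_equal(rep_$sensitivity[["pass"]], 1.0)
  # pure noise: no candidates, empty metrics, full rejection
  repq <- run_window_scenario(oracle_classifier(), list(quiet_session()))
  expect_equal(repq$n, 0L)
  expect_true(is.na(repq$weighted_f1))
  expect_equal(repq$candidate_stats$rejected, repq$candidate_stats$windows_total)
})

test_that("segmented and window scenarios agree for an oracle model on
           well-separated super-threshold events", {
  cfg <- synth_config(seed = 23, duration_s = 120, min_spacing = 2.5,
                      counts = c("shot" = 3, "short pass medial" = 4,
                                 "strong contact" = 5))
  s <- generate_session(cfg)
  a <- run_segmented_scenario(oracle_classifier(), list(s))
  b <- run_window_scenario(oracle_classifier(), list(s))
  expect_equal(a$weighted_f1, 1.0)
  expect_equal(b$weighted_f1, 1.0)
  expect_equal(unname(a$sensitivity), unname(b$sensitivity))
})
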