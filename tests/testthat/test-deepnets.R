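# Architecture fidelity against the reference layer tables, gradient
# correctness against numeric differentiation, training-loop contracts.

test_that("CNN reproduces every reference shape and parameter count", {
  m <- build_cnn()
  tab <- model_summary(m)
  expect_equal(tab$output_shape,
               c("(398, 256)", "(199, 256)", "(197, 128)", "(197, 128)",
                 "(98, 128)", "(96, 16)", "(96, 16)", "(48, 16)", "(768)",
                 "(768)", "(3)"))
  expect_equal(tab$n_params, c(4864, 0, 98432, 0, 0, 6160, 0, 0, 0, 0, 2307))
  expect_equal(n_parameters(m), 4864 + 98432 + 6160 + 2307)
  # the layer table matches the actual parameter arrays
  expect_equal(n_parameters(m, actual = TRUE), n_parameters(m))
})

test_that("LSTM reproduces the reference parameter counts", {
  m <- build_lstm()
  tab <- model_summary(m)
  expect_equal(tab$n_params, c(18432, 256, 195))
  # double-bias recurrent layer: 4u(Cin + u) + 2 * 4u
  expect_equal(tab$n_params[1], 4 * 64 * (6 + 64) + 2 * 4 * 64)
  # normalization: 2 learned + 2 running statistics per unit
  expect_equal(tab$n_params[2], 4 * 64)
  expect_equal(tab$n_params[3], (64 + 1) * 3)
  expect_equal(n_parameters(m, actual = TRUE), 18432 + 256 + 195)
})

test_that("convLSTM reproduces the reference shapes and parameter counts", {
  m <- build_convlstm()
  tab <- model_summary(m)
  expect_equal(tab$output_shape[1], "(1, 48, 128)")
  expect_equal(tab$output_shape[3], "(6144)")
  expect_equal(tab$n_params, c(206336, 0, 0, 18435))
  # single bias per gate: 4f(k*Cin + k*f + 1)
  expect_equal(tab$n_params[1], 4 * 128 * (3 * 6 + 3 * 128 + 1))
  expect_equal(tab$n_params[4], (6144 + 1) * 3)
  expect_equal(n_parameters(m, actual = TRUE), 206336 + 18435)
  expect_error(build_convlstm(num_segments = 7), "divisible")
})

test_that("analytic gradients match numeric differentiation", {
  ns <- asNamespace("kicksense")
  gradcheck <- function(model, b = 2, eps = 1e-5, k_checks = 6) {
    set.seed(42)
    x <- array(stats::rnorm(b * 400 * 6, sd = 0.3), c(b, 400, 6))
    y <- ns$.onehot(sample(c("shot", "pass", "null"), b, replace = TRUE))
    loss_at <- function(m) {
      fw <- ns$.net_forward(m, x, training = TRUE)
      ns$softmax_xent(fw$logits, y)$loss
    }
    fw <- ns$.net_forward(model, x, training = TRUE)
    lo <- ns$softmax_xent(fw$logits, y)
    g <- ns$.net_backward(model, fw, lo$dz)
    worst <- 0
    for (nm in names(g)) {
      idx <- sample(length(model$params[[nm]]),
                    min(k_checks, length(model$params[[nm]])))
      for (i in idx) {
        m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
        m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
        num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
        rel <- abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i]))
        worst <- max(worst, rel)
      }
    }
    worst
  }
  expect_lt(gradcheck(build_cnn(filters = c(8, 6, 4), dropouts = c(0, 0, 0),
                                seed = 2)), 1e-4)
  expect_lt(gradcheck(build_lstm(units = 6, l1 = 0, l2 = 0, seed = 2)), 1e-4)
  expect_lt(gradcheck(build_convlstm(filters = 5, dropout = 0, seed = 2)), 1e-4)
})

test_that("probability output is a proper, shape-checked softmax", {
  m <- fixture("tiny_cnn", function() build_cnn(filters = c(8, 6, 4), seed = 3))
  set.seed(4)
  x <- array(stats::rnorm(3 * 400 * 6), c(3, 400, 6))
  p <- predict_proba(m, x)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicated inputs give identical rows at inference
  x2 <- x[c(1, 1, 2), , ]
  p2 <- predict_proba(m, x2)
  expect_equal(p2[1, ], p2[2, ])
  expect_error(predict_proba(m, array(0, c(2, 399, 6))), "400")
})

test_that("the LR schedule multiplies by 0.2 per 20-epoch stagnation", {
  tc <- train_config()
  expect_equal(tc$batch_size, 64)
  expect_equal(tc$epochs, 100)
  expect_equal(tc$patience, 40)
  expect_equal(tc$lr_factor * tc$lr_factor, 0.04)
  # constant windows: validation F1 can never improve after epoch 1
  n <- 12
  x <- array(0, c(n, 400, 6))
  ws <- window_set(x, rep(c("shot", "pass", "null"), 4),
                   rep("none", n), rep(c("a", "b"), 6))
  m <- build_cnn(filters = c(4, 4, 4), dropouts = c(0, 0, 0), seed = 1)
  m$lr <- 0.05
  fit <- train_model(m, ws, ws,
                     train_config(epochs = 45, patience = 44, lr_patience = 20,
                                  batch_size = 6, seed = 1))
  expect_equal(fit$history$lr[45], 0.05 * 0.2^2, tolerance = 1e-12)
})

test_that("training is deterministic given the seed and rejects one class", {
  n <- 18
  set.seed(9)
  x <- array(stats::rnorm(n * 400 * 6, sd = 0.2), c(n, 400, 6))
  labs <- rep(c("shot", "pass", "null"), 6)
  ws <- window_set(x, labs, rep("none", n), rep(c("a", "b", "c"), each = 6))
  m <- build_cnn(filters = c(6, 4, 4), seed = 2)
  tc <- train_config(epochs = 3, patience = 2, lr_patience = 1,
                     batch_size = 6, seed = 7)
  f1 <- train_model(m, ws, ws, tc)
  f2 <- train_model(m, ws, ws, tc)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  # under-sampling balances counts before training
  expect_true(all(table(undersample_windows(ws, 1)$labels) == 6))
  one <- subset_windows(ws, which(labs == "shot"))
  expect_error(train_model(m, one, ws, tc), "single class")
})

test_that("search spaces match the reference ranges and the search runs", {
  sp <- search_space("cnn")
  expect_equal(sp$filter1$values, c(64, 128, 256, 512))
  expect_equal(sp$filter2$values, c(16, 32, 64, 128, 256))
  expect_equal(sp$poolsize$values, 2:5)
  expect_equal(sp$kernelsize$values, 2:4)
  expect_equal(c(sp$dropout1$lo, sp$dropout1$hi), c(0.01, 1))
  expect_equal(c(sp$learning_rate$lo, sp$learning_rate$hi), c(0.001, 0.1))
  expect_equal(search_space("lstm")$units$values, c(64, 128, 256, 512))
  expect_equal(search_space("convlstm")$num_segments$values, c(2, 4, 5, 8, 10))
  # reference optima ship as builder defaults
  expect_equal(build_cnn()$hyper$filters, c(256, 128, 16))
  expect_equal(build_cnn()$lr, 0.09996)
  expect_equal(build_lstm()$hyper$units, 64)
  expect_equal(build_lstm()$hyper$clipvalue, 0.19517)
  expect_equal(build_convlstm()$hyper$num_segments, 8)
  expect_equal(build_convlstm()$lr, 0.09403)

  expect_error(hyperparameter_search("cnn", NULL, space = list()), "empty")
  # budget 1 returns the single sampled configuration
  n <- 24
  set.seed(3)
  x <- array(stats::rnorm(n * 400 * 6, sd = 0.2), c(n, 400, 6))
  ws <- window_set(x, rep(c("shot", "pass", "null"), 8), rep("none", n),
                   rep(c("a", "b"), each = 12))
  sp_small <- list(filter1 = list(type = "categorical", values = c(4, 8)),
                   filter2 = list(type = "categorical", values = 4),
                   filter3 = list(type = "categorical", values = 4),
                   poolsize = list(type = "categorical", values = 2),
                   kernelsize = list(type = "categorical", values = 3),
                   dropout1 = list(type = "loguniform", lo = 0.01, hi = 0.2),
                   dropout2 = list(type = "loguniform", lo = 0.01, hi = 0.2),
                   dropout3 = list(type = "loguniform", lo = 0.01, hi = 0.2),
                   learning_rate = list(type = "loguniform", lo = 0.01, hi = 0.1))
  res <- hyperparameter_search("cnn", ws, budget = 1, space = sp_small,
                               n_folds = 2, epochs = 1, seed = 2)
  expect_equal(nrow(res$trials), 1)
  expect_true(res$best$filter1 %in% c(4, 8))
})
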