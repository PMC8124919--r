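# The three sequence classifiers — a 1D CNN, a single-layer LSTM and a
# convolutional LSTM — with their reference layer hyperparameters, a shared
# SGD training loop (under-sampling, early stopping, learning-rate schedule),
# and prediction. All forward/backward math lives in nn_layers.R.

#' Build the 1D CNN classifier
#'
#' Three convolutional blocks (valid padding, ReLU, max-pooling) followed by a
#' dense softmax head. Layers: conv(256, k=3) -> pool(2) -> conv(128, k=3) ->
#' dropout 0.30228 -> pool(2) -> conv(16, k=3) -> dropout 0.03576 -> pool(2)
#' -> flatten(768) -> dropout 0.43372 -> dense(3). Default learning rate
#' 0.09996. Intermediate shapes on a 400 x 6 input: (398,256), (199,256),
#' (197,128), (98,128), (96,16), (48,16), 768.
#'
#' @param filters Convolution filter counts.
#' @param kernel Kernel size (shared).
#' @param pool Pooling size (shared).
#' @param dropouts The three dropout rates.
#' @param lr Learning rate.
#' @param seed Seed for weight initialization.
#' @return A `kick_net` model spec of architecture `"cnn"`.
#' @export
build_cnn <- function(filters = c(256, 128, 16), kernel = 3, pool = 2,
                      dropouts = c(0.30228, 0.03576, 0.43372),
                      lr = 0.09996, seed = 1L) {
  t1 <- WINDOW_LEN - kernel + 1L; p1 <- t1 %/% pool
  t2 <- p1 - kernel + 1L; p2 <- t2 %/% pool
  t3 <- p2 - kernel + 1L; p3 <- t3 %/% pool
  flat <- p3 * filters[3]
  params <- with_seed(seed, list(
    W1 = glorot(kernel * 6, filters[1], c(kernel * 6, filters[1])),
    b1 = numeric(filters[1]),
    W2 = glorot(kernel * filters[1], filters[2], c(kernel * filters[1], filters[2])),
    b2 = numeric(filters[2]),
    W3 = glorot(kernel * filters[2], filters[3], c(kernel * filters[2], filters[3])),
    b3 = numeric(filters[3]),
    Wd = glorot(flat, 3, c(flat, 3)),
    bd = numeric(3)))
  layers <- data.frame(
    layer = c("conv1d", "maxpool", "conv1d", "dropout", "maxpool", "conv1d",
              "dropout", "maxpool", "flatten", "dropout", "dense"),
    hyper = c(sprintf("filters %d, kernel %d", filters[1], kernel),
              sprintf("pool %d", pool),
              sprintf("filters %d, kernel %d", filters[2], kernel),
              sprintf("rate %.5f", dropouts[1]), sprintf("pool %d", pool),
              sprintf("filters %d, kernel %d", filters[3], kernel),
              sprintf("rate %.5f", dropouts[2]), sprintf("pool %d", pool),
              "", sprintf("rate %.5f", dropouts[3]), "softmax"),
    output_shape = c(sprintf("(%d, %d)", t1, filters[1]),
                     sprintf("(%d, %d)", p1, filters[1]),
                     sprintf("(%d, %d)", t2, filters[2]),
                     sprintf("(%d, %d)", t2, filters[2]),
                     sprintf("(%d, %d)", p2, filters[2]),
                     sprintf("(%d, %d)", t3, filters[3]),
                     sprintf("(%d, %d)", t3, filters[3]),
                     sprintf("(%d, %d)", p3, filters[3]),
                     sprintf("(%d)", flat), sprintf("(%d)", flat), "(3)"),
    n_params = c(filters[1] * (kernel * 6 + 1), 0,
                 filters[2] * (kernel * filters[1] + 1), 0, 0,
                 filters[3] * (kernel * filters[2] + 1), 0, 0, 0, 0,
                 (flat + 1) * 3))
  structure(list(arch = "cnn", params = params, layers = layers, lr = lr,
                 hyper = list(filters = filters, kernel = kernel, pool = pool,
                              dropouts = dropouts),
                 trained = FALSE),
            class = "kick_net")
}

#' Build the LSTM classifier
#'
#' A single 64-unit recurrent layer returning its final hidden state, with two
#' independent bias vectors per gate set (input path and recurrent path), then
#' batch normalization, then a dense softmax head with L1/L2 kernel penalties.
#' Gradients are clipped by value during training. Default learning rate
#' 0.06955.
#'
#' @param units Hidden units.
#' @param l1,l2 Kernel penalties on the dense head.
#' @param clipvalue Gradient value-clipping threshold.
#' @param lr Learning rate.
#' @param seed Seed for weight initialization.
#' @return A `kick_net` model spec of architecture `"lstm"`.
#' @export
build_lstm <- function(units = 64, l1 = 0.00013, l2 = 0.00111,
                       clipvalue = 0.19517, lr = 0.06955, seed = 1L) {
  params <- with_seed(seed, list(
    Wx = glorot(6, 4 * units, c(6, 4 * units)),
    Wh = .orthogonal_ish(units, 4 * units),
    bx = .lstm_bias(units),
    bh = .lstm_bias(units),
    gamma = rep(1, units), beta = numeric(units),
    Wd = glorot(units, 3, c(units, 3)), bd = numeric(3)))
  layers <- data.frame(
    layer = c("lstm", "batchnorm", "dense"),
    hyper = c(sprintf("units %d", units), "", "softmax"),
    output_shape = c(sprintf("(%d)", units), sprintf("(%d)", units), "(3)"),
    n_params = c(4 * units * (6 + units) + 2 * 4 * units, 4 * units,
                 (units + 1) * 3))
  structure(list(arch = "lstm", params = params, layers = layers, lr = lr,
                 hyper = list(units = units, l1 = l1, l2 = l2,
                              clipvalue = clipvalue),
                 run_mean = numeric(units), run_var = rep(1, units),
                 trained = FALSE),
            class = "kick_net")
}

# forget-gate bias 1 (standard LSTM initialization), others 0; split across
# the two bias vectors
.lstm_bias <- function(u) c(numeric(u), rep(0.5, u), numeric(2 * u))

# semi-orthogonal initialization for recurrent kernels (per-gate orthogonal
# blocks, the convention of the reference deep-learning frameworks)
.orthogonal_ish <- function(n, m) {
  gates <- 4L
  mg <- m %/% gates
  out <- matrix(0, n, m)
  for (g in seq_len(gates)) {
    a <- matrix(stats::rnorm(n * mg), n, mg)
    qr_ <- qr(a)
    q <- qr.Q(qr_)
    # fix the sign convention so the draw is uniform over orthogonal matrices
    q <- q %*% diag(sign(diag(qr.R(qr_))), ncol(q))
    out[, ((g - 1) * mg + 1):(g * mg)] <- q[, seq_len(mg), drop = FALSE]
  }
  out
}

#' Build the convolutional LSTM classifier
#'
#' The 2 s window is split into `num_segments` time steps over a 1 x 50
#' spatial grid of 6 channels; a convolutional-recurrent layer (128 filters,
#' 1 x 3 kernel, valid input padding so the grid shrinks to 48, same-padded
#' recurrent convolution, single bias per gate) returns its final state, which
#' passes through dropout, flatten (48 x 128 = 6144) and a dense softmax head.
#' Default learning rate 0.09403.
#'
#' @param num_segments Time steps the 400-sample window is split into
#'   (must divide 400).
#' @param filters Recurrent convolution filters.
#' @param kernel Kernel size.
#' @param dropout Dropout rate before the dense head.
#' @param lr Learning rate.
#' @param seed Seed for weight initialization.
#' @return A `kick_net` model spec of architecture `"convlstm"`.
#' @export
build_convlstm <- function(num_segments = 8, filters = 128, kernel = 3,
                           dropout = 0.22620, lr = 0.09403, seed = 1L) {
  if (WINDOW_LEN %% num_segments != 0)
    stop(WINDOW_LEN, " samples are not divisible into ", num_segments,
         " segments", call. = FALSE)
  s_in <- WINDOW_LEN %/% num_segments
  s_out <- s_in - kernel + 1L
  flat <- s_out * filters
  params <- with_seed(seed, list(
    Wx = glorot(kernel * 6, 4 * filters, c(kernel * 6, 4 * filters)),
    Wh = .orthogonal_ish(kernel * filters, 4 * filters),
    b = c(numeric(filters), rep(0.5, filters), numeric(2 * filters)),
    Wd = glorot(flat, 3, c(flat, 3)), bd = numeric(3)))
  layers <- data.frame(
    layer = c("convlstm", "dropout", "flatten", "dense"),
    hyper = c(sprintf("filters %d, kernel %d, segments %d",
                      filters, kernel, num_segments),
              sprintf("rate %.5f", dropout), "", "softmax"),
    output_shape = c(sprintf("(1, %d, %d)", s_out, filters),
                     sprintf("(1, %d, %d)", s_out, filters),
                     sprintf("(%d)", flat), "(3)"),
    n_params = c(4 * filters * (kernel * 6 + kernel * filters + 1), 0, 0,
                 (flat + 1) * 3))
  structure(list(arch = "convlstm", params = params, layers = layers, lr = lr,
                 hyper = list(num_segments = num_segments, filters = filters,
                              kernel = kernel, dropout = dropout),
                 trained = FALSE),
            class = "kick_net")
}

#' Layer table of a model
#'
#' Per-layer hyperparameters, output shapes and parameter counts, mirroring
#' the architecture overview tables.
#'
#' @param model A `kick_net`.
#' @return data.frame with columns `layer`, `hyper`, `output_shape`,
#'   `n_params`.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "kick_net"))
  model$layers
}

#' Total parameter count of a model
#' @param model A `kick_net`.
#' @param actual Count the actual parameter arrays instead of the layer table.
#' @return Integer.
#' @export
n_parameters <- function(model, actual = FALSE) {
  if (actual) {
    n <- sum(vapply(model$params, length, numeric(1)))
    if (model$arch == "lstm") n <- n + 2 * length(model$run_mean) # running stats
    return(n)
  }
  sum(model_summary(model)$n_params)
}

#' @export
print.kick_net <- function(x, ...) {
  cat(sprintf("<kick_net> %s, %s, lr %g, %d parameters\n", x$arch,
              if (x$trained) "trained" else "untrained", x$lr, n_parameters(x)))
  print(model_summary(x), row.names = FALSE)
  invisible(x)
}

# --- forward / backward per architecture --------------------------------------

.net_forward <- function(model, x, training = FALSE) {
  p <- model$params
  h <- model$hyper
  cache <- list()
  if (model$arch == "cnn") {
    c1 <- conv1d_forward(x, p$W1, p$b1); r1 <- relu_forward(c1$out)
    m1 <- maxpool_forward(r1$out, h$pool)
    c2 <- conv1d_forward(m1$out, p$W2, p$b2); r2 <- relu_forward(c2$out)
    d1 <- dropout_forward(r2$out, h$dropouts[1], training)
    m2 <- maxpool_forward(d1$out, h$pool)
    c3 <- conv1d_forward(m2$out, p$W3, p$b3); r3 <- relu_forward(c3$out)
    d2 <- dropout_forward(r3$out, h$dropouts[2], training)
    m3 <- maxpool_forward(d2$out, h$pool)
    flat <- matrix(m3$out, dim(x)[1])
    d3 <- dropout_forward(flat, h$dropouts[3], training)
    dn <- dense_forward(d3$out, p$Wd, p$bd)
    cache <- list(c1 = c1, r1 = r1, m1 = m1, c2 = c2, r2 = r2, d1 = d1,
                  m2 = m2, c3 = c3, r3 = r3, d2 = d2, m3 = m3, d3 = d3,
                  dn = dn, flat_dims = dim(m3$out))
  } else if (model$arch == "lstm") {
    ls <- lstm_forward(x, p, keep_cache = training)
    bn <- batchnorm_forward(ls$out, p$gamma, p$beta, model$run_mean,
                            model$run_var, training,
                            init_running = !isTRUE(model$bn_seen))
    dn <- dense_forward(bn$out, p$Wd, p$bd)
    cache <- list(ls = ls, bn = bn, dn = dn)
  } else { # convlstm
    d <- dim(x)
    s_in <- WINDOW_LEN %/% h$num_segments
    xr <- array(x, c(d[1], s_in, h$num_segments, 6))
    xs <- aperm(xr, c(1, 3, 2, 4)) # (b, steps, S, Cin)
    cl <- convlstm_forward(xs, p, h$kernel, keep_cache = training)
    dr <- dropout_forward(cl$out, h$dropout, training)
    flat <- matrix(dr$out, d[1])
    dn <- dense_forward(flat, p$Wd, p$bd)
    cache <- list(cl = cl, dr = dr, dn = dn, flat_dims = dim(cl$out))
  }
  list(logits = cache$dn$out, cache = cache)
}

.net_backward <- function(model, fw, dlogits) {
  p <- model$params
  h <- model$hyper
  cc <- fw$cache
  g <- list()
  dn <- dense_backward(cc$dn, p$Wd, dlogits)
  g$Wd <- dn$dw; g$bd <- dn$db
  if (model$arch == "cnn") {
    dflat <- dropout_backward(cc$d3, dn$dx)
    dm3 <- array(dflat, cc$flat_dims)
    dd2 <- maxpool_backward(cc$m3, dm3)
    dr3 <- dropout_backward(cc$d2, dd2)
    dc3 <- relu_backward(cc$r3, dr3)
    b3 <- conv1d_backward(cc$c3, p$W3, dc3)
    g$W3 <- b3$dw; g$b3 <- b3$db
    dd1 <- maxpool_backward(cc$m2, b3$da)
    dr2 <- dropout_backward(cc$d1, dd1)
    dc2 <- relu_backward(cc$r2, dr2)
    b2 <- conv1d_backward(cc$c2, p$W2, dc2)
    g$W2 <- b2$dw; g$b2 <- b2$db
    dm1 <- maxpool_backward(cc$m1, b2$da)
    dc1 <- relu_backward(cc$r1, dm1)
    b1 <- conv1d_backward(cc$c1, p$W1, dc1)
    g$W1 <- b1$dw; g$b1 <- b1$db
  } else if (model$arch == "lstm") {
    bn <- batchnorm_backward(cc$bn, p$gamma, dn$dx)
    g$gamma <- bn$dgamma; g$beta <- bn$dbeta
    lb <- lstm_backward(cc$ls, p, bn$dx)
    g$Wx <- lb$Wx; g$Wh <- lb$Wh; g$bx <- lb$bx; g$bh <- lb$bh
    # L1/L2 kernel penalties on the dense head
    g$Wd <- g$Wd + h$l1 * sign(p$Wd) + 2 * h$l2 * p$Wd
  } else {
    ddr <- array(dn$dx, cc$flat_dims)
    dcl <- dropout_backward(cc$dr, ddr)
    cb <- convlstm_backward(cc$cl, p, dcl)
    g$Wx <- cb$Wx; g$Wh <- cb$Wh; g$b <- cb$b
  }
  g
}

# --- training -----------------------------------------------------------------

#' Training schedule configuration
#'
#' Batch size 64, at most 100 epochs, early stopping with patience 40 on the
#' epoch-level validation weighted F1, learning-rate reduction by factor 0.2
#' after 20 stagnant epochs, plain SGD (momentum 0 by default), and random
#' under-sampling of the majority classes before training.
#'
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param lr_patience Epochs without improvement before the LR is reduced.
#' @param lr_factor Multiplicative LR reduction factor.
#' @param momentum SGD momentum.
#' @param undersample Balance classes by random under-sampling.
#' @param seed Seed driving under-sampling, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64, epochs = 100, patience = 40,
                         lr_patience = 20, lr_factor = 0.2, momentum = 0,
                         undersample = TRUE, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size > 0, epochs > 0, patience > 0, lr_patience > 0,
            patience > lr_patience)
  structure(list(batch_size = batch_size, epochs = epochs, patience = patience,
                 lr_patience = lr_patience, lr_factor = lr_factor,
                 momentum = momentum, undersample = undersample,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

.onehot <- function(labels) {
  y <- matrix(0, length(labels), length(EVAL_CLASSES),
              dimnames = list(NULL, EVAL_CLASSES))
  y[cbind(seq_along(labels), match(labels, EVAL_CLASSES))] <- 1
  y
}

#' Train a neural model
#'
#' Shared SGD loop for the three architectures: majority classes are randomly
#' under-sampled to the minority count (once per run, seed-controlled), the
#' epoch-level validation weighted F1 drives early stopping and the
#' learning-rate schedule, and the best-validation parameters are restored at
#' the end. Deterministic given the seed.
#'
#' @param model An untrained `kick_net` from [build_cnn()], [build_lstm()] or
#'   [build_convlstm()].
#' @param train_ws,val_ws Labelled [window_set()]s.
#' @param config A [train_config()].
#' @return The trained model with a `history` data.frame (epoch, loss,
#'   validation weighted F1, learning rate).
#' @export
train_model <- function(model, train_ws, val_ws, config = train_config()) {
  stopifnot(inherits(model, "kick_net"), inherits(config, "train_config"))
  if (length(unique(train_ws$labels)) < 2)
    stop("training set contains a single class", call. = FALSE)
  if (config$undersample)
    train_ws <- undersample_windows(train_ws, seed = config$seed)
  x <- train_ws$x
  y <- .onehot(train_ws$labels)
  n <- nrow(y)
  with_seed(config$seed + 17L, {
    lr <- model$lr
    vel <- lapply(model$params, function(p) 0 * p)
    best_f1 <- -Inf; best_params <- model$params
    best_run <- list(mean = model$run_mean, var = model$run_var)
    stale <- 0L; lr_stale <- 0L
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_f1 = numeric(), lr = numeric())
    clip <- model$hyper$clipvalue
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (at in seq(1, n, by = config$batch_size)) {
        idx <- ord[at:min(at + config$batch_size - 1, n)]
        xb <- x[idx, , , drop = FALSE]
        fw <- .net_forward(model, xb, training = TRUE)
        if (model$arch == "lstm") {
          model$run_mean <- fw$cache$bn$run_mean
          model$run_var <- fw$cache$bn$run_var
          model$bn_seen <- TRUE
        }
        lo <- softmax_xent(fw$logits, y[idx, , drop = FALSE])
        losses <- c(losses, lo$loss)
        g <- .net_backward(model, fw, lo$dz)
        if (!is.null(clip)) g <- lapply(g, function(gr) pmin(pmax(gr, -clip), clip))
        for (nm in names(g)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - lr * g[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      val_pred <- .net_predict_labels(model, val_ws$x)
      vf1 <- weighted_f1(val_ws$labels, val_pred)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                     val_f1 = vf1, lr = lr))
      if (config$verbose)
        message(sprintf("epoch %3d  loss %.4f  val F1 %.4f  lr %.5f",
                        epoch, mean(losses), vf1, lr))
      if (vf1 > best_f1 + 1e-6) {
        best_f1 <- vf1; best_params <- model$params
        best_run <- list(mean = model$run_mean, var = model$run_var)
        stale <- 0L; lr_stale <- 0L
      } else {
        stale <- stale + 1L; lr_stale <- lr_stale + 1L
      }
      if (lr_stale >= config$lr_patience) {
        lr <- lr * config$lr_factor
        lr_stale <- 0L
      }
      if (stale >= config$patience) break
    }
    model$params <- best_params
    model$run_mean <- best_run$mean
    model$run_var <- best_run$var
    model$trained <- TRUE
    model$history <- hist
    model$best_val_f1 <- best_f1
    model
  })
}

.net_predict_proba <- function(model, x, chunk = 256L) {
  n <- dim(x)[1]
  out <- matrix(0, n, 3, dimnames = list(NULL, EVAL_CLASSES))
  for (at in seq(1, n, by = chunk)) {
    idx <- at:min(at + chunk - 1, n)
    fw <- .net_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- softmax(fw$logits)
  }
  out
}

.net_predict_labels <- function(model, x) {
  p <- .net_predict_proba(model, x)
  EVAL_CLASSES[max.col(p, ties.method = "first")]
}

#' Class probabilities for windows
#'
#' @param model A trained `kick_net`.
#' @param x A [window_set()] or an n x 400 x 6 array (a single 400 x 6 matrix
#'   is promoted to a batch of one).
#' @return n x 3 matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "kick_net"))
  if (inherits(x, "window_set")) x <- x$x
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (length(dim(x)) != 3 || dim(x)[2] != WINDOW_LEN || dim(x)[3] != 6)
    stop("input must be n x ", WINDOW_LEN, " x 6 (got ",
         paste(dim(x), collapse = " x "), ")", call. = FALSE)
  .net_predict_proba(model, x)
}

#' @export
classify_windows.kick_net <- function(model, ws, ...) {
  p <- predict_proba(model, ws)
  EVAL_CLASSES[max.col(p, ties.method = "first")]
}

# --- hyperparameter search ----------------------------------------------------

#' Reference search space for an architecture
#'
#' The sampling rules of the hyperparameter optimization: categorical filter /
#' pool / kernel / unit / segment choices and log-uniform dropout, penalty and
#' learning-rate ranges.
#'
#' @param arch `"cnn"`, `"lstm"` or `"convlstm"`.
#' @return Named list of sampling specs (`list(type, values)` or
#'   `list(type, lo, hi)`).
#' @export
search_space <- function(arch = c("cnn", "lstm", "convlstm")) {
  arch <- match.arg(arch)
  cat_ <- function(v) list(type = "categorical", values = v)
  logu <- function(lo, hi) list(type = "loguniform", lo = lo, hi = hi)
  switch(arch,
    cnn = list(filter1 = cat_(2^(6:9)), filter2 = cat_(2^(4:8)),
               filter3 = cat_(2^(4:8)), poolsize = cat_(2:5),
               kernelsize = cat_(2:4),
               dropout1 = logu(0.01, 1), dropout2 = logu(0.01, 1),
               dropout3 = logu(0.01, 1), learning_rate = logu(0.001, 0.1)),
    lstm = list(units = cat_(2^(6:9)), l1 = logu(1e-4, 0.1),
                l2 = logu(1e-4, 0.1), clipvalue = logu(0.1, 0.8),
                learning_rate = logu(0.001, 0.1)),
    convlstm = list(filter = cat_(2^(4:8)), kernelsize = cat_(2:4),
                    dropout = logu(0.01, 1),
                    num_segments = cat_(c(2, 4, 5, 8, 10)),
                    learning_rate = logu(0.001, 0.1)))
}

.sample_space <- function(space) {
  lapply(space, function(s) {
    if (s$type == "categorical") sample(s$values, 1)
    else exp(stats::runif(1, log(s$lo), log(s$hi)))
  })
}

.build_from_config <- function(arch, cfg, seed) {
  switch(arch,
    cnn = build_cnn(filters = c(cfg$filter1, cfg$filter2, cfg$filter3),
                    kernel = cfg$kernelsize, pool = cfg$poolsize,
                    dropouts = c(cfg$dropout1, cfg$dropout2, cfg$dropout3),
                    lr = cfg$learning_rate, seed = seed),
    lstm = build_lstm(units = cfg$units, l1 = cfg$l1, l2 = cfg$l2,
                      clipvalue = cfg$clipvalue, lr = cfg$learning_rate,
                      seed = seed),
    convlstm = build_convlstm(num_segments = cfg$num_segments,
                              filters = cfg$filter, kernel = cfg$kernelsize,
                              dropout = cfg$dropout, lr = cfg$learning_rate,
                              seed = seed))
}

#' Random hyperparameter search with session-grouped CV
#'
#' Samples `budget` configurations from the architecture's search space and
#' scores each by the mean validation weighted F1 over session-grouped
#' k-fold cross-validation; unpromising trials are pruned after the first
#' fold (score below 80 percent of the best first-fold score so far). The
#' reference optima ship as the build_* defaults; this utility re-runs the
#' search at desk scale.
#'
#' @param arch Architecture id.
#' @param ws Labelled [window_set()] with session ids.
#' @param budget Number of sampled configurations (>= 1).
#' @param space Search space (defaults to [search_space()] for `arch`).
#' @param n_folds CV folds (grouped by session).
#' @param epochs Training epochs per fold (desk-scale).
#' @param seed Seed.
#' @return List: `best` config (with `score`), `trials` data.frame.
#' @export
hyperparameter_search <- function(arch, ws, budget = 5,
                                  space = search_space(arch), n_folds = 3,
                                  epochs = 5, seed = 1L) {
  if (length(space) == 0) stop("empty search space", call. = FALSE)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  uniq <- unique(ws$session_ids)
  k <- min(n_folds, length(uniq))
  fold_of <- with_seed(seed, stats::setNames(sample(rep_len(seq_len(k),
                                                            length(uniq))), uniq))
  folds <- fold_of[ws$session_ids]
  trials <- list()
  best <- NULL; best_score <- -Inf; best_first <- -Inf
  for (trial in seq_len(budget)) {
    cfg <- with_seed(seed + trial, .sample_space(space))
    scores <- numeric(0)
    pruned <- FALSE
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(ws$labels[tr])) < 3 || !any(!tr)) next
      model <- .build_from_config(arch, cfg, seed = seed + trial)
      tc <- train_config(epochs = epochs, patience = epochs + 1L,
                         lr_patience = max(1L, epochs), seed = seed + trial)
      fit <- train_model(model, subset_windows(ws, which(tr)),
                         subset_windows(ws, which(!tr)), tc)
      scores <- c(scores, fit$best_val_f1)
      if (f == 1 && length(scores) == 1) {
        if (scores[1] < 0.8 * best_first) { pruned <- TRUE; break }
        best_first <- max(best_first, scores[1])
      }
    }
    sc <- if (pruned) NA_real_ else mean(scores)
    trials[[trial]] <- data.frame(trial = trial, score = sc, pruned = pruned)
    if (!pruned && !is.na(sc) && sc > best_score) {
      best_score <- sc
      best <- c(cfg, list(score = sc))
    }
  }
  if (is.null(best)) best <- c(with_seed(seed + 1L, .sample_space(space)),
                               list(score = NA_real_))
  list(best = best, trials = do.call(rbind, trials))
}
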