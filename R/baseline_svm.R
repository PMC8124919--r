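# Literature baseline: kick-phase segmentation (sagittal angular velocity /
# acceleration landmarks), six absolute-sum features, and a linear one-vs-rest
# SVM over shot/pass/null with session-grouped cross-validation for the cost
# parameter.

#' Locate the ball contact in a window
#'
#' The ball contact is the instant of maximum angular acceleration in the
#' sagittal plane: the index of the maximum first difference of the `gx`
#' channel (discrete derivative at 200 Hz, no smoothing). Ties break to the
#' earliest index.
#'
#' @param window 400 x 6 signal matrix in [IMU_CHANNELS] order.
#' @return Integer contact index.
#' @export
find_ball_contact <- function(window) {
  gx <- window[, 4]
  d <- diff(gx)
  if (length(d) == 0 || max(d) == min(d))
    stop("degenerate window: constant sagittal angular velocity", call. = FALSE)
  which.max(d) + 1L
}

#' Locate the kick-phase start before a contact
#'
#' The leg-acceleration onset: the last zero crossing of the sagittal angular
#' velocity (`gx`) prior to the ball contact — the largest index below
#' `contact` where `gx` is exactly zero or changes sign. If no crossing exists
#' the window start is used and a warning is logged.
#'
#' @param window 400 x 6 signal matrix.
#' @param contact Contact index from [find_ball_contact()].
#' @return Integer start index (`start < contact`).
#' @export
find_phase_start <- function(window, contact) {
  gx <- window[, 4]
  stopifnot(contact >= 2, contact <= nrow(window))
  for (k in (contact - 1L):1L) {
    if (gx[k] == 0) return(k)
    if (k >= 2 && gx[k] * gx[k - 1] < 0) return(k)
  }
  warning("no sagittal zero crossing before contact; using window start")
  1L
}

#' Kick-phase absolute-sum features
#'
#' Segments the kick phase (leg-acceleration onset to ball contact) and
#' computes the absolute sum of each of the six channels over it — the
#' six-dimensional feature vector of the baseline classifier. Computed on
#' scaled signals.
#'
#' @param window 400 x 6 signal matrix (scaled).
#' @return Named numeric vector of six nonnegative features.
#' @export
extract_features <- function(window) {
  contact <- find_ball_contact(window)
  start <- find_phase_start(window, contact)
  f <- colSums(abs(window[start:contact, , drop = FALSE]))
  stats::setNames(f, paste0("abssum_", IMU_CHANNELS))
}

# feature matrix for a window set; degenerate windows flagged, not dropped
.features_of_set <- function(ws) {
  n <- n_windows(ws)
  feats <- matrix(0, n, 6, dimnames = list(NULL, paste0("abssum_", IMU_CHANNELS)))
  ok <- logical(n)
  for (i in seq_len(n)) {
    f <- tryCatch(suppressWarnings(extract_features(ws$x[i, , ])),
                  error = function(e) NULL)
    if (!is.null(f)) { feats[i, ] <- f; ok[i] <- TRUE }
  }
  list(features = feats, ok = ok)
}

#' Train the linear SVM baseline
#'
#' Random under-sampling of the majority classes, then selection of the cost
#' parameter C from the grid 2^-10 ... 2^10 by the best mean weighted F1 over
#' session-grouped 5-fold cross-validation (windows of one session are never
#' split across training and validation), then a refit on all training data.
#' Multiclass is handled one-vs-rest over three binary linear SVMs.
#'
#' @param ws A labelled [window_set()] with at least two classes.
#' @param c_grid Candidate cost values.
#' @param n_folds Cross-validation folds (grouped by session id).
#' @param seed Seed for under-sampling and fold assignment.
#' @return A `kick_svm` model: binary fits, selected `C`, CV table.
#' @export
train_svm <- function(ws, c_grid = 2^(-10:10), n_folds = 5, seed = 1L) {
  present <- intersect(EVAL_CLASSES, unique(ws$labels))
  if (length(present) < length(EVAL_CLASSES))
    stop("class(es) absent from training data: ",
         paste(setdiff(EVAL_CLASSES, present), collapse = ", "), call. = FALSE)
  ws <- undersample_windows(ws, seed = seed)
  fs <- .features_of_set(ws)
  keep <- fs$ok
  feats <- fs$features[keep, , drop = FALSE]
  labels <- ws$labels[keep]
  sessions <- ws$session_ids[keep]
  uniq <- unique(sessions)
  k <- min(n_folds, length(uniq))
  fold_of <- with_seed(seed + 1L,
    stats::setNames(sample(rep_len(seq_len(k), length(uniq))), uniq))
  folds <- fold_of[sessions]
  cv <- data.frame(C = c_grid, mean_f1 = NA_real_)
  for (ci in seq_along(c_grid)) {
    scores <- numeric(0)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2 || !any(!tr)) next
      m <- .fit_ovr(feats[tr, , drop = FALSE], labels[tr], c_grid[ci])
      pred <- .predict_ovr(m, feats[!tr, , drop = FALSE])
      scores <- c(scores, weighted_f1(labels[!tr], pred))
    }
    cv$mean_f1[ci] <- mean(scores)
  }
  best <- cv$C[which.max(cv$mean_f1)]
  structure(list(fits = .fit_ovr(feats, labels, best), C = best, cv = cv),
            class = "kick_svm")
}

.fit_ovr <- function(feats, labels, cost) {
  fits <- list()
  for (cl in EVAL_CLASSES) {
    if (!any(labels == cl)) next
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    fits[[cl]] <- e1071::svm(feats, y, kernel = "linear", cost = cost,
                             scale = TRUE)
  }
  fits
}

.predict_ovr <- function(fits, feats) {
  dec <- sapply(names(fits), function(cl) {
    d <- attr(stats::predict(fits[[cl]], feats, decision.values = TRUE),
              "decision.values")
    # orient toward the "pos" class regardless of libsvm's internal ordering
    if (colnames(d)[1] == "pos/neg") as.numeric(d) else -as.numeric(d)
  })
  dec <- matrix(dec, ncol = length(fits), dimnames = list(NULL, names(fits)))
  colnames(dec)[max.col(dec, ties.method = "first")]
}

#' @export
print.kick_svm <- function(x, ...) {
  cat(sprintf("<kick_svm> linear one-vs-rest SVM, C = %g (grid 2^-10..2^10)\n", x$C))
  invisible(x)
}

#' @export
classify_windows.kick_svm <- function(model, ws, ...) {
  fs <- .features_of_set(ws)
  pred <- rep("null", n_windows(ws)) # degenerate windows scored as null
  if (any(fs$ok))
    pred[fs$ok] <- .predict_ovr(model$fits, fs$features[fs$ok, , drop = FALSE])
  pred
}

#' Predict the class of windows with the SVM baseline
#' @param model A `kick_svm` from [train_svm()].
#' @param ws A [window_set()].
#' @return Character vector of predicted classes; windows with a degenerate
#'   kick phase are scored `null`.
#' @export
predict_svm <- function(model, ws) classify_windows(model, ws)
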