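# Evaluation harness: per-class counts, F1 / weighted F1 / sensitivity, the
# fine-grained column-normalized confusion matrix, and the three evaluation
# scenarios (segmented lab, moving-window lab, moving-window field).

EVAL_CLASSES <- c("shot", "pass", "null")

#' Classify a window set
#'
#' Generic prediction interface shared by the SVM baseline, the neural nets
#' and the ground-truth oracle used in tests.
#'
#' @param model A trained classifier.
#' @param ws A [window_set()].
#' @param ... Passed to methods.
#' @return Character vector of predicted class labels (`shot`/`pass`/`null`).
#' @export
classify_windows <- function(model, ws, ...) UseMethod("classify_windows")

#' Ground-truth oracle classifier
#'
#' Predicts every window's true label; used to validate the evaluation
#' scenarios independently of any learned model.
#'
#' @return An object of class `oracle_classifier`.
#' @export
oracle_classifier <- function() structure(list(), class = "oracle_classifier")

#' @export
classify_windows.oracle_classifier <- function(model, ws, ...) {
  ifelse(ws$labels %in% EVAL_CLASSES, ws$labels, "null")
}

#' Per-class prediction counts
#'
#' @param truth,pred Character vectors of true and predicted class labels.
#' @param classes Class universe (default shot/pass/null).
#' @return data.frame with one row per class: `tp`, `fn`, `fp`, `support`.
#' @export
class_counts <- function(truth, pred, classes = EVAL_CLASSES) {
  stopifnot(length(truth) == length(pred))
  out <- data.frame(class = classes, tp = 0L, fn = 0L, fp = 0L, support = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    out$tp[i] <- sum(truth == cl & pred == cl)
    out$fn[i] <- sum(truth == cl & pred != cl)
    out$fp[i] <- sum(truth != cl & pred == cl)
    out$support[i] <- sum(truth == cl)
  }
  out
}

#' Per-class F1 score
#'
#' Harmonic mean of precision and recall; a class with zero precision and
#' recall scores 0 (the 0/0 case is guarded).
#'
#' @param counts A row set from [class_counts()].
#' @return Numeric vector of per-class F1 values.
#' @export
f1_class <- function(counts) {
  p <- ifelse(counts$tp + counts$fp > 0, counts$tp / (counts$tp + counts$fp), 0)
  r <- ifelse(counts$tp + counts$fn > 0, counts$tp / (counts$tp + counts$fn), 0)
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Support-weighted mean F1
#'
#' Weighted average of per-class F1 scores with class instance counts as
#' weights; an empty class contributes 0 with weight 0.
#'
#' @param counts A row set from [class_counts()].
#' @return Scalar weighted F1 in \[0, 1\].
#' @export
f1_weighted <- function(counts) {
  if (sum(counts$support) == 0)
    stop("weighted F1 undefined: all class supports are zero", call. = FALSE)
  sum(counts$support * f1_class(counts)) / sum(counts$support)
}

#' Weighted F1 directly from label vectors
#' @param truth,pred Character label vectors.
#' @return Scalar weighted F1.
#' @export
weighted_f1 <- function(truth, pred) f1_weighted(class_counts(truth, pred))

#' Per-class sensitivity
#'
#' Proportion of correctly identified samples of each class,
#' `TP / (TP + FN)`; undefined (NA) for classes with zero support.
#'
#' @param counts A row set from [class_counts()].
#' @return Named numeric vector of sensitivities.
#' @export
sensitivity_class <- function(counts) {
  s <- ifelse(counts$support > 0, counts$tp / (counts$tp + counts$fn), NA_real_)
  stats::setNames(s, counts$class)
}

#' Fine-grained column-normalized confusion matrix
#'
#' Tabulates predicted class (rows) against the true fine-grained ball-contact
#' type (columns, in the canonical [CONTACT_TYPES] order, `unknown` excluded)
#' and normalizes each column by its sample count, so each nonempty column
#' sums to 1. For a perfect classifier the cell where a contact type's true
#' class meets the prediction is 1 and all other cells are 0.
#'
#' @param predictions Character vector of predicted classes.
#' @param fine_types Character vector of true contact types.
#' @return 3 x 7 matrix, rows shot/pass/null, columns the contact types.
#' @export
fine_grained_confusion <- function(predictions, fine_types) {
  stopifnot(length(predictions) == length(fine_types))
  cols <- setdiff(CONTACT_TYPES, "unknown")
  bad <- setdiff(unique(fine_types), CONTACT_TYPES)
  if (length(bad) > 0)
    stop("unknown fine_type value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  keep <- fine_types != "unknown"
  predictions <- predictions[keep]; fine_types <- fine_types[keep]
  m <- matrix(0, 3, length(cols), dimnames = list(EVAL_CLASSES, cols))
  for (b in cols) {
    idx <- fine_types == b
    if (!any(idx)) next
    for (cl in EVAL_CLASSES) m[cl, b] <- sum(predictions[idx] == cl) / sum(idx)
  }
  m
}

#' Assemble an evaluation report
#'
#' @param scenario Scenario id string.
#' @param truth,pred Class label vectors of the evaluated windows.
#' @param fine_types True fine-grained contact types of the windows.
#' @param candidate_stats Optional list of candidate-selection counts.
#' @param config Optional resolved configuration to embed (audit trail).
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(scenario, truth, pred, fine_types,
                              candidate_stats = NULL, config = NULL) {
  if (length(truth) == 0) {
    rep <- list(scenario = scenario, n = 0L, weighted_f1 = NA_real_,
                sensitivity = stats::setNames(rep(NA_real_, 3), EVAL_CLASSES),
                confusion = NULL, candidate_stats = candidate_stats,
                config = config)
    return(structure(rep, class = "evaluation_report"))
  }
  counts <- class_counts(truth, pred)
  structure(list(scenario = scenario, n = length(truth),
                 weighted_f1 = f1_weighted(counts),
                 sensitivity = sensitivity_class(counts),
                 counts = counts,
                 confusion = fine_grained_confusion(pred, fine_types),
                 candidate_stats = candidate_stats, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: %d windows\n", x$scenario, x$n))
  if (x$n > 0) {
    cat(sprintf("  weighted F1: %.3f\n", x$weighted_f1))
    s <- x$sensitivity
    cat(sprintf("  sensitivity: shot %.3f / pass %.3f / null %.3f\n",
                s[["shot"]], s[["pass"]], s[["null"]]))
  }
  if (!is.null(x$candidate_stats)) {
    cs <- x$candidate_stats
    cat(sprintf("  windows %d = rejected %d + candidates %d (rejection %.1f%%)\n",
                cs$windows_total, cs$rejected, cs$candidates,
                100 * cs$rejected / max(1, cs$windows_total)))
  }
  invisible(x)
}

#' Segmented-window evaluation scenario
#'
#' Evaluates a classifier on one 2 s window per labelled ball contact of the
#' given (laboratory) sessions; `unknown` contacts are excluded.
#'
#' @param model A classifier with a [classify_windows()] method.
#' @param sessions List of labelled [session()] objects.
#' @return An [evaluation_report()] with scenario id `segmented_lab`.
#' @export
run_segmented_scenario <- function(model, sessions) {
  ws <- segment_sessions(sessions, drop_excluded = TRUE)
  if (n_windows(ws) == 0)
    stop("segmented scenario requires labelled ball contacts", call. = FALSE)
  pred <- classify_windows(model, ws)
  evaluation_report("segmented_lab", ws$labels, pred, ws$fine_types)
}

#' Moving-window evaluation scenario
#'
#' Runs the full stream pipeline: moving windows, peak-detection candidate
#' selection, then classification of the candidates only. Rejected windows
#' are counted; candidates whose only contacts are `unknown` are excluded
#' from the metrics.
#'
#' @param model A classifier with a [classify_windows()] method.
#' @param sessions List of [session()] objects (lab- or field-flagged; the
#'   code path is identical).
#' @param scenario Report id, e.g. `"window_lab"` or `"window_field"`.
#' @param params Candidate-selection parameters ([candidate_params()]).
#' @return An [evaluation_report()] including candidate statistics.
#' @export
run_window_scenario <- function(model, sessions, scenario = "window_lab",
                                params = candidate_params()) {
  sets <- lapply(sessions, select_candidates, params = params)
  stats <- list(
    windows_total = sum(vapply(sets, function(s) s$stats$windows_total, numeric(1))),
    rejected = sum(vapply(sets, function(s) s$stats$rejected, numeric(1))),
    candidates = sum(vapply(sets, function(s) s$stats$candidates, numeric(1))))
  ws <- bind_windows(lapply(sets, function(s) s$windows))
  keep <- ws$labels != "excluded"
  stats$labelled_contacts <- sum(ws$fine_types[keep] != "none")
  if (!any(keep))
    return(evaluation_report(scenario, character(0), character(0),
                             character(0), candidate_stats = stats))
  ws <- subset_windows(ws, which(keep))
  pred <- classify_windows(model, ws)
  evaluation_report(scenario, ws$labels, pred, ws$fine_types,
                    candidate_stats = stats)
}
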