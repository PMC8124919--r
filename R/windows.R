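# Window containers: fixed-shape 2 s x 6-channel signal blocks with labels,
# shared by the SVM baseline, the neural nets and the evaluation scenarios.

#' Construct a window set
#'
#' A `window_set` holds n scaled signal blocks of 400 samples x 6 channels
#' (2 s at 200 Hz) as an n x 400 x 6 array, with per-window class labels,
#' fine-grained contact types and session ids (used for session-grouped
#' cross-validation splits).
#'
#' @param blocks List of 400 x 6 matrices, or an n x 400 x 6 array.
#' @param labels Character vector of class labels.
#' @param fine_types Character vector of fine-grained contact types.
#' @param session_ids Character vector of source session ids.
#' @param meta Optional data.frame of per-window metadata.
#' @return An object of class `window_set`.
#' @export
window_set <- function(blocks, labels, fine_types, session_ids,
                       meta = NULL) {
  if (is.list(blocks)) {
    n <- length(blocks)
    x <- array(0, c(n, WINDOW_LEN, 6))
    for (i in seq_len(n)) {
      b <- blocks[[i]]
      if (!all(dim(b) == c(WINDOW_LEN, 6)))
        stop("window block ", i, " is not ", WINDOW_LEN, " x 6", call. = FALSE)
      x[i, , ] <- b
    }
  } else {
    x <- blocks
    if (length(dim(x)) != 3 || dim(x)[2] != WINDOW_LEN || dim(x)[3] != 6)
      stop("blocks array must be n x ", WINDOW_LEN, " x 6", call. = FALSE)
    n <- dim(x)[1]
  }
  stopifnot(length(labels) == n, length(fine_types) == n,
            length(session_ids) == n)
  structure(list(x = x, labels = as.character(labels),
                 fine_types = as.character(fine_types),
                 session_ids = as.character(session_ids),
                 meta = meta),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  tab <- table(factor(x$labels, levels = CLASS_LABELS))
  cat(sprintf("<window_set> %d windows (shot %d / pass %d / null %d / excluded %d)\n",
              length(x$labels), tab["shot"], tab["pass"], tab["null"], tab["excluded"]))
  invisible(x)
}

#' Number of windows in a set
#' @param ws A [window_set()].
#' @return Integer count.
#' @export
n_windows <- function(ws) length(ws$labels)

#' Subset a window set
#' @param ws A [window_set()].
#' @param idx Integer or logical index vector.
#' @return The subsetted [window_set()].
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$x[idx, , , drop = FALSE], ws$labels[idx], ws$fine_types[idx],
             ws$session_ids[idx],
             meta = if (!is.null(ws$meta)) ws$meta[idx, , drop = FALSE])
}

#' Concatenate window sets
#' @param ... [window_set()] objects.
#' @return The combined [window_set()].
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  x <- do.call(abind3, lapply(sets, function(s) s$x))
  window_set(x,
             unlist(lapply(sets, function(s) s$labels)),
             unlist(lapply(sets, function(s) s$fine_types)),
             unlist(lapply(sets, function(s) s$session_ids)),
             meta = NULL)
}

abind3 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(n, dim(parts[[1]])[2], dim(parts[[1]])[3]))
  at <- 1L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[at:(at + k - 1), , ] <- p
    at <- at + k
  }
  out
}

#' Segment one window per labelled ball contact
#'
#' Cuts a 2 s block centered on every labelled contact of a session from the
#' scaled streams — the segmented-evaluation (and training) view of the data.
#' Contacts of type `unknown` are dropped when `drop_excluded` is set.
#'
#' @param x A [session()].
#' @param drop_excluded Drop `unknown` contacts (label `excluded`).
#' @return A [window_set()] with one window per contact.
#' @export
segment_event_windows <- function(x, drop_excluded = TRUE) {
  stopifnot(inherits(x, "session"))
  ev <- x$events
  if (drop_excluded) ev <- ev[ev$class != "excluded", , drop = FALSE]
  blocks <- vector("list", nrow(ev))
  keep <- logical(nrow(ev))
  padded <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    st <- x$streams[[ev$foot[i]]]
    if (is.null(st)) next
    st <- scale_stream(st)
    p <- round((ev$time[i] - st$times[1]) * st$rate) + 1L
    blk <- .cut_block(st$data, p, WINDOW_LEN)
    blocks[[i]] <- blk$block
    padded[i] <- blk$padded
    keep[i] <- TRUE
  }
  ev <- ev[keep, , drop = FALSE]
  window_set(blocks[keep], ev$class, ev$fine_type,
             rep(x$session_id, nrow(ev)),
             meta = data.frame(time = ev$time, foot = ev$foot,
                               padded = padded[keep]))
}

#' Segment labelled windows from several sessions
#' @param sessions List of [session()] objects.
#' @param drop_excluded Drop `unknown` contacts.
#' @return A combined [window_set()].
#' @export
segment_sessions <- function(sessions, drop_excluded = TRUE) {
  bind_windows(lapply(sessions, segment_event_windows,
                      drop_excluded = drop_excluded))
}

#' Random under-sampling to balanced class counts
#'
#' Discards majority-class windows at random until every class present has
#' the minority-class count. Drawn once per call, seed-controlled.
#'
#' @param ws A [window_set()] (no `excluded` windows).
#' @param seed Integer seed for the subset draw.
#' @return The balanced [window_set()].
#' @export
undersample_windows <- function(ws, seed = 1L) {
  tab <- table(ws$labels)
  m <- min(tab)
  idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      i <- which(ws$labels == cl)
      if (length(i) > m) sample(i, m) else i
    }))
  })
  subset_windows(ws, sort(idx))
}
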