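#' Window sets
#'
#' A `window_set` stacks fixed-length windows cut from one or more
#' recordings: an array `[n_windows x channels x window_samples]`, a label
#' per window (1 = seizure; augmentation may later introduce soft labels in
#' `[0, 1]`), and per-window provenance (patient id and start second).
#'
#' @param windows numeric array `[n x channels x samples]`.
#' @param labels numeric vector in `[0, 1]`, length `n`.
#' @param sources data frame with columns `patient_id`, `start_s`.
#' @param window_s window length in seconds.
#' @param fs sampling rate of the source recordings.
#' @param channel_names channel labels shared by all windows.
#' @return A `window_set`.
#' @export
window_set <- function(windows, labels, sources, window_s, fs,
                       channel_names = NULL) {
  stopifnot(length(dim(windows)) == 3L)
  n <- dim(windows)[1]
  if (length(labels) != n || nrow(sources) != n)
    stop_validation("windows, labels and sources disagree on n")
  if (n > 0 && (any(labels < 0) || any(labels > 1)))
    stop_validation("labels must lie in [0, 1]")
  structure(list(windows = windows, labels = as.numeric(labels),
                 sources = sources, window_s = window_s, fs = fs,
                 channel_names = channel_names %||%
                   sprintf("CH%02d", seq_len(dim(windows)[2]))),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  n <- dim(x$windows)[1]
  cat(sprintf("<window_set> %d windows x %d ch x %d samples (%g s @ %g Hz), %d seizure-labelled\n",
              n, dim(x$windows)[2], dim(x$windows)[3], x$window_s, x$fs,
              sum(x$labels >= 0.5)))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1]

# fraction of [a, b) covered by the union of half-open intervals
interval_coverage <- function(a, b, iv) {
  if (nrow(iv) == 0L) return(0)
  covered <- pmax(0, pmin(b, iv$end_s) - pmax(a, iv$start_s))
  sum(covered) / (b - a)   # intervals are non-overlapping by construction
}

#' Segment a recording into labelled fixed-length windows
#'
#' Cuts windows of `window_s` seconds at stride `window_s - overlap_s`,
#' discarding any trailing partial window. Window `i` covers the half-open
#' span `[i * stride, i * stride + window_s)`. A window is labelled seizure
#' (1) iff the fraction of its duration inside annotated seizure intervals
#' is at least `label_rule`. Values are copied verbatim from the signal —
#' no filtering or normalization happens here.
#'
#' @param rec an [eeg_recording].
#' @param window_s window length in seconds (default 30).
#' @param overlap_s overlap between consecutive windows; `0 <= overlap_s <
#'   window_s`.
#' @param label_rule seizure-coverage fraction threshold in `(0, 1]`.
#' @return A `window_set` (empty, with a warning, if the recording is
#'   shorter than one window).
#' @export
segment <- function(rec, window_s = 30, overlap_s = 0, label_rule = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window_s <= 0) stop_validation("window_s must be positive")
  if (overlap_s < 0 || overlap_s >= window_s)
    stop_validation("need 0 <= overlap_s < window_s")
  fs <- rec$fs
  wlen <- round(window_s * fs)
  stride_s <- window_s - overlap_s
  stride <- round(stride_s * fs)
  total <- ncol(rec$signal)
  nch <- nrow(rec$signal)
  nw <- if (total >= wlen) (total - wlen) %/% stride + 1L else 0L
  if (nw == 0L) {
    warning("recording shorter than one window; empty window set")
    return(window_set(array(0, c(0L, nch, wlen)),
                      numeric(0),
                      data.frame(patient_id = character(0), start_s = numeric(0)),
                      window_s, fs, rec$channel_names))
  }
  w <- array(0, c(nw, nch, wlen))
  labels <- numeric(nw)
  starts <- numeric(nw)
  for (i in seq_len(nw)) {
    s0 <- (i - 1L) * stride
    w[i, , ] <- rec$signal[, (s0 + 1L):(s0 + wlen), drop = FALSE]
    start_t <- s0 / fs
    labels[i] <- as.numeric(
      interval_coverage(start_t, start_t + window_s, rec$seizures) >= label_rule)
    starts[i] <- start_t
  }
  window_set(w, labels,
             data.frame(patient_id = rec$patient_id, start_s = starts),
             window_s, fs, rec$channel_names)
}

#' Segment and pool several recordings
#'
#' @param recs list of [eeg_recording] objects (same channel count and fs).
#' @inheritParams segment
#' @return One pooled `window_set`.
#' @export
segment_all <- function(recs, window_s = 30, overlap_s = 0, label_rule = 0.5) {
  sets <- lapply(recs, segment, window_s = window_s, overlap_s = overlap_s,
                 label_rule = label_rule)
  bind_window_sets(sets)
}

bind_window_sets <- function(sets) {
  sets <- Filter(function(s) n_windows(s) > 0L, sets)
  if (!length(sets)) stop_validation("no windows to pool")
  dims <- vapply(sets, function(s) dim(s$windows)[2:3], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_validation("window sets disagree on channels or window length")
  w <- do.call(abind3, lapply(sets, `[[`, "windows"))
  window_set(w, unlist(lapply(sets, `[[`, "labels")),
             do.call(rbind, lapply(sets, `[[`, "sources")),
             sets[[1]]$window_s, sets[[1]]$fs, sets[[1]]$channel_names)
}

# rbind for [n x C x S] arrays along the first margin
abind3 <- function(...) {
  xs <- list(...)
  n <- sum(vapply(xs, function(x) dim(x)[1], 0L))
  d <- dim(xs[[1]])
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    if (dim(x)[1] > 0L) out[(at + 1L):(at + dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

subset_windows <- function(ws, idx) {
  out <- ws
  out$windows <- ws$windows[idx, , , drop = FALSE]
  out$labels <- ws$labels[idx]
  out$sources <- ws$sources[idx, , drop = FALSE]
  rownames(out$sources) <- NULL
  for (f in c("origin", "prov_i", "prov_j", "lambda"))
    if (!is.null(out[[f]])) out[[f]] <- out[[f]][idx]
  out
}

#' Train/test split of a window set
#'
#' Deterministic under `seed`. With `stratified = TRUE` (default) class
#' proportions are preserved to within one window per class; hard classes
#' are taken as `label >= 0.5`. With `by_patient = TRUE` whole patients are
#' assigned to one side (train fraction then holds approximately, by
#' window count), for patient-disjoint evaluation.
#'
#' @param ws a `window_set`.
#' @param train_frac fraction of windows for training, in `(0, 1)`.
#' @param seed integer seed.
#' @param stratified preserve class balance across the split.
#' @param by_patient make the split patient-disjoint.
#' @return List with elements `train`, `test`, `train_idx`, `test_idx`.
#' @export
split_windows <- function(ws, train_frac = 0.7, seed = 1L,
                          stratified = TRUE, by_patient = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  if (train_frac <= 0 || train_frac >= 1)
    stop_validation("train_frac must lie strictly between 0 and 1")
  n <- n_windows(ws)
  cls <- as.integer(ws$labels >= 0.5)
  if (by_patient) {
    pats <- unique(ws$sources$patient_id)
    if (length(pats) < 2L)
      stop_validation("patient-disjoint split needs >= 2 patients")
    train_idx <- with_seed(seed, {
      ord <- sample(pats)
      cnt <- vapply(ord, function(p) sum(ws$sources$patient_id == p), 0L)
      k <- which(cumsum(cnt) >= train_frac * n)[1]
      which(ws$sources$patient_id %in% ord[seq_len(k)])
    })
  } else if (stratified) {
    if (length(unique(cls)) < 2L)
      stop_validation("stratified split requires both classes present")
    train_idx <- with_seed(seed, {
      unlist(lapply(unique(cls), function(cl) {
        idx <- which(cls == cl)
        idx[sample.int(length(idx), round(train_frac * length(idx)))]
      }))
    })
  } else {
    train_idx <- with_seed(seed, sample(n, round(train_frac * n)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_windows(ws, train_idx),
       test = subset_windows(ws, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Rebalance classes by undersampling
#'
#' `policy = "undersample"` keeps every minority-class window and a seeded
#' random subset of majority windows of equal count; `"none"` returns the
#' input unchanged. Seizure recordings are grossly imbalanced (ictal seconds
#' are a tiny fraction of a record), so some balancing policy is usually
#' needed before training.
#'
#' @param ws a `window_set`.
#' @param policy `"undersample"` or `"none"`.
#' @param seed integer seed.
#' @return A `window_set`.
#' @export
balance_windows <- function(ws, policy = c("undersample", "none"), seed = 1L) {
  policy <- match.arg(policy)
  if (policy == "none") return(ws)
  cls <- as.integer(ws$labels >= 0.5)
  n1 <- sum(cls == 1L); n0 <- sum(cls == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_validation("undersampling requires both classes present")
  minority <- if (n1 <= n0) 1L else 0L
  keep_min <- which(cls == minority)
  maj <- which(cls != minority)
  keep_maj <- with_seed(seed, maj[sample.int(length(maj), length(keep_min))])
  subset_windows(ws, sort(c(keep_min, keep_maj)))
}

#' Fit a per-channel z-score normalizer
#'
#' Means and SDs are computed per channel over all training windows pooled;
#' apply the same statistics to any later set (in particular the test set)
#' with [apply_normalizer()]. Raw microvolt scales destabilize gradient
#' training, so normalization is a separate explicit step before the model.
#'
#' @param ws training `window_set`.
#' @return A `window_normalizer` with per-channel `mean` and `sd`.
#' @export
fit_normalizer <- function(ws) {
  stopifnot(inherits(ws, "window_set"), n_windows(ws) > 0L)
  nch <- dim(ws$windows)[2]
  mu <- vapply(seq_len(nch), function(ch) mean(ws$windows[, ch, ]), 0)
  sg <- vapply(seq_len(nch), function(ch) sd(as.numeric(ws$windows[, ch, ])), 0)
  sg[sg == 0] <- 1
  structure(list(mean = mu, sd = sg), class = "window_normalizer")
}

#' Apply a fitted normalizer to a window set
#' @param ws a `window_set`.
#' @param norm a `window_normalizer` from [fit_normalizer()].
#' @return The normalized `window_set`.
#' @export
apply_normalizer <- function(ws, norm) {
  stopifnot(inherits(norm, "window_normalizer"))
  for (ch in seq_len(dim(ws$windows)[2]))
    ws$windows[, ch, ] <- (ws$windows[, ch, ] - norm$mean[ch]) / norm$sd[ch]
  ws
}
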