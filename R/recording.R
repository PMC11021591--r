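#' Multichannel EEG recording
#'
#' Container for one continuous multichannel recording: a channels-by-samples
#' signal matrix in microvolts, its sampling rate, and zero or more annotated
#' seizure intervals. All intervals are half-open `[start_s, end_s)` seconds
#' from recording onset.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one label per channel.
#' @param seizures data frame with columns `start_s`, `end_s`, or a list of
#'   length-2 numeric vectors. Intervals must lie inside the recording and
#'   are normalized to be sorted and non-overlapping.
#' @param patient_id identifier carried through windowing for provenance.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_names = NULL,
                          seizures = NULL, patient_id = "unknown") {
  if (!is.matrix(signal) || !is.numeric(signal) || nrow(signal) < 1L)
    stop_validation("signal must be a numeric matrix with >= 1 channel row")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_validation("fs must be a single positive number")
  if (is.null(channel_names))
    channel_names <- sprintf("CH%02d", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop_validation("channel_names length (%d) != channel count (%d)",
                    length(channel_names), nrow(signal))
  seizures <- normalize_seizures(seizures, ncol(signal) / fs)
  structure(list(signal = signal, fs = fs,
                 channel_names = as.character(channel_names),
                 seizures = seizures, patient_id = as.character(patient_id)),
            class = "eeg_recording")
}

normalize_seizures <- function(seizures, duration_s) {
  if (is.null(seizures) || (is.data.frame(seizures) && nrow(seizures) == 0L) ||
      (is.list(seizures) && length(seizures) == 0L)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  if (is.list(seizures) && !is.data.frame(seizures)) {
    seizures <- do.call(rbind, lapply(seizures, function(iv) {
      data.frame(start_s = iv[[1]], end_s = iv[[2]])
    }))
  }
  if (!all(c("start_s", "end_s") %in% names(seizures)))
    stop_validation("seizures need columns start_s and end_s")
  s <- seizures[order(seizures$start_s), c("start_s", "end_s"), drop = FALSE]
  tol <- 1e-9
  if (any(s$start_s < -tol) || any(s$end_s > duration_s + tol))
    stop_validation("seizure interval outside recording [0, %g]", duration_s)
  if (any(s$end_s <= s$start_s))
    stop_validation("seizure interval must have start_s < end_s")
  if (nrow(s) > 1L && any(s$start_s[-1L] < s$end_s[-nrow(s)] - tol))
    stop_validation("seizure intervals overlap")
  rownames(s) <- NULL
  s
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> patient %s: %d ch x %d samples @ %g Hz (%.1f s), %d seizure interval(s)\n",
    x$patient_id, nrow(x$signal), ncol(x$signal), x$fs,
    ncol(x$signal) / x$fs, nrow(x$seizures)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [eeg_recording].
#' @return length of the recording in seconds.
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$fs
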