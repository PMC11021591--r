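# Minimal European Data Format (EDF, 16-bit) reader/writer.
#
# No EDF package ships with this stack, and the format is simple enough to
# support directly: a 256-byte ASCII header, 256 ASCII bytes per signal, then
# int16 little-endian data records (record-major, signal-major within a
# record). We write 1-second records, which requires integer durations and
# integer sampling rates. Physical scaling follows the standard
#   phys = (dig - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) + phys_min
# The writer rounds phys_min/max to their printed 8-character form *before*
# digitizing so a write/read round trip is exact up to int16 quantization.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)  # left-justified, space-padded
}

num_field <- function(x, width) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  s <- gsub(" ", "", s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Emits 16-bit EDF with one-second data records. The recording duration and
#' sampling rate must be whole numbers. Per-signal physical ranges are taken
#' from the data, so amplitude resolution is `range/65534` per signal.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()], [write_annotations()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop_validation("EDF writer needs an integer fs")
  n_rec <- ncol(rec$signal) / fs
  if (n_rec != round(n_rec))
    stop_validation("EDF writer needs a whole number of seconds (got %g s)",
                    n_rec)
  n_rec <- as.integer(n_rec)
  ns <- nrow(rec$signal)

  pmin_v <- apply(rec$signal, 1, min)
  pmax_v <- apply(rec$signal, 1, max)
  flat <- pmax_v - pmin_v <= 0
  pmax_v[flat] <- pmin_v[flat] + 1
  # round ranges to their printed form so reader and writer agree exactly
  pmin_v <- as.numeric(gsub(" ", "", vapply(pmin_v, num_field, "", width = 8)))
  pmax_v <- as.numeric(gsub(" ", "", vapply(pmax_v, num_field, "", width = 8)))
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste("X X X", rec$patient_id), 80),
    pad_field("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4),
    paste(pad_field(rec$channel_names, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_v, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_v, num_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_v - pmin_v)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((rec$signal[s, idx] - pmin_v[s]) * scale[s] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_header_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1):(off + width)]))
}

#' Read an EDF recording with optional seizure annotations
#'
#' Reads 16-bit EDF. If `annotation_path` is given it is parsed with
#' [read_annotations()] and the intervals are attached to the recording;
#' intervals outside the recording are a validation error. If `channels` is
#' given, recordings that do not contain every requested channel label raise
#' a validation error (callers scanning a directory can catch it and drop
#' the recording, mirroring the keep-only-consistent-channels convention);
#' matching channels are returned in the requested order.
#'
#' @param path EDF file.
#' @param annotation_path optional plain-text annotation file ("start end"
#'   seconds per line, `#` comments allowed).
#' @param channels optional character vector of required channel labels.
#' @param patient_id optional override; default is taken from the EDF
#'   patient field.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, annotation_path = NULL, channels = NULL,
                     patient_id = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop_format("not an EDF file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  version <- read_header_field(hdr, 0, 8)
  if (version != "0") stop_format("unsupported EDF version '%s'", version)
  patient <- read_header_field(hdr, 8, 80)
  hdr_bytes <- as.integer(read_header_field(hdr, 184, 8))
  n_rec <- as.integer(read_header_field(hdr, 236, 8))
  rec_dur <- as.numeric(read_header_field(hdr, 244, 8))
  ns <- as.integer(read_header_field(hdr, 252, 4))
  if (is.na(ns) || ns < 1) stop_format("bad signal count in EDF header")
  sig_hdr <- readBin(con, "raw", 256L * ns)
  fld <- function(off0, width, i) # i-th signal's field, fields stored per-type
    read_header_field(sig_hdr, off0 * ns + (i - 1) * width, width)
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), "")
  pmin_v <- as.numeric(vapply(seq_len(ns), function(i) fld(16 + 80 + 8, 8, i), ""))
  pmax_v <- as.numeric(vapply(seq_len(ns), function(i) fld(16 + 80 + 8 + 8, 8, i), ""))
  dmin_v <- as.numeric(vapply(seq_len(ns), function(i) fld(16 + 80 + 8 + 16, 8, i), ""))
  dmax_v <- as.numeric(vapply(seq_len(ns), function(i) fld(16 + 80 + 8 + 24, 8, i), ""))
  spr <- as.integer(vapply(seq_len(ns), function(i) fld(16 + 80 + 8 + 32 + 80, 8, i), ""))
  if (any(is.na(spr)) || any(spr < 1)) stop_format("bad samples-per-record")
  if (length(unique(spr)) != 1L)
    stop_format("mixed per-signal sampling rates are not supported")
  if (is.na(rec_dur) || rec_dur <= 0) stop_format("bad record duration")
  fs <- spr[1] / rec_dur

  seek(con, hdr_bytes)
  total <- sum(spr) * n_rec
  dig <- readBin(con, "integer", n = total, size = 2L, endian = "little")
  if (length(dig) < total) stop_format("EDF data truncated: %s", path)
  sig <- matrix(0, ns, spr[1] * n_rec)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- dig[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      sig[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (v - dmin_v[s]) * (pmax_v[s] - pmin_v[s]) / (dmax_v[s] - dmin_v[s]) +
        pmin_v[s]
    }
  }

  if (!is.null(channels)) {
    miss <- setdiff(channels, labels)
    if (length(miss))
      stop_validation("recording %s lacks required channel(s): %s",
                      basename(path), paste(miss, collapse = ", "))
    keep <- match(channels, labels)
    sig <- sig[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  pid <- patient_id %||% {
    parts <- strsplit(patient, " ")[[1]]
    if (length(parts) >= 4) parts[4] else patient
  }
  seiz <- NULL
  if (!is.null(annotation_path))
    seiz <- read_annotations(annotation_path, ncol(sig) / fs)
  eeg_recording(sig, fs, labels, seiz, patient_id = pid)
}

#' Read a plain-text seizure annotation file
#'
#' One interval per line, `start_s end_s` in seconds (whitespace separated);
#' blank lines and `#` comments are ignored. Intervals beyond `duration_s`
#' are a validation error.
#'
#' @param path annotation file.
#' @param duration_s recording duration used for bounds checking.
#' @return Data frame with columns `start_s`, `end_s`.
#' @export
read_annotations <- function(path, duration_s) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop_format("annotation line not 'start end': '%s'",
                            lines[which(bad)[1]])
  iv <- data.frame(start_s = as.numeric(vapply(parts, `[`, "", 1L)),
                   end_s = as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(iv)))
    stop_format("non-numeric annotation in %s", path)
  normalize_seizures(iv, duration_s)
}

#' Write the plain-text annotation file for a recording
#' @param rec an [eeg_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(rec, path) {
  lines <- sprintf("%.6f %.6f", rec$seizures$start_s, rec$seizures$end_s)
  writeLines(lines, path)
  invisible(path)
}

#' Parse a CHB-MIT style summary file (optional adapter)
#'
#' Extracts per-file seizure intervals from the documented subset of the
#' CHB-MIT `*-summary.txt` dialect: blocks introduced by `File Name:`, with
#' `Seizure [i ]Start Time: <n> seconds` / `Seizure [i ]End Time: <n>
#' seconds` pairs.
#'
#' @param path summary file path.
#' @return Named list (by EDF file name) of data frames with `start_s`,
#'   `end_s`.
#' @export
parse_chbmit_summary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur <- NULL
  starts <- ends <- numeric(0)
  flush <- function() {
    if (!is.null(cur)) {
      if (length(starts) != length(ends))
        stop_format("unpaired seizure times for %s", cur)
      out[[cur]] <<- data.frame(start_s = starts, end_s = ends)
    }
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^File Name:[[:space:]]*(.+)$", ln))[[1]]
    if (length(m)) { flush(); cur <- trimws(m[2]); starts <- ends <- numeric(0); next }
    m <- regmatches(ln, regexec(
      "^Seizure[[:space:]]*[0-9]*[[:space:]]*Start Time:[[:space:]]*([0-9.]+)", ln))[[1]]
    if (length(m)) { starts <- c(starts, as.numeric(m[2])); next }
    m <- regmatches(ln, regexec(
      "^Seizure[[:space:]]*[0-9]*[[:space:]]*End Time:[[:space:]]*([0-9.]+)", ln))[[1]]
    if (length(m)) ends <- c(ends, as.numeric(m[2]))
  }
  flush()
  out
}
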