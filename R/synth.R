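#' Configuration for the synthetic EEG generator
#'
#' Describes a fixed-rate multichannel recording whose background is a sum of
#' band-limited oscillations (delta/theta/alpha/beta) plus 1/f-shaped and
#' white noise, and whose annotated seizure intervals add a rhythmic
#' spike-wave caricature: a sinusoid at `rhythm_hz` scaled to
#' `amplitude_gain` times the per-channel background standard deviation, with
#' superimposed periodic sharp transients. The point of the generator is
#' separability for testing, not physiological realism.
#'
#' @param n_channels number of channels (default 18, a common scalp montage).
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param duration_s recording length in seconds (integer, so the EDF writer
#'   can emit 1-second data records).
#' @param seizure_intervals list of `c(start_s, end_s)` half-open intervals.
#' @param band_freqs named list of `c(lo, hi)` Hz edges for the background
#'   bands.
#' @param band_amps amplitudes (arbitrary units ~ microvolts) per band.
#' @param rhythm_hz frequency of the ictal rhythm (default 3 Hz, the classic
#'   spike-and-wave repetition rate).
#' @param amplitude_gain ictal rhythm amplitude in units of per-channel
#'   background SD; must be > 1 so seizure windows are separable.
#' @param spike_rate_hz rate of superimposed sharp transients.
#' @param pink_amp amplitude of the 1/f-shaped noise component.
#' @param noise_sd SD of additive white Gaussian noise.
#' @param seizure_len_s default seizure-interval length used by
#'   [generate_dataset()] when placing intervals.
#' @param seed integer seed; generation is fully deterministic given it.
#'
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_channels = 18, fs = 256, duration_s = 300,
                         seizure_intervals = list(),
                         band_freqs = list(delta = c(1, 4), theta = c(4, 8),
                                           alpha = c(8, 13), beta = c(13, 30)),
                         band_amps = c(4, 3, 2, 1),
                         rhythm_hz = 3, amplitude_gain = 3,
                         spike_rate_hz = 2, pink_amp = 2, noise_sd = 1,
                         seizure_len_s = 30, seed = 1L) {
  cfg <- structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration_s = duration_s,
    seizure_intervals = seizure_intervals, band_freqs = band_freqs,
    band_amps = band_amps, rhythm_hz = rhythm_hz,
    amplitude_gain = amplitude_gain, spike_rate_hz = spike_rate_hz,
    pink_amp = pink_amp, noise_sd = noise_sd,
    seizure_len_s = seizure_len_s, seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_channels < 1L) stop_validation("need >= 1 channel")
  if (cfg$fs <= 0) stop_validation("fs must be positive")
  if (cfg$duration_s <= 0) stop_validation("duration_s must be positive")
  if (cfg$fs <= 2 * cfg$rhythm_hz)
    stop_validation("fs (%g) must exceed 2 x rhythm_hz (%g)",
                    cfg$fs, 2 * cfg$rhythm_hz)
  if (cfg$amplitude_gain <= 1)
    stop_validation("amplitude_gain must be > 1 for separable seizures")
  if (length(cfg$band_amps) != length(cfg$band_freqs))
    stop_validation("band_amps and band_freqs lengths differ")
  # reuse interval normalization for bounds/overlap checks
  normalize_seizures(cfg$seizure_intervals, cfg$duration_s)
  invisible(cfg)
}

# white noise spectrally shaped to ~1/f amplitude above f0, unit variance
pink_noise <- function(n, fs, f0 = 1) {
  z <- rnorm(n)
  fz <- fft(z)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  scale <- 1 / sqrt(pmax(freq, f0))
  x <- Re(fft(fz * scale, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic EEG recording
#'
#' Deterministic under `cfg$seed`: the same configuration always yields a
#' bit-identical signal. Annotated intervals in `cfg$seizure_intervals` are
#' carried onto the returned recording unchanged.
#'
#' @param cfg a [synth_config()].
#' @param patient_id identifier stored on the recording.
#' @return An [eeg_recording].
#' @export
generate_recording <- function(cfg, patient_id = "synth") {
  validate_synth_config(cfg)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  seiz <- normalize_seizures(cfg$seizure_intervals, cfg$duration_s)
  sig <- with_seed(cfg$seed, {
    m <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      bg <- numeric(n)
      for (b in seq_along(cfg$band_freqs)) {
        f <- runif(1, cfg$band_freqs[[b]][1], cfg$band_freqs[[b]][2])
        phi <- runif(1, 0, 2 * pi)
        bg <- bg + cfg$band_amps[b] * sin(2 * pi * f * t + phi)
      }
      bg <- bg + cfg$pink_amp * pink_noise(n, cfg$fs)
      bg <- bg + rnorm(n, sd = cfg$noise_sd)
      sigma <- sd(bg)
      x <- bg
      if (nrow(seiz) > 0L) {
        phi_s <- runif(1, 0, 2 * pi)
        for (k in seq_len(nrow(seiz))) {
          idx <- which(t >= seiz$start_s[k] & t < seiz$end_s[k])
          if (!length(idx)) next
          tt <- t[idx] - seiz$start_s[k]
          rhythm <- cfg$amplitude_gain * sigma *
            sin(2 * pi * cfg$rhythm_hz * tt + phi_s)
          # sharp transients: narrow Gaussian bumps at spike_rate_hz
          spikes <- numeric(length(idx))
          if (cfg$spike_rate_hz > 0) {
            at <- seq(0.5 / cfg$spike_rate_hz, max(tt), by = 1 / cfg$spike_rate_hz)
            for (a in at)
              spikes <- spikes + exp(-((tt - a)^2) / (2 * 0.02^2))
          }
          x[idx] <- x[idx] + rhythm +
            1.5 * cfg$amplitude_gain * sigma * spikes
        }
      }
      m[ch, ] <- x
    }
    m
  })
  eeg_recording(sig, cfg$fs, sprintf("SYN%02d", seq_len(cfg$n_channels)),
                seiz, patient_id = patient_id)
}

#' Generate a dataset of synthetic recordings
#'
#' Seizure intervals of length `cfg_template$seizure_len_s` are placed so
#' that approximately `seizure_fraction` of the total duration is ictal:
#' each recording receives `round(seizure_fraction * duration / len)`
#' intervals. With `align = TRUE` (default) the intervals occupy distinct
#' slots of a `seizure_len_s` grid, so when windows are cut at the same
#' length every window is either fully ictal or fully background —
#' unambiguous labels for testing. With `align = FALSE` each interval is
#' instead jittered uniformly inside its own equal-duration block
#' (non-overlap still guaranteed), which produces realistic
#' partial-coverage boundary windows for exercising the label rule.
#' Per-recording seeds are derived from `seed`, so the list is
#' reproducible as a whole.
#'
#' @param n_recordings number of recordings.
#' @param cfg_template a [synth_config()]; its `seizure_intervals` and
#'   `seed` are overridden per recording.
#' @param seizure_fraction target fraction of ictal time in `[0, 1]`.
#' @param align place intervals on the `seizure_len_s` grid (see above).
#' @param seed integer seed for the whole dataset.
#' @return List of [eeg_recording] objects with patient ids `P01, P02, ...`.
#' @export
generate_dataset <- function(n_recordings, cfg_template,
                             seizure_fraction = 0.1, align = TRUE,
                             seed = 1L) {
  if (seizure_fraction < 0 || seizure_fraction > 1)
    stop_validation("seizure_fraction must lie in [0, 1]")
  len <- cfg_template$seizure_len_s
  n_iv <- round(seizure_fraction * cfg_template$duration_s / len)
  if (n_iv * len > cfg_template$duration_s)
    stop_validation("seizure_fraction too high for interval length %g", len)
  seeds <- derive_seeds(seed, 2L * n_recordings)
  lapply(seq_len(n_recordings), function(i) {
    cfg <- cfg_template
    cfg$seed <- seeds[2L * i - 1L]
    cfg$seizure_intervals <- if (n_iv > 0L) {
      starts <- with_seed(seeds[2L * i], {
        if (align) {
          slots <- seq(0, cfg$duration_s - len, by = len)
          sort(slots[sample.int(length(slots), n_iv)])
        } else {
          block <- cfg$duration_s / n_iv
          (seq_len(n_iv) - 1) * block + runif(n_iv, 0, block - len)
        }
      })
      lapply(starts, function(s) c(s, s + len))
    } else list()
    generate_recording(cfg, patient_id = sprintf("P%02d", i))
  })
}

#' Inject evaluation-time noise into windows
#'
#' Robustness probe: adds broadband Gaussian noise and a slow sinusoidal
#' baseline drift to every window. Intended for *test* windows only, to
#' mimic non-denoised input; amplitudes are in the units of the windows as
#' given (apply after normalization to express them in SD units).
#'
#' @param ws a `window_set`.
#' @param noise_sd SD of added white noise (0 = none).
#' @param drift_amp amplitude of the baseline drift (0 = none).
#' @param drift_hz drift frequency in Hz.
#' @param seed integer seed.
#' @return The window set with perturbed windows; labels untouched.
#' @export
add_window_noise <- function(ws, noise_sd = 0, drift_amp = 0,
                             drift_hz = 0.3, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  if (noise_sd == 0 && drift_amp == 0) return(ws)
  dm <- dim(ws$windows)
  t <- (seq_len(dm[3]) - 1) / ws$fs
  ws$windows <- with_seed(seed, {
    w <- ws$windows
    if (noise_sd > 0)
      w <- w + array(rnorm(prod(dm), sd = noise_sd), dm)
    if (drift_amp > 0) {
      for (i in seq_len(dm[1])) {
        phi <- runif(dm[2], 0, 2 * pi)
        for (ch in seq_len(dm[2]))
          w[i, ch, ] <- w[i, ch, ] +
            drift_amp * sin(2 * pi * drift_hz * t + phi[ch])
      }
    }
    w
  })
  ws
}
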