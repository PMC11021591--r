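# EDF round trip, annotations, segmentation, splitting, balancing

test_that("EDF write/read round-trips a synthetic recording", {
  rec <- generate_recording(tiny_synth_cfg(duration_s = 10,
                                           seizure_intervals = list()))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(dim(back$signal), dim(rec$signal))
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(nrow(back$seizures), 0L)
  expect_equal(ncol(back$signal), 10 * rec$fs)
  # int16 quantization bounds the round-trip error per channel
  for (ch in seq_len(nrow(rec$signal))) {
    step <- diff(range(rec$signal[ch, ])) / 65534
    expect_lt(max(abs(back$signal[ch, ] - rec$signal[ch, ])), 2 * step)
  }
  unlink(path)
})

test_that("read_edf enforces a required channel set in order", {
  rec <- generate_recording(tiny_synth_cfg(duration_s = 4))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  sel <- read_edf(path, channels = c("SYN02", "SYN01"))
  expect_equal(sel$channel_names, c("SYN02", "SYN01"))
  expect_equal(sel$signal[1, 1:10], rec$signal[2, 1:10], tolerance = 1e-3)
  expect_error(read_edf(path, channels = c("SYN01", "FZ")),
               class = "ictalnet_validation_error")
  expect_error(read_edf(tempfile()), class = "ictalnet_format_error")
  unlink(path)
})

test_that("annotation files parse, bound-check and round-trip", {
  ann <- tempfile(fileext = ".ann")
  writeLines(c("# seizure intervals", "100 130", ""), ann)
  iv <- read_annotations(ann, 300)
  expect_equal(iv$start_s, 100)
  expect_equal(iv$end_s, 130)
  writeLines("290 310", ann)
  expect_error(read_annotations(ann, 300), class = "ictalnet_validation_error")
  writeLines("10 5", ann)
  expect_error(read_annotations(ann, 300), class = "ictalnet_validation_error")
  writeLines("1 2 3", ann)
  expect_error(read_annotations(ann, 300), class = "ictalnet_format_error")

  rec <- generate_recording(tiny_synth_cfg(duration_s = 60))
  write_annotations(rec, ann)
  expect_equal(read_annotations(ann, 60), rec$seizures, tolerance = 1e-9)
  unlink(ann)
})

test_that("CHB-MIT style summary files parse (documented subset)", {
  f <- tempfile()
  writeLines(c(
    "Data Sampling Rate: 256 Hz", "",
    "File Name: chb01_03.edf",
    "Number of Seizures in File: 1",
    "Seizure Start Time: 2996 seconds",
    "Seizure End Time: 3036 seconds",
    "",
    "File Name: chb01_04.edf",
    "Number of Seizures in File: 0"), f)
  out <- parse_chbmit_summary(f)
  expect_named(out, c("chb01_03.edf", "chb01_04.edf"))
  expect_equal(out[["chb01_03.edf"]]$start_s, 2996)
  expect_equal(out[["chb01_03.edf"]]$end_s, 3036)
  expect_equal(nrow(out[["chb01_04.edf"]]), 0L)
  unlink(f)
})

test_that("window counts obey the closed-form law", {
  # n = floor((dur - w) / (w - o)) + 1 for dur >= w, else 0
  set.seed(11)
  fs <- 8
  for (i in 1:100) {
    dur <- sample(3:80, 1)
    w <- sample(2:10, 1)
    o <- sample(0:(w - 1), 1)
    rec <- eeg_recording(matrix(0, 2, dur * fs), fs)
    nw <- if (dur >= w) floor((dur - w) / (w - o)) + 1 else 0
    ws <- if (dur < w) suppressWarnings(segment(rec, w, o)) else
      segment(rec, w, o)
    expect_identical(n_windows(ws), as.integer(nw))
  }
  # hour-scale instance: 3600 s, 30 s windows -> 120 windows
  rec <- eeg_recording(matrix(0, 1, 3600 * 4), 4)
  ws <- segment(rec, 30, 0)
  expect_identical(n_windows(ws), 120L)
  expect_identical(dim(ws$windows)[3], 120L)  # 30 s x 4 Hz
})

test_that("interval labelling matches a per-sample brute-force labeler", {
  set.seed(22)
  fs <- 16
  for (i in 1:100) {
    dur <- sample(20:60, 1)
    # random non-overlapping intervals
    cuts <- sort(runif(4, 0, dur))
    iv <- data.frame(start_s = cuts[c(1, 3)], end_s = cuts[c(2, 4)])
    rec <- eeg_recording(matrix(rnorm(dur * fs), 1), fs, seizures = iv)
    w <- sample(3:8, 1)
    rule <- runif(1, 0.1, 0.9)
    ws <- segment(rec, w, 0, label_rule = rule)
    # brute force: label by the fraction of sample midpoints inside intervals
    t_all <- (seq_len(dur * fs) - 1) / fs
    inside <- rep(FALSE, length(t_all))
    for (k in seq_len(nrow(iv)))
      inside <- inside | (t_all >= iv$start_s[k] & t_all < iv$end_s[k])
    for (j in seq_len(n_windows(ws))) {
      idx <- ((j - 1) * w * fs + 1):(j * w * fs)
      frac <- mean(inside[idx])
      # skip knife-edge cases where sampling and measure disagree by < 1 sample
      if (abs(frac - rule) > 1 / (w * fs))
        expect_identical(ws$labels[j], as.numeric(frac >= rule),
                         label = sprintf("case %d window %d", i, j))
    }
  }
})

test_that("segment labels the worked boundary example correctly", {
  fs <- 16
  rec <- eeg_recording(matrix(0, 1, 300 * fs), fs,
                       seizures = data.frame(start_s = 100, end_s = 130))
  ws <- segment(rec, 30, 0, label_rule = 0.5)
  # window [90,120): 20/30 s inside -> 1 ; [120,150): 10/30 s -> 0
  expect_equal(ws$labels[ws$sources$start_s == 90], 1)
  expect_equal(ws$labels[ws$sources$start_s == 120], 0)
  expect_equal(sum(ws$labels), 1)
})

test_that("windows are verbatim slices of the source signal", {
  rec <- generate_recording(tiny_synth_cfg(duration_s = 12))
  ws <- segment(rec, 4, 1)            # stride 3 s
  fs <- rec$fs
  for (j in seq_len(n_windows(ws))) {
    s0 <- (j - 1) * 3 * fs
    expect_identical(ws$windows[j, , ],
                     rec$signal[, (s0 + 1):(s0 + 4 * fs)])
  }
})

test_that("split is a seeded stratified partition", {
  ws <- random_window_set(n = 100, labels = rep(c(0, 1), each = 50))
  sp <- split_windows(ws, 0.7, seed = 5)
  expect_length(sp$train_idx, 70)
  expect_length(sp$test_idx, 30)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(union(sp$train_idx, sp$test_idx), 1:100)
  expect_equal(sum(sp$train$labels), 35)      # class balance preserved
  sp2 <- split_windows(ws, 0.7, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_windows(ws, 0.7, seed = 6)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  expect_error(split_windows(random_window_set(10, labels = rep(0, 10)), 0.7),
               class = "ictalnet_validation_error")
  expect_error(split_windows(ws, 1.2), class = "ictalnet_validation_error")
})

test_that("patient-disjoint split separates patients", {
  ws <- random_window_set(n = 40)
  ws$sources$patient_id <- rep(c("A", "B", "C", "D"), each = 10)
  sp <- split_windows(ws, 0.5, seed = 2, by_patient = TRUE)
  expect_length(intersect(unique(sp$train$sources$patient_id),
                          unique(sp$test$sources$patient_id)), 0)
})

test_that("undersampling balances classes deterministically", {
  ws <- random_window_set(n = 60, labels = c(rep(1, 6), rep(0, 54)))
  b <- balance_windows(ws, "undersample", seed = 7)
  expect_equal(n_windows(b), 12)
  expect_equal(sum(b$labels), 6)
  expect_identical(balance_windows(ws, "undersample", seed = 7)$windows,
                   b$windows)
  expect_identical(balance_windows(ws, "none"), ws)
  expect_error(balance_windows(random_window_set(5, labels = rep(1, 5)),
                               "undersample"),
               class = "ictalnet_validation_error")
})

test_that("normalizer standardizes training windows per channel", {
  ws <- random_window_set(n = 30, nch = 3)
  ws$windows <- ws$windows * 40 + 12          # microvolt-ish scales
  norm <- fit_normalizer(ws)
  z <- apply_normalizer(ws, norm)
  for (ch in 1:3) {
    expect_equal(mean(z$windows[, ch, ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.numeric(z$windows[, ch, ])), 1, tolerance = 1e-10)
  }
  # same statistics applied to a second set, not refitted
  ws2 <- random_window_set(n = 10, nch = 3, seed = 9)
  z2 <- apply_normalizer(ws2, norm)
  expect_equal(z2$windows[1, 1, ],
               (ws2$windows[1, 1, ] - norm$mean[1]) / norm$sd[1])
})
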