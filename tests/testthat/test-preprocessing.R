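make_rec <- function(x, fs = 256, nch = 1) {
  data <- matrix(rep(x, each = nch), nrow = nch)
  eeg_recording(data, fs, paste0("CH", seq_len(nch)))
}

central_rms <- function(x, frac = 0.5) {
  n <- length(x)
  keep <- seq(round(n * (1 - frac) / 2) + 1, round(n * (1 + frac) / 2))
  sqrt(mean(x[keep]^2))
}

test_that("band-pass + notch suppresses 50 Hz and passes 10 Hz", {
  fs <- 256
  t <- seq_len(60 * fs) / fs
  r50 <- bandpass_notch(make_rec(sin(2 * pi * 50 * t), fs))
  expect_lt(central_rms(r50$data[1, ]), 0.1 * central_rms(sin(2 * pi * 50 * t)))
  r10 <- bandpass_notch(make_rec(sin(2 * pi * 10 * t), fs))
  expect_lt(abs(central_rms(r10$data[1, ]) / central_rms(sin(2 * pi * 10 * t)) - 1),
            0.11)
  z <- bandpass_notch(make_rec(rep(0, 60 * fs), fs))
  expect_true(all(z$data == 0))
})

test_that("filtering is linear and commutes with pooling", {
  fs <- 256
  set.seed(1)
  a <- rnorm(20 * fs); b <- rnorm(20 * fs)
  fa <- bandpass_notch(make_rec(a, fs))$data[1, ]
  fb <- bandpass_notch(make_rec(b, fs))$data[1, ]
  fab <- bandpass_notch(make_rec(a + b, fs))$data[1, ]
  expect_equal(fab, fa + fb, tolerance = 1e-9)
  rec <- eeg_recording(rbind(TP9 = a, AF7 = b, AF8 = b + a, TP10 = a - b),
                       fs, c("TP9", "AF7", "AF8", "TP10"))
  path1 <- pool_channels(bandpass_notch(rec))
  path2 <- bandpass_notch(pool_channels(rec))
  expect_equal(path1$data, path2$data, tolerance = 1e-9)
})

test_that("channel pooling averages TP and AF pairs", {
  rec <- eeg_recording(rbind(TP9 = c(1, 2), AF7 = c(0, 0), AF8 = c(2, 2),
                             TP10 = c(3, 4)),
                       256, c("TP9", "AF7", "AF8", "TP10"))
  pooled <- pool_channels(rec)
  expect_equal(pooled$channel_names, c("TP", "AF"))
  expect_equal(unname(pooled$data["TP", ]), c(2, 3))
  expect_equal(unname(pooled$data["AF", ]), c(1, 1))
  # idempotence when the pair is identical
  rec2 <- eeg_recording(rbind(TP9 = c(5, 6), AF7 = c(1, 1), AF8 = c(1, 1),
                              TP10 = c(5, 6)),
                        256, c("TP9", "AF7", "AF8", "TP10"))
  expect_equal(unname(pool_channels(rec2)$data["TP", ]), c(5, 6))
  rec3 <- eeg_recording(rbind(TP9 = c(1, 1), AF7 = c(1, 1), AF8 = c(1, 1)),
                        256, c("TP9", "AF7", "AF8"))
  expect_error(pool_channels(rec3), "TP10")
})

test_that("muscle screener flags exactly the injected artifact component", {
  cfg_on <- eeg_sim_config(duration_s = 30, fs = 256, muscle_artifact = TRUE,
                           muscle_amplitude = 5, seed = 21)
  scr <- screen_components(generate_eeg(cfg_on))
  expect_equal(sum(scr$reports$flagged), 1)
  flagged <- which(scr$reports$flagged)
  # the flagged component's mixing is focal on the injected channel
  expect_equal(rownames(scr$mixing)[which.max(abs(scr$mixing[, flagged]))], "AF7")
  cfg_off <- eeg_sim_config(duration_s = 30, fs = 256, seed = 21)
  scr0 <- screen_components(generate_eeg(cfg_off))
  expect_equal(sum(scr0$reports$flagged), 0)
  # nothing removed -> reconstruction equals the input
  expect_equal(scr0$cleaned$data, generate_eeg(cfg_off)$data, tolerance = 1e-6)
})

test_that("screener never flags clean data and always flags strong artifact", {
  for (seed in 1:15) {
    clean <- screen_components(generate_eeg(
      eeg_sim_config(duration_s = 20, fs = 256, seed = seed)))
    expect_equal(sum(clean$reports$flagged), 0)
    arty <- screen_components(generate_eeg(
      eeg_sim_config(duration_s = 20, fs = 256, muscle_artifact = TRUE,
                     muscle_amplitude = 5, seed = seed)))
    expect_gte(sum(arty$reports$flagged), 1)
  }
})

test_that("rank-deficient recordings error naming the degenerate channel", {
  x <- rnorm(1000)
  rec <- eeg_recording(rbind(TP9 = x, AF7 = x, AF8 = rnorm(1000), TP10 = rnorm(1000)),
                       256, c("TP9", "AF7", "AF8", "TP10"))
  expect_error(screen_components(rec), "TP9|AF7")
})

test_that("segment extraction uses the last 25 s of each question", {
  fs <- 256
  n <- 240 * fs
  idx <- seq_len(n)
  rec <- eeg_recording(rbind(TP = idx, AF = -idx), fs, c("TP", "AF"),
                       events = make_question_events(8, 30, fs))
  segs <- extract_segments(rec, "SCR")
  expect_length(segs, 16)
  tp1 <- Filter(function(s) s$channel == "TP" && s$question_index == 1, segs)[[1]]
  expect_length(tp1$samples, 25 * fs)
  # question 1 spans samples [0, 30 fs); its last 25 s start at sample 5 fs
  expect_equal(tp1$samples[1], 5 * fs + 1)
  expect_equal(tp1$samples[25 * fs], 30 * fs)
  q8 <- Filter(function(s) s$channel == "AF" && s$question_index == 8, segs)[[1]]
  expect_equal(q8$samples[1], -(7 * 30 * fs + 5 * fs + 1))
})

test_that("CTR segments are the central 25 s of the 240 s block", {
  fs <- 256
  idx <- seq_len(240 * fs)
  rec <- eeg_recording(rbind(TP = idx, AF = idx), fs, c("TP", "AF"))
  segs <- extract_segments(rec, "CTR")
  expect_length(segs, 2)
  expect_equal(segs[[1]]$samples[1], 107.5 * fs + 1)  # 0-based offset 27520
  expect_length(segs[[1]]$samples, 25 * fs)
})

test_that("segment extraction validates durations and markers", {
  fs <- 64
  rec <- eeg_recording(matrix(rnorm(2 * 20 * fs), 2), fs, c("TP", "AF"),
                       events = data.frame(sample_index = 1L, label = "question_1"))
  expect_error(extract_segments(rec, "SCR"), "shorter")
  rec2 <- eeg_recording(matrix(rnorm(2 * 240 * fs), 2), fs, c("TP", "AF"))
  expect_error(extract_segments(rec2, "SLR"), "markers")
})

test_that("decimation halves and quarters sampling rate with correct lengths", {
  fs <- 256
  seg <- condition_segment(sin(2 * pi * 10 * seq_len(25 * fs) / fs), fs, "CTR", "TP")
  d4 <- downsample_segment(seg, 4)
  expect_equal(d4$fs, 64)
  expect_length(d4$samples, 1600)
  # a 10 Hz tone survives decimation
  expect_lt(abs(central_rms(d4$samples) / central_rms(seg$samples) - 1), 0.05)
  expect_identical(downsample_segment(seg, 1), seg)
  expect_error(downsample_segment(seg, 0), class = "topobind_invalid_config")
})
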