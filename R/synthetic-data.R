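# Synthetic EEG, dynamical-system fixtures and Libet-clock trial schedules.
# Every generator takes an explicit seed and is bit-reproducible; all
# randomness is drawn under a local RNG state so global streams are untouched.

#' Configuration for the synthetic EEG generator
#'
#' Describes a 4-channel Muse-style recording: quasi-sinusoidal band
#' oscillations (carrier at the band centre, slow Brownian phase drift,
#' mild amplitude modulation) shared across channels, per-channel 1/f
#' background, optional
#' 50 Hz line interference and an optional focal broadband muscle artifact
#' whose log-log PSD slope over 7-45 Hz is positive (so that the
#' muscle-component screener has a recoverable target).
#'
#' @param duration_s recording length in seconds (> 0)
#' @param fs sampling rate in Hz (default 256, the Muse-S rate)
#' @param n_channels number of channels (default 4: TP9, AF7, AF8, TP10)
#' @param band_weights named non-negative weights for the six canonical
#'   bands (delta, theta, alpha, sigma, beta, gamma); unit standard
#'   deviation per source before weighting
#' @param one_over_f_exponent spectral exponent of the background
#'   (PSD proportional to 1/f^exponent; default 1)
#' @param one_over_f_amp amplitude of the 1/f background relative to a
#'   unit-SD oscillatory source (one independent realisation per channel)
#' @param line_noise_amp relative amplitude of a common 50 Hz sinusoid
#' @param muscle_artifact logical; inject a broadband artifact into a
#'   single channel
#' @param muscle_amplitude artifact SD relative to unit background
#' @param muscle_channel channel receiving the artifact (default "AF7")
#' @param scale_uv overall output scale in microvolts per unit SD
#' @param seed integer seed
#' @return an object of class `eeg_sim_config`
#' @export
eeg_sim_config <- function(duration_s,
                           fs = 256,
                           n_channels = 4,
                           band_weights = c(delta = 1.0, theta = 0.6,
                                            alpha = 1.2, sigma = 0.2,
                                            beta = 0.3, gamma = 0.1),
                           one_over_f_exponent = 1.0,
                           one_over_f_amp = 1.0,
                           line_noise_amp = 0.2,
                           muscle_artifact = FALSE,
                           muscle_amplitude = 0,
                           muscle_channel = "AF7",
                           scale_uv = 10,
                           seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be positive")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  bw <- rep(0, 6)
  names(bw) <- names(band_scheme())
  if (length(band_weights)) {
    unknown <- setdiff(names(band_weights), names(bw))
    if (length(unknown)) stop_invalid("unknown band(s): ", paste(unknown, collapse = ", "))
    bw[names(band_weights)] <- band_weights
  }
  if (any(bw < 0)) stop_invalid("band weights must be non-negative")
  if (all(bw == 0) && one_over_f_amp <= 0 && line_noise_amp <= 0 &&
      !(muscle_artifact && muscle_amplitude > 0))
    stop_invalid("at least one signal component must be active")
  structure(list(duration_s = duration_s, fs = fs, n_channels = n_channels,
                 band_weights = bw,
                 one_over_f_exponent = one_over_f_exponent,
                 one_over_f_amp = one_over_f_amp,
                 line_noise_amp = line_noise_amp,
                 muscle_artifact = isTRUE(muscle_artifact),
                 muscle_amplitude = muscle_amplitude,
                 muscle_channel = muscle_channel,
                 scale_uv = scale_uv, seed = as.integer(seed)),
            class = "eeg_sim_config")
}

# quasi-sinusoidal band oscillation: carrier at the band centre with slow
# Brownian phase drift (linewidth ~ bw_hz) and mild slow amplitude
# modulation -- the classic narrowband model of a cortical rhythm.  Unit SD.
band_oscillation <- function(n, fs, lo, hi) {
  fc <- (lo + hi) / 2
  bw_hz <- max(0.05, 0.02 * (hi - lo))
  phase <- cumsum(rnorm(n, sd = sqrt(2 * pi * bw_hz / fs)))
  am <- 1 + 0.2 * shaped_noise(n, fs, function(f) as.numeric(f > 0 & f < 0.5))
  x <- am * sin(2 * pi * fc * (seq_len(n) - 1) / fs + phase)
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

# white noise spectrally shaped by amplitude `shape(f)`; unit SD output
shaped_noise <- function(n, fs, shape) {
  x <- rnorm(n)
  X <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n  # two-sided frequency magnitude
  amp <- shape(f)
  amp[!is.finite(amp)] <- 0
  y <- Re(fft(X * amp, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y <- y / s
  y
}

#' Generate a synthetic multi-channel EEG recording
#'
#' @param config an [eeg_sim_config()]
#' @param events optional data frame (sample_index, label) attached to the
#'   recording, e.g. from [make_question_events()]
#' @return an [eeg_recording()]
#' @export
generate_eeg <- function(config, events = NULL) {
  stopifnot(inherits(config, "eeg_sim_config"))
  n <- round(config$duration_s * config$fs)
  fs <- config$fs
  ch_names <- c("TP9", "AF7", "AF8", "TP10")[seq_len(config$n_channels)]
  bands <- band_scheme()
  with_local_seed(config$seed, {
    data <- matrix(0, nrow = config$n_channels, ncol = n)
    # oscillatory band sources, spread across channels (non-focal mixing)
    for (b in names(bands)) {
      w <- config$band_weights[[b]]
      if (w <= 0) next
      lo <- bands[[b]][1]; hi <- min(bands[[b]][2], fs / 2)
      if (hi <= lo) next
      src <- band_oscillation(n, fs, lo, hi)
      mix <- 0.8 + 0.4 * runif(config$n_channels)
      data <- data + w * (mix %o% src)
    }
    # independent 1/f background per channel
    if (config$one_over_f_amp > 0) {
      expo <- config$one_over_f_exponent
      for (c in seq_len(config$n_channels)) {
        bg <- shaped_noise(n, fs, function(f) ifelse(f <= 0, 0, pmax(f, 0.5)^(-expo / 2)))
        data[c, ] <- data[c, ] + config$one_over_f_amp * bg
      }
    }
    # common 50 Hz line interference
    if (config$line_noise_amp > 0 && fs / 2 > 50) {
      phase <- runif(1, 0, 2 * pi)
      line <- sqrt(2) * sin(2 * pi * 50 * seq_len(n) / fs + phase)
      data <- data + config$line_noise_amp * matrix(line, config$n_channels, n, byrow = TRUE)
    }
    # focal broadband muscle artifact: PSD rises with frequency above ~5 Hz,
    # with a bursting (log-normal) envelope as in postural EMG -- the
    # envelope makes the source super-Gaussian, hence ICA-identifiable
    if (config$muscle_artifact && config$muscle_amplitude > 0) {
      idx <- match(config$muscle_channel, ch_names)
      if (is.na(idx)) stop_invalid("muscle_channel not among channels")
      # amplitude ~ f between 5 and 60 Hz: PSD ~ f^2 across the screened
      # 7-45 Hz band, with the artifact's variance concentrated there
      art <- shaped_noise(n, fs, function(f) ifelse(f < 5, 0, pmin(f, 60)))
      env <- exp(0.7 * shaped_noise(n, fs, function(f) as.numeric(f > 0 & f < 1)))
      art <- art * env
      art <- art / sd(art)
      data[idx, ] <- data[idx, ] + config$muscle_amplitude * art
    }
    data <- data * config$scale_uv
    rownames(data) <- ch_names
    eeg_recording(data, fs, ch_names, events = events)
  })
}

#' Event markers for a block of reflection questions
#'
#' @param n_questions number of questions (default 8)
#' @param question_s duration of each question in seconds (default 30)
#' @param fs sampling rate in Hz
#' @return data frame with columns `sample_index` (1-based) and `label`
#' @export
make_question_events <- function(n_questions = 8, question_s = 30, fs = 256) {
  data.frame(sample_index = as.integer(round((seq_len(n_questions) - 1) * question_s * fs)) + 1L,
             label = paste0("question_", seq_len(n_questions)),
             stringsAsFactors = FALSE)
}

#' Scalar test-signal fixtures for the embedding and persistence stages
#'
#' `sine` has one spectral peak (period 32 samples); `two_tone` mixes two
#' incommensurate tones; `lorenz` is the first coordinate of the standard
#' chaotic Lorenz trajectory (sigma = 10, rho = 28, beta = 8/3); and
#' `white_noise` is i.i.d. Gaussian.
#'
#' @param name one of "sine", "two_tone", "lorenz", "white_noise"
#' @param n number of samples (>= 16)
#' @param seed integer seed (jitters the Lorenz initial condition and the
#'   noise stream; the sine fixtures are deterministic in phase)
#' @return numeric vector of length `n`
#' @export
generate_fixture <- function(name, n, seed = 1L) {
  if (!is.numeric(n) || n < 16) stop_invalid("n must be at least 16")
  name <- match.arg(name, c("sine", "two_tone", "lorenz", "white_noise"))
  i <- seq_len(n) - 1
  with_local_seed(seed, {
    switch(name,
      sine = sin(2 * pi * i / 32),
      two_tone = sin(2 * pi * i / 32) + 0.7 * sin(2 * pi * i / 9),
      white_noise = rnorm(n),
      lorenz = {
        deriv <- function(t, y, parms) {
          list(c(parms$sigma * (y[2] - y[1]),
                 y[1] * (parms$rho - y[3]) - y[2],
                 y[1] * y[2] - parms$beta * y[3]))
        }
        y0 <- c(1 + rnorm(1, sd = 0.05), 1, 1)
        burn <- 500
        times <- seq(0, (n + burn) * 0.02, by = 0.02)
        sol <- deSolve::ode(y = y0, times = times, func = deriv,
                            parms = list(sigma = 10, rho = 28, beta = 8 / 3),
                            method = "lsoda")
        as.numeric(sol[(burn + 1):(burn + n), 2])
      })
  })
}

#' Configuration for the Libet-clock trial simulator
#'
#' The schedule mirrors the canonical intentional-binding design: four
#' randomized conditions (action-only, tone-only, and two action-tone
#' agency conditions judged on the action or on the tone), each with
#' `n_trials_per_condition` trials.  Ground-truth perceptual shifts are
#' injected only in the agency conditions; judgment noise is Gaussian
#' (the error model is an explicit assumption, stated in the docs).
#'
#' @param n_trials_per_condition trials per condition (default 20)
#' @param action_tone_delay_ms delay between keypress and tone (default 250)
#' @param clock_period_ms full rotation period of the clock dot
#'   (default 2560 ms, the standard Libet-clock convention)
#' @param action_shift_ms ground-truth shift of action judgments in agency
#'   blocks (positive = perceived later, toward the tone)
#' @param tone_shift_ms ground-truth shift of tone judgments in agency
#'   blocks (negative = perceived earlier, toward the action)
#' @param judgment_noise_sd_ms SD of the Gaussian judgment error (ms)
#' @param seed integer seed
#' @return object of class `trial_sim_config`
#' @export
trial_sim_config <- function(n_trials_per_condition = 20,
                             action_tone_delay_ms = 250,
                             clock_period_ms = 2560,
                             action_shift_ms = 0,
                             tone_shift_ms = 0,
                             judgment_noise_sd_ms = 70,
                             seed = 1L) {
  if (n_trials_per_condition < 1) stop_invalid("need at least 1 trial per condition")
  if (clock_period_ms <= 0) stop_invalid("clock_period_ms must be positive")
  if (judgment_noise_sd_ms < 0) stop_invalid("judgment noise sd must be >= 0")
  structure(list(n_trials_per_condition = as.integer(n_trials_per_condition),
                 action_tone_delay_ms = action_tone_delay_ms,
                 clock_period_ms = clock_period_ms,
                 action_shift_ms = action_shift_ms,
                 tone_shift_ms = tone_shift_ms,
                 judgment_noise_sd_ms = judgment_noise_sd_ms,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Conditions of the intentional-binding task
#' @export
binding_conditions <- function() {
  c("action_only", "tone_only", "agency_judge_action", "agency_judge_tone")
}

#' Simulate one subject's Libet-clock trials
#'
#' Baseline conditions report the actual clock angle plus noise; agency
#' conditions additionally shift the judged event by the configured
#' ground-truth action/tone shift.  Reported times wrap onto the clock
#' period (angles stored in \[0, 360)).
#'
#' @param config a [trial_sim_config()]
#' @return data frame with one row per trial: `trial`, `condition`,
#'   `actual_deg`, `reported_deg`, `actual_ms`, `reported_ms`,
#'   `clock_period_ms`
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "trial_sim_config"))
  conds <- binding_conditions()
  k <- config$n_trials_per_condition
  period <- config$clock_period_ms
  with_local_seed(config$seed, {
    condition <- sample(rep(conds, each = k))
    n <- length(condition)
    actual_deg <- runif(n, 0, 360)
    shift_ms <- ifelse(condition == "agency_judge_action", config$action_shift_ms,
                ifelse(condition == "agency_judge_tone", config$tone_shift_ms, 0))
    noise_ms <- if (config$judgment_noise_sd_ms > 0)
      rnorm(n, sd = config$judgment_noise_sd_ms) else rep(0, n)
    reported_deg <- (actual_deg + (shift_ms + noise_ms) / period * 360) %% 360
    data.frame(trial = seq_len(n), condition = condition,
               actual_deg = actual_deg, reported_deg = reported_deg,
               actual_ms = actual_deg / 360 * period,
               reported_ms = reported_deg / 360 * period,
               clock_period_ms = period, stringsAsFactors = FALSE)
  })
}

#' Write / read an EEG recording as CSV (muselsl column layout)
#'
#' Columns: `timestamps` (seconds) then one column per channel in
#' microvolts.  Events are written separately as (timestamp,label).
#'
#' @param rec an [eeg_recording()]
#' @param path output CSV path
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(timestamps = (seq_len(ncol(rec$data)) - 1) / rec$fs)
  for (ch in rec$channel_names) df[[ch]] <- rec$data[ch, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param events_path optional path for the event CSV
#' @export
write_events_csv <- function(rec, events_path) {
  ev <- rec$events
  ev$timestamp <- (ev$sample_index - 1) / rec$fs
  write.csv(ev[, c("timestamp", "label")], events_path, row.names = FALSE)
  invisible(events_path)
}

#' @rdname write_eeg_csv
#' @param fs sampling rate of the stored recording (Hz); inferred from the
#'   timestamp column when omitted
#' @export
read_eeg_csv <- function(path, fs = NULL) {
  df <- read.csv(path)
  if (is.null(fs)) fs <- 1 / median(diff(df$timestamps))
  chans <- setdiff(names(df), "timestamps")
  data <- t(as.matrix(df[, chans, drop = FALSE]))
  rownames(data) <- chans
  eeg_recording(data, fs, chans)
}
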