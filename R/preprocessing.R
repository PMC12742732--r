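# EEG preprocessing: container, zero-phase FIR band-pass + notch, ICA-based
# muscle-component screening, TP/AF channel pooling, per-condition segment
# extraction and anti-aliased decimation.

#' Multi-channel EEG recording
#'
#' @param data channels x samples matrix (microvolts), rownames = channels
#' @param fs sampling rate in Hz
#' @param channel_names channel labels (unique); defaults to rownames
#' @param events optional data frame with `sample_index` (1-based) and
#'   `label`
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data), events = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names)) stop_invalid("channel names required")
  if (anyDuplicated(channel_names)) stop_invalid("channel names must be unique")
  if (length(channel_names) != nrow(data))
    stop_invalid("channel_names length must match rows of data")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  rownames(data) <- channel_names
  if (!is.null(events)) {
    stopifnot(all(c("sample_index", "label") %in% names(events)))
    if (any(events$sample_index < 1 | events$sample_index > ncol(data)))
      stop_invalid("event sample indices out of range")
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz [%s]\n",
              nrow(x$data), ncol(x$data), x$fs,
              paste(x$channel_names, collapse = ", ")))
  if (!is.null(x$events)) cat(sprintf("  %d event marker(s)\n", nrow(x$events)))
  invisible(x)
}

#' FIR band-pass / notch filter specification
#'
#' Kernel lengths follow the Hamming-window transition-bandwidth rule
#' (about 3.3 / (transition width / fs) taps); the 0.1 Hz high-pass edge
#' therefore implies a long kernel, applied zero-phase by compensating
#' the linear-phase group delay.  The notch is a narrow band-stop around
#' `notch_hz` (default 49-51 Hz).
#'
#' @param highpass_hz high-pass edge in Hz (default 0.1)
#' @param lowpass_hz low-pass edge in Hz (default 45)
#' @param notch_hz mains frequency to suppress (default 50; `NA` disables)
#' @param fir_length band-pass kernel length in taps (odd; default from the
#'   transition-bandwidth rule at the high-pass edge, capped at 8193)
#' @param notch_halfwidth_hz half-width of the stop band (default 1)
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(highpass_hz = 0.1, lowpass_hz = 45, notch_hz = 50,
                        fir_length = NULL, notch_halfwidth_hz = 1) {
  if (highpass_hz <= 0 || lowpass_hz <= highpass_hz)
    stop_invalid("need 0 < highpass < lowpass")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 notch_hz = notch_hz, fir_length = fir_length,
                 notch_halfwidth_hz = notch_halfwidth_hz),
            class = "filter_spec")
}

odd_taps <- function(n, cap = Inf) {
  n <- min(ceiling(n), cap)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

# zero-phase linear filtering with a symmetric (linear-phase) FIR kernel:
# FFT convolution, then removal of the (K-1)/2-sample group delay
apply_fir_zerophase <- function(x, kernel) {
  K <- length(kernel)
  stopifnot(K %% 2 == 1)
  n <- length(x)
  y <- convolve(x, rev(kernel), type = "open")  # length n + K - 1
  d <- (K - 1) / 2
  y[(d + 1):(d + n)]
}

#' Zero-phase FIR band-pass and notch filtering
#'
#' Applies a linear-phase FIR band-pass (Hamming design) and, when
#' `notch_hz` is set and below Nyquist, a narrow FIR band-stop, each
#' channel independently and with the group delay compensated so the
#' output is zero-phase.
#'
#' @param rec an [eeg_recording()]
#' @param spec a [filter_spec()]
#' @return filtered [eeg_recording()]
#' @export
bandpass_notch <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  fs <- rec$fs
  if (fs / 2 <= spec$lowpass_hz)
    stop_invalid("sampling rate too low for the requested low-pass edge")
  L <- spec$fir_length %||% odd_taps(3.3 * fs / spec$highpass_hz, cap = 8193)
  bp <- signal::fir1(L - 1, c(spec$highpass_hz, spec$lowpass_hz) / (fs / 2),
                     type = "pass")
  kernel <- bp
  if (!is.null(spec$notch_hz) && !is.na(spec$notch_hz) &&
      spec$notch_hz < fs / 2) {
    Ln <- odd_taps(3.3 * fs / (spec$notch_halfwidth_hz / 2))
    lo <- (spec$notch_hz - spec$notch_halfwidth_hz) / (fs / 2)
    hi <- (spec$notch_hz + spec$notch_halfwidth_hz) / (fs / 2)
    notch <- signal::fir1(Ln - 1, c(lo, hi), type = "stop")
    kernel <- convolve(kernel, rev(notch), type = "open")
  }
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- apply_fir_zerophase(rec$data[i, ], kernel)
  out
}

# ---- ICA-based muscle-component screening --------------------------------

# minimal deterministic symmetric FastICA (tanh contrast) on channels x
# samples data; returns unit-variance sources and the mixing matrix
fastica_decompose <- function(X, n_components = nrow(X), seed = 1L,
                              max_iter = 200, tol = 1e-7) {
  nc <- nrow(X)
  if (n_components > nc) stop_invalid("n_components exceeds channel count")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    sds <- apply(X, 1, sd)
    bad <- if (any(sds == 0)) rownames(X)[which(sds == 0)[1]] else {
      cc <- abs(cor(t(X))); diag(cc) <- 0
      rownames(X)[which(cc == max(cc), arr.ind = TRUE)[1, 1]]
    }
    stop("rank-deficient data: channel ", bad, " is constant or a linear copy")
  }
  k <- seq_len(n_components)
  V <- diag(1 / sqrt(eg$values[k]), n_components) %*% t(eg$vectors[, k, drop = FALSE])
  Z <- V %*% Xc
  W <- with_local_seed(seed, {
    qr.Q(qr(matrix(rnorm(n_components^2), n_components)))
  })
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(1 - G^2), n_components) %*% W
    sv <- svd(W1)
    W1 <- sv$u %*% t(sv$v)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- eg$vectors[, k, drop = FALSE] %*% diag(sqrt(eg$values[k]), n_components) %*% t(W)
  # deterministic sign: largest-magnitude mixing weight positive
  for (j in seq_len(ncol(A))) {
    top <- which.max(abs(A[, j]))
    if (A[top, j] < 0) { A[, j] <- -A[, j]; S[j, ] <- -S[j, ] }
  }
  rownames(A) <- rownames(X)
  list(sources = S, mixing = A, mean = mu)
}

#' Screen independent components for muscle artifact
#'
#' Decomposes the recording into maximally independent components
#' (deterministic given `seed`), then flags components that look like
#' muscle activity: positive log-log PSD slope over 7-45 Hz, focal mixing
#' (max |weight| / sum |weights| above `focality_threshold`) and a smooth
#' spectrum (R^2 of the log-log fit above `r2_threshold`).  The cleaned
#' recording excludes the flagged components; when nothing is flagged the
#' reconstruction equals the input to numerical tolerance.
#'
#' @param rec an [eeg_recording()]
#' @param n_components number of components (<= number of channels)
#' @param seed seed for the ICA initialisation
#' @param slope_threshold flag requires slope > this (default 0)
#' @param focality_threshold flag requires focality > this (default 0.6)
#' @param r2_threshold flag requires trimmed log-log fit R^2 > this.
#'   Default 0: the R^2 is always reported but does not gate the flag,
#'   because on few-channel mixtures rhythm leakage through the unmixing
#'   dominates the fit residuals of genuinely broadband components
#'   (brain components routinely fit *better*); see the methods vignette
#' @return list with `reports` (one row per component: slope_7_45,
#'   focality, smoothness, flagged), `cleaned` (the reconstructed
#'   [eeg_recording()]), and `mixing` (channels x components matrix)
#' @export
screen_components <- function(rec, n_components = nrow(rec$data), seed = 1L,
                              slope_threshold = 0, focality_threshold = 0.6,
                              r2_threshold = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  dec <- fastica_decompose(rec$data, n_components, seed = seed)
  reports <- do.call(rbind, lapply(seq_len(n_components), function(j) {
    ps <- welch_psd(dec$sources[j, ], rec$fs,
                    window_s = min(4, floor(ncol(rec$data) / rec$fs / 2)))
    # log-log fit on log-spaced bins, each summarised by its lower quartile:
    # estimates the smooth spectral floor, robust to narrow oscillatory
    # peaks riding on the component spectrum
    edges <- exp(seq(log(7), log(45), length.out = 13))
    bin <- findInterval(ps$freq, edges, rightmost.closed = TRUE)
    sel <- bin >= 1 & bin <= 12 & ps$psd > 0
    bp <- tapply(ps$psd[sel], bin[sel], quantile, probs = 0.25, names = FALSE)
    bf <- tapply(ps$freq[sel], bin[sel], function(f) exp(mean(log(f))))
    lp <- log10(bp); lf <- log10(bf)
    fit <- lm(lp ~ lf)
    # trimmed refit: discard the two most peak-inflated bins (largest
    # upward residuals, e.g. a leaked alpha carrier) before judging
    # slope and smoothness of the spectral floor
    drop2 <- order(resid(fit), decreasing = TRUE)[1:2]
    fit <- lm(lp[-drop2] ~ lf[-drop2])
    slope <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
    focality <- max(abs(dec$mixing[, j])) / sum(abs(dec$mixing[, j]))
    data.frame(component_index = j, slope_7_45 = slope, focality = focality,
               smoothness = r2,
               flagged = slope > slope_threshold &
                 focality > focality_threshold & r2 > r2_threshold)
  }))
  keep <- !reports$flagged
  cleaned <- rec
  cleaned$data <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$mean
  rownames(cleaned$data) <- rec$channel_names
  list(reports = reports, cleaned = cleaned, mixing = dec$mixing)
}

#' Pool Muse channels into TP and AF averages
#'
#' TP = (TP9 + TP10) / 2, AF = (AF7 + AF8) / 2.
#'
#' @param rec an [eeg_recording()] containing TP9, TP10, AF7, AF8
#' @return two-channel [eeg_recording()] named TP, AF
#' @export
pool_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- c("TP9", "TP10", "AF7", "AF8")
  missing <- setdiff(need, rec$channel_names)
  if (length(missing))
    stop_invalid("missing channel(s): ", paste(missing, collapse = ", "))
  pooled <- rbind(TP = (rec$data["TP9", ] + rec$data["TP10", ]) / 2,
                  AF = (rec$data["AF7", ] + rec$data["AF8", ]) / 2)
  eeg_recording(pooled, rec$fs, c("TP", "AF"), events = rec$events)
}

#' One pooled-channel, per-condition 25-second segment
#'
#' @param samples numeric vector
#' @param fs sampling rate in Hz
#' @param group "SCR", "SLR" or "CTR"
#' @param channel "TP" or "AF"
#' @param question_index 1..8 for reflection groups, NA for CTR
#' @return object of class `condition_segment`
#' @export
condition_segment <- function(samples, fs, group, channel, question_index = NA) {
  structure(list(samples = as.numeric(samples), fs = fs, group = group,
                 channel = channel, question_index = question_index),
            class = "condition_segment")
}

#' Extract the analysis segments from a pooled recording
#'
#' Reflection groups (SCR/SLR): eight question markers delimit 30 s
#' questions; each segment is the last `segment_s` seconds of its
#' question.  Control (CTR): one segment per channel, the central
#' `segment_s` seconds of the `total_s`-second block (symmetric about the
#' midpoint).  Half-open sample intervals, 0-based offsets.
#'
#' @param rec pooled [eeg_recording()] (channels TP, AF) with question
#'   markers in `rec$events` for SCR/SLR
#' @param group "SCR", "SLR" or "CTR"
#' @param question_s question duration in seconds (default 30)
#' @param segment_s segment length in seconds (default 25)
#' @param total_s CTR block duration in seconds (default 240)
#' @return list of [condition_segment()]s (channels x questions)
#' @export
extract_segments <- function(rec, group, question_s = 30, segment_s = 25,
                             total_s = 240) {
  stopifnot(inherits(rec, "eeg_recording"))
  group <- match.arg(group, c("SCR", "SLR", "CTR"))
  fs <- rec$fs
  seg_len <- round(segment_s * fs)
  n <- ncol(rec$data)
  segs <- list()
  if (group == "CTR") {
    start0 <- round((total_s - segment_s) / 2 * fs)  # 0-based offset
    if (start0 + seg_len > n) stop_invalid("recording shorter than the CTR block")
    for (ch in rec$channel_names) {
      segs[[length(segs) + 1]] <- condition_segment(
        rec$data[ch, (start0 + 1):(start0 + seg_len)], fs, group, ch, NA)
    }
  } else {
    if (segment_s > question_s) stop_invalid("question shorter than the segment")
    ev <- rec$events
    if (is.null(ev) || !any(grepl("^question_", ev$label)))
      stop_invalid("missing question markers for group ", group)
    qev <- ev[grepl("^question_", ev$label), , drop = FALSE]
    qev <- qev[order(qev$sample_index), , drop = FALSE]
    qlen <- round(question_s * fs)
    for (q in seq_len(nrow(qev))) {
      q0 <- qev$sample_index[q] - 1  # 0-based question start
      if (q0 + qlen > n) stop_invalid("question ", q, " shorter than ", question_s, " s")
      start0 <- q0 + qlen - seg_len  # last segment_s seconds
      for (ch in rec$channel_names) {
        segs[[length(segs) + 1]] <- condition_segment(
          rec$data[ch, (start0 + 1):(start0 + seg_len)], fs, group, ch, q)
      }
    }
  }
  segs
}

#' Downsample a segment with anti-alias filtering
#'
#' FIR anti-alias low-pass then decimation by `factor`; the new sampling
#' rate is `fs / factor` and the length is `floor(n / factor)`.
#'
#' @param seg a [condition_segment()]
#' @param factor integer decimation factor (>= 1)
#' @return decimated [condition_segment()]
#' @export
downsample_segment <- function(seg, factor = 4) {
  stopifnot(inherits(seg, "condition_segment"))
  if (factor < 1 || factor != round(factor)) stop_invalid("factor must be a positive integer")
  if (factor == 1) return(seg)
  y <- signal::decimate(seg$samples, q = factor, ftype = "fir")
  new_len <- floor(length(seg$samples) / factor)
  seg$samples <- as.numeric(y[seq_len(new_len)])
  seg$fs <- seg$fs / factor
  seg
}
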