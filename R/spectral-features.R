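# Welch power spectral density and six-band relative band powers.

#' The six-band scheme
#'
#' delta (0.5, 5), theta (5, 8), alpha (8, 13), sigma (13, 16),
#' beta (16, 30), gamma (30, 45) Hz; bands are half-open `[low, high)`.
#'
#' @return named list of `c(low, high)` pairs in Hz
#' @export
band_scheme <- function() {
  list(delta = c(0.5, 5), theta = c(5, 8), alpha = c(8, 13),
       sigma = c(13, 16), beta = c(16, 30), gamma = c(30, 45))
}

#' Welch power spectral density
#'
#' Hann-windowed overlapping segments, per-segment mean removal, one-sided
#' density scaling (power of a unit-amplitude sinusoid integrates to 1/2).
#'
#' @param x numeric vector, or a [condition_segment()]
#' @param fs sampling rate in Hz (taken from the segment when `x` is one)
#' @param window_s window length in seconds (default 4; frequency
#'   resolution is 1/window_s)
#' @param overlap fractional overlap between windows (default 0.5)
#' @return list with `freq` (Hz) and `psd` (power / Hz)
#' @export
welch_psd <- function(x, fs = NULL, window_s = 4, overlap = 0.5) {
  if (inherits(x, "condition_segment")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop_invalid("fs required")
  nper <- round(window_s * fs)
  step <- max(1, round(nper * (1 - overlap)))
  if (length(x) < nper + step)
    stop_invalid("segment too short: need at least two Welch windows")
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  norm <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nfreq)])^2 / norm
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nper)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * fs / nper, psd = psd * dbl)
}

#' Relative band power
#'
#' Mean PSD within each band, normalised by the sum of the six band means
#' (not by total integrated power) -- so the six fractions always sum to 1.
#'
#' @param psd a list `(freq, psd)` from [welch_psd()]
#' @param scheme band scheme, default [band_scheme()]
#' @return named numeric vector of fractions, one per band
#' @export
relative_band_power <- function(psd, scheme = band_scheme()) {
  means <- vapply(scheme, function(b) {
    sel <- psd$freq >= b[1] & psd$freq < b[2]
    if (!any(sel)) stop_invalid("no PSD bins in band [", b[1], ", ", b[2], ")")
    mean(psd$psd[sel])
  }, numeric(1))
  total <- sum(means)
  if (total == 0) return(setNames(rep(0, length(means)), names(means)))
  means / total
}

#' Average per-question feature vectors
#'
#' Element-wise arithmetic mean of a list of equal-length named numeric
#' vectors (e.g. relative band powers of the eight questions); simplex
#' inputs stay on the simplex.
#'
#' @param values non-empty list of numeric vectors
#' @return numeric vector
#' @export
average_over_questions <- function(values) {
  if (!length(values)) stop_invalid("empty feature list")
  m <- do.call(rbind, values)
  colMeans(m)
}
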