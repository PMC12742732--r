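# Sample entropy and multiscale entropy via coarse-graining.

#' Coarse-grain a series
#'
#' Non-overlapping windows of length `tau`, each replaced by its mean;
#' the result has `floor(n / tau)` points (trailing remainder dropped).
#'
#' @param x numeric series
#' @param tau scale factor (>= 1)
#' @return numeric vector
#' @export
coarse_grain <- function(x, tau) {
  if (tau < 1 || tau != round(tau)) stop_invalid("tau must be a positive integer")
  if (tau > length(x)) stop_invalid("tau exceeds the series length")
  if (tau == 1) return(x)
  nwin <- floor(length(x) / tau)
  colMeans(matrix(x[seq_len(nwin * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A / B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r_tol` and `A` the pairs still matching when
#' extended by one point (templates start at 1..n-m for both lengths;
#' self-matches excluded).  Returns `NA` (undefined) when either count is
#' zero or the series has no variance.
#'
#' @param x numeric series
#' @param m pattern length (default 2)
#' @param r tolerance as a fraction of `sd(x)` (default 0.2), or an
#'   absolute tolerance when `r_absolute = TRUE`
#' @param r_absolute interpret `r` as an absolute tolerance
#' @return scalar entropy, or `NA_real_` when undefined
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, r_absolute = FALSE) {
  if (length(x) <= m + 1) stop_invalid("series too short for pattern length m")
  s <- sd(x)
  if (!r_absolute && s == 0) return(NA_real_)
  r_tol <- if (r_absolute) r else r * s
  if (r_tol <= 0) return(NA_real_)
  counts <- cpp_sampen_counts(as.numeric(x), as.integer(m), r_tol)
  B <- counts[1]; A <- counts[2]
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Multiscale entropy
#'
#' Sample entropy of successive coarse-grained versions of the series.
#' The tolerance is fixed from the SD of the *original* series across all
#' scales (the common convention); set `r_from_original = FALSE` to
#' re-estimate it per scale.
#'
#' @param x numeric series
#' @param m pattern length (default 2)
#' @param r tolerance fraction (default 0.2)
#' @param scales coarse-graining factors (default 1:20)
#' @param r_from_original fix the tolerance from the raw series SD
#' @return data frame `(scale, sampen)`; undefined scales are `NA`
#' @export
multiscale_entropy <- function(x, m = 2, r = 0.2, scales = 1:20,
                               r_from_original = TRUE) {
  r_tol <- r * sd(x)
  vals <- vapply(scales, function(tau) {
    y <- coarse_grain(x, tau)
    if (length(y) <= m + 1) return(NA_real_)
    if (r_from_original) sample_entropy(y, m, r_tol, r_absolute = TRUE)
    else sample_entropy(y, m, r)
  }, numeric(1))
  data.frame(scale = scales, sampen = vals)
}
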