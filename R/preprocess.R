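#' Average stimulus-locked sweeps
#'
#' Pointwise arithmetic mean of equal-length voltage sweeps. Averaging n
#' independent noise sweeps reduces the noise standard deviation by
#' 1/sqrt(n), which is why averaged SEP recordings (typically 200 sweeps)
#' show the evoked response above the electrophysiological noise floor.
#'
#' @param sweeps A list of equal-length numeric vectors, or a matrix with
#'   one sweep per column.
#' @return A numeric vector: the pointwise mean sweep.
#' @export
average_sweeps <- function(sweeps) {
  if (is.matrix(sweeps)) {
    if (ncol(sweeps) < 1) stop("validation error: no sweeps to average")
    return(rowMeans(sweeps))
  }
  if (!is.list(sweeps) || length(sweeps) == 0)
    stop("validation error: sweeps must be a non-empty list or matrix")
  lens <- lengths(sweeps)
  if (length(unique(lens)) != 1)
    stop("validation error: sweeps have unequal lengths")
  rowMeans(matrix(unlist(sweeps), nrow = lens[1]))
}

#' Zero-phase bandpass filter
#'
#' Band-limits a recording by spectral masking: Fourier components with
#' (folded) frequency inside `[low, high]` pass unchanged, the rest are
#' zeroed. The mask is real and symmetric, so the filter has exactly zero
#' phase — component latency is a classification feature and must not be
#' shifted by a group delay — and it is a projection, so filtering twice
#' with the same band equals filtering once (a recursive filter such as a
#' forward-backward Butterworth can satisfy neither property exactly: its
#' transition bands attenuate twice on the second pass).
#'
#' @param rec An `sep_recording`.
#' @param low,high Band edges in Hz; `0 < low < high < sampling_rate/2`.
#' @return A filtered copy of `rec` with its `bandpass` metadata updated;
#'   length preserved.
#' @export
bandpass_filter <- function(rec, low, high) {
  validate_sep_recording(rec)
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("validation error: need 0 < low < high < sampling_rate/2")
  rec$samples <- bandpass_series(rec$samples, rec$sampling_rate, low, high)
  rec$bandpass <- c(low, high)
  validate_sep_recording(rec)
  rec
}

# filter a bare numeric series (also the synthetic generator's noise path)
bandpass_series <- function(x, rate, low, high) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * rate / n
  folded <- pmin(freqs, rate - freqs)
  mask <- folded >= low & folded <= high
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}
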