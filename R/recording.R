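#' SEP recording objects
#'
#' An `sep_recording` holds one averaged, stimulus-aligned somatosensory
#' evoked potential trace together with its acquisition metadata. Voltages
#' are in microvolts; time is in milliseconds post-stimulus with `t0_offset`
#' giving the time of the first sample relative to stimulus onset.
#'
#' @param samples Numeric vector of voltages (uV), length >= 2, all finite.
#' @param sampling_rate Sampling rate in Hz (> 0). Must exceed twice the
#'   upper bandpass edge when a bandpass is recorded.
#' @param t0_offset Time of the first sample relative to stimulus onset (ms).
#' @param n_sweeps_averaged Number of stimulus-locked sweeps averaged into
#'   this trace (0 if unknown).
#' @param bandpass Length-2 numeric `c(low, high)` in Hz, or `NULL` if the
#'   acquisition band is unknown.
#' @param condition One of `"normal"`, `"sham"`, `"C4"`, `"C5"`, `"C6"`,
#'   `"unknown"`.
#' @param subject_id Opaque subject identifier string.
#'
#' @return An object of class `sep_recording`.
#' @export
sep_recording <- function(samples, sampling_rate, t0_offset = 0,
                          n_sweeps_averaged = 0, bandpass = NULL,
                          condition = "unknown", subject_id = "unknown") {
  rec <- structure(
    list(
      samples = as.numeric(samples),
      sampling_rate = as.numeric(sampling_rate),
      t0_offset = as.numeric(t0_offset),
      n_sweeps_averaged = as.integer(n_sweeps_averaged),
      bandpass = if (is.null(bandpass)) NULL else as.numeric(bandpass),
      condition = as.character(condition),
      subject_id = as.character(subject_id)
    ),
    class = "sep_recording"
  )
  validate_sep_recording(rec)
}

#' @export
sep_conditions <- function() c("normal", "sham", "C4", "C5", "C6", "unknown")

#' Validate an SEP recording
#'
#' Checks the structural invariants: finite samples of length >= 2, positive
#' sampling rate, Nyquist-consistent bandpass, condition drawn from the
#' closed label set.
#'
#' @param rec An `sep_recording`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_sep_recording <- function(rec) {
  if (!inherits(rec, "sep_recording")) stop("not an sep_recording")
  if (length(rec$samples) < 2) stop("recording must have at least 2 samples")
  if (!all(is.finite(rec$samples))) stop("recording samples must be finite")
  if (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  if (!is.null(rec$bandpass)) {
    if (length(rec$bandpass) != 2 || any(!is.finite(rec$bandpass)))
      stop("bandpass must be c(low, high) in Hz")
    if (rec$bandpass[1] >= rec$bandpass[2])
      stop("bandpass low must be below bandpass high")
    if (rec$sampling_rate <= 2 * rec$bandpass[2])
      stop("sampling_rate must exceed twice the bandpass upper edge")
  }
  if (!rec$condition %in% sep_conditions())
    stop("condition must be one of: ", paste(sep_conditions(), collapse = ", "))
  invisible(rec)
}

#' Duration of a recording in milliseconds
#' @param rec An `sep_recording`.
#' @export
sep_duration_ms <- function(rec) {
  length(rec$samples) / rec$sampling_rate * 1000
}

#' Time axis of a recording (ms post-stimulus)
#' @param rec An `sep_recording`.
#' @export
sep_time_axis <- function(rec) {
  rec$t0_offset + (seq_along(rec$samples) - 1) / rec$sampling_rate * 1000
}

#' @export
print.sep_recording <- function(x, ...) {
  cat("<sep_recording>", x$subject_id, sprintf("[%s]", x$condition), "\n")
  cat(sprintf("  %d samples @ %g Hz (%.1f ms), t0 = %g ms\n",
              length(x$samples), x$sampling_rate, sep_duration_ms(x),
              x$t0_offset))
  if (!is.null(x$bandpass))
    cat(sprintf("  bandpass %g-%g Hz, ", x$bandpass[1], x$bandpass[2]))
  cat(sprintf("%d sweeps averaged\n", x$n_sweeps_averaged))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".meta")

#' Read an averaged SEP recording
#'
#' The delimited-text dialect is one voltage value (uV) per line with a
#' key-value sidecar `<path>.meta` holding `sampling_rate`, `t0_offset_ms`,
#' `n_sweeps_averaged`, `bandpass_low`, `bandpass_high`, `condition` and
#' `subject_id` (one `key: value` pair per line). Missing optional metadata
#' defaults to unknown/0/none with a warning; a missing or non-positive
#' `sampling_rate` is an error. EDF files are read through the first signal
#' channel, which must be recorded in uV or mV (mV is converted to uV).
#'
#' @param path Path to the recording file.
#' @param format `"delimited_text"` or `"edf"`.
#' @return An `sep_recording`.
#' @export
read_sep_recording <- function(path, format = c("delimited_text", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "edf") return(read_sep_edf(path))

  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  samples <- suppressWarnings(as.numeric(raw))
  if (anyNA(samples))
    stop("format error: unparsable numbers in ", path)

  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    for (line in readLines(sp, warn = FALSE)) {
      line <- trimws(line)
      if (!nzchar(line) || startsWith(line, "#")) next
      kv <- regmatches(line, regexpr("[:=]", line), invert = TRUE)[[1]]
      if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
    }
  } else {
    warning("no metadata sidecar found at ", sp)
  }

  num <- function(key) if (is.null(meta[[key]])) NULL else as.numeric(meta[[key]])
  sampling_rate <- num("sampling_rate")
  if (is.null(sampling_rate))
    stop("validation error: sidecar must provide sampling_rate")
  if (is.na(sampling_rate) || sampling_rate <= 0)
    stop("validation error: sampling_rate must be positive")

  missing_keys <- setdiff(
    c("t0_offset_ms", "n_sweeps_averaged", "bandpass_low", "bandpass_high",
      "condition", "subject_id"),
    names(meta))
  if (length(missing_keys))
    warning("sidecar missing optional keys (defaulted): ",
            paste(missing_keys, collapse = ", "))

  bandpass <- NULL
  if (!is.null(meta$bandpass_low) && !is.null(meta$bandpass_high))
    bandpass <- c(num("bandpass_low"), num("bandpass_high"))

  sep_recording(
    samples = samples,
    sampling_rate = sampling_rate,
    t0_offset = if (is.null(meta$t0_offset_ms)) 0 else num("t0_offset_ms"),
    n_sweeps_averaged = if (is.null(meta$n_sweeps_averaged)) 0
                        else as.integer(num("n_sweeps_averaged")),
    bandpass = bandpass,
    condition = if (is.null(meta$condition)) "unknown" else meta$condition,
    subject_id = if (is.null(meta$subject_id)) "unknown" else meta$subject_id
  )
}

#' Write an averaged SEP recording as delimited text plus sidecar
#'
#' Values are written with 17 significant digits so that a read/write
#' round trip reproduces the samples exactly.
#'
#' @param rec An `sep_recording`.
#' @param path Output path; the sidecar is written to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_sep_recording <- function(rec, path) {
  validate_sep_recording(rec)
  writeLines(sprintf("%.17g", rec$samples), path)
  meta <- c(
    sprintf("sampling_rate: %.17g", rec$sampling_rate),
    sprintf("t0_offset_ms: %.17g", rec$t0_offset),
    sprintf("n_sweeps_averaged: %d", rec$n_sweeps_averaged),
    if (!is.null(rec$bandpass)) c(
      sprintf("bandpass_low: %.17g", rec$bandpass[1]),
      sprintf("bandpass_high: %.17g", rec$bandpass[2])),
    sprintf("condition: %s", rec$condition),
    sprintf("subject_id: %s", rec$subject_id)
  )
  writeLines(meta, sidecar_path(path))
  invisible(path)
}

# Minimal EDF (European Data Format) reader: 256-byte fixed-width ASCII main
# header, 256 bytes per signal header block, then int16 little-endian data
# records. Reads the first signal channel only.
read_sep_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  hdr(8)                      # version
  hdr(80); hdr(80)            # patient / recording id
  hdr(8); hdr(8)              # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                     # reserved
  n_records <- as.integer(hdr(8))
  record_duration <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("format error: EDF header has no signals")
  field <- function(nchars) vapply(seq_len(ns), function(i) hdr(nchars), "")
  labels <- field(16)
  field(80)                   # transducer
  dims <- field(8)            # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                   # prefiltering
  n_samp <- as.integer(field(8))
  field(32)                   # reserved
  seek(con, header_bytes)

  dim1 <- toupper(dims[1])
  scale_to_uv <- if (dim1 %in% c("UV", "µV", "MICROV")) 1
                 else if (dim1 == "MV") 1000
                 else stop("validation error: first EDF channel must be uV or mV, got '",
                           dims[1], "'")
  gain <- (phys_max[1] - phys_min[1]) / (dig_max[1] - dig_min[1])
  offset <- phys_min[1] - gain * dig_min[1]

  samples <- numeric(0)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- readBin(con, "integer", n = n_samp[s], size = 2,
                   signed = TRUE, endian = "little")
      if (s == 1) samples <- c(samples, x)
    }
  }
  rate <- n_samp[1] / record_duration
  sep_recording(samples = (samples * gain + offset) * scale_to_uv,
                sampling_rate = rate,
                subject_id = if (nzchar(labels[1])) labels[1] else "unknown")
}
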