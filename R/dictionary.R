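#' Dictionary configuration for Gabor matching pursuit
#'
#' The dictionary enumerates Gabor atoms g(t) = K exp(-pi ((t-u)/s)^2)
#' cos(2 pi f (t-u) + phi) on a deterministic grid: dyadic scales
#' s = 2^j samples, translations u in steps of `translation_step_factor *
#' s/2` samples, and frequencies f in steps of `frequency_step_factor *
#' sampling_rate / (2 s)` from 0 Hz up to (but excluding) Nyquist. K
#' normalizes each discretized atom to unit L2 norm; phase is never
#' enumerated — it is resolved in closed form per projection.
#'
#' @param scale_min_samples Smallest dyadic scale in samples (default 2).
#' @param translation_step_factor Multiplier on the u step s/2 (default 1).
#' @param frequency_step_factor Multiplier on the f step rate/(2s)
#'   (default 1).
#' @return A list of class `mp_dictionary_config`.
#' @export
mp_dictionary_config <- function(scale_min_samples = 2,
                                 translation_step_factor = 1,
                                 frequency_step_factor = 1) {
  stopifnot(scale_min_samples >= 2, translation_step_factor > 0,
            frequency_step_factor > 0)
  structure(list(scale_min_samples = scale_min_samples,
                 translation_step_factor = translation_step_factor,
                 frequency_step_factor = frequency_step_factor),
            class = "mp_dictionary_config")
}

#' Enumerate the Gabor dictionary parameter grid
#'
#' Deterministic enumeration of (u, s, f) triples for a signal of
#' `n_samples` samples: dyadic scales `s = 2^j` for
#' `j = log2(scale_min_samples) .. floor(log2(n_samples)) - 1`, translation
#' and frequency grids as described in [mp_dictionary_config()]. Rows are
#' sorted by (u, f, s) so that ties in the pursuit's argmax resolve to the
#' smallest u, then f, then s.
#'
#' @param n_samples Signal length in samples (>= 16).
#' @param sampling_rate Sampling rate in Hz.
#' @param config An `mp_dictionary_config`.
#' @return A data.frame with columns `u` (samples), `s` (samples), `f` (Hz).
#' @export
build_gabor_dictionary <- function(n_samples, sampling_rate,
                                   config = mp_dictionary_config()) {
  if (n_samples < 16) stop("n_samples must be >= 16")
  j_min <- ceiling(log2(config$scale_min_samples))
  j_max <- floor(log2(n_samples)) - 1
  if (j_max < j_min) stop("configuration error: empty scale grid")
  nyq <- sampling_rate / 2
  grids <- lapply(2^(j_min:j_max), function(s) {
    ustep <- max(1, config$translation_step_factor * s / 2)
    fstep <- config$frequency_step_factor * sampling_rate / (2 * s)
    u <- seq(0, n_samples - 1, by = ustep)
    f <- seq(0, nyq - fstep / 2, by = fstep)
    f <- f[f < nyq]
    expand.grid(u = u, s = s, f = f, KEEP.OUT.ATTRS = FALSE)
  })
  params <- do.call(rbind, grids)
  if (nrow(params) == 0) stop("configuration error: empty dictionary grid")
  params <- params[order(params$u, params$f, params$s), , drop = FALSE]
  rownames(params) <- NULL
  params
}

# Raw (unnormalized) Gaussian envelope and quadrature carriers for one atom.
# t, u, s in samples; f in Hz.
gabor_env_carriers <- function(n_samples, sampling_rate, u, s, f) {
  d <- (seq_len(n_samples) - 1) - u
  env <- exp(-pi * (d / s)^2)
  theta <- 2 * pi * f * d / sampling_rate
  list(c = env * cos(theta), s = env * sin(theta))
}

#' Materialize a unit-norm Gabor atom waveform
#'
#' @param n_samples Signal length in samples.
#' @param sampling_rate Hz.
#' @param u Center time in samples.
#' @param s Scale in samples.
#' @param f Frequency in Hz.
#' @param phase Phase in radians.
#' @return Numeric vector of length `n_samples` with unit L2 norm.
#' @export
gabor_atom_waveform <- function(n_samples, sampling_rate, u, s, f, phase = 0) {
  d <- (seq_len(n_samples) - 1) - u
  w <- exp(-pi * (d / s)^2) * cos(2 * pi * f * d / sampling_rate + phase)
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-300) stop("degenerate atom (zero norm)")
  w / nrm
}

# Materialized dictionary: unit-norm cosine/sine atom matrices (atoms x n)
# plus the per-atom quadrature inner product x = <gc, gs> used for
# closed-form optimal-phase projections. Cached per (n, rate, config).
.dict_cache <- new.env(parent = emptyenv())

materialize_gabor_dictionary <- function(n_samples, sampling_rate,
                                         config = mp_dictionary_config()) {
  key <- paste(n_samples, sampling_rate,
               config$scale_min_samples, config$translation_step_factor,
               config$frequency_step_factor, sep = "|")
  hit <- .dict_cache[[key]]
  if (!is.null(hit)) return(hit)

  params <- build_gabor_dictionary(n_samples, sampling_rate, config)
  m <- nrow(params)
  t_idx <- seq_len(n_samples) - 1
  Gc <- matrix(0, m, n_samples)
  Gs <- matrix(0, m, n_samples)
  # fill per (s, u) block: envelope shared across the f grid
  blocks <- split(seq_len(m), list(params$s, params$u), drop = TRUE)
  for (rows in blocks) {
    u <- params$u[rows[1]]; s <- params$s[rows[1]]
    d <- t_idx - u
    env <- exp(-pi * (d / s)^2)
    ang <- 2 * pi * d / sampling_rate
    for (i in rows) {
      th <- ang * params$f[i]
      Gc[i, ] <- env * cos(th)
      Gs[i, ] <- env * sin(th)
    }
  }
  nc <- sqrt(rowSums(Gc^2))
  ns <- sqrt(rowSums(Gs^2))
  sin_ok <- ns > 1e-12
  Gc <- Gc / nc
  Gs[sin_ok, ] <- Gs[sin_ok, , drop = FALSE] / ns[sin_ok]
  x <- rowSums(Gc * Gs)
  denom <- 1 - x^2
  usable_quad <- sin_ok & denom > 1e-10
  dict <- list(params = params, Gc = Gc, Gs = Gs, x = x, denom = denom,
               quad = usable_quad, n_samples = n_samples,
               sampling_rate = sampling_rate, config = config)
  # cache only typical analysis sizes to bound memory
  if (length(.dict_cache) < 4) .dict_cache[[key]] <- dict
  dict
}

#' Drop cached materialized dictionaries
#' @export
clear_dictionary_cache <- function() {
  rm(list = ls(.dict_cache), envir = .dict_cache)
  invisible(NULL)
}
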