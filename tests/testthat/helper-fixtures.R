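# Shared fixtures, built in code. Small signal sizes (n = 128-256) keep the
# dictionary-based tests fast; the packaged epoch (n = 1000) is only used
# where end-to-end behavior is the point.

test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(test_cache[[key]])) test_cache[[key]] <- force(expr)
  test_cache[[key]]
}

make_sine_recording <- function(freq, n = 1000, rate = 10000, amp = 1,
                                condition = "unknown") {
  t <- (seq_len(n) - 1) / rate
  sep_recording(amp * sin(2 * pi * freq * t), rate, condition = condition)
}

# a small recording whose content is a known sum of Gabor atoms
planted_recording <- function(atoms, n = 256, rate = 2000) {
  w <- numeric(n)
  for (a in atoms)
    w <- w + a$coef * gabor_atom_waveform(n, rate, a$u, a$s, a$f,
                                          if (is.null(a$phase)) 0 else a$phase)
  sep_recording(w, rate)
}

# construct an sep_tfc_cat directly (no decomposition needed)
toy_cat <- function(subject_id, condition, high, middle = NULL, low = NULL) {
  tfc_df <- function(m, rel) {
    if (is.null(m)) return(data.frame(rank = integer(0), time_ms = numeric(0),
                                      frequency_hz = numeric(0),
                                      power_uv2 = numeric(0),
                                      relative_energy = numeric(0)))
    data.frame(rank = seq_len(nrow(m)) + 1, time_ms = m[, 1],
               frequency_hz = m[, 2], power_uv2 = rep(1, nrow(m)),
               relative_energy = rel)
  }
  structure(list(
    high = data.frame(rank = 1, time_ms = high[1], frequency_hz = high[2],
                      power_uv2 = high[3], relative_energy = 0.8),
    middle = tfc_df(middle, if (is.null(middle)) numeric(0)
                    else rep(0.05, nrow(middle))),
    low = tfc_df(low, if (is.null(low)) numeric(0)
                 else rep(0.005, nrow(low))),
    threshold = 0.02, subject_id = subject_id, condition = condition),
    class = "sep_tfc_cat")
}

# A synthetic cohort of categorized recordings with class structure loosely
# following the calibrated condition models, drawn directly in feature space
# so classifier tests need no decomposition.
toy_study_cats <- function(n_normal = 12, n_c4 = 6, n_c5 = 6, n_c6 = 6,
                           seed = 1, sep = 1) {
  set.seed(seed)
  out <- list()
  add <- function(cond, high_mu, mids, lows) {
    id <- sprintf("%s_%02d", cond, sum(vapply(out, function(cc)
      cc$condition == cond, logical(1))) + 1)
    mid_m <- if (length(mids)) do.call(rbind, lapply(mids, function(mu)
      mu + stats::rnorm(2, 0, c(2, 8) / sep))) else NULL
    low_m <- if (length(lows)) do.call(rbind, lapply(lows, function(mu)
      mu + stats::rnorm(2, 0, c(2, 8) / sep))) else NULL
    out[[length(out) + 1]] <<- toy_cat(id, cond,
      high_mu + stats::rnorm(3, 0, c(2, 5, 8) / sep), mid_m, low_m)
  }
  for (i in seq_len(n_normal))
    add("normal", c(13, 51, 50), list(c(20, 120)), list(c(30, 160)))
  for (i in seq_len(n_c4))
    add("C4", c(15, 35, 28), list(c(13, 159), c(37, 34)), list(c(26, 66)))
  for (i in seq_len(n_c5))
    add("C5", c(15, 35, 28), list(c(17, 105)), list(c(28, 75)))
  for (i in seq_len(n_c6))
    add("C6", c(15, 35, 28), list(c(11, 78)), list(c(18, 100)))
  out
}
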