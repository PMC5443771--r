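# Small-signal pursuit tests: n = 256 at 2 kHz gives a ~4k-atom dictionary,
# n = 128 a ~1.7k-atom one (small enough for exhaustive oracles).

test_that("dictionary enumeration follows the construction rules", {
  params <- build_gabor_dictionary(1024, 10000)
  expect_true(all(params$s %in% 2^(1:9)))
  expect_true(max(params$s) <= 512)
  expect_true(all(params$f >= 0 & params$f < 5000))
  expect_true(all(params$u >= 0 & params$u <= 1023))

  # independent counting oracle: enumerate the step rules directly
  expected <- 0
  for (j in 1:9) {
    s <- 2^j
    n_u <- length(seq(0, 1023, by = s / 2))
    n_f <- sum(seq(0, 5000, by = 10000 / (2 * s)) < 5000)
    expected <- expected + n_u * n_f
  }
  expect_identical(nrow(params), as.integer(expected))

  expect_error(build_gabor_dictionary(8, 1000), "n_samples")
  expect_error(build_gabor_dictionary(64, 1000,
    mp_dictionary_config(scale_min_samples = 64)), "empty")
})

test_that("materialized atoms have unit norm within 1e-9", {
  dict <- septfc:::materialize_gabor_dictionary(128, 1000)
  norms <- sqrt(rowSums(dict$Gc^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  sin_norms <- sqrt(rowSums(dict$Gs[dict$quad, ]^2))
  expect_lt(max(abs(sin_norms - 1)), 1e-9)
  # gabor_atom_waveform obeys the same contract at arbitrary parameters
  w <- gabor_atom_waveform(256, 2000, u = 71.3, s = 37.1, f = 133.7,
                           phase = 2.1)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
})

test_that("pursuit recovers a planted dictionary element", {
  dict <- septfc:::materialize_gabor_dictionary(256, 2000)
  p <- dict$params[2000, ]
  rec <- planted_recording(list(list(u = p$u, s = p$s, f = p$f, coef = 7.1)),
                          n = 256, rate = 2000)
  mp <- mp_decompose(rec, max_atoms = 3)
  expect_gte(mp$tfcs$relative_energy[1], 0.99)
  ustep_ms <- (p$s / 2) / 2000 * 1000
  fstep <- 2000 / (2 * p$s)
  expect_lt(abs(mp$tfcs$time_ms[1] - p$u / 2000 * 1000), ustep_ms)
  expect_lt(abs(mp$tfcs$frequency_hz[1] - p$f), fstep)
  expect_equal(mp$tfcs$power_uv2[1], 7.1^2, tolerance = 0.01)
})

test_that("energy bookkeeping is exact and residuals decrease", {
  set.seed(5)
  for (i in 1:4) {
    rec <- sep_recording(rnorm(128), 1000)
    mp <- mp_decompose(rec, max_atoms = 12, residual_energy_stop = 0.01)
    expect_lt(abs(mp$signal_energy -
                    (sum(mp$tfcs$power_uv2) + mp$residual_energy)),
              1e-6 * mp$signal_energy)
    expect_true(all(mp$tfcs$relative_energy >= 0 &
                      mp$tfcs$relative_energy <= 1))
    expect_lte(sum(mp$tfcs$relative_energy), 1 + 1e-9)
    # rank ordering non-increasing in power
    expect_true(all(diff(mp$tfcs$power_uv2) <= 1e-12))
  }
  # residual strictly non-increasing across iterations
  rec <- sep_recording(rnorm(128), 1000)
  res <- vapply(1:6, function(k)
    mp_decompose(rec, max_atoms = k, residual_energy_stop = 0)$residual_energy,
    0)
  expect_true(all(diff(res) <= 1e-9))
})

test_that("each greedy step is exhaustively optimal on a reduced dictionary", {
  set.seed(9)
  rec <- sep_recording(rnorm(128), 1000)
  dict <- septfc:::materialize_gabor_dictionary(128, 1000)
  expect_lt(nrow(dict$params), 5000)
  r <- rec$samples
  for (step in 1:3) {
    mp <- mp_decompose(sep_recording(r, 1000), max_atoms = 1,
                       residual_energy_stop = 0, refine = FALSE)
    chosen <- mp$tfcs$power_uv2[1]
    # independent oracle: per-atom optimal-phase energy via least squares
    best <- 0
    for (i in seq_len(nrow(dict$params))) {
      gc <- dict$Gc[i, ]
      X <- if (dict$quad[i]) cbind(gc, dict$Gs[i, ]) else cbind(gc)
      fit <- lm.fit(X, r)
      best <- max(best, sum(r^2) - sum(fit$residuals^2))
    }
    expect_gte(chosen + 1e-9, best)
    r <- r - mp_reconstruct(mp$atoms, 128, 1000)
  }
})

test_that("pursuit is deterministic", {
  set.seed(21)
  rec <- sep_recording(rnorm(256), 2000)
  a <- mp_decompose(rec, max_atoms = 6)
  b <- mp_decompose(rec, max_atoms = 6)
  expect_identical(a$atoms, b$atoms)
})

test_that("two well-separated planted atoms are both recovered", {
  ok <- 0
  for (seed in 1:5) {
    set.seed(seed)
    s <- 32
    a1 <- list(u = 60, s = s, f = 250 + runif(1, -5, 5), coef = 3)
    a2 <- list(u = 190, s = s, f = 250 + runif(1, -5, 5), coef = 2)  # du = 4s
    rec <- planted_recording(list(a1, a2), n = 256, rate = 2000)
    mp <- mp_decompose(rec, max_atoms = 2)
    ustep_ms <- (s / 2) / 2000 * 1000
    fstep <- 2000 / (2 * s)
    hit <- function(a) any(abs(mp$tfcs$time_ms - a$u / 2) <= ustep_ms &
                             abs(mp$tfcs$frequency_hz - a$f) <= fstep)
    if (hit(a1) && hit(a2)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("degenerate inputs are handled", {
  expect_identical(nrow(mp_decompose(sep_recording(numeric(128), 1000))$tfcs),
                   0L)
  bad <- sep_recording(rnorm(128), 1000)
  bad$samples[5] <- NaN
  expect_error(mp_decompose(bad), "NaN|finite")
})

test_that("reconstruction inverts the decomposition", {
  empty <- mp_decompose(sep_recording(numeric(128), 1000))
  expect_identical(mp_reconstruct(empty$atoms, 128, 1000), numeric(128))

  # single atom: reconstruct equals coefficient times the generator output
  atoms <- data.frame(u_samples = 100, s_samples = 32, center_time_ms = 50,
                      scale_ms = 16, frequency_hz = 120, phase = 1.1,
                      coefficient = 4.2)
  expect_equal(mp_reconstruct(atoms, 256, 2000),
               4.2 * gabor_atom_waveform(256, 2000, 100, 32, 120, 1.1))

  set.seed(3)
  rec <- planted_recording(list(
    list(u = 60, s = 32, f = 150, coef = 5, phase = 0.4),
    list(u = 180, s = 32, f = 420, coef = 2, phase = 2.2)), n = 256,
    rate = 2000)
  mp <- mp_decompose(rec, max_atoms = 20, residual_energy_stop = 1e-4)
  err <- sqrt(sum((mp_reconstruct(mp$atoms, 256, 2000) - rec$samples)^2) /
                sum(rec$samples^2))
  expect_lte(err, 1e-2)
})

test_that("time-frequency map concentrates atom energy correctly", {
  atoms <- list(list(u = 500, s = 128, f = 80, coef = 3))
  rec <- planted_recording(atoms, n = 1000, rate = 10000)
  mp <- mp_decompose(rec, max_atoms = 1)
  map <- time_frequency_map(mp, time_grid = seq(0, 100, 0.5),
                            freq_grid = seq(0, 500, 2))
  idx <- which(map$values == max(map$values), arr.ind = TRUE)
  expect_lt(abs(map$time_grid[idx[1]] - 50), 0.5 + 1e-9)
  expect_lt(abs(map$freq_grid[idx[2]] - 80), 2 + 1e-9)
  # numeric integration oracle: map mass vs summed power within 2%
  mass <- sum(map$values) * 0.5 * 2
  expect_lt(abs(mass - sum(mp$tfcs$power_uv2)), 0.02 * sum(mp$tfcs$power_uv2))
  # a grid that misses the atom warns
  expect_warning(time_frequency_map(mp, seq(0, 20, 0.5), seq(0, 40, 2)),
                 "mass")
})
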