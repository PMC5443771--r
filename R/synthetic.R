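#' Load the calibrated per-condition generative models
#'
#' Condition models describe, for each condition (normal, sham, C4, C5,
#' C6), the moments of the dominant high-energy component in time (ms),
#' frequency (Hz) and power (uV^2), plus a set of time-frequency regions in
#' which middle- and low-energy components occur with given rates. The
#' packaged defaults are calibrated to the reference rat study; the file is
#' plain YAML so the models can be edited without touching code.
#'
#' @param path Path to a YAML model file; default is the packaged one.
#' @return A validated list of class `sep_condition_models`.
#' @export
sep_condition_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "condition_models.yaml", package = "septfc")
  cfg <- yaml::read_yaml(path)
  # resolve condition aliases (e.g. sham: normal)
  for (cond in names(cfg$conditions)) {
    if (is.character(cfg$conditions[[cond]]))
      cfg$conditions[[cond]] <- cfg$conditions[[cfg$conditions[[cond]]]]
  }
  validate_condition_models(structure(cfg, class = "sep_condition_models"))
}

validate_condition_models <- function(cfg) {
  stopifnot(cfg$epoch$n_samples >= 16, cfg$epoch$sampling_rate > 0,
            cfg$noise$per_sweep_sd_uv >= 0, cfg$noise$n_sweeps >= 1)
  for (cond in names(cfg$conditions)) {
    cm <- cfg$conditions[[cond]]
    h <- cm$high
    if (h$time_sd <= 0 || h$freq_sd <= 0 || h$power_sd <= 0)
      stop("condition ", cond, ": all high-component SDs must be > 0")
    if (h$power_mean <= 0)
      stop("condition ", cond, ": high power mean must be > 0")
    groups <- list()
    for (rg in cm$regions) {
      if (rg$time_sd <= 0 || rg$freq_sd <= 0)
        stop("condition ", cond, ": region SDs must be > 0")
      if (rg$occurrence < 0 || rg$occurrence > 1)
        stop("condition ", cond, ": occurrence must be in [0, 1]")
      if (!rg$band %in% c("middle", "low"))
        stop("condition ", cond, ": region band must be middle or low")
      if (!is.null(rg$exclusive_group))
        groups[[rg$exclusive_group]] <-
          c(groups[[rg$exclusive_group]], rg$occurrence)
    }
    for (g in names(groups)) {
      if (sum(groups[[g]]) > 1 + 1e-9)
        stop("condition ", cond, ": exclusive group '", g,
             "' occurrence rates sum above 1")
    }
  }
  cfg
}

#' Study design for synthetic SEP generation
#'
#' Default group sizes mirror the reference study: 36 normal recordings
#' (the pre-surgery trace of each compressed animal), 12 per injury group
#' (C4, C5, C6) and 12 sham. The 72 normal + injury recordings form the
#' classification dataset; sham is generated for the sham-vs-normal
#' consistency analysis and excluded from classification.
#'
#' @param group_sizes Named integer vector of recordings per condition.
#' @param master_seed Integer master seed; a fixed seed makes the whole
#'   dataset reproducible.
#' @param models An `sep_condition_models` object.
#' @return A list of class `sep_study_design`.
#' @export
sep_study_design <- function(group_sizes = c(normal = 36, C4 = 12, C5 = 12,
                                             C6 = 12, sham = 12),
                             master_seed = 1,
                             models = sep_condition_models()) {
  stopifnot(all(group_sizes > 0), all(names(group_sizes) %in% sep_conditions()))
  structure(list(group_sizes = group_sizes,
                 master_seed = as.integer(master_seed),
                 models = models),
            class = "sep_study_design")
}

# draw from N(mean, sd) restricted to (lo, hi) by resampling, preserving
# the in-range shape (no boundary atom that clipping would create)
rtrunc_norm <- function(mean, sd, lo = -Inf, hi = Inf) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  stop("truncated-normal sampling failed: interval (", lo, ", ", hi,
       ") has negligible mass under N(", mean, ", ", sd, ")")
}

#' Sample planted component parameters for one condition
#'
#' Draws the dominant component from the condition's high moments
#' (truncated Gaussians keeping time inside the epoch, frequency inside
#' (0, Nyquist) and power positive) and, per region, plants a component at
#' the region's moments with a relative energy drawn uniformly from its
#' band (middle 2-10%, low 0.2-1%). Regions sharing an `exclusive_group`
#' are drawn as a per-subject categorical assignment; others are
#' independent Bernoulli(occurrence). Phases are uniform. Uses the current
#' RNG state: seed before calling for reproducibility.
#'
#' @param models An `sep_condition_models`.
#' @param condition Condition name.
#' @return A data.frame with columns `band`, `time_ms`, `scale_ms`,
#'   `freq_hz`, `phase`, `power_uv2` (high only) and `rel_energy`
#'   (middle/low only).
#' @export
sample_components <- function(models, condition) {
  cm <- models$conditions[[condition]]
  if (is.null(cm)) stop("no model for condition '", condition, "'")
  epoch_ms <- models$epoch$n_samples / models$epoch$sampling_rate * 1000
  nyq <- models$epoch$sampling_rate / 2
  f_lo <- models$epoch$bandpass[1]   # no component below the acquisition band
  bands <- models$energy_bands
  # envelope length tied to the drawn frequency: spectral SD = f / resolution
  region_scale <- function(f) {
    q <- models$scales$region_freq_resolution
    min(models$scales$region_max_ms,
        max(models$scales$region_min_ms, 1000 * q / (2 * sqrt(pi) * f)))
  }
  h <- cm$high
  rows <- list(data.frame(
    band = "high",
    time_ms = rtrunc_norm(h$time_mean, h$time_sd, 0, epoch_ms),
    scale_ms = models$scales$high_ms,
    freq_hz = rtrunc_norm(h$freq_mean, h$freq_sd, f_lo, nyq),
    phase = stats::runif(1, 0, 2 * pi),
    power_uv2 = rtrunc_norm(h$power_mean, h$power_sd, 0, Inf),
    rel_energy = NA_real_))

  regions <- cm$regions
  groups <- vapply(regions, function(rg)
    if (is.null(rg$exclusive_group)) NA_character_ else rg$exclusive_group, "")
  planted <- logical(length(regions))
  # mutually exclusive region sets: one categorical draw per group
  for (g in unique(groups[!is.na(groups)])) {
    members <- which(groups == g)
    probs <- vapply(regions[members], function(rg) rg$occurrence, 0)
    pick <- sample.int(length(members) + 1, 1,
                       prob = c(probs, max(0, 1 - sum(probs))))
    if (pick <= length(members)) planted[members[pick]] <- TRUE
  }
  planted[is.na(groups)] <-
    stats::runif(sum(is.na(groups))) < vapply(regions[is.na(groups)],
                                              function(rg) rg$occurrence, 0)
  for (i in which(planted)) {
    rg <- regions[[i]]
    band_range <- bands[[rg$band]]
    f <- rtrunc_norm(rg$freq_mean, rg$freq_sd, f_lo, nyq)
    rows[[length(rows) + 1]] <- data.frame(
      band = rg$band,
      time_ms = rtrunc_norm(rg$time_mean, rg$time_sd, 0, epoch_ms),
      scale_ms = if (is.null(rg$scale_ms)) region_scale(f) else rg$scale_ms,
      freq_hz = f,
      phase = stats::runif(1, 0, 2 * pi),
      power_uv2 = NA_real_,
      rel_energy = stats::runif(1, band_range[1], band_range[2]))
  }
  do.call(rbind, rows)
}

#' Synthesize one averaged SEP recording
#'
#' Builds the waveform as the sum of the planted Gabor components plus an
#' averaged broadband noise floor (equivalent in distribution to averaging
#' `n_sweeps` independent Gaussian-noise sweeps, then band-limiting to the
#' acquisition band). Component powers are resolved so that each planted
#' middle/low component holds its drawn share of the total trace energy:
#' with high power P, expected noise energy E_n and drawn relative energies
#' r_i, the total energy is E = (P + E_n) / (1 - sum(r_i)) and each
#' component gets power r_i * E.
#'
#' @param models An `sep_condition_models`.
#' @param condition Condition name (sham uses the normal model).
#' @param subject_id Subject identifier.
#' @param seed Integer seed for this recording's draws.
#' @return An `sep_recording` with a `planted` attribute holding the
#'   sampled component table.
#' @export
synthesize_recording <- function(models, condition, subject_id,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ep <- models$epoch
  n <- ep$n_samples; rate <- ep$sampling_rate
  comps <- sample_components(models, condition)

  noise_sd <- models$noise$per_sweep_sd_uv
  n_sweeps <- models$noise$n_sweeps
  band <- as.numeric(ep$bandpass)
  band_frac <- (band[2] - band[1]) / (rate / 2)
  e_noise <- n * noise_sd^2 / n_sweeps * band_frac

  r_sum <- sum(comps$rel_energy, na.rm = TRUE)
  if (r_sum >= 0.9)
    stop("drawn relative energies sum to >= 90%; model is inconsistent")
  p_high <- comps$power_uv2[comps$band == "high"]
  e_total <- (p_high + e_noise) / (1 - r_sum)
  comps$power_uv2[is.na(comps$power_uv2)] <-
    comps$rel_energy[is.na(comps$power_uv2)] * e_total

  wave <- numeric(n)
  for (i in seq_len(nrow(comps))) {
    wave <- wave + sqrt(comps$power_uv2[i]) *
      gabor_atom_waveform(n, rate,
                          u = (comps$time_ms[i] - ep$t0_offset_ms) / 1000 * rate,
                          s = comps$scale_ms[i] / 1000 * rate,
                          f = comps$freq_hz[i], phase = comps$phase[i])
  }
  if (noise_sd > 0) {
    noise <- stats::rnorm(n, 0, noise_sd / sqrt(n_sweeps))
    wave <- wave + bandpass_series(noise, rate, band[1], band[2])
  }
  rec <- sep_recording(samples = wave, sampling_rate = rate,
                       t0_offset = ep$t0_offset_ms,
                       n_sweeps_averaged = n_sweeps, bandpass = band,
                       condition = condition, subject_id = subject_id)
  attr(rec, "planted") <- comps
  rec
}

#' Generate a full synthetic SEP study
#'
#' One recording per synthetic subject, per the design's group sizes;
#' subject ids are unique and per-subject seeds are drawn deterministically
#' from the master seed, so a fixed master seed reproduces the dataset
#' exactly.
#'
#' @param design An `sep_study_design`.
#' @return An object of class `sep_study`: list(recordings, manifest,
#'   design) where `manifest` has columns subject_id, condition, seed.
#' @export
generate_sep_study <- function(design) {
  stopifnot(inherits(design, "sep_study_design"))
  set.seed(design$master_seed)
  total <- sum(design$group_sizes)
  seeds <- sample.int(.Machine$integer.max - 1, total)
  manifest <- data.frame(
    subject_id = unlist(lapply(names(design$group_sizes), function(cond)
      sprintf("%s_%02d", cond, seq_len(design$group_sizes[[cond]])))),
    condition = rep(names(design$group_sizes), design$group_sizes),
    seed = seeds, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(total), function(i)
    synthesize_recording(design$models, manifest$condition[i],
                         manifest$subject_id[i], manifest$seed[i]))
  names(recordings) <- manifest$subject_id
  structure(list(recordings = recordings, manifest = manifest,
                 design = design),
            class = "sep_study")
}

#' @export
print.sep_study <- function(x, ...) {
  cat("<sep_study>", length(x$recordings), "recordings\n")
  print(table(x$manifest$condition))
  invisible(x)
}

#' Write a synthetic study to disk as delimited text + sidecars
#'
#' @param study An `sep_study`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (also written as `manifest.csv`),
#'   invisibly.
#' @export
write_sep_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in study$recordings)
    write_sep_recording(rec, file.path(dir, paste0(rec$subject_id, ".txt")))
  manifest <- study$manifest
  manifest$file <- paste0(manifest$subject_id, ".txt")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a study directory written by [write_sep_study()]
#'
#' @param dir Directory containing `manifest.csv` and recording files.
#' @return An `sep_study` (without a design element).
#' @export
read_sep_study <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(mf)), function(i)
    read_sep_recording(file.path(dir, mf$file[i])))
  names(recordings) <- mf$subject_id
  structure(list(recordings = recordings, manifest = mf, design = NULL),
            class = "sep_study")
}
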