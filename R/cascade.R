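#' Stage-I feature vector of a categorized recording
#'
#' The high-energy TFC's (time, frequency, power): the coordinates in which
#' normal and injured responses occupy distinct regions. Middle/low TFCs do
#' not enter this vector.
#'
#' @param cat An `sep_tfc_cat`.
#' @return A named numeric 3-vector (time_ms, frequency_hz, power_uv2).
#' @export
features_stage_I <- function(cat) {
  c(time_ms = cat$high$time_ms, frequency_hz = cat$high$frequency_hz,
    power_uv2 = cat$high$power_uv2)
}

balanced_weights <- function(y) {
  tab <- table(y)
  w <- as.numeric(length(y) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

#' Fit one RBF-kernel sub-classifier
#'
#' Soft-margin support vector machine with radial basis kernel at (C,
#' gamma). Features are z-scored with training-set statistics stored in the
#' fit (time, frequency and power are on incommensurate scales and the RBF
#' kernel is scale-sensitive). Class weighting inversely proportional to
#' class frequency is applied when `class_weighting = "balanced"`.
#'
#' @param x Numeric feature matrix (one row per training point).
#' @param y Factor of two class labels.
#' @param cost,gamma SVM regularization and kernel-width parameters.
#' @param class_weighting `"balanced"` or `"none"`.
#' @return A list of class `sep_svm_stage`: the fitted svm, the scaler and
#'   the class levels.
#' @export
fit_stage <- function(x, y, cost = 1, gamma = 1,
                      class_weighting = c("balanced", "none")) {
  class_weighting <- match.arg(class_weighting)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("validation error: training set must contain two classes")
  if (min(table(y)) < 2)
    stop("validation error: need >= 2 training points per class")
  x <- as.matrix(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  wts <- if (class_weighting == "balanced") balanced_weights(y) else NULL
  model <- e1071::svm(x = xs, y = y, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE, class.weights = wts)
  structure(list(model = model, center = center, scale = scale_,
                 levels = levels(y), cost = cost, gamma = gamma,
                 class_weighting = class_weighting),
            class = "sep_svm_stage")
}

#' Predict with a fitted sub-classifier
#'
#' @param fit An `sep_svm_stage`.
#' @param x New feature matrix.
#' @return A list: `label` (factor) and `decision` (signed decision values;
#'   positive favors the first training level).
#' @export
predict_stage <- function(fit, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  p <- predict(fit$model, xs, decision.values = TRUE)
  dv <- as.numeric(attr(p, "decision.values"))
  # align sign: positive decision value favors levels[1]
  first <- colnames(attr(p, "decision.values"))[1]
  if (!startsWith(first, fit$levels[1])) dv <- -dv
  list(label = p, decision = dv)
}

# majority vote over per-TFC predictions for one recording; count ties are
# resolved by the class with the larger mean decision value, an exact
# decision-value tie by `tie_default`.
vote_label <- function(labels, decisions, levels, tie_default) {
  n1 <- sum(labels == levels[1]); n2 <- sum(labels == levels[2])
  if (n1 > n2) return(levels[1])
  if (n2 > n1) return(levels[2])
  md <- mean(decisions)
  if (md > 0) levels[1] else if (md < 0) levels[2] else tie_default
}

# ---- internal cascade data preparation -------------------------------------

#' Default time-frequency analysis window for per-TFC classification
#'
#' Middle- and low-energy TFC points are classified within the window the
#' distribution analysis operates in: 0-50 ms and 10-250 Hz (the lower
#' frequency edge is the acquisition highpass; components reported below
#' it are filtering artifacts, not physiology). Points outside the window
#' are ignored by stages II/III.
#'
#' @return Named numeric vector (time_lo, time_hi, freq_lo, freq_hi).
#' @export
sep_analysis_window <- function() {
  c(time_lo = 0, time_hi = 50, freq_lo = 10, freq_hi = 250)
}

cascade_point_cloud <- function(cats, category, window) {
  rows <- lapply(seq_along(cats), function(i) {
    tab <- cats[[i]][[category]]
    if (nrow(tab) == 0) return(NULL)
    keep <- tab$time_ms >= window[1] & tab$time_ms <= window[2] &
      tab$frequency_hz >= window[3] & tab$frequency_hz <= window[4]
    if (!any(keep)) return(NULL)
    cbind(rec = i, time_ms = tab$time_ms[keep],
          frequency_hz = tab$frequency_hz[keep])
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, 3,
                              dimnames = list(NULL, c("rec", "time_ms",
                                                      "frequency_hz")))
  m
}

prepare_cascade_data <- function(cats, window = sep_analysis_window()) {
  stopifnot(length(cats) >= 2)
  cond <- vapply(cats, function(cc) cc$condition, "")
  x1 <- t(vapply(cats, features_stage_I, numeric(3)))
  y1 <- factor(ifelse(cond == "normal", "normal", "injured"),
               levels = c("normal", "injured"))
  list(cond = cond, x1 = x1, y1 = y1,
       mid = cascade_point_cloud(cats, "middle", window),
       low = cascade_point_cloud(cats, "low", window),
       y2 = factor(ifelse(cond == "C5", "C5", "C4C6"),
                   levels = c("C5", "C4C6")),
       y3 = factor(cond, levels = c("C4", "C6")))
}

stage_train_idx <- function(prep, stage, rec_idx) {
  switch(stage,
         I = rec_idx,
         II = rec_idx[prep$cond[rec_idx] %in% c("C4", "C5", "C6")],
         III = rec_idx[prep$cond[rec_idx] %in% c("C4", "C6")])
}

fit_cascade_stage <- function(prep, stage, rec_idx, cost, gamma,
                              class_weighting) {
  recs <- stage_train_idx(prep, stage, rec_idx)
  if (stage == "I")
    return(fit_stage(prep$x1[recs, , drop = FALSE], prep$y1[recs],
                     cost, gamma, class_weighting))
  src <- if (stage == "II") prep$mid else prep$low
  yrec <- if (stage == "II") prep$y2 else prep$y3
  rows <- src[, "rec"] %in% recs
  fit_stage(src[rows, c("time_ms", "frequency_hz"), drop = FALSE],
            yrec[src[rows, "rec"]], cost, gamma, class_weighting)
}

# recording-level stage prediction for stages II/III: vote over the
# recording's per-TFC predictions; an empty TFC set falls back to the
# stage's documented default.
predict_stage_recordings <- function(fit, prep, stage, rec_idx) {
  src <- if (stage == "II") prep$mid else prep$low
  fallback <- if (stage == "II") "C4C6" else "C4"
  tie_default <- if (stage == "II") "C4C6" else "C6"
  out <- character(length(rec_idx))
  rows_all <- src[, "rec"] %in% rec_idx
  if (any(rows_all)) {
    p <- predict_stage(fit, src[rows_all, c("time_ms", "frequency_hz"),
                                drop = FALSE])
    rec_of_row <- src[rows_all, "rec"]
  }
  for (k in seq_along(rec_idx)) {
    if (!any(rows_all) || !any(rec_of_row == rec_idx[k])) {
      out[k] <- fallback
      next
    }
    sel <- rec_of_row == rec_idx[k]
    out[k] <- vote_label(as.character(p$label[sel]), p$decision[sel],
                         fit$levels, tie_default)
  }
  out
}

# ---- the cascade model ------------------------------------------------------

#' Fit the three-stage SEP injury-level cascade
#'
#' The central fitting function: trains Classifier I (normal vs injured, on
#' the high-energy TFC's time/frequency/power), Classifier II (C5 vs pooled
#' C4/C6, on per-TFC middle-energy time-frequency points) and Classifier
#' III (C4 vs C6, on low-energy points) as RBF-kernel support vector
#' machines. Stage II and III are trained on individual TFC points labeled
#' by their recording's group; at prediction time a recording's label is
#' the majority vote over its per-TFC predictions.
#'
#' @param cats A list of `sep_tfc_cat` objects with conditions in
#'   normal/C4/C5/C6 (sham recordings are excluded upstream).
#' @param params Named list with entries `I`, `II`, `III`, each
#'   `c(log2C, log2gamma)`. The defaults are the optima reported for the
#'   reference rat dataset; use [cross_validate_cascade()] to re-tune.
#' @param class_weighting Passed to [fit_stage()].
#' @return An object of class `sep_cascade`.
#' @seealso [predict.sep_cascade()], [cross_validate_cascade()]
#' @export
fit_sep_cascade <- function(cats,
                            params = list(I = c(1, -12), II = c(2, 6),
                                          III = c(8, 2)),
                            class_weighting = "balanced",
                            analysis_window = sep_analysis_window()) {
  prep <- prepare_cascade_data(cats, analysis_window)
  all_idx <- seq_along(cats)
  stages <- lapply(c(I = "I", II = "II", III = "III"), function(st)
    fit_cascade_stage(prep, st, all_idx, cost = 2^params[[st]][1],
                      gamma = 2^params[[st]][2],
                      class_weighting = class_weighting))
  structure(list(stages = stages, params = params,
                 class_weighting = class_weighting,
                 threshold = cats[[1]]$threshold,
                 analysis_window = analysis_window,
                 n_train = length(cats)),
            class = "sep_cascade")
}

#' @export
print.sep_cascade <- function(x, ...) {
  cat("<sep_cascade> three-stage RBF-SVM cascade\n")
  for (st in c("I", "II", "III"))
    cat(sprintf("  Classifier %-3s (log2C, log2gamma) = (%g, %g)\n", st,
                x$params[[st]][1], x$params[[st]][2]))
  cat(sprintf("  trained on %d recordings, relative-energy threshold %.1f%%\n",
              x$n_train, 100 * x$threshold))
  invisible(x)
}

#' @export
summary.sep_cascade <- function(object, ...) print(object)

#' Predict injury-level labels with a fitted cascade
#'
#' Stage I sees the high-energy TFC vector; a recording predicted normal
#' stops there. Otherwise stage II votes over the recording's middle-energy
#' TFCs (an empty middle set falls through to stage III with a warning); a
#' C5 verdict stops. Otherwise stage III votes over the low-energy TFCs (an
#' empty low set yields C4, the first class of that branch).
#'
#' @param object An `sep_cascade`.
#' @param cats A list of `sep_tfc_cat` objects (or a single one).
#' @param ... Unused.
#' @return A factor with levels normal/C4/C5/C6.
#' @export
predict.sep_cascade <- function(object, cats, ...) {
  if (inherits(cats, "sep_tfc_cat")) cats <- list(cats)
  prep <- prepare_cascade_data_predict(cats, object$analysis_window)
  idx <- seq_along(cats)
  out <- character(length(cats))
  p1 <- predict_stage(object$stages$I, prep$x1)
  is_normal <- as.character(p1$label) == "normal"
  out[is_normal] <- "normal"
  todo <- idx[!is_normal]
  if (length(todo)) {
    has_mid <- vapply(todo, function(i)
      any(prep$mid[, "rec"] == i), logical(1))
    if (any(!has_mid))
      warning(sum(!has_mid),
              " recording(s) without middle-energy TFCs fell through to stage III")
    with_mid <- todo[has_mid]
    if (length(with_mid)) {
      p2 <- predict_stage_recordings(object$stages$II, prep, "II", with_mid)
      out[with_mid[p2 == "C5"]] <- "C5"
    }
    stage3 <- c(todo[!has_mid],
                if (length(with_mid)) with_mid[p2 != "C5"])
    if (length(stage3))
      out[stage3] <- predict_stage_recordings(object$stages$III, prep,
                                              "III", stage3)
  }
  factor(out, levels = c("normal", "C4", "C5", "C6"))
}

# prediction-time variant: no labels required
prepare_cascade_data_predict <- function(cats, window = sep_analysis_window()) {
  x1 <- t(vapply(cats, features_stage_I, numeric(3)))
  list(x1 = x1,
       mid = cascade_point_cloud(cats, "middle", window),
       low = cascade_point_cloud(cats, "low", window))
}
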