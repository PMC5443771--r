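#' Random k-fold partitions for repeated cross-validation
#'
#' Partitions n recordings into `folds` subsets per run. When n is not a
#' multiple of `folds` the larger subsets (size base+1) are assigned to
#' fold positions chosen uniformly at random, so for n = 72 and 10 folds
#' each run yields eight subsets of 7 and two of 8, with every recording
#' tested exactly once per run.
#'
#' @param n Number of recordings.
#' @param runs Number of independent repartitions.
#' @param folds Folds per run.
#' @param seed Integer seed (set once for all runs).
#' @return A list of `runs` lists, each containing `folds` integer vectors
#'   of test indices.
#' @export
make_cv_partitions <- function(n, runs = 10, folds = 10, seed = 1) {
  stopifnot(n >= folds)
  set.seed(seed)
  base <- n %/% folds
  extra <- n %% folds
  lapply(seq_len(runs), function(run) {
    sizes <- rep(base, folds)
    if (extra > 0) sizes[sample.int(folds, extra)] <- base + 1
    perm <- sample.int(n)
    split(perm, rep(seq_len(folds), sizes))
  })
}

# signed decision values aligned so positive favors `lev1`
svm_decision <- function(model, x, lev1) {
  p <- predict(model, x, decision.values = TRUE)
  dv <- as.numeric(attr(p, "decision.values"))
  if (!startsWith(colnames(attr(p, "decision.values"))[1], lev1)) dv <- -dv
  list(label = as.character(p), decision = dv)
}

# same quantities computed straight from the support vectors; equivalent to
# predict(..., decision.values = TRUE) for a radial-kernel binary svm fit
# with scale = FALSE, but without the prediction-method overhead (the grid
# search calls this tens of thousands of times)
svm_decision_fast <- function(model, x, lev1) {
  sv <- model$SV
  d2 <- outer(rowSums(x^2), rep(1, nrow(sv))) +
    outer(rep(1, nrow(x)), rowSums(sv^2)) - 2 * tcrossprod(x, sv)
  dv <- as.vector(exp(-model$gamma * d2) %*% model$coefs) - model$rho
  lib_levels <- model$levels[model$labels]
  lab <- ifelse(dv > 0, lib_levels[1], lib_levels[2])
  if (lib_levels[1] != lev1) dv <- -dv
  list(label = lab, decision = dv)
}

# ---- per-fold cached stage data --------------------------------------------

# scaled train/test structures for one stage and one (train, test) split;
# NULL when the stage has no trainable data in this split
build_stage_fold <- function(prep, stage, train_idx, test_idx,
                             class_weighting) {
  recs_tr <- stage_train_idx(prep, stage, train_idx)
  recs_te <- stage_train_idx(prep, stage, test_idx)
  if (stage == "I") {
    xtr <- prep$x1[recs_tr, , drop = FALSE]; ytr <- droplevels(prep$y1[recs_tr])
    xte <- prep$x1[recs_te, , drop = FALSE]
    yte <- as.character(prep$y1[recs_te])
  } else {
    src <- if (stage == "II") prep$mid else prep$low
    yrec <- if (stage == "II") prep$y2 else prep$y3
    rows <- src[, "rec"] %in% recs_tr
    xtr <- src[rows, c("time_ms", "frequency_hz"), drop = FALSE]
    ytr <- droplevels(yrec[src[rows, "rec"]])
    rows_te <- src[, "rec"] %in% recs_te
    xte <- src[rows_te, c("time_ms", "frequency_hz"), drop = FALSE]
    yte <- as.character(yrec[recs_te])
  }
  if (length(recs_te) == 0 || nlevels(ytr) < 2 || min(table(ytr)) < 2)
    return(NULL)
  center <- colMeans(xtr)
  scl <- apply(xtr, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  zs <- function(m) sweep(sweep(m, 2, center), 2, scl, "/")
  list(stage = stage,
       xtr = zs(xtr), ytr = ytr,
       wts = if (class_weighting == "balanced") balanced_weights(ytr) else NULL,
       xte = zs(xte), yte = yte,
       te_recs = recs_te,
       te_rec_of_row = if (stage == "I") recs_te else
         (if (nrow(xte)) src[src[, "rec"] %in% recs_te, "rec"] else integer(0)),
       center = center, scale = scl)
}

# recording-level accuracy of one (cost, gamma) pair on one cached fold
stage_fold_accuracy <- function(fd, cost, gamma) {
  m <- e1071::svm(x = fd$xtr, y = fd$ytr, kernel = "radial", cost = cost,
                  gamma = gamma, scale = FALSE, class.weights = fd$wts, fitted = FALSE,
                  tolerance = 0.01)
  lev <- levels(fd$ytr)
  if (fd$stage == "I") {
    pr <- svm_decision_fast(m, fd$xte, lev[1])$label
    return(mean(pr == fd$yte))
  }
  fallback <- if (fd$stage == "II") "C4C6" else "C4"
  tie_default <- if (fd$stage == "II") "C4C6" else "C6"
  pred <- rep(fallback, length(fd$te_recs))
  if (nrow(fd$xte) > 0) {
    d <- svm_decision_fast(m, fd$xte, lev[1])
    for (k in seq_along(fd$te_recs)) {
      sel <- fd$te_rec_of_row == fd$te_recs[k]
      if (any(sel))
        pred[k] <- vote_label(d$label[sel], d$decision[sel], lev, tie_default)
    }
  }
  mean(pred == fd$yte)
}

# exhaustive integer-log2 grid evaluation over cached folds; first strict
# maximum wins, so ties resolve to the smallest log2C, then log2gamma
grid_search_folds <- function(fold_data, log2C, log2gamma) {
  surface <- matrix(NA_real_, length(log2C), length(log2gamma),
                    dimnames = list(log2C, log2gamma))
  best <- c(NA, NA); best_acc <- -Inf
  fold_data <- Filter(Negate(is.null), fold_data)
  if (length(fold_data) == 0) stop("no evaluable folds for grid search")
  for (i in seq_along(log2C)) {
    cost <- 2^log2C[i]
    for (j in seq_along(log2gamma)) {
      gamma <- 2^log2gamma[j]
      acc <- mean(vapply(fold_data, stage_fold_accuracy, 0,
                         cost = cost, gamma = gamma))
      surface[i, j] <- acc
      if (acc > best_acc) { best_acc <- acc; best <- c(log2C[i], log2gamma[j]) }
    }
  }
  list(best = best, accuracy = best_acc, surface = surface)
}

#' Exhaustive log2 grid search for one SVM task
#'
#' Evaluates every integer (log2 C, log2 gamma) pair in the given ranges by
#' k-fold cross-validated accuracy and returns the maximizing pair; ties
#' resolve to the smallest log2 C, then the smallest log2 gamma.
#'
#' @param x Feature matrix; @param y class factor.
#' @param folds A list of test-index vectors, or an integer k (random
#'   k-fold split drawn with `seed`).
#' @param log2C,log2gamma Integer grids (defaults -2:20 and -14:10, i.e.
#'   575 candidate pairs).
#' @param class_weighting Passed to the per-fold fits.
#' @param seed Seed used only when `folds` is an integer.
#' @return list(best = c(log2C, log2gamma), accuracy, surface matrix).
#' @export
svm_grid_search <- function(x, y, folds = 10, log2C = -2:20,
                            log2gamma = -14:10,
                            class_weighting = "balanced", seed = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  if (is.numeric(folds) && length(folds) == 1)
    folds <- make_cv_partitions(nrow(x), runs = 1, folds = folds,
                                seed = seed)[[1]]
  prep <- list(x1 = x, y1 = y)   # reuse the stage-I fold builder
  fold_data <- lapply(folds, function(te)
    build_stage_fold(prep, "I", setdiff(seq_len(nrow(x)), te), te,
                     class_weighting))
  grid_search_folds(fold_data, log2C, log2gamma)
}

# cascade prediction on prep-level data with already-fitted stage models
cascade_predict_indices <- function(models, prep, test_idx) {
  out <- character(length(test_idx))
  p1 <- predict_stage(models$I, prep$x1[test_idx, , drop = FALSE])
  is_normal <- as.character(p1$label) == "normal"
  out[is_normal] <- "normal"
  todo <- test_idx[!is_normal]
  pos <- which(!is_normal)
  if (length(todo)) {
    has_mid <- vapply(todo, function(i) any(prep$mid[, "rec"] == i),
                      logical(1))
    with_mid <- todo[has_mid]
    if (length(with_mid)) {
      p2 <- predict_stage_recordings(models$II, prep, "II", with_mid)
      out[pos[has_mid][p2 == "C5"]] <- "C5"
    }
    s3_idx <- c(todo[!has_mid], if (length(with_mid)) with_mid[p2 != "C5"])
    s3_pos <- c(pos[!has_mid], if (length(with_mid)) pos[has_mid][p2 != "C5"])
    if (length(s3_idx))
      out[s3_pos] <- predict_stage_recordings(models$III, prep, "III", s3_idx)
  }
  out
}

#' Repeated 10-fold cross-validation of the cascade with grid search
#'
#' Implements the evaluation protocol of the reference analysis: `runs`
#' random `folds`-fold partitions of the dataset; for each stage, an
#' exhaustive integer-log2 grid search in which each (C, gamma) pair is
#' scored by its mean cross-validated recording-level accuracy (the
#' hyperparameter surface is averaged over the first `search_runs` runs to
#' bound compute; the chosen pair's accuracies are then computed over all
#' runs x folds). Finally the full cascade, refitted per fold at the
#' chosen pairs, is evaluated for four-class accuracy.
#'
#' Stage accuracies are per-stage tasks: Classifier I on all recordings
#' (normal vs injured), Classifier II on the injury recordings (C5 vs
#' C4/C6, majority vote over middle-energy TFC points; a recording without
#' middle TFCs counts as a C4/C6-side prediction), Classifier III on the
#' C4 and C6 recordings (vote over low-energy points; no low TFCs defaults
#' to C4).
#'
#' @param cats List of `sep_tfc_cat` objects.
#' @param runs,folds Repetitions and folds (default 10 x 10).
#' @param seed Integer seed controlling the partitions.
#' @param log2C,log2gamma Integer search grids.
#' @param search_runs How many of the runs the grid-search surface is
#'   averaged over (default 2).
#' @param class_weighting Passed to the per-fold fits.
#' @param analysis_window Time-frequency window for stage II/III points
#'   (default [sep_analysis_window()]).
#' @param expected_composition Named vector of required recordings per
#'   condition (default the 36/12/12/12 reference design); `NULL` skips
#'   the check.
#' @return An object of class `sep_cv`.
#' @export
cross_validate_cascade <- function(cats, runs = 10, folds = 10, seed = 1,
                                   log2C = -2:20, log2gamma = -14:10,
                                   search_runs = 2,
                                   class_weighting = "balanced",
                                   analysis_window = sep_analysis_window(),
                                   expected_composition = c(normal = 36,
                                                            C4 = 12, C5 = 12,
                                                            C6 = 12)) {
  prep <- prepare_cascade_data(cats, analysis_window)
  if (!is.null(expected_composition)) {
    have <- table(factor(prep$cond, levels = names(expected_composition)))
    if (!all(have == expected_composition))
      stop("validation error: dataset composition is ",
           paste(have, collapse = "/"), ", expected ",
           paste(expected_composition, collapse = "/"))
  }
  n <- length(cats)
  partitions <- make_cv_partitions(n, runs, folds, seed)
  search_runs <- min(search_runs, runs)

  fold_cache <- lapply(c(I = "I", II = "II", III = "III"), function(st)
    lapply(seq_len(runs), function(run)
      lapply(partitions[[run]], function(te)
        build_stage_fold(prep, st, setdiff(seq_len(n), te), te,
                         class_weighting))))

  stage_results <- lapply(c(I = "I", II = "II", III = "III"), function(st) {
    search_folds <- unlist(fold_cache[[st]][seq_len(search_runs)],
                           recursive = FALSE)
    gs <- grid_search_folds(search_folds, log2C, log2gamma)
    cost <- 2^gs$best[1]; gamma <- 2^gs$best[2]
    acc_runs <- vapply(seq_len(runs), function(run) {
      fds <- Filter(Negate(is.null), fold_cache[[st]][[run]])
      mean(vapply(fds, stage_fold_accuracy, 0, cost = cost, gamma = gamma))
    }, 0)
    # gamma-sensitivity guard: accuracy drop > 10 pp at log2gamma +/- 1
    gi <- match(gs$best[2], log2gamma)
    ci <- match(gs$best[1], log2C)
    nb <- gs$surface[ci, c(max(1, gi - 1), min(ncol(gs$surface), gi + 1))]
    list(best = gs$best, surface = gs$surface,
         per_run = acc_runs, mean = mean(acc_runs), sd = stats::sd(acc_runs),
         gamma_sensitive = any(gs$accuracy - nb > 0.10))
  })

  params <- lapply(stage_results, `[[`, "best")
  overall_folds <- matrix(NA_real_, runs, folds)
  pred_run1 <- character(n)
  for (run in seq_len(runs)) {
    for (k in seq_len(folds)) {
      te <- partitions[[run]][[k]]
      tr <- setdiff(seq_len(n), te)
      models <- lapply(c(I = "I", II = "II", III = "III"), function(st)
        fit_cascade_stage(prep, st, tr, cost = 2^params[[st]][1],
                          gamma = 2^params[[st]][2],
                          class_weighting = class_weighting))
      pred <- cascade_predict_indices(models, prep, te)
      overall_folds[run, k] <- mean(pred == prep$cond[te])
      if (run == 1) pred_run1[te] <- pred
    }
  }
  per_run <- rowMeans(overall_folds)
  lev <- c("normal", "C4", "C5", "C6")
  confusion <- table(truth = factor(prep$cond, lev),
                     predicted = factor(pred_run1, lev))
  structure(list(
    stages = stage_results, params = params,
    overall = list(fold_accuracies = overall_folds, per_run = per_run,
                   mean = mean(per_run), sd = stats::sd(per_run),
                   min = min(per_run), max = max(per_run)),
    predictions_run1 = pred_run1, confusion = confusion,
    partitions = partitions,
    settings = list(runs = runs, folds = folds, seed = seed,
                    search_runs = search_runs, log2C = range(log2C),
                    log2gamma = range(log2gamma),
                    class_weighting = class_weighting)),
    class = "sep_cv")
}

#' @export
print.sep_cv <- function(x, ...) {
  cat(sprintf("<sep_cv> %d x %d-fold cross-validation (seed %d)\n",
              x$settings$runs, x$settings$folds, x$settings$seed))
  for (st in c("I", "II", "III")) {
    s <- x$stages[[st]]
    cat(sprintf("  Classifier %-3s acc %.1f%% +/- %.1f  (log2C, log2gamma) = (%g, %g)%s\n",
                st, 100 * s$mean, 100 * s$sd, s$best[1], s$best[2],
                if (isTRUE(s$gamma_sensitive)) "  [gamma-sensitive]" else ""))
  }
  o <- x$overall
  cat(sprintf("  Overall cascade  %.1f%% +/- %.1f (range %.1f-%.1f)\n",
              100 * o$mean, 100 * o$sd, 100 * o$min, 100 * o$max))
  invisible(x)
}

#' Export a cross-validation report
#'
#' @param cv An `sep_cv`.
#' @param csv_path Optional path for the per-(run, fold) accuracy CSV.
#' @param json_path Optional path for the JSON summary.
#' @return The summary list, invisibly.
#' @export
cv_report <- function(cv, csv_path = NULL, json_path = NULL) {
  of <- cv$overall$fold_accuracies
  long <- data.frame(run = rep(seq_len(nrow(of)), ncol(of)),
                     fold = rep(seq_len(ncol(of)), each = nrow(of)),
                     accuracy = as.vector(of))
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE)
  summary <- list(
    overall = cv$overall[c("mean", "sd", "min", "max")],
    stages = lapply(cv$stages, function(s)
      list(mean = s$mean, sd = s$sd, log2C = s$best[1], log2gamma = s$best[2],
           gamma_sensitive = s$gamma_sensitive)),
    settings = cv$settings)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(summary)
}
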