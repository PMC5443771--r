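test_that("stage-I features are the high TFC coordinates only", {
  cc <- toy_cat("s", "normal", c(12.9, 50.7, 50.4),
                middle = rbind(c(20, 120)), low = rbind(c(30, 160)))
  expect_equal(unname(features_stage_I(cc)), c(12.9, 50.7, 50.4))
  zero <- toy_cat("z", "C4", c(0, 0, 0))
  expect_equal(unname(features_stage_I(zero)), c(0, 0, 0))
  # permuting middle/low rows leaves the vector unchanged
  cc2 <- toy_cat("s", "normal", c(12.9, 50.7, 50.4),
                 middle = rbind(c(99, 99), c(20, 120)),
                 low = rbind(c(1, 1)))
  expect_equal(features_stage_I(cc2), features_stage_I(cc))
})

sep_gaussians <- function(n = 40, d = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * 2), ncol = 2),
             matrix(rnorm(n / 2 * 2, mean = d), ncol = 2))
  list(x = x, y = factor(rep(c("a", "b"), each = n / 2)))
}

test_that("sub-classifier fitting separates well-separated classes", {
  g <- sep_gaussians()
  fit <- fit_stage(g$x, g$y, cost = 1, gamma = 0.5)
  p <- predict_stage(fit, g$x)
  expect_equal(mean(p$label == g$y), 1)
  # deterministic decision values
  fit2 <- fit_stage(g$x, g$y, cost = 1, gamma = 0.5)
  expect_identical(predict_stage(fit2, g$x)$decision, p$decision)
  expect_error(fit_stage(g$x, factor(rep("a", 40))), "two classes")
  expect_error(fit_stage(g$x[1:3, ], factor(c("a", "a", "b"))), ">= 2")
})

test_that("predictions agree with an independent kernel machine", {
  skip_if_not_installed("kernlab")
  set.seed(6)
  n <- 120
  x <- matrix(rnorm(n * 2), ncol = 2)
  y <- factor(ifelse(x[, 1] + 0.7 * x[, 2] + rnorm(n, 0, 0.4) > 0, "a", "b"))
  xt <- matrix(rnorm(100 * 2), ncol = 2)
  fit <- fit_stage(x, y, cost = 2, gamma = 0.5, class_weighting = "none")
  p1 <- predict_stage(fit, xt)$label
  xs <- scale(x)
  k <- kernlab::ksvm(xs, y, kernel = "rbfdot",
                     kpar = list(sigma = 0.5), C = 2, scaled = FALSE)
  xts <- scale(xt, center = attr(xs, "scaled:center"),
               scale = attr(xs, "scaled:scale"))
  p2 <- kernlab::predict(k, xts)
  expect_gte(mean(as.character(p1) == as.character(p2)), 0.98)
})

test_that("fast decision values equal the standard prediction path", {
  g <- sep_gaussians(n = 60, d = 2, seed = 3)
  fit <- fit_stage(g$x, g$y, cost = 4, gamma = 0.3)
  xt <- matrix(rnorm(40), ncol = 2)
  xts <- sweep(sweep(xt, 2, fit$center), 2, fit$scale, "/")
  ref <- septfc:::svm_decision(fit$model, xts, "a")
  fast <- septfc:::svm_decision_fast(fit$model, xts, "a")
  expect_equal(fast$decision, ref$decision, tolerance = 1e-10)
  expect_identical(fast$label, ref$label)
})

test_that("grid search is an exhaustive argmax with lexicographic ties", {
  set.seed(12)
  n <- 30
  x <- matrix(rnorm(n * 2), ncol = 2)
  y <- factor(ifelse(x[, 1] + rnorm(n, 0, 1.2) > 0, "a", "b"))
  folds <- make_cv_partitions(n, 1, 5, seed = 2)[[1]]
  log2C <- c(-2, 0, 3, 8); log2gamma <- c(-6, -2, 0, 3)
  gs <- svm_grid_search(x, y, folds, log2C, log2gamma)
  # exhaustive re-evaluation oracle, independent of grid_search internals
  oracle <- matrix(NA_real_, length(log2C), length(log2gamma))
  for (i in seq_along(log2C)) for (j in seq_along(log2gamma)) {
    accs <- vapply(folds, function(te) {
      tr <- setdiff(seq_len(n), te)
      fit <- fit_stage(x[tr, ], y[tr], cost = 2^log2C[i],
                       gamma = 2^log2gamma[j])
      mean(predict_stage(fit, x[te, , drop = FALSE])$label == y[te])
    }, 0)
    oracle[i, j] <- mean(accs)
  }
  expect_equal(unname(gs$surface), oracle, tolerance = 1e-12)
  expect_gte(gs$accuracy + 1e-12, max(oracle))
  # tie-break: first (smallest log2C, then log2gamma) among the argmax set
  amax <- which(oracle == max(oracle), arr.ind = TRUE)
  amax <- amax[order(amax[, 1], amax[, 2]), , drop = FALSE]
  expect_equal(gs$best, c(log2C[amax[1, 1]], log2gamma[amax[1, 2]]))
})

test_that("the default search grid spans the 23 x 25 integer lattice", {
  g <- sep_gaussians(n = 20, d = 10, seed = 5)
  gs <- svm_grid_search(g$x, g$y, folds = 2)
  expect_identical(dim(gs$surface), c(23L, 25L))
  expect_identical(sum(!is.na(gs$surface)), 575L)
})

test_that("recording votes follow majority then mean decision value", {
  lev <- c("C5", "C4C6")
  expect_equal(septfc:::vote_label(c("C5", "C5", "C4C6"), c(1, 2, -9), lev,
                                   "C4C6"), "C5")
  # tie in counts: larger mean decision value wins
  expect_equal(septfc:::vote_label(c("C5", "C4C6"), c(3, -1), lev, "C4C6"),
               "C5")
  expect_equal(septfc:::vote_label(c("C5", "C4C6"), c(1, -3), lev, "C4C6"),
               "C4C6")
  # exact decision tie falls to the stage default
  expect_equal(septfc:::vote_label(c("C5", "C4C6"), c(2, -2), lev, "C4C6"),
               "C4C6")
})

test_that("the fitted cascade predicts one label per recording", {
  cats <- toy_study_cats(seed = 7, sep = 2)
  model <- fit_sep_cascade(cats, params = list(I = c(4, -2), II = c(2, 0),
                                               III = c(2, 0)))
  expect_s3_class(model, "sep_cascade")
  pred <- predict(model, cats)
  expect_identical(length(pred), length(cats))
  expect_true(all(!is.na(pred)))
  expect_setequal(levels(pred), c("normal", "C4", "C5", "C6"))
  # strongly separated toy classes are classified correctly in-sample
  truth <- vapply(cats, function(cc) cc$condition, "")
  expect_gte(mean(as.character(pred) == truth), 0.9)
})

test_that("cascade short-circuits and falls back as documented", {
  cats <- toy_study_cats(seed = 8, sep = 2)
  model <- fit_sep_cascade(cats, params = list(I = c(4, -2), II = c(2, 0),
                                               III = c(2, 0)))
  # a clearly normal recording stops at stage I
  normal_cat <- toy_cat("n", "unknown", c(13, 51, 50))  # no middle, no low
  expect_equal(as.character(predict(model, normal_cat)), "normal")
  # injured-looking with no middle TFCs falls through to stage III (warning),
  # and with no low TFCs stage III emits C4
  injured_bare <- toy_cat("i", "unknown", c(15, 20, 10))
  expect_warning(p <- predict(model, injured_bare), "middle")
  expect_equal(as.character(p), "C4")
})

test_that("CV partitions have the stated size multiset and cover all", {
  parts <- make_cv_partitions(72, runs = 10, folds = 10, seed = 9)
  for (run in parts) {
    sizes <- sort(unname(lengths(run)))
    expect_identical(sizes, c(rep(7L, 8), rep(8L, 2)))
    expect_identical(sort(unname(unlist(run))), 1:72)
  }
  expect_identical(make_cv_partitions(72, 2, 10, seed = 1),
                   make_cv_partitions(72, 2, 10, seed = 1))
})

test_that("fold models never depend on their test recordings", {
  cats <- toy_study_cats(seed = 10)
  prep <- septfc:::prepare_cascade_data(cats)
  n <- length(cats)
  tr <- 1:20
  fd_a <- septfc:::build_stage_fold(prep, "I", tr, 21:25, "balanced")
  fd_b <- septfc:::build_stage_fold(prep, "I", tr, 26:30, "balanced")
  expect_identical(fd_a$xtr, fd_b$xtr)
  expect_identical(fd_a$ytr, fd_b$ytr)
  probe <- matrix(c(14, 40, 30), 1)
  fit <- septfc:::fit_cascade_stage(prep, "I", tr, 2, 0.1, "balanced")
  # refitting with a different test set is the same model
  fit2 <- septfc:::fit_cascade_stage(prep, "I", tr, 2, 0.1, "balanced")
  expect_identical(predict_stage(fit, probe), predict_stage(fit2, probe))
})

test_that("repeated cross-validation reports coherent accuracies", {
  cats <- toy_study_cats(n_normal = 10, n_c4 = 5, n_c5 = 5, n_c6 = 5,
                         seed = 11, sep = 1.5)
  cv <- cross_validate_cascade(cats, runs = 2, folds = 5, seed = 3,
                               log2C = c(0, 4), log2gamma = c(-4, 0),
                               search_runs = 1,
                               expected_composition = NULL)
  o <- cv$overall
  expect_equal(o$mean, mean(o$per_run))
  expect_lte(o$min, o$mean); expect_lte(o$mean, o$max)
  expect_identical(dim(o$fold_accuracies), c(2L, 5L))
  # run-1 predictions cover every recording exactly once
  expect_identical(sum(cv$confusion), length(cats))
  expect_equal(unname(rowSums(cv$confusion)),
               as.vector(table(factor(vapply(cats, function(cc) cc$condition,
                                             ""),
                                      c("normal", "C4", "C5", "C6")))))
  # composition guard
  expect_error(cross_validate_cascade(cats, runs = 1, folds = 5),
               "composition")
})

test_that("feature noise does not improve cross-validated accuracy", {
  base <- sep_gaussians(n = 60, d = 2.5, seed = 20)
  acc_at_noise <- function(noise_sd) {
    accs <- numeric(10)
    for (s in 1:10) {
      set.seed(100 + s)
      x <- base$x + matrix(rnorm(length(base$x), 0, noise_sd),
                           nrow = nrow(base$x))
      folds <- make_cv_partitions(60, 1, 5, seed = s)[[1]]
      accs[s] <- mean(vapply(folds, function(te) {
        tr <- setdiff(1:60, te)
        fit <- fit_stage(x[tr, ], base$y[tr], cost = 2, gamma = 0.5)
        mean(predict_stage(fit, x[te, , drop = FALSE])$label == base$y[te])
      }, 0))
    }
    mean(accs)
  }
  levels <- c(0, 0.5, 1, 2, 4)
  accs <- vapply(levels, acc_at_noise, 0)
  expect_true(all(diff(accs) <= 0.03))   # never rises beyond sampling noise
  expect_lt(accs[5], accs[1])            # and clearly degrades overall
})
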