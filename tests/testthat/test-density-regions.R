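pts_df <- function(t, f, id = NULL) {
  if (is.null(id))
    id <- if (length(t)) paste0("s", seq_along(t)) else character(0)
  data.frame(subject_id = id, time_ms = t, frequency_hz = f)
}

test_that("the density estimate is a unit-mass product-Gaussian KDE", {
  one <- estimate_tf_pdf(pts_df(13.2, 158.1))
  idx <- which(one$values == max(one$values), arr.ind = TRUE)
  expect_lt(abs(one$time_grid[idx[1]] - 13.2), 0.5)
  expect_lt(abs(one$freq_grid[idx[2]] - 158.1), 2)

  set.seed(14)
  pts <- pts_df(runif(40, 5, 45), runif(40, 20, 230))
  den <- estimate_tf_pdf(pts)
  expect_equal(sum(den$values) * 0.5 * 2, 1, tolerance = 1e-6)
  expect_true(all(den$values >= 0))

  expect_error(estimate_tf_pdf(pts_df(numeric(0), numeric(0))), "one point")
  expect_error(estimate_tf_pdf(pts_df(60, 100)), "cover")
  expect_error(estimate_tf_pdf(pts_df(10, 100), bandwidth = c(0, 5)),
               "bandwidth")
})

test_that("KDE values match a brute-force two-loop oracle to 1e-10", {
  set.seed(2)
  pts <- pts_df(runif(25, 5, 45), runif(25, 20, 230))
  bw <- c(1.7, 9.3)
  den <- estimate_tf_pdf(pts, bandwidth = bw)
  # independent normalization constant via full two-loop sum
  raw <- matrix(0, length(den$time_grid), length(den$freq_grid))
  for (i in seq_along(den$time_grid)) for (j in seq_along(den$freq_grid)) {
    acc <- 0
    for (k in seq_len(nrow(pts)))
      acc <- acc + dnorm(den$time_grid[i], pts$time_ms[k], bw[1]) *
        dnorm(den$freq_grid[j], pts$frequency_hz[k], bw[2])
    raw[i, j] <- acc / nrow(pts)
  }
  raw <- raw / (sum(raw) * 0.5 * 2)
  cells <- cbind(sample(length(den$time_grid), 50, TRUE),
                 sample(length(den$freq_grid), 50, TRUE))
  expect_lt(max(abs(den$values[cells] - raw[cells])), 1e-10)
})

test_that("local peak detection matches an exhaustive neighborhood scan", {
  set.seed(8)
  pts <- pts_df(c(rnorm(30, 12, 2), rnorm(30, 38, 2)),
                c(rnorm(30, 150, 10), rnorm(30, 40, 10)))
  den <- estimate_tf_pdf(pts, bandwidth = c(1.5, 8))
  peaks0 <- find_local_peaks(den, rel_threshold = 0, merge_cells = 0)
  # oracle: scan every interior cell for strict 8-neighborhood maxima
  v <- den$values
  found <- NULL
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    nb <- v[max(1, i - 1):min(nrow(v), i + 1),
            max(1, j - 1):min(ncol(v), j + 1)]
    if (v[i, j] > max(nb[nb != v[i, j]], -Inf) && sum(nb == v[i, j]) == 1)
      found <- rbind(found, c(den$time_grid[i], den$freq_grid[j], v[i, j]))
  }
  expect_equal(nrow(peaks0), nrow(found))
  expect_equal(peaks0$value, sort(found[, 3], decreasing = TRUE))

  # bimodal map: exactly 2 peaks at 80%, sorted by value
  peaks <- find_local_peaks(den, rel_threshold = 0.5)
  expect_identical(nrow(peaks), 2L)
  expect_true(all(diff(peaks$value) <= 0))
})

test_that("peak count is non-increasing in the relative threshold", {
  set.seed(19)
  pts <- pts_df(runif(60, 2, 48), runif(60, 15, 240))
  den <- estimate_tf_pdf(pts, bandwidth = c(1, 6))
  counts <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(th)
    nrow(find_local_peaks(den, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("well-separated mixture components are recovered as peaks", {
  hits <- 0
  bw <- c(1.5, 8)
  mu1 <- c(12, 150); mu2 <- c(38, 50)   # separation >> 4 bandwidths
  for (seed in 1:20) {
    set.seed(seed)
    pts <- pts_df(c(rnorm(25, mu1[1], 2), rnorm(25, mu2[1], 2)),
                  c(rnorm(25, mu1[2], 10), rnorm(25, mu2[2], 10)))
    pts <- pts[pts$time_ms > 0 & pts$time_ms < 50 &
                 pts$frequency_hz > 0 & pts$frequency_hz < 250, ]
    den <- estimate_tf_pdf(pts, bandwidth = bw)
    pk <- find_local_peaks(den, rel_threshold = 0.2)
    near <- function(mu) any(abs(pk$time_ms - mu[1]) <= 0.5 + bw[1] &
                               abs(pk$frequency_hz - mu[2]) <= 2 + bw[2])
    if (nrow(pk) == 2 && near(mu1) && near(mu2)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("region summaries report moments and subject occurrence", {
  # 14 of 24 subjects contribute a point inside the region
  inside <- pts_df(rnorm(14, 13, 2), rnorm(14, 160, 15),
                   id = paste0("r", 1:14))
  outside <- pts_df(rnorm(10, 40, 2), rnorm(10, 40, 5),
                    id = paste0("r", 15:24))
  rs <- summarize_region(rbind(inside, outside), c(0, 25), c(125, 225),
                         peak = c(13.1, 153), cohort_size = 24)
  expect_equal(rs$occurrence_rate, 14 / 24)
  expect_identical(rs$n_subjects, 14L)
  # arithmetic oracle on the filtered subset
  expect_equal(rs$time_mean, mean(inside$time_ms))
  expect_equal(rs$freq_sd, sd(inside$frequency_hz))

  same <- pts_df(rep(20, 5), rep(100, 5), id = paste0("q", 1:5))
  rs2 <- summarize_region(same, c(10, 30), c(50, 150), cohort_size = 5)
  expect_equal(rs2$time_sd, 0)
  expect_equal(rs2$occurrence_rate, 1)

  empty <- summarize_region(same, c(40, 45), c(200, 240), cohort_size = 5)
  expect_equal(empty$occurrence_rate, 0)
  expect_true(is.na(empty$time_mean))

  expect_error(summarize_region(same, c(30, 10), c(50, 150), cohort_size = 5),
               "degenerate")
  expect_error(summarize_region(same, c(10, 30), c(50, 150),
                                peak = c(35, 100), cohort_size = 5),
               "peak")
})

test_that("density mass over rectangles is monotone under nesting", {
  set.seed(4)
  pts <- pts_df(runif(40, 5, 45), runif(40, 20, 230))
  den <- estimate_tf_pdf(pts)
  mass <- function(tr, fr) {
    sel_t <- den$time_grid >= tr[1] & den$time_grid <= tr[2]
    sel_f <- den$freq_grid >= fr[1] & den$freq_grid <= fr[2]
    sum(den$values[sel_t, sel_f]) * 0.5 * 2
  }
  m_small <- mass(c(10, 20), c(50, 100))
  m_big <- mass(c(5, 30), c(25, 150))
  expect_lte(m_small, m_big)
  expect_lte(m_big, 1 + 1e-9)
})

test_that("packaged reference regions drive the group tables", {
  ref <- reference_regions()
  expect_identical(nrow(ref[ref$group == "C4" & ref$category == "low", ]), 1L)
  expect_identical(nrow(ref[ref$group == "C6" & ref$category == "low", ]), 2L)
  expect_identical(nrow(ref[ref$group == "C4C6", ]), 3L)

  cats <- toy_study_cats(n_normal = 2, n_c4 = 3, n_c5 = 3, n_c6 = 3, seed = 2)
  tab <- sep_region_tables(cats)
  expect_identical(nrow(tab[tab$group == "C4" & tab$category == "low", ]), 1L)
  expect_identical(nrow(tab[tab$group == "C6" & tab$category == "low", ]), 2L)
  expect_true(all(tab$occurrence_rate >= 0 & tab$occurrence_rate <= 1))

  # a group with no recordings yields no rows
  no_c5 <- cats[vapply(cats, function(cc) cc$condition != "C5", logical(1))]
  tab2 <- sep_region_tables(no_c5)
  expect_identical(nrow(tab2[tab2$group == "C5", ]), 0L)
})
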