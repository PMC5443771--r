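#' Categorize TFCs by relative energy
#'
#' Splits a recording's TFCs into exactly one high-energy component (the
#' largest power; ties broken by earliest time, then lowest frequency),
#' middle-energy components (relative energy strictly greater than
#' `threshold`, default 2%) and low-energy components (the rest). The
#' three sets partition the input.
#'
#' @param tfcs A non-empty TFC data.frame (columns `time_ms`,
#'   `frequency_hz`, `power_uv2`, `relative_energy`), or an `sep_mp` object.
#' @param threshold Relative-energy boundary between middle and low, in
#'   (0, 1); a component exactly at the boundary is low (the comparison is
#'   strict).
#' @param subject_id,condition Metadata tags; taken from an `sep_mp` input
#'   when not supplied.
#' @return An object of class `sep_tfc_cat` with elements `high` (1-row
#'   data.frame), `middle`, `low`, `threshold`, `subject_id`, `condition`.
#' @export
categorize_tfcs <- function(tfcs, threshold = 0.02, subject_id = NULL,
                            condition = NULL) {
  if (inherits(tfcs, "sep_mp")) {
    if (is.null(subject_id)) subject_id <- tfcs$subject_id
    if (is.null(condition)) condition <- tfcs$condition
    tfcs <- tfcs$tfcs
  }
  if (is.null(subject_id)) subject_id <- "unknown"
  if (is.null(condition)) condition <- "unknown"
  if (!is.data.frame(tfcs) || nrow(tfcs) == 0)
    stop("validation error: empty TFC list (nonzero input always yields >= 1 atom)")
  if (!(threshold > 0 && threshold < 1))
    stop("validation error: threshold must be in (0, 1)")

  ord <- order(-tfcs$power_uv2, tfcs$time_ms, tfcs$frequency_hz)
  tfcs <- tfcs[ord, , drop = FALSE]
  rownames(tfcs) <- NULL
  high <- tfcs[1, , drop = FALSE]
  rest <- tfcs[-1, , drop = FALSE]
  is_mid <- rest$relative_energy > threshold
  structure(list(high = high,
                 middle = rest[is_mid, , drop = FALSE],
                 low = rest[!is_mid, , drop = FALSE],
                 threshold = threshold,
                 subject_id = subject_id, condition = condition),
            class = "sep_tfc_cat")
}

#' @export
print.sep_tfc_cat <- function(x, ...) {
  cat("<sep_tfc_cat>", x$subject_id, sprintf("[%s]", x$condition), "\n")
  cat(sprintf("  high: %.1f ms / %.1f Hz / %.2f uV^2 (%.1f%% of signal)\n",
              x$high$time_ms, x$high$frequency_hz, x$high$power_uv2,
              100 * x$high$relative_energy))
  cat(sprintf("  %d middle (> %.1f%%), %d low\n", nrow(x$middle),
              100 * x$threshold, nrow(x$low)))
  invisible(x)
}

#' Flatten a categorized recording back to one TFC table
#'
#' @param cat An `sep_tfc_cat`.
#' @param with_category Append a `category` column (high/middle/low).
#' @return A TFC data.frame.
#' @export
flatten_tfc_cat <- function(cat, with_category = FALSE) {
  out <- rbind(cat$high, cat$middle, cat$low)
  if (with_category)
    out$category <- rep(c("high", "middle", "low"),
                        c(nrow(cat$high), nrow(cat$middle), nrow(cat$low)))
  rownames(out) <- NULL
  out
}

#' Pooled time-frequency point cloud for one TFC category
#'
#' Flattens a list of categorized recordings into a subject-tagged point
#' cloud. The high category carries power as a third coordinate (its
#' distribution lives in time-frequency-power space); middle and low are
#' two-dimensional.
#'
#' @param cats A list of `sep_tfc_cat` objects.
#' @param category `"high"`, `"middle"` or `"low"`.
#' @return A data.frame with columns `subject_id`, `condition`, `time_ms`,
#'   `frequency_hz`, and `power_uv2` for the high category.
#' @export
tfc_points <- function(cats, category = c("high", "middle", "low")) {
  if (length(cats) == 0) stop("validation error: empty group")
  if (inherits(cats, "sep_tfc_cat")) cats <- list(cats)
  category <- match.arg(category)
  rows <- lapply(cats, function(cc) {
    stopifnot(inherits(cc, "sep_tfc_cat"))
    tab <- cc[[category]]
    if (nrow(tab) == 0) return(NULL)
    out <- data.frame(subject_id = cc$subject_id, condition = cc$condition,
                      time_ms = tab$time_ms, frequency_hz = tab$frequency_hz)
    if (category == "high") out$power_uv2 <- tab$power_uv2
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), condition = character(0),
                      time_ms = numeric(0), frequency_hz = numeric(0))
    if (category == "high") out$power_uv2 <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Export categorized TFC tables
#'
#' @param cats A list of `sep_tfc_cat` objects.
#' @param path Optional CSV output path.
#' @return A data.frame: the TFC table schema plus a `category` column.
#' @export
categorized_tfc_table <- function(cats, path = NULL) {
  if (inherits(cats, "sep_tfc_cat")) cats <- list(cats)
  out <- do.call(rbind, lapply(cats, function(cc) {
    tab <- flatten_tfc_cat(cc, with_category = TRUE)
    cbind(data.frame(subject_id = cc$subject_id, condition = cc$condition),
          tab)
  }))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
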