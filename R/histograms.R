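#' Log-binned histogram of positive values, optionally per class
#'
#' Histograms with logarithmically spaced (geometric) bin edges, used to
#' amplify distributional differences at high magnitudes and for the
#' heavy-tailed segmental statistics. Bins are right-open except the
#' last, which is closed. Non-positive and out-of-range values cannot be
#' binned on a log axis and are excluded with counts recorded (relevant
#' for exactly-zero absolute skewness).
#'
#' @param values positive numeric values.
#' @param n_bins number of bins (default 100).
#' @param range `c(lo, hi)` with `0 < lo < hi`; defaults to the range of
#'   the positive values.
#' @param class optional factor/character vector splitting `values` into
#'   classes counted separately.
#' @param variable optional variable name stored with the result.
#' @return a list of class `log_histogram`: `edges` (length
#'   `n_bins + 1`), `counts` (matrix `n_bins x n_classes`), `rel_freq`
#'   (per-class relative frequencies), `n_excluded` (per class:
#'   non-positive or out of range), `variable`.
#' @export
log_histogram <- function(values, n_bins = 100, range = NULL, class = NULL,
                          variable = NA_character_) {
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  values <- as.numeric(values)
  if (is.null(class)) class <- rep("all", length(values))
  class <- as.character(class)
  stopifnot(length(class) == length(values))
  keep_finite <- is.finite(values)
  pos <- keep_finite & values > 0

  if (is.null(range)) {
    if (!any(pos)) stop("no positive values to bin", call. = FALSE)
    range <- c(min(values[pos]), max(values[pos]))
  }
  lo <- range[1]
  hi <- range[2]
  if (!(lo > 0 && hi > lo)) {
    stop("range must satisfy 0 < lo < hi", call. = FALSE)
  }
  edges <- lo * (hi / lo)^(seq(0, n_bins) / n_bins)
  edges[1] <- lo
  edges[n_bins + 1] <- hi

  classes <- sort(unique(class))
  counts <- matrix(0L, n_bins, length(classes),
    dimnames = list(NULL, classes)
  )
  n_excluded <- setNames(integer(length(classes)), classes)
  for (cl in classes) {
    v <- values[class == cl & keep_finite]
    in_range <- v >= lo & v <= hi & v > 0
    n_excluded[cl] <- sum(class == cl) - sum(in_range)
    idx <- findInterval(v[in_range], edges,
      rightmost.closed = TRUE, all.inside = FALSE
    )
    counts[, cl] <- tabulate(idx, nbins = n_bins)
  }
  tot <- colSums(counts)
  rel <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/")
  if (all(tot == 0)) {
    warning("all values outside the histogram range", call. = FALSE)
  }
  structure(
    list(
      edges = edges, counts = counts, rel_freq = rel,
      n_excluded = n_excluded, variable = variable
    ),
    class = "log_histogram"
  )
}

#' @export
print.log_histogram <- function(x, ...) {
  cat("<log_histogram> ",
    if (!is.na(x$variable)) paste0(x$variable, ", "), nrow(x$counts),
    " log bins over [", format(x$edges[1], digits = 4), ", ",
    format(x$edges[length(x$edges)], digits = 4), "]\n",
    sep = ""
  )
  for (cl in colnames(x$counts)) {
    cat(
      "  ", cl, ": ", sum(x$counts[, cl]), " counted, ",
      x$n_excluded[cl], " excluded\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
plot.log_histogram <- function(x, ...) {
  mids <- sqrt(x$edges[-1] * x$edges[-length(x$edges)])
  cls <- colnames(x$rel_freq)
  graphics::matplot(mids, x$rel_freq,
    type = "s", log = "x", lty = 1,
    xlab = x$variable %||% "value", ylab = "relative frequency", ...
  )
  graphics::legend("topright", legend = cls, lty = 1, col = seq_along(cls))
  invisible(x)
}
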