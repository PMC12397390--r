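#' Per-sample magnitude of the 3-axis acceleration vector
#'
#' Reduces a recording to the Euclidean norm
#' \eqn{m_i = \sqrt{x_i^2 + y_i^2 + z_i^2}} of the instantaneous
#' acceleration vector, removing orientation dependence. A resting sensor
#' reads approximately 1 g = 9.81 m/s^2. Because the +/-4 g range applies
#' per axis, magnitudes up to \eqn{4\sqrt{3}} g are possible.
#'
#' @param rec an [accel_recording()].
#' @param normalize divide by g = 9.81 m/s^2 to obtain the dimensionless
#'   magnitude (default `FALSE`; the analysis operates on raw m/s^2).
#' @return numeric vector of class `magnitude_series` carrying attributes
#'   `animal_id`, `condition`, `sampling_rate`, `rotation_rpm`,
#'   `normalized`.
#' @export
#' @examples
#' rec <- accel_recording(1, "sham", x = 3, y = 4, z = 0)
#' compute_magnitude(rec)[1] # 5
compute_magnitude <- function(rec, normalize = FALSE) {
  stopifnot(inherits(rec, "accel_recording"))
  m <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  if (normalize) m <- m / STANDARD_GRAVITY
  structure(m,
    animal_id = rec$animal_id, condition = rec$condition,
    sampling_rate = rec$sampling_rate, rotation_rpm = rec$rotation_rpm,
    normalized = normalize, class = "magnitude_series"
  )
}

#' Split a magnitude series into non-overlapping segments
#'
#' Cuts the series into `N = floor(I / S)` consecutive segments of equal
#' length `S` (default 1500 samples = one minute at 25 Hz); a trailing
#' remainder shorter than `S` is dropped. A full 12 h recording at 25 Hz
#' (`I` = 1,080,000) yields `N` = 720 segments.
#'
#' @param m numeric vector (typically a [compute_magnitude()] result).
#' @param S segment length in samples, at least 2.
#' @return an `S x N` numeric matrix (segments as columns) with attributes
#'   `S`, `N` and `n_dropped` (remainder samples discarded).
#' @export
segment_series <- function(m, S = 1500) {
  S <- as.integer(S)
  if (S < 2) stop("segment length S must be >= 2", call. = FALSE)
  I <- length(m)
  N <- I %/% S
  if (N < 1) {
    stop("series of length ", I, " is shorter than one segment (S = ", S,
      ")",
      call. = FALSE
    )
  }
  seg <- matrix(as.numeric(m[seq_len(N * S)]), nrow = S, ncol = N)
  structure(seg, S = S, N = N, n_dropped = I - N * S)
}

#' First four statistical moments of one segment
#'
#' Computes the estimators used throughout the pipeline: the arithmetic
#' mean, the unbiased variance with `1/(S-1)`, and skewness and kurtosis
#' whose third/fourth central moments use a `1/S` factor while the
#' denominators are powers of the *unbiased* standard deviation. This mixed
#' form is deliberate and is not interchangeable with the textbook biased
#' or bias-corrected estimators. Kurtosis is plain (non-excess; a Gaussian
#' segment gives values near 3).
#'
#' @param segment numeric vector of at least 2 samples.
#' @return named numeric vector `c(mu, var, skew, kurt)`; for a constant
#'   segment `var` is 0 and `skew`/`kurt` are `NA` (degenerate).
#' @export
#' @examples
#' segment_moments(c(1, 2, 3, 4)) # mu 2.5, var 5/3, skew 0, kurt 0.9225
segment_moments <- function(segment) {
  S <- length(segment)
  if (S < 2) stop("segment must have length >= 2", call. = FALSE)
  mu <- mean(segment)
  d <- segment - mu
  v <- sum(d^2) / (S - 1)
  if (v == 0) {
    return(c(mu = mu, var = 0, skew = NA_real_, kurt = NA_real_))
  }
  c(
    mu = mu, var = v,
    skew = (sum(d^3) / S) / sqrt(v)^3,
    kurt = (sum(d^4) / S) / sqrt(v)^4
  )
}

#' Segmental moment table for one magnitude series
#'
#' Vectorized application of [segment_moments()] to every segment of the
#' series, with g-normalized variants attached: \eqn{\tilde\mu = \mu/g},
#' \eqn{\tilde\sigma^2 = \sigma^2/g^2}, \eqn{\tilde\gamma = |\gamma|/g^3},
#' \eqn{\tilde\kappa = \kappa/g^4}. The absolute value of skewness is used
#' in the normalized column (required downstream for logarithmic binning);
#' the raw signed skewness is kept alongside.
#'
#' @param m numeric vector or [compute_magnitude()] result.
#' @param S segment length in samples (default 1500).
#' @param g gravity used for normalization (default 9.81 m/s^2).
#' @return a tibble of class `segment_stats` with columns `animal_id`,
#'   `segment`, `mu`, `var`, `skew`, `kurt`, `mu_n`, `var_n`, `skew_n`,
#'   `kurt_n` and attributes `S`, `N`, `n_dropped`, `n_degenerate`, `g`.
#'   Degenerate (constant) segments carry `NA` skewness/kurtosis.
#' @export
segment_statistics <- function(m, S = 1500, g = STANDARD_GRAVITY) {
  seg <- segment_series(m, S)
  Sn <- attr(seg, "S")
  N <- attr(seg, "N")
  mu <- colMeans(seg)
  d <- seg - rep(mu, each = Sn)
  d2 <- d * d
  v <- colSums(d2) / (Sn - 1)
  m3 <- colSums(d2 * d) / Sn
  m4 <- colSums(d2 * d2) / Sn
  degen <- v == 0
  sdev <- sqrt(v)
  skew <- ifelse(degen, NA_real_, m3 / sdev^3)
  kurt <- ifelse(degen, NA_real_, m4 / sdev^4)

  out <- tibble::tibble(
    animal_id = attr(m, "animal_id") %||% NA_integer_,
    segment = seq_len(N),
    mu = mu, var = v, skew = skew, kurt = kurt
  )
  out <- normalize_moments(out, g = g)
  structure(out,
    S = Sn, N = N, n_dropped = attr(seg, "n_dropped"),
    n_degenerate = sum(degen), g = g,
    condition = attr(m, "condition"),
    rotation_rpm = attr(m, "rotation_rpm"),
    class = c("segment_stats", class(out))
  )
}

#' Attach g-normalized moment columns
#'
#' Applies the order-matched gravity normalization literally:
#' `mu/g`, `var/g^2`, `|skew|/g^3`, `kurt/g^4`. The g^3 and g^4 powers on
#' the (already dimensionless) shape moments follow the published
#' convention for histogram display; group comparisons in this package use
#' the raw columns.
#'
#' @param stats data frame with columns `mu`, `var`, `skew`, `kurt`.
#' @param g gravity in m/s^2, > 0.
#' @return `stats` with added/overwritten columns `mu_n`, `var_n`,
#'   `skew_n`, `kurt_n`.
#' @export
normalize_moments <- function(stats, g = STANDARD_GRAVITY) {
  stopifnot(is.numeric(g), g > 0)
  stats$mu_n <- stats$mu / g
  stats$var_n <- stats$var / g^2
  stats$skew_n <- abs(stats$skew) / g^3
  stats$kurt_n <- stats$kurt / g^4
  stats
}

#' Per-animal summary of segmental statistics
#'
#' Aggregates a segmental moment table to one row per animal: the means of
#' the segmental moments over all segments, the mean absolute segmental
#' skewness (the group-comparison feature), and the overall variance of
#' the full magnitude series (the input to the MAD-median outlier rule),
#' computed with the `1/(I-1)` convention. Degenerate segments are
#' excluded from the skewness/kurtosis means and counted.
#'
#' @param stats a `segment_stats` table from [segment_statistics()].
#' @param m the magnitude series the table was computed from.
#' @return a one-row tibble with columns `animal_id`, `condition`,
#'   `rotation_rpm`, `n_segments`, `n_degenerate`, `mu_mean`, `var_mean`,
#'   `skew_mean` (signed), `abs_skew_mean`, `kurt_mean`, `overall_var`.
#' @export
dataset_summary <- function(stats, m) {
  if (!nrow(stats)) stop("empty segment statistics", call. = FALSE)
  ok <- !is.na(stats$skew)
  tibble::tibble(
    animal_id = stats$animal_id[1],
    condition = attr(stats, "condition") %||% NA_character_,
    rotation_rpm = as.numeric(attr(stats, "rotation_rpm") %||% NA_real_),
    n_segments = nrow(stats),
    n_degenerate = sum(!ok),
    mu_mean = mean(stats$mu),
    var_mean = mean(stats$var),
    skew_mean = if (any(ok)) mean(stats$skew[ok]) else NA_real_,
    abs_skew_mean = if (any(ok)) mean(abs(stats$skew[ok])) else NA_real_,
    kurt_mean = if (any(ok)) mean(stats$kurt[ok]) else NA_real_,
    overall_var = var(as.numeric(m))
  )
}

#' Directional transforms of a recording
#'
#' Supplementary per-axis views of the signal: cumulative trapezoidal
#' first and second integrals (velocity- and position-like series, no
#' drift correction) and instantaneous spherical coordinates of the
#' acceleration vector. Convention: `theta` is the polar angle from +z in
#' `[0, pi]`, `phi = atan2(y, x)` in `(-pi, pi]`. Zero-magnitude samples
#' have undefined angles and are returned as `NA`.
#'
#' @param rec an [accel_recording()].
#' @return a tibble with columns `time`, `x`, `y`, `z`, `vx`, `vy`, `vz`,
#'   `px`, `py`, `pz`, `phi`, `theta`.
#' @export
directional_transforms <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  dt <- 1 / rec$sampling_rate
  n <- length(rec$x)
  tt <- (seq_len(n) - 1) * dt
  integ <- function(v) {
    if (n < 2) {
      return(numeric(n))
    }
    as.numeric(pracma::cumtrapz(tt, v))
  }
  vx <- integ(rec$x)
  vy <- integ(rec$y)
  vz <- integ(rec$z)
  mag <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  zero <- mag == 0
  theta <- acos(pmin(1, pmax(-1, rec$z / ifelse(zero, NA, mag))))
  phi <- atan2(rec$y, rec$x)
  phi[zero & rec$x == 0 & rec$y == 0] <- NA_real_
  tibble::tibble(
    time = tt,
    x = rec$x, y = rec$y, z = rec$z,
    vx = vx, vy = vy, vz = vz,
    px = integ(vx), py = integ(vy), pz = integ(vz),
    phi = phi, theta = theta
  )
}
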