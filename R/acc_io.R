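#' Construct an acceleration recording
#'
#' Container for one animal's time-stamped 3-axis accelerometer signal plus
#' the metadata the analysis needs. All axis values are held in the internal
#' canonical unit m/s^2; `g` is taken as 9.81 m/s^2 exactly.
#'
#' @param animal_id integer animal label.
#' @param condition `"sham"` or `"PD"`.
#' @param x,y,z equal-length numeric vectors of per-axis acceleration in
#'   m/s^2.
#' @param sampling_rate sampling frequency in Hz (default 25).
#' @param start_time wall-clock time of the first sample (`POSIXct` or a
#'   string parseable as `"%Y-%m-%d %H:%M:%S"`, interpreted as UTC).
#' @param sensor_id optional sensor label.
#' @param rotation_rpm optional apomorphine-induced rotation rate (rpm).
#' @param validate run structural validation (default `TRUE`).
#'
#' @return an object of class `accel_recording`: a list with the fields
#'   above.
#' @export
#' @examples
#' rec <- accel_recording(1, "sham",
#'   x = c(0, 0), y = c(0, 0), z = c(9.81, 9.81)
#' )
#' rec$sampling_rate
accel_recording <- function(animal_id, condition, x, y, z,
                            sampling_rate = 25,
                            start_time = as.POSIXct("2024-01-01 19:45:00",
                              tz = "UTC"
                            ),
                            sensor_id = NA_character_,
                            rotation_rpm = NA_real_,
                            validate = TRUE) {
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  rec <- structure(
    list(
      animal_id = as.integer(animal_id),
      condition = as.character(condition),
      sensor_id = as.character(sensor_id),
      start_time = start_time,
      sampling_rate = as.numeric(sampling_rate),
      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
      rotation_rpm = as.numeric(rotation_rpm)
    ),
    class = "accel_recording"
  )
  if (validate) validate_recording(rec)
  rec
}

#' Validate the structural invariants of a recording
#'
#' Checks equal axis lengths, a positive sampling rate, a recognised
#' condition label, and that every axis sample lies within the configured
#' sensor range of +/-4 g (+/-39.24 m/s^2).
#'
#' @param rec an [accel_recording()].
#' @param range_g per-axis full scale in units of g (default 4).
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_recording <- function(rec, range_g = 4) {
  stopifnot(inherits(rec, "accel_recording"))
  n <- length(rec$x)
  if (length(rec$y) != n || length(rec$z) != n) {
    stop("axis length mismatch: x=", n, " y=", length(rec$y),
      " z=", length(rec$z),
      call. = FALSE
    )
  }
  if (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  if (!rec$condition %in% c("sham", "PD")) {
    stop("condition must be 'sham' or 'PD', got '", rec$condition, "'",
      call. = FALSE
    )
  }
  lim <- range_g * STANDARD_GRAVITY + 1e-9
  bad <- !is.finite(rec$x) | !is.finite(rec$y) | !is.finite(rec$z) |
    abs(rec$x) > lim | abs(rec$y) > lim | abs(rec$z) > lim
  if (any(bad)) {
    stop(
      "axis values outside +/-", range_g, " g at ", sum(bad),
      " sample(s), first at index ", which(bad)[1],
      call. = FALSE
    )
  }
  invisible(rec)
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(
    "<accel_recording> animal ", x$animal_id, " (", x$condition, ")\n",
    "  ", length(x$x), " samples @ ", x$sampling_rate, " Hz (",
    round(length(x$x) / x$sampling_rate / 3600, 2), " h), start ",
    format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"), " UTC\n",
    sep = ""
  )
  if (!is.na(x$rotation_rpm)) {
    cat("  rotation: ", x$rotation_rpm, " rpm\n", sep = "")
  }
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.csv$", ".yaml", path)
}

#' Read one recording from a CSV file with a YAML sidecar
#'
#' The on-disk dialect is one CSV per animal with header `time,x,y,z` (time
#' in seconds from the first sample) and a sidecar `<name>.yaml` holding
#' `animal_id`, `condition`, `sensor_id`, `start_time`, `sampling_rate`,
#' `unit` and optionally `rotation_rpm`. Axis values are converted to the
#' canonical unit m/s^2: `g` values are multiplied by 9.81 and raw 16-bit
#' counts by `4 * 9.81 / 32768` (the +/-4 g full-scale factor).
#'
#' Timestamps must be uniform at `1/sampling_rate` to within 1e-6 s; gaps
#' or jitter beyond that are rejected (packet loss is not modelled).
#'
#' @param path path to the CSV file.
#' @param unit unit of the stored axis values; overrides the sidecar when
#'   given. One of `"m_s2"`, `"g"`, `"raw_counts"`.
#' @return an [accel_recording()] in m/s^2.
#' @export
read_recording <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- yaml::read_yaml(sc)
  unit <- unit %||% meta$unit %||% "m_s2"
  unit <- match.arg(unit, c("m_s2", "g", "raw_counts"))

  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ","),
    error = function(e) {
      stop("parse error in '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(dt))) {
    stop("malformed header in '", path, "': expected columns time,x,y,z",
      call. = FALSE
    )
  }
  bad <- which(!complete.cases(dt[, need, with = FALSE]))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L, " of '", path, "'",
      call. = FALSE
    )
  }

  fs <- as.numeric(meta$sampling_rate %||% 25)
  tt <- dt$time
  if (length(tt) > 1) {
    expected <- tt[1] + (seq_along(tt) - 1) / fs
    if (max(abs(tt - expected)) > 1e-6) {
      stop("non-uniform timestamps in '", path,
        "' (tolerance 1e-6 s at ", fs, " Hz)",
        call. = FALSE
      )
    }
  }

  scale <- switch(unit,
    m_s2 = 1,
    g = STANDARD_GRAVITY,
    raw_counts = RAW_COUNT_SCALE
  )
  accel_recording(
    animal_id = meta$animal_id %||% NA_integer_,
    condition = meta$condition %||% "sham",
    x = dt$x * scale, y = dt$y * scale, z = dt$z * scale,
    sampling_rate = fs,
    start_time = meta$start_time %||% "2024-01-01 19:45:00",
    sensor_id = meta$sensor_id %||% NA_character_,
    rotation_rpm = as.numeric(meta$rotation_rpm %||% NA_real_)
  )
}

#' Write a recording to CSV plus YAML sidecar
#'
#' Inverse of [read_recording()]: values are stored in the requested unit
#' and the sidecar records all metadata needed to reconstruct the object.
#'
#' @param rec an [accel_recording()].
#' @param path output CSV path; the sidecar is written next to it.
#' @param unit storage unit (see [read_recording()]).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, unit = c("m_s2", "g", "raw_counts")) {
  unit <- match.arg(unit)
  validate_recording(rec)
  scale <- switch(unit,
    m_s2 = 1,
    g = STANDARD_GRAVITY,
    raw_counts = RAW_COUNT_SCALE
  )
  n <- length(rec$x)
  dt <- data.table::data.table(
    time = (seq_len(n) - 1) / rec$sampling_rate,
    x = rec$x / scale, y = rec$y / scale, z = rec$z / scale
  )
  data.table::fwrite(dt, path)
  yaml::write_yaml(
    list(
      animal_id = rec$animal_id,
      condition = rec$condition,
      sensor_id = rec$sensor_id,
      start_time = format(rec$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      sampling_rate = rec$sampling_rate,
      unit = unit,
      rotation_rpm = rec$rotation_rpm
    ),
    sidecar_path(path),
    precision = 15
  )
  invisible(path)
}

#' Trim a recording to a fixed wall-clock analysis window
#'
#' Restricts a recording to the active-phase window used by the analysis
#' (by default 12 h starting at 19:45). The first sample at or after the
#' window start is taken (partial seconds truncate toward the window
#' interior) and exactly `duration * sampling_rate` samples are kept.
#'
#' @param rec an [accel_recording()].
#' @param window_start clock time `"HH:MM"` or `"HH:MM:SS"`; the first
#'   occurrence at or after the recording start is used.
#' @param duration window length in seconds (default 43200 = 12 h).
#' @return the trimmed [accel_recording()] with an updated `start_time`.
#' @export
#' @examples
#' rec <- accel_recording(1, "sham",
#'   x = rnorm(25 * 120), y = rnorm(25 * 120), z = rnorm(25 * 120) + 9.81,
#'   start_time = "2024-01-01 19:40:00"
#' )
#' trimmed <- trim_to_window(rec, "19:45", duration = 60)
#' length(trimmed$x) # 60 s * 25 Hz = 1500
trim_to_window <- function(rec, window_start = "19:45", duration = 43200) {
  validate_recording(rec)
  fs <- rec$sampling_rate
  n_out <- duration * fs
  if (abs(n_out - round(n_out)) > 1e-9) {
    stop("duration * sampling_rate must be an integer number of samples",
      call. = FALSE
    )
  }
  n_out <- as.integer(round(n_out))

  if (!grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", window_start)) {
    stop("window_start must be 'HH:MM' or 'HH:MM:SS'", call. = FALSE)
  }
  parts <- as.numeric(strsplit(window_start, ":")[[1]])
  target_sec <- parts[1] * 3600 + parts[2] * 60 +
    if (length(parts) == 3) parts[3] else 0

  t0 <- rec$start_time
  day0 <- as.POSIXct(format(t0, "%Y-%m-%d", tz = "UTC"), tz = "UTC")
  win_start <- day0 + target_sec
  if (win_start < t0) win_start <- win_start + 86400

  offset <- as.numeric(difftime(win_start, t0, units = "secs"))
  # truncate partial sampling intervals toward the window interior
  start_idx <- as.integer(ceiling(offset * fs - 1e-9)) + 1L
  n_avail <- length(rec$x) - start_idx + 1L
  if (n_avail < n_out) {
    stop(
      "recording does not cover the window: need ", n_out,
      " samples from ", format(win_start, tz = "UTC"), ", have ",
      max(n_avail, 0L), " (short by ", n_out - max(n_avail, 0L),
      " samples = ", round((n_out - max(n_avail, 0L)) / fs, 1), " s)",
      call. = FALSE
    )
  }
  keep <- start_idx:(start_idx + n_out - 1L)
  out <- rec
  out$x <- rec$x[keep]
  out$y <- rec$y[keep]
  out$z <- rec$z[keep]
  out$start_time <- t0 + (start_idx - 1L) / fs
  out
}

#' Assemble the cohort data matrix of magnitude series
#'
#' Stacks per-animal magnitude series into the `D x I` dataset matrix used
#' for PCA screening, with one row per dataset ordered by animal id.
#'
#' @param magnitudes a list of magnitude series as returned by
#'   [compute_magnitude()] (each carries its animal id and condition).
#' @return a numeric matrix of class `dataset_matrix` with attributes
#'   `animal_id` (row order) and `condition` (per-row labels).
#' @export
build_matrix <- function(magnitudes) {
  if (!length(magnitudes)) stop("no magnitude series given", call. = FALSE)
  lens <- vapply(magnitudes, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("ragged magnitude lengths: ", paste(unique(lens), collapse = ", "),
      call. = FALSE
    )
  }
  ids <- vapply(magnitudes, function(m) attr(m, "animal_id"), numeric(1))
  cond <- vapply(magnitudes, function(m) attr(m, "condition"), character(1))
  ord <- order(ids)
  M <- do.call(rbind, lapply(magnitudes[ord], as.numeric))
  rownames(M) <- ids[ord]
  structure(M,
    animal_id = as.integer(ids[ord]), condition = cond[ord],
    class = c("dataset_matrix", class(M))
  )
}

#' Write a simulated or assembled cohort to disk
#'
#' Writes one CSV + sidecar per recording and a YAML manifest listing the
#' files with their metadata, the format [read_cohort()] expects.
#'
#' @param recordings list of [accel_recording()] objects.
#' @param dir output directory (created if missing).
#' @param unit storage unit for the CSV files.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(recordings, dir, unit = "m_s2") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(recordings, function(rec) {
    f <- sprintf("animal_%02d.csv", rec$animal_id)
    write_recording(rec, file.path(dir, f), unit = unit)
    list(
      file = f, animal_id = rec$animal_id, condition = rec$condition,
      rotation_rpm = rec$rotation_rpm
    )
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(animals = entries), manifest, precision = 15)
  invisible(manifest)
}

#' Read a cohort from a manifest file
#'
#' @param manifest path to a YAML manifest written by [write_cohort()].
#' @return a list of [accel_recording()] objects.
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) {
    stop("manifest not found: ", manifest, call. = FALSE)
  }
  mf <- yaml::read_yaml(manifest)
  base <- dirname(manifest)
  lapply(mf$animals, function(e) {
    rec <- read_recording(file.path(base, e$file))
    if (!is.null(e$rotation_rpm) && is.na(rec$rotation_rpm)) {
      rec$rotation_rpm <- as.numeric(e$rotation_rpm)
    }
    rec
  })
}
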