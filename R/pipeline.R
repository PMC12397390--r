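#' Configuration for a full cohort analysis
#'
#' Bundles every tunable of the analysis pipeline. Exactly one input
#' source must be given: a cohort `manifest` on disk, or a `sim`
#' configuration from which a synthetic cohort is generated.
#'
#' @param manifest path to a YAML cohort manifest (see [read_cohort()]).
#' @param sim a [sim_config()] for a synthetic cohort.
#' @param outlier_ids animals simulated with inflated variance (synthetic
#'   input only).
#' @param S segment length in samples (default 1500 = 1 min at 25 Hz).
#' @param window_start active-phase window start, clock time (default
#'   `"19:45"`).
#' @param window_duration window length in seconds; `NULL` (default)
#'   analyses recordings at full length, `43200` reproduces the 12 h
#'   active-phase trim.
#' @param g gravity for normalization (9.81 m/s^2).
#' @param alpha family-wise significance level (default 0.05).
#' @param tests battery applied to each feature, in this order.
#' @param outlier_rule apply the per-class MAD-median exclusion (default
#'   `TRUE`).
#' @param pca compute the PCA latent projection of the magnitude matrix
#'   (diagnostic output; default `TRUE`).
#' @param n_bins log-histogram bins (default 100).
#' @param out_dir optional directory for CSV/JSON stage outputs.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(manifest = NULL, sim = NULL,
                            outlier_ids = integer(0),
                            S = 1500,
                            window_start = "19:45",
                            window_duration = NULL,
                            g = STANDARD_GRAVITY,
                            alpha = 0.05,
                            tests = c(
                              "mann_whitney_u", "bws",
                              "kolmogorov_smirnov"
                            ),
                            outlier_rule = TRUE,
                            pca = TRUE,
                            n_bins = 100,
                            out_dir = NULL) {
  if (is.null(manifest) == is.null(sim)) {
    stop("give exactly one of 'manifest' or 'sim'", call. = FALSE)
  }
  if (!is.null(sim)) validate_sim_config(sim)
  if (S < 2) stop("S must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  tests <- match.arg(tests,
    c("mann_whitney_u", "bws", "kolmogorov_smirnov"),
    several.ok = TRUE
  )
  structure(
    list(
      manifest = manifest, sim = sim, outlier_ids = outlier_ids,
      S = as.integer(S), window_start = window_start,
      window_duration = window_duration, g = g, alpha = alpha,
      tests = tests, outlier_rule = isTRUE(outlier_rule),
      pca = isTRUE(pca), n_bins = n_bins, out_dir = out_dir
    ),
    class = "analysis_config"
  )
}

run_test_battery <- function(feature_values, condition, tests, alpha,
                             feature_name) {
  a <- feature_values[condition == "sham"]
  b <- feature_values[condition == "PD"]
  results <- lapply(tests, function(tn) {
    switch(tn,
      mann_whitney_u = mann_whitney_u(a, b),
      bws = bws_test(a, b),
      kolmogorov_smirnov = kolmogorov_smirnov(a, b)
    )
  })
  p_raw <- setNames(
    vapply(results, function(r) r$p, numeric(1)),
    tests
  )
  holm <- holm_bonferroni(p_raw, alpha = alpha)
  table <- tibble::tibble(
    feature = feature_name,
    test = holm$label,
    statistic = vapply(
      holm$label,
      function(l) results[[match(l, tests)]]$statistic, numeric(1)
    ),
    method = vapply(
      holm$label,
      function(l) results[[match(l, tests)]]$method, character(1)
    ),
    p = holm$p,
    p_adjusted = holm$p_adjusted,
    significant = holm$significant,
    n1 = length(a),
    n2 = length(b)
  )
  list(tests = results, holm = holm, table = table)
}

#' Run the full accelerometry analysis pipeline
#'
#' Orchestrates load/simulate, optional active-phase trimming, magnitude
#' reduction, segmental moments, per-animal summaries, PCA screening,
#' per-class MAD-median outlier exclusion, log-binned histograms, the
#' nonparametric test battery with Holm-Bonferroni adjustment on the mean
#' segmental variance and the mean absolute segmental skewness, the Welch
#' t-test on rotation rates and the severity correlation. Hypothesis
#' tests are applied after outlier exclusion. The run is deterministic
#' for a fixed input (manifest or simulation seed).
#'
#' @param cfg an [analysis_config()].
#' @return a list of class `accel_report`; see the fields in the
#'   examples. If `cfg$out_dir` is set, stage tables are also written as
#'   CSV plus a JSON summary.
#' @export
#' @examples
#' cfg <- analysis_config(
#'   sim = sim_config(seed = 1, duration_s = 600),
#'   S = 150
#' )
#' rep <- run_analysis(cfg)
#' rep$comparisons$variance$table
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))

  # --- input -------------------------------------------------------------
  if (!is.null(cfg$manifest)) {
    recordings <- read_cohort(cfg$manifest)
    truth <- NULL
  } else {
    sim <- simulate_cohort(cfg$sim, outlier_ids = cfg$outlier_ids)
    recordings <- sim$recordings
    truth <- sim$truth
  }

  if (!is.null(cfg$window_duration)) {
    recordings <- lapply(recordings, function(rec) {
      tryCatch(
        trim_to_window(rec, cfg$window_start, cfg$window_duration),
        error = function(e) {
          stop("stage trim, animal ", rec$animal_id, ": ",
            conditionMessage(e),
            call. = FALSE
          )
        }
      )
    })
  }

  # --- features ----------------------------------------------------------
  mags <- lapply(recordings, compute_magnitude)
  per_animal <- lapply(seq_along(mags), function(i) {
    tryCatch(
      {
        st <- segment_statistics(mags[[i]], S = cfg$S, g = cfg$g)
        list(stats = st, summary = dataset_summary(st, mags[[i]]))
      },
      error = function(e) {
        stop("stage features, animal ",
          attr(mags[[i]], "animal_id"), ": ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  })
  summaries <- do.call(rbind, lapply(per_animal, `[[`, "summary"))
  seg_all <- do.call(rbind, lapply(per_animal, function(x) {
    st <- x$stats
    st$condition <- attr(st, "condition")
    st
  }))

  latent <- if (cfg$pca) pca_latent(build_matrix(mags)) else NULL

  # --- outlier screening (per class, on the overall variance) ------------
  if (cfg$outlier_rule) {
    reports <- lapply(split(summaries, summaries$condition), function(cls) {
      if (nrow(cls) < 3) {
        # too few datasets to estimate a class median/MAD: never flag
        return(tibble::tibble(
          animal_id = cls$animal_id, condition = cls$condition,
          value = cls$overall_var, score = NA_real_, flagged = FALSE
        ))
      }
      mad_median_scores(cls$overall_var,
        animal_id = cls$animal_id,
        condition = cls$condition[1]
      )
    })
    outlier_report <- do.call(rbind, lapply(reports, tibble::as_tibble))
    final <- exclude_outliers(summaries, outlier_report)
  } else {
    outlier_report <- NULL
    final <- summaries
    attr(final, "D_all") <- nrow(summaries)
    attr(final, "D_final") <- nrow(summaries)
  }
  final_ids <- final$animal_id

  # --- histograms (final cohort, pooled per class) -----------------------
  seg_final <- seg_all[seg_all$animal_id %in% final_ids, ]
  mag_pool <- unlist(lapply(
    mags[match(final_ids, vapply(mags, attr, numeric(1), "animal_id"))],
    function(m) as.numeric(m) / cfg$g
  ))
  mag_class <- rep(final$condition, each = length(mags[[1]]))
  histograms <- list(
    magnitude = log_histogram(mag_pool,
      n_bins = cfg$n_bins,
      class = mag_class, variable = "magnitude (g)"
    ),
    mu = log_histogram(seg_final$mu_n,
      n_bins = cfg$n_bins,
      class = seg_final$condition, variable = "segmental mean (norm.)"
    ),
    var = log_histogram(seg_final$var_n,
      n_bins = cfg$n_bins,
      class = seg_final$condition, variable = "segmental variance (norm.)"
    ),
    skew = log_histogram(seg_final$skew_n,
      n_bins = cfg$n_bins,
      class = seg_final$condition, variable = "segmental |skewness| (norm.)"
    ),
    kurt = log_histogram(seg_final$kurt_n,
      n_bins = cfg$n_bins,
      class = seg_final$condition, variable = "segmental kurtosis (norm.)"
    )
  )

  # --- group tests after exclusion ---------------------------------------
  comparisons <- list()
  if (all(c("sham", "PD") %in% final$condition)) {
    comparisons$variance <- run_test_battery(
      final$var_mean, final$condition, cfg$tests, cfg$alpha, "variance"
    )
    comparisons$skewness <- run_test_battery(
      final$abs_skew_mean, final$condition, cfg$tests, cfg$alpha,
      "abs_skewness"
    )
  }

  rot_ok <- !is.na(final$rotation_rpm)
  rotation_test <- NULL
  correlation <- NULL
  if (all(c("sham", "PD") %in% final$condition[rot_ok])) {
    ra <- final$rotation_rpm[rot_ok & final$condition == "sham"]
    rb <- final$rotation_rpm[rot_ok & final$condition == "PD"]
    if (length(ra) >= 2 && length(rb) >= 2) {
      rotation_test <- welch_t_test(ra, rb)
    }
  }
  if (sum(rot_ok) >= 3) {
    correlation <- tryCatch(
      correlate_severity(
        final$var_mean[rot_ok],
        final$rotation_rpm[rot_ok]
      ),
      error = function(e) NULL
    )
  }

  report <- structure(
    list(
      config = cfg,
      cohort = list(
        D_all = attr(final, "D_all"),
        D_final = attr(final, "D_final"),
        excluded = attr(final, "excluded")
      ),
      summaries = summaries,
      final_summaries = final,
      truth = truth,
      latent = latent,
      outlier_report = outlier_report,
      histograms = histograms,
      comparisons = comparisons,
      rotation_test = rotation_test,
      correlation = correlation,
      provenance = list(
        seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA_integer_,
        r_version = as.character(getRversion()),
        timestamp = NA_character_
      )
    ),
    class = "accel_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write the stage tables of an analysis report to disk
#'
#' @param report an `accel_report` from [run_analysis()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) {
    data.table::fwrite(as.data.frame(x), file.path(dir, f))
  }
  wcsv(report$summaries, "summaries.csv")
  wcsv(report$final_summaries, "final_summaries.csv")
  if (!is.null(report$outlier_report) && nrow(report$outlier_report)) {
    wcsv(report$outlier_report, "outlier_report.csv")
  }
  if (!is.null(report$latent)) {
    lat <- data.frame(
      animal_id = report$latent$animal_id %||%
        seq_len(nrow(report$latent$coordinates)),
      condition = report$latent$condition %||% NA_character_,
      report$latent$coordinates
    )
    wcsv(lat, "latent.csv")
  }
  if (length(report$comparisons)) {
    wcsv(
      do.call(rbind, lapply(report$comparisons, `[[`, "table")),
      "tests.csv"
    )
  }
  for (nm in names(report$histograms)) {
    h <- report$histograms[[nm]]
    wcsv(
      data.frame(
        edge_lo = h$edges[-length(h$edges)], edge_hi = h$edges[-1],
        h$counts, check.names = FALSE
      ),
      paste0("histogram_", nm, ".csv")
    )
  }
  summary_json <- list(
    D_all = report$cohort$D_all,
    D_final = report$cohort$D_final,
    excluded_ids = if (!is.null(report$cohort$excluded)) {
      report$cohort$excluded$animal_id
    } else {
      integer(0)
    },
    alpha = report$config$alpha,
    seed = report$provenance$seed,
    r_version = report$provenance$r_version
  )
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.accel_report <- function(x, ...) {
  cat("<accel_report>\n")
  cat(
    "  cohort: D_all =", x$cohort$D_all, "-> D_final =",
    x$cohort$D_final, "\n"
  )
  if (!is.null(x$cohort$excluded) && nrow(x$cohort$excluded)) {
    cat(
      "  excluded:",
      paste(sprintf(
        "%d (score %.2f)", x$cohort$excluded$animal_id,
        x$cohort$excluded$score
      ), collapse = ", "), "\n"
    )
  }
  for (nm in names(x$comparisons)) {
    tb <- x$comparisons[[nm]]$table
    cat("  ", nm, ":\n", sep = "")
    for (i in seq_len(nrow(tb))) {
      cat(sprintf(
        "    %-20s p = %.4g  p_adj = %.4g  %s\n",
        tb$test[i], tb$p[i], tb$p_adjusted[i],
        if (tb$significant[i]) "significant" else "n.s."
      ))
    }
  }
  if (!is.null(x$rotation_test)) {
    cat(sprintf(
      "  rotation (Welch): t = %.3f, p = %.3g\n",
      x$rotation_test$statistic, x$rotation_test$p
    ))
  }
  if (!is.null(x$correlation)) {
    cat(sprintf(
      "  severity correlation: r = %.3f (p = %.3g), rho = %.3f (p = %.3g)\n",
      x$correlation$statistic, x$correlation$p,
      x$correlation$spearman_rho, x$correlation$spearman_p
    ))
  }
  invisible(x)
}
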