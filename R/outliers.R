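#' Two-dimensional PCA latent projection of the dataset matrix
#'
#' Projects the `D x I` magnitude matrix onto its leading principal
#' components for visual quality screening. Columns (samples) are
#' mean-centered before the decomposition; the latent coordinates are
#' `T = U Sigma` truncated to `n_components` dimensions. Because `D` is
#' tiny compared to `I`, the decomposition is computed from the `D x D`
#' Gram matrix of the centered rows rather than a full SVD; the result is
#' identical up to the usual sign indeterminacy, which is fixed by making
#' the largest-magnitude entry of each component of `U` positive.
#'
#' @param M a matrix (typically from [build_matrix()]), rows = datasets.
#' @param n_components number of latent dimensions to keep (default 2).
#' @return a list of class `pca_latent`: `coordinates` (`D x
#'   n_components`), `singular_values` (all `min(D, I)` implied by the
#'   centered rank), `explained_variance` (fractions summing to 1), and
#'   `animal_id`/`condition` copied from the matrix attributes when
#'   present.
#' @export
pca_latent <- function(M, n_components = 2) {
  M <- as.matrix(M)
  D <- nrow(M)
  if (D < 2) stop("need at least 2 datasets for PCA", call. = FALSE)
  if (n_components > min(dim(M))) {
    stop("n_components exceeds min(D, I) = ", min(dim(M)), call. = FALSE)
  }
  Mc <- sweep(M, 2, colMeans(M), "-")
  G <- tcrossprod(Mc) # D x D
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  sv <- sqrt(ev)
  U <- eg$vectors
  # deterministic sign: largest |entry| of each left singular vector > 0
  for (j in seq_len(ncol(U))) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  Tmat <- U %*% diag(sv, nrow = length(sv))
  coords <- Tmat[, seq_len(n_components), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(n_components))
  tot <- sum(ev)
  structure(
    list(
      coordinates = coords,
      singular_values = sv,
      explained_variance = if (tot > 0) ev / tot else rep(0, length(ev)),
      animal_id = attr(M, "animal_id"),
      condition = attr(M, "condition")
    ),
    class = "pca_latent"
  )
}

#' MAD-median outlier threshold
#'
#' The rejection threshold of the MAD-median rule,
#' \eqn{K = \sqrt{\chi^2_{0.975,1}} \approx 2.24}, computed from the
#' chi-squared quantile at run time.
#'
#' @param p quantile of the chi-squared distribution (default 0.975).
#' @return numeric threshold.
#' @export
#' @examples
#' round(mad_threshold(), 2) # 2.24
mad_threshold <- function(p = 0.975) {
  sqrt(qchisq(p, df = 1))
}

#' MAD-median outlier scores for one class
#'
#' Scores each value (here: the overall magnitude variance of one
#' dataset) by its absolute deviation from the class median in units of
#' the consistency-corrected MAD:
#' \deqn{score = |x - median(x)| / (MAD(x) / 0.6745),}
#' flagging values whose score exceeds \eqn{K = \sqrt{\chi^2_{0.975,1}}}.
#' The rule is applied separately per class; for even counts the median is
#' the mean of the two central order statistics. Scores are invariant
#' under scaling and shifts of the inputs.
#'
#' If the MAD is zero the scores are degenerate (0/0 for values at the
#' median, infinite otherwise); the report carries `mad_degenerate =
#' TRUE` and values at the median are not flagged.
#'
#' @param values numeric vector (at least 3 values).
#' @param animal_id optional ids for the report rows.
#' @param condition optional class label stored with the report.
#' @return a tibble of class `outlier_report` with columns `animal_id`,
#'   `condition`, `value`, `score`, `flagged`, and attributes `K`,
#'   `center`, `mad_raw`, `mad_degenerate`.
#' @export
#' @examples
#' r <- mad_median_scores(c(1, 2, 3, 4, 100))
#' r$score[5] # 97 * 0.6745 = 65.4265
#' r$flagged
mad_median_scores <- function(values, animal_id = seq_along(values),
                              condition = NA_character_) {
  if (length(values) < 3) {
    stop("need at least 3 values per class for the MAD-median rule",
      call. = FALSE
    )
  }
  K <- mad_threshold()
  ctr <- median(values)
  mad_raw <- mad(values, center = ctr, constant = 1)
  score <- abs(values - ctr) / (mad_raw / 0.6745)
  degen <- mad_raw == 0
  flagged <- !is.na(score) & is.finite(score) & score > K
  if (degen) flagged <- !is.na(score) & is.infinite(score)
  out <- tibble::tibble(
    animal_id = animal_id,
    condition = condition,
    value = as.numeric(values),
    score = score,
    flagged = flagged
  )
  structure(out,
    K = K, center = ctr, mad_raw = mad_raw, mad_degenerate = degen,
    class = c("outlier_report", class(out))
  )
}

#' Remove flagged datasets from a cohort summary
#'
#' Drops the rows of a per-animal summary table that an outlier report
#' flags, recording the exclusions (ids and scores) as an attribute. Rows
#' that are kept are returned unchanged.
#'
#' @param summaries per-animal summary tibble (must have `animal_id`).
#' @param report an `outlier_report` (or several row-bound reports)
#'   covering the cohort.
#' @return the reduced tibble with attributes `excluded` (tibble of
#'   dropped rows with scores) and `D_all`/`D_final`.
#' @export
exclude_outliers <- function(summaries, report) {
  if (!all(summaries$animal_id %in% report$animal_id)) {
    stop("outlier report does not cover the cohort", call. = FALSE)
  }
  flagged_ids <- report$animal_id[report$flagged]
  keep <- !summaries$animal_id %in% flagged_ids
  out <- summaries[keep, , drop = FALSE]
  structure(out,
    excluded = report[report$flagged, , drop = FALSE],
    D_all = nrow(summaries), D_final = sum(keep)
  )
}
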