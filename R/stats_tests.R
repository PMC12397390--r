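new_accel_test <- function(test, statistic, p, method, n1, n2,
                           ties = FALSE, extra = list()) {
  structure(
    c(list(
      test = test, statistic = as.numeric(statistic),
      p = as.numeric(p), method = method,
      n1 = as.integer(n1), n2 = as.integer(n2), ties = ties
    ), extra),
    class = "accel_test"
  )
}

#' @export
print.accel_test <- function(x, ...) {
  cat("<accel_test> ", x$test, " (", x$method, ")\n",
    "  statistic = ", format(x$statistic, digits = 6),
    ", p = ", format(x$p, digits = 4),
    ", n = ", x$n1, " vs ", x$n2,
    if (isTRUE(x$ties)) "  [ties: midranks]" else "", "\n",
    sep = ""
  )
  invisible(x)
}

check_samples <- function(a, b, min_n = 1) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < min_n || length(b) < min_n) {
    stop("both samples need at least ", min_n, " observations",
      call. = FALSE
    )
  }
  if (anyNA(a) || anyNA(b)) stop("samples contain NA", call. = FALSE)
  list(a = a, b = b)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test of the null hypothesis that both samples share one
#' underlying distribution. Uses the exact null distribution of U when
#' `n1 + n2 <= 25` and the pooled sample is tie-free, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @return an `accel_test` with the U statistic of sample `a`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p # exact two-sided: 0.1
mann_whitney_u <- function(a, b) {
  s <- check_samples(a, b, 1)
  ties <- anyDuplicated(c(s$a, s$b)) > 0
  exact <- !ties && length(s$a) + length(s$b) <= 25
  res <- suppressWarnings(
    wilcox.test(s$a, s$b, exact = exact, correct = TRUE)
  )
  new_accel_test(
    "mann_whitney_u", unname(res$statistic), res$p.value,
    if (exact) "exact" else "asymptotic",
    length(s$a), length(s$b),
    ties = ties
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test on the maximum distance between the empirical
#' distribution functions. The exact p-value is used for small tie-free
#' samples (as in [stats::ks.test()]).
#'
#' @param a,b numeric samples.
#' @return an `accel_test` with the D statistic.
#' @export
kolmogorov_smirnov <- function(a, b) {
  s <- check_samples(a, b, 1)
  ties <- anyDuplicated(c(s$a, s$b)) > 0
  res <- suppressWarnings(ks.test(s$a, s$b))
  exact <- !ties && length(s$a) * length(s$b) < 10000
  new_accel_test(
    "kolmogorov_smirnov", unname(res$statistic), res$p.value,
    if (exact) "exact" else "asymptotic",
    length(s$a), length(s$b),
    ties = ties
  )
}

# --- Baumgartner-Weiss-Schindler ------------------------------------------

# B statistic from the sorted pooled (mid)ranks of the two groups,
# original 1998 formulation: B = (B_X + B_Y) / 2.
bws_statistic_from_ranks <- function(rx, ry) {
  n <- length(rx)
  m <- length(ry)
  gi <- sort(rx)
  hj <- sort(ry)
  i <- seq_len(n)
  j <- seq_len(m)
  bx <- sum((gi - (m + n) / n * i)^2 /
    ((i / (n + 1)) * (1 - i / (n + 1)) * (m * (m + n) / n))) / n
  by <- sum((hj - (m + n) / m * j)^2 /
    ((j / (m + 1)) * (1 - j / (m + 1)) * (n * (m + n) / m))) / m
  (bx + by) / 2
}

# cache of subset/complement index matrices and tie-free null B values,
# keyed by "n_m" (cheap to rebuild, expensive to recompute per call)
.bws_cache <- new.env(parent = emptyenv())

bws_enumeration <- function(n, m) {
  key <- paste0(n, "_", m)
  if (!is.null(.bws_cache[[key]])) {
    return(.bws_cache[[key]])
  }
  N <- n + m
  subs <- utils::combn(N, n)
  comp <- apply(subs, 2, function(ix) seq_len(N)[-ix])
  comp <- matrix(comp, nrow = m)
  .bws_cache[[key]] <- list(subs = subs, comp = comp, nullB = NULL)
  .bws_cache[[key]]
}

# all B values over assignments of the rank vector r to groups of n vs m
bws_null_values <- function(r, n, m, en = bws_enumeration(n, m)) {
  N <- n + m
  i <- seq_len(n)
  j <- seq_len(m)
  wx <- (i / (n + 1)) * (1 - i / (n + 1)) * (m * N / n)
  wy <- (j / (m + 1)) * (1 - j / (m + 1)) * (n * N / m)
  Rx <- matrix(r[en$subs], nrow = n)
  Ry <- matrix(r[en$comp], nrow = m)
  Rx <- apply(Rx, 2, sort)
  Ry <- apply(Ry, 2, sort)
  bx <- colSums((Rx - (N / n) * i)^2 / wx) / n
  by <- colSums((Ry - (N / m) * j)^2 / wy) / m
  (bx + by) / 2
}

#' Baumgartner-Weiss-Schindler two-sample test
#'
#' Rank-based two-sample test whose statistic B (the mean of two weighted
#' rank-discrepancy sums, one per group) up-weights discrepancies in the
#' distribution tails relative to classical rank tests. Ties are handled
#' by midranks and flagged.
#'
#' P-value methods: `"exact_permutation"` enumerates all
#' `choose(n1+n2, n1)` group assignments of the observed (mid)ranks
#' (feasible up to 1e5 assignments, which covers the study's 5-vs-10
#' design with 3003); `"monte_carlo"` samples assignments;
#' `"asymptotic"` uses the limiting null distribution of B (an
#' Anderson-Darling-type weighted Brownian-bridge integral) and is
#' refused below a pooled size of 20, where it is unreliable. The default
#' `"auto"` picks exact enumeration when feasible, Monte Carlo otherwise.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @param method p-value method, see above.
#' @param n_mc Monte Carlo draws (default 10000).
#' @return an `accel_test` with the B statistic.
#' @export
#' @examples
#' bws_test(c(1, 2, 3), c(10, 11, 12))$statistic # 2.6296...
bws_test <- function(a, b,
                     method = c(
                       "auto", "exact_permutation", "monte_carlo",
                       "asymptotic"
                     ),
                     n_mc = 10000) {
  method <- match.arg(method)
  s <- check_samples(a, b, 2)
  n <- length(s$a)
  m <- length(s$b)
  N <- n + m
  pooled <- c(s$a, s$b)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled) # midranks under ties
  B <- bws_statistic_from_ranks(r[seq_len(n)], r[n + seq_len(m)])

  if (method == "auto") {
    method <- if (choose(N, n) <= 1e5) "exact_permutation" else "monte_carlo"
  }

  p <- switch(method,
    exact_permutation = {
      if (choose(N, n) > 1e5) {
        stop("exact enumeration infeasible: choose(", N, ", ", n,
          ") > 1e5; use monte_carlo",
          call. = FALSE
        )
      }
      en <- bws_enumeration(n, m)
      if (!ties) {
        # tie-free null depends on (n, m) only; cache it
        if (is.null(en$nullB)) {
          en$nullB <- bws_null_values(seq_len(N), n, m, en)
          .bws_cache[[paste0(n, "_", m)]] <- en
        }
        nullB <- en$nullB
      } else {
        nullB <- bws_null_values(r, n, m, en)
      }
      mean(nullB >= B - 1e-9)
    },
    monte_carlo = {
      hits <- 0L
      for (k in seq_len(n_mc)) {
        ix <- sample.int(N, n)
        Bk <- bws_statistic_from_ranks(r[ix], r[-ix])
        if (Bk >= B - 1e-9) hits <- hits + 1L
      }
      (hits + 1) / (n_mc + 1)
    },
    asymptotic = {
      if (N < 20) {
        stop("asymptotic BWS p-value refused for n1 + n2 < 20; ",
          "use exact_permutation or monte_carlo",
          call. = FALSE
        )
      }
      1 - bws_asymptotic_cdf(B)
    }
  )

  new_accel_test("bws", B, p, method, n, m, ties = ties)
}

#' Limiting null CDF of the BWS statistic
#'
#' The B statistic converges under the null to the integral of a squared
#' Brownian bridge weighted by `1/(t(1-t))`, the same limit as the
#' Anderson-Darling statistic. This evaluates that CDF by the standard
#' alternating series with a numerically integrated kernel.
#'
#' @param b quantile(s), `b > 0`.
#' @param terms number of series terms (default 8; the series converges
#'   very fast for b above ~0.3).
#' @return `P(B <= b)` under the limiting null distribution.
#' @export
#' @examples
#' round(bws_asymptotic_cdf(2.4924), 3) # ~0.95, the classical 5% level
bws_asymptotic_cdf <- function(b, terms = 8) {
  vapply(b, function(z) {
    if (!is.finite(z) || z <= 1e-3) {
      return(0)
    }
    tot <- 0
    for (j in 0:(terms - 1)) {
      cj <- (-1)^j * gamma(j + 0.5) * (4 * j + 1) /
        (gamma(0.5) * factorial(j))
      b2 <- (4 * j + 1)^2 * pi^2 / (8 * z)
      ig <- integrate(
        function(w) exp(z / (8 * (w^2 + 1)) - b2 * (w^2 + 1)),
        0, Inf,
        rel.tol = 1e-9
      )$value
      tot <- tot + cj * ig
    }
    min(1, max(0, sqrt(2 * pi) / z * tot))
  }, numeric(1))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with the Welch-Satterthwaite degrees of
#' freedom, used for the apomorphine rotation-rate comparison.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @return an `accel_test` with the t statistic and `df` field.
#' @export
welch_t_test <- function(a, b) {
  s <- check_samples(a, b, 2)
  if (sd(s$a) == 0 && sd(s$b) == 0) {
    if (mean(s$a) == mean(s$b)) {
      stop("both groups constant with equal means: t undefined",
        call. = FALSE
      )
    }
  }
  res <- t.test(s$a, s$b, var.equal = FALSE)
  new_accel_test(
    "welch_t", unname(res$statistic), res$p.value, "asymptotic",
    length(s$a), length(s$b),
    extra = list(df = unname(res$parameter))
  )
}

#' Correlation between a severity marker and a feature
#'
#' Reports both the Pearson and the Spearman correlation of paired
#' per-animal values (e.g. mean segmental variance against
#' apomorphine-induced rotation rate).
#'
#' @param variances numeric vector (feature values).
#' @param rotations numeric vector of equal length (severity marker).
#' @return an `accel_test` whose `statistic`/`p` are the Pearson results,
#'   with extra fields `spearman_rho` and `spearman_p`.
#' @export
correlate_severity <- function(variances, rotations) {
  s <- check_samples(variances, rotations, 3)
  if (length(s$a) != length(s$b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (sd(s$a) == 0 || sd(s$b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  pe <- cor.test(s$a, s$b, method = "pearson")
  sp <- suppressWarnings(cor.test(s$a, s$b, method = "spearman"))
  new_accel_test(
    "correlation", unname(pe$estimate), pe$p.value, "asymptotic",
    length(s$a), length(s$b),
    extra = list(
      spearman_rho = unname(sp$estimate),
      spearman_p = sp$p.value
    )
  )
}

#' Holm-Bonferroni adjustment with sequential rejection
#'
#' Sorts the raw p-values ascending and multiplies each literally by its
#' step-down factor, \eqn{\tilde p_i = p_i (N_{HT} + 1 - i)}, without the
#' running-maximum monotonization of the textbook step-down procedure (so
#' the largest raw p-value is always returned unchanged). Significance is
#' decided sequentially: tests are visited in ascending order and once
#' one adjusted p-value exceeds `alpha`, that test and all subsequent
#' ones are declared non-significant, even if a later adjusted value
#' drops below `alpha` again. Adjusted values above 1 are capped at 1 and
#' flagged; decisions are unaffected by the cap.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise significance level (default 0.05).
#' @param labels optional test labels carried through the sort.
#' @return a tibble of class `holm_result`, sorted by ascending raw p,
#'   with columns `label`, `p`, `rank`, `multiplier`, `p_adjusted`
#'   (capped), `capped`, `significant`; attribute `alpha`.
#' @export
#' @examples
#' holm_bonferroni(c(0.013, 0.018, 0.019))$p_adjusted # 0.039 0.036 0.019
holm_bonferroni <- function(p_values, alpha = 0.05,
                            labels = names(p_values) %||%
                              paste0("test", seq_along(p_values))) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  n_ht <- length(p)
  ord <- order(p)
  ps <- p[ord]
  mult <- n_ht + 1 - seq_len(n_ht)
  adj_raw <- ps * mult
  capped <- adj_raw > 1
  adj <- pmin(adj_raw, 1)
  sig <- cumprod(adj <= alpha) == 1 # sequential stop rule
  out <- tibble::tibble(
    label = labels[ord],
    p = ps,
    rank = seq_len(n_ht),
    multiplier = mult,
    p_adjusted = adj,
    capped = capped,
    significant = as.logical(sig)
  )
  structure(out,
    alpha = alpha, N_HT = n_ht,
    class = c("holm_result", class(out))
  )
}
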