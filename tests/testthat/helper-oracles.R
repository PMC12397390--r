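# Independent brute-force oracles used to pin the fast implementations.
# These deliberately use literal loops over the defining formulas and the
# full enumeration of group assignments; they share no code with R/.

# first four moments: mean, unbiased variance, and skewness/kurtosis with
# 1/S numerators over powers of the unbiased standard deviation
oracle_moments <- function(x) {
  S <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / S
  ss2 <- 0
  ss3 <- 0
  ss4 <- 0
  for (v in x) {
    d <- v - mu
    ss2 <- ss2 + d^2
    ss3 <- ss3 + d^3
    ss4 <- ss4 + d^4
  }
  var <- ss2 / (S - 1)
  c(
    mu = mu, var = var,
    skew = (ss3 / S) / sqrt(var)^3,
    kurt = (ss4 / S) / sqrt(var)^4
  )
}

# Mann-Whitney U of sample a within the pooled ranks
oracle_u_stat <- function(ranks_a, n_a) {
  sum(ranks_a) - n_a * (n_a + 1) / 2
}

# exact two-sided MWU p by enumerating every C(n+m, n) assignment
oracle_mwu_p <- function(a, b) {
  n <- length(a)
  N <- n + length(b)
  r <- rank(c(a, b))
  u_obs <- oracle_u_stat(r[seq_len(n)], n)
  subs <- combn(N, n)
  u_all <- apply(subs, 2, function(ix) oracle_u_stat(r[ix], n))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# two-sample KS statistic by a literal ECDF sweep over the pooled values
oracle_ks_D <- function(a, b) {
  grid <- sort(c(a, b))
  d <- 0
  for (t in grid) {
    d <- max(d, abs(mean(a <= t) - mean(b <= t)))
  }
  d
}

# BWS statistic, literal transcription of the original two-sum form
oracle_bws_B <- function(a, b) {
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  gi <- sort(r[seq_len(n)])
  hj <- sort(r[n + seq_len(m)])
  bx <- 0
  for (i in seq_len(n)) {
    bx <- bx + (gi[i] - (m + n) / n * i)^2 /
      ((i / (n + 1)) * (1 - i / (n + 1)) * (m * (m + n) / n))
  }
  by <- 0
  for (j in seq_len(m)) {
    by <- by + (hj[j] - (m + n) / m * j)^2 /
      ((j / (m + 1)) * (1 - j / (m + 1)) * (n * (m + n) / m))
  }
  (bx / n + by / m) / 2
}

# exact BWS permutation p over all assignments of the pooled values
oracle_bws_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  N <- length(pooled)
  b_obs <- oracle_bws_B(a, b)
  subs <- combn(N, n)
  hits <- 0
  for (k in seq_len(ncol(subs))) {
    ix <- subs[, k]
    bk <- oracle_bws_B(pooled[ix], pooled[-ix])
    if (bk >= b_obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(subs)
}

# short synthetic recording for structural tests
make_rec <- function(n = 100, seed = 1, fs = 25, condition = "sham",
                     animal_id = 1, start_time = "2024-01-01 19:45:00") {
  set.seed(seed)
  accel_recording(animal_id, condition,
    x = rnorm(n, 0, 0.3), y = rnorm(n, 0, 0.3), z = 9.81 + rnorm(n, 0, 0.3),
    sampling_rate = fs, start_time = start_time
  )
}
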