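test_that("magnitude is the per-sample Euclidean norm", {
  rec <- accel_recording(1, "sham",
    x = c(3, 0, 0), y = c(4, 0, 0), z = c(0, 9.81, 0)
  )
  m <- compute_magnitude(rec)
  expect_equal(as.numeric(m), c(5, 9.81, 0))
  expect_equal(as.numeric(compute_magnitude(rec, normalize = TRUE))[2], 1)

  # all axes at +4 g: magnitude reaches 4*sqrt(3) g
  g4 <- 4 * 9.81
  rec2 <- accel_recording(1, "sham", x = g4, y = g4, z = g4)
  expect_equal(as.numeric(compute_magnitude(rec2)), 4 * sqrt(3) * 9.81)
  expect_equal(as.numeric(compute_magnitude(rec2)), 67.97, tolerance = 1e-4)
})

test_that("segmentation drops the remainder and keeps segment count", {
  expect_identical(ncol(segment_series(seq_len(3000), 1500)), 2L)
  s <- segment_series(seq_len(3001), 1500)
  expect_identical(ncol(s), 2L)
  expect_identical(attr(s, "n_dropped"), 1L)
  expect_identical(as.numeric(s[, 1]), as.numeric(1:1500))
  expect_error(segment_series(1:10, 1500), "shorter than one segment")
  expect_error(segment_series(1:10, 1), ">= 2")
})

test_that("segment moments match the printed hand example", {
  m <- segment_moments(c(1, 2, 3, 4))
  expect_equal(m[["mu"]], 2.5)
  expect_equal(m[["var"]], 5 / 3)
  expect_equal(m[["skew"]], 0)
  expect_equal(m[["kurt"]], 0.9225)

  const <- segment_moments(c(5, 5, 5, 5))
  expect_equal(const[["mu"]], 5)
  expect_equal(const[["var"]], 0)
  expect_true(is.na(const[["skew"]]) && is.na(const[["kurt"]]))
})

test_that("vectorized segmental moments equal the brute-force oracle", {
  set.seed(42)
  x <- exp(rnorm(1500, 0, 0.4)) + 9
  expect_equal(segment_moments(x), oracle_moments(x), tolerance = 1e-12)

  # whole-table path on several segments, including a skewed and a spiky one
  m <- c(x, rlnorm(1500, 2, 1), rnorm(1500), rep(1, 500) + rep(c(0, 3), 750))
  st <- segment_statistics(m, S = 1500)
  expect_identical(nrow(st), 4L)
  for (n in 1:4) {
    seg <- m[((n - 1) * 1500 + 1):(n * 1500)]
    o <- oracle_moments(seg)
    expect_equal(st$mu[n], o[["mu"]], tolerance = 1e-12)
    expect_equal(st$var[n], o[["var"]], tolerance = 1e-12)
    expect_equal(st$skew[n], o[["skew"]], tolerance = 1e-12)
    expect_equal(st$kurt[n], o[["kurt"]], tolerance = 1e-12)
  }
})

test_that("axis scaling propagates as c, c^2 and leaves shape moments", {
  rec <- make_rec(n = 600, seed = 9)
  c0 <- 2.7
  rec2 <- rec
  rec2$x <- rec$x * c0
  rec2$y <- rec$y * c0
  rec2$z <- rec$z * c0
  s1 <- segment_statistics(compute_magnitude(rec), S = 150)
  s2 <- segment_statistics(compute_magnitude(rec2), S = 150)
  expect_equal(s2$mu, s1$mu * c0, tolerance = 1e-12)
  expect_equal(s2$var, s1$var * c0^2, tolerance = 1e-12)
  expect_equal(s2$skew, s1$skew, tolerance = 1e-10)
  expect_equal(s2$kurt, s1$kurt, tolerance = 1e-10)
})

test_that("segment permutation preserves the multiset of statistics", {
  set.seed(10)
  m <- rnorm(1200, 9.81, 0.3)
  st <- segment_statistics(m, S = 200)
  perm <- c(4, 1, 6, 3, 2, 5)
  mp <- as.numeric(matrix(m, nrow = 200)[, perm])
  stp <- segment_statistics(mp, S = 200)
  expect_equal(sort(stp$var), sort(st$var), tolerance = 1e-14)
  expect_equal(sort(stp$skew), sort(st$skew), tolerance = 1e-14)
})

test_that("gravity normalization is applied literally per order", {
  st <- tibble::tibble(mu = 9.81, var = 9.81^2, skew = -0.5, kurt = 50)
  out <- normalize_moments(st, g = 9.81)
  expect_equal(out$mu_n, 1)
  expect_equal(out$var_n, 1)
  expect_equal(out$skew_n, 0.5 / 9.81^3) # absolute value of skewness
  expect_equal(out$kurt_n, 50 / 9.81^4)

  idn <- normalize_moments(st, g = 1)
  expect_equal(idn$mu_n, st$mu)
  expect_equal(idn$skew_n, abs(st$skew))
})

test_that("dataset summary averages segments and uses 1/(I-1) overall", {
  set.seed(11)
  rec <- make_rec(n = 3000, seed = 11)
  m <- compute_magnitude(rec)
  st <- segment_statistics(m, S = 1500)
  s <- dataset_summary(st, m)
  expect_equal(s$var_mean, mean(st$var))
  expect_equal(s$overall_var, sum((m - mean(m))^2) / (length(m) - 1))
  expect_equal(s$abs_skew_mean, mean(abs(st$skew)))
  expect_identical(s$n_segments, 2L)

  # two segments with known variances average to their midpoint
  x <- c(
    scale(rnorm(100)) * sqrt(0.1),
    scale(rnorm(100)) * sqrt(0.3)
  )
  st2 <- segment_statistics(as.numeric(x), S = 100)
  expect_equal(mean(st2$var), 0.2, tolerance = 1e-12)

  # degenerate segments are excluded from shape-moment means
  md <- c(rep(1, 100), rnorm(100, 0, 1))
  st3 <- segment_statistics(md, S = 100)
  expect_identical(attr(st3, "n_degenerate"), 1L)
  s3 <- dataset_summary(st3, md)
  expect_identical(s3$n_degenerate, 1L)
  expect_equal(s3$kurt_mean, st3$kurt[2])
})

test_that("directional transforms match cumulative-sum oracles", {
  rec <- accel_recording(1, "sham",
    x = rep(0, 50), y = rep(0, 50), z = rep(9.81, 50),
    sampling_rate = 25
  )
  tr <- directional_transforms(rec)
  # constant acceleration: velocity grows linearly in z, theta constant 0
  expect_equal(tr$vz, 9.81 * tr$time, tolerance = 1e-12)
  expect_equal(tr$vx, rep(0, 50))
  expect_true(all(tr$theta == 0))

  # trapezoidal integral against a literal loop
  rec2 <- make_rec(n = 200, seed = 12)
  tr2 <- directional_transforms(rec2)
  dt <- 1 / 25
  v <- numeric(200)
  for (i in 2:200) {
    v[i] <- v[i - 1] + (rec2$x[i - 1] + rec2$x[i]) / 2 * dt
  }
  expect_equal(tr2$vx, v, tolerance = 1e-10)

  # axis swap shifts phi by the quadrant
  rec3 <- accel_recording(1, "sham", x = 1, y = 0, z = 1)
  rec4 <- accel_recording(1, "sham", x = 0, y = 1, z = 1)
  expect_equal(
    directional_transforms(rec4)$phi,
    directional_transforms(rec3)$phi + pi / 2
  )

  # zero-magnitude sample has undefined angles
  rec5 <- accel_recording(1, "sham", x = c(0, 1), y = c(0, 0), z = c(0, 0))
  tr5 <- directional_transforms(rec5)
  expect_true(is.na(tr5$theta[1]))
  expect_false(is.na(tr5$theta[2]))
})
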