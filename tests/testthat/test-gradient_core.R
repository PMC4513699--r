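test_that("nearest-rank percentile matches its definition on key cases", {
  expect_equal(percentile(1:100, 89), 89)
  expect_equal(percentile(rep(3.5, 10), 42), 3.5)
  expect_equal(percentile(5, 89), 5)
  expect_equal(percentile(c(9, 1, 4), 0), 1)
  expect_error(percentile(numeric(0), 50), "non-empty")
  expect_error(percentile(1:5, 100), "\\[0, 100\\)")
})

test_that("percentile and filtered_mean agree with the type-1 quantile oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:500, 1)
    v <- switch(sample(3, 1),
                runif(n, 0, 1e4),
                rpois(n, 20) + 0,          # heavy ties
                rnorm(n, 50, 10))
    q <- runif(1, 0, 99.9)
    oracle_thr <- unname(stats::quantile(v, q / 100, type = 1))
    expect_identical(percentile(v, q), oracle_thr)
    fm <- filtered_mean(v, q)
    expect_identical(fm$filtered_mean, mean(v[v >= oracle_thr]))
    expect_identical(fm$raw_mean, mean(v))
    expect_gte(fm$filtered_mean, fm$raw_mean)
    expect_gte(fm$n_kept, 1)
  }
})

test_that("filtered_mean reproduces the worked examples", {
  expect_equal(filtered_mean(1:100, 89)$filtered_mean, mean(89:100))  # 94.5
  expect_equal(filtered_mean(1:100, 89)$filtered_mean, 94.5)
  expect_equal(filtered_mean(c(0, 0, 0, 10), 89)$filtered_mean, 10)
  fm0 <- filtered_mean(c(4, 8, 15, 16), 0)
  expect_equal(fm0$filtered_mean, fm0$raw_mean)
})

test_that("filtered_mean is non-decreasing in q", {
  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(5:200, 1), 0, 100)
    fms <- sapply(seq(0, 98, by = 2), function(q) filtered_mean(v, q)$filtered_mean)
    expect_true(all(diff(fms) >= -1e-12))
  }
})

test_that("three-point OLS equals the closed form and the lm oracle", {
  expect_equal(fit_slope(c(1, 1.37, 1.74))$slope, 0.37, tolerance = 1e-12)
  expect_equal(fit_slope(c(1, 1.37, 1.74))$intercept, 0.63, tolerance = 1e-12)
  expect_equal(fit_slope(c(5, 5, 5))$slope, 0)
  expect_equal(fit_slope(c(2, 9, 4))$slope, 1.0, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:50) {
    y <- rnorm(3, 10, 4)
    expect_equal(fit_slope(y)$slope, (y[3] - y[1]) / 2, tolerance = 1e-12)
    fit <- stats::lm(y ~ x, data = data.frame(x = c(1, 2, 3), y = y))
    expect_equal(fit_slope(y)$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(fit_slope(y)$intercept, unname(coef(fit)[1]),
                 tolerance = 1e-9)
  }
  expect_error(fit_slope(c(1, 2, 3), x = c(1, 1, 2)), "increasing")
})

test_that("basal normalization divides through and is scale invariant", {
  nm <- normalize_to_basal(c(8405.4, 11515.4, 14625.4))
  expect_identical(nm[1], 1)
  expect_equal(round(nm, 3), c(1, 1.370, 1.740))
  expect_equal(normalize_to_basal(c(1, 1, 1)), c(1, 1, 1))
  set.seed(3)
  for (c_ in c(0.01, 0.5, 2, 1000)) {
    m <- runif(3, 1, 10)
    expect_equal(normalize_to_basal(c_ * m), normalize_to_basal(m),
                 tolerance = 1e-12)
  }
  expect_error(normalize_to_basal(c(0, 1, 2)), "> 0")
})

test_that("score_line reproduces the plateau-profile slope signature", {
  prof <- rep(c(8405.4, 11515.4, 14625.4), each = 200)
  r <- score_line(prof, q = 89)
  expect_equal(r$raw_slope, 3110, tolerance = 1e-9)
  expect_equal(r$normalized_slope, 0.37, tolerance = 1e-4)
  expect_equal(r$normalized_means[1], 1)
  expect_true(r$valid)
  flat <- score_line(rep(6, 300))
  expect_equal(flat$raw_slope, 0)
  expect_equal(flat$normalized_slope, 0)
})

test_that("normalized slope is invariant to positive intensity scaling", {
  set.seed(21)
  for (i in 1:25) {
    prof <- runif(sample(60:600, 1), 1, 1e4)
    base <- score_line(prof)
    for (c_ in c(0.25, 2.5, 100)) {
      scaled <- score_line(c_ * prof)
      expect_equal(scaled$normalized_slope, base$normalized_slope,
                   tolerance = 1e-9)
      expect_equal(scaled$raw_slope, c_ * base$raw_slope, tolerance = 1e-9)
    }
  }
})

test_that("normalized slope times basal filtered mean equals the raw slope", {
  set.seed(31)
  for (i in 1:100) {
    prof <- runif(sample(30:400, 1), 0.5, 5e3)
    r <- score_line(prof, q = runif(1, 0, 99))
    expect_equal(r$normalized_slope * r$filtered_means[1], r$raw_slope,
                 tolerance = 1e-9 * max(1, abs(r$raw_slope)))
  }
})

test_that("a non-positive basal segment flags the line invalid", {
  prof <- c(rep(0, 100), rep(5, 100), rep(9, 100))
  r <- score_line(prof, q = 0)
  # q = 0 keeps everything; basal mean 0 cannot normalize
  expect_false(r$valid)
  expect_true(is.na(r$normalized_slope))
  expect_true(is.finite(r$raw_slope))
})

test_that("per-sample regression mode stays close to segment-mean mode", {
  set.seed(8)
  prof <- rep(c(100, 150, 200), each = 150) * runif(450, 0.95, 1.05)
  a <- score_line(prof, regression_mode = "segment_means")
  b <- score_line(prof, regression_mode = "all_samples")
  expect_equal(a$raw_slope, b$raw_slope, tolerance = 0.05)
})

test_that("threshold sweep reports one row per threshold with separation", {
  set.seed(9)
  mk <- function(lo, hi) lapply(1:4, function(i)
    rep(c(lo, (lo + hi) / 2, hi), each = 40) * runif(120, 0.97, 1.03))
  groups <- list(steep = mk(100, 200), flat = mk(100, 110))
  curve <- threshold_sweep(groups)
  expect_s3_class(curve, "sweep_curve")
  expect_equal(nrow(curve), 50)
  expect_equal(curve$q, seq(0, 98, by = 2))
  expect_named(curve, c("q", "mean_steep", "mean_flat", "separation"))
  expect_true(all(curve$separation > 0))
})

test_that("identical groups have zero separation; distinct noiseless groups positive", {
  mk_exact <- function(lo, hi) lapply(1:3, function(i)
    rep(c(lo, (lo + hi) / 2, hi), each = 30))
  same <- threshold_sweep(list(a = mk_exact(50, 100), b = mk_exact(50, 100)))
  expect_true(all(same$separation == 0))
  diffg <- threshold_sweep(list(a = mk_exact(50, 100), b = mk_exact(50, 60)))
  expect_true(all(diffg$separation > 0))
  expect_length(unique(diffg$separation), 1)  # no noise: constant over q
  expect_error(threshold_sweep(list(a = mk_exact(1, 2))), "2 groups")
})
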