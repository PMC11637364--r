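test_that("functional connectivity handles duplicates, sign and 2 nodes", {
  set.seed(1)
  x <- rnorm(200)
  fc <- functional_connectivity(cbind(x, x, -x))
  expect_equal(fc$values[1, 2], 1)
  expect_equal(fc$values[1, 3], -1)
  expect_true(isSymmetric(fc$values))
  expect_equal(diag(fc$values), rep(1, 3))
  two <- functional_connectivity(cbind(x, rnorm(200)))
  expect_equal(two$fc_mean, two$values[1, 2])
  flat <- functional_connectivity(cbind(x, rep(1, 200)))
  expect_equal(flat$values[1, 2], 0)
  expect_equal(flat$flagged, 2L)
  expect_error(functional_connectivity(matrix(1, 2, 2)), "time points")
})

test_that("FC fit is affine invariant and near zero under the null", {
  set.seed(2)
  m <- matrix(rnorm(84 * 84), 84); m <- cor(m)
  expect_equal(fc_fit(m, m), 1)
  expect_equal(fc_fit(m, 0.5 * m + 0.1), 1)
  null_r <- replicate(20, {
    a <- cor(matrix(rnorm(90 * 84), 90))
    b <- cor(matrix(rnorm(90 * 84), 90))
    fc_fit(a, b)
  })
  expect_lt(median(abs(null_r)), 0.1)
  expect_error(fc_fit(m, m[1:10, 1:10]), "size")
})

test_that("FCD window bookkeeping and degenerate inputs", {
  # 30 min at TR 720 ms: 2500 samples, 83-TR windows -> 2418 windows
  set.seed(3)
  x <- matrix(rnorm(2500 * 4), 2500)
  fd <- fcd(x, TR = 720)
  expect_equal(fd$window_trs, 83)
  expect_equal(nrow(fd$window_fcs), 2418)
  expect_equal(dim(fd$fcd_matrix), c(2418, 2418))
  expect_true(isSymmetric(fd$fcd_matrix))
  expect_equal(diag(fd$fcd_matrix), rep(1, 2418))
  expect_error(fcd(x[1:50, ], TR = 720), "window")
  # a periodically repeating signal gives FCD values of exactly 1
  per <- matrix(rnorm(83 * 4), 83)
  rep2 <- rbind(per, per)
  fd2 <- fcd(rep2, TR = 720)
  expect_equal(fd2$fcd_matrix[1, 84], 1, tolerance = 1e-12)
})

test_that("stationary noise yields a unimodal low FCD distribution", {
  set.seed(4)
  x <- matrix(rnorm(600 * 10), 600)
  fd <- fcd(x, TR = 720)
  expect_lt(abs(median(fd$values)), 0.25)
  # adjacent overlapping windows correlate, but the bulk does not
  expect_gt(mean(abs(fd$values) < 0.4), 0.7)
})

test_that("KS similarity matches analytic cases", {
  expect_equal(ks_similarity(1:100, 1:100), 1)
  expect_equal(ks_similarity(1:50, 101:150), 0)
  set.seed(5)
  a <- runif(4000); b <- runif(4000, 0.5, 1.5)
  expect_equal(ks_similarity(a, b), 0.5, tolerance = 0.03)
  expect_error(ks_similarity(numeric(0), 1:5), "empty")
})

test_that("MMF is the weighted mean with a synchronization gate", {
  expect_equal(mmf(1, 1, 0.1)$mmf, 1)
  expect_equal(mmf(0.6, 0.8, 0.1)$mmf, (0.6 + 0.75 * 0.8) / 1.75)
  expect_equal(mmf(0.6, 0.8, 0.1)$mmf, 0.6857, tolerance = 1e-4)
  rej <- mmf(0.9, 0.9, 0.3)
  expect_true(rej$rejected)
  expect_true(is.na(rej$mmf))
  expect_false(mmf(0.9, 0.9, 0.25)$rejected)
  # monotone in both components
  grid <- seq(0, 1, by = 0.25)
  for (k in seq_len(length(grid) - 1)) {
    expect_lt(mmf(grid[k], 0.5, 0)$mmf, mmf(grid[k + 1], 0.5, 0)$mmf)
    expect_lt(mmf(0.5, grid[k], 0)$mmf, mmf(0.5, grid[k + 1], 0)$mmf)
  }
})

test_that("Welch spectra locate peaks and conserve power", {
  t <- (0:59999) / 1000
  x <- sin(2 * pi * 10 * t)
  w <- welch_psd(x, dt = 1)
  expect_equal(w$freq[which.max(w$power)], 10, tolerance = 0.26)
  df <- w$freq[2] - w$freq[1]
  expect_equal(sum(w$power) * df, var(x), tolerance = 0.05)
  set.seed(6)
  n <- rnorm(60000)
  wn <- welch_psd(n, dt = 1)
  expect_equal(sum(wn$power) * df, var(n), tolerance = 0.05)
  # flat within broad confidence: compare low vs high band medians
  lo <- median(wn$power[wn$freq < 100])
  hi <- median(wn$power[wn$freq > 400])
  expect_lt(abs(log(lo / hi)), 0.3)
  expect_error(welch_psd(rnorm(10), dt = 1), "segments")
})

test_that("Poincare maps find windowed maxima and their pairs", {
  t <- seq(0, 5000, by = 1)
  s <- 12 * sin(2 * pi * 10 * t / 1000)
  pm <- poincare_map(s, dt = 1)
  expect_equal(median(diff(pm$times)), 100)
  expect_true(all(abs(pm$maxima - 12) < 0.1))
  expect_equal(ncol(pm$pairs), 2)
  expect_true(all(abs(pm$pairs - 12) < 0.1))
  expect_equal(nrow(poincare_map(seq_len(1000), dt = 1)$pairs), 0)
  # alternating 12/3 maxima from a two-frequency waveform
  s2 <- 7.5 * sin(2 * pi * 5 * t / 1000) +
    4.5 * sin(2 * pi * 2.5 * t / 1000 - pi / 2)
  pm2 <- poincare_map(s2, dt = 1)
  expect_true(all(diff(pm2$maxima > 6) != 0))   # strictly alternating
})

test_that("quadrant classification and occupancy follow the 6 mV rule", {
  lowp <- matrix(c(3, 3, 2.5, 3.2), 2, byrow = TRUE)
  cl <- classify_regimes(lowp, c(0, 100, 200), 300)
  expect_equal(unname(cl$occupancy["low_FP"]), 2 / 3)
  expect_equal(cl$regime_count, 1)
  fast <- matrix(12, 4, 2)
  cf <- classify_regimes(fast, seq(0, 400, by = 100), 500)
  expect_equal(unname(cf$occupancy["fast_LC"]), 0.8)
  mixed <- rbind(c(12, 3), c(3, 12), c(12, 3))
  cm <- classify_regimes(mixed, c(0, 100, 300, 400), 400)
  expect_equal(unname(cm$occupancy["slow_LC"]), 1)
  # all three regimes above the 7.5% occupancy rule
  pairs <- rbind(matrix(3, 10, 2), matrix(12, 10, 2),
                 matrix(c(12, 3), 10, 2, byrow = TRUE))
  times <- seq(0, length.out = 31, by = 100)
  c3 <- classify_regimes(pairs, times, 3000)
  expect_equal(c3$regime_count, 3)
  expect_true(all(c3$occupancy >= 0.075))
  expect_lte(sum(c3$occupancy), 1)
})

test_that("per-node regime analysis is stable under dt refinement", {
  t1 <- seq(0, 20000, by = 1)
  sig <- function(t) {
    a <- ifelse(t %% 8000 < 4000, 12, 3)
    a * sin(2 * pi * 5 * t / 1000)   # maxima 200 ms apart, on-grid
  }
  p1 <- poincare_classify(matrix(sig(t1), ncol = 1), dt = 1)
  t2 <- seq(0, 20000, by = 0.5)
  p2 <- poincare_classify(matrix(sig(t2), ncol = 1), dt = 0.5)
  expect_equal(p1$occupancy, p2$occupancy, tolerance = 0.02)
  expect_equal(p1$regime_count, p2$regime_count)
  expect_equal(sum(p1$count_histogram), 1)
})

test_that("window resampling is seeded and behaves at the extremes", {
  set.seed(7)
  n_tr <- 2600
  emp <- generate_surrogate_empirical(6, seed = 1)
  base <- matrix(rnorm(n_tr * 6), n_tr)
  shared <- rnorm(n_tr)
  sig <- sweep(0.3 * base, 1, 0.15 * shared, `+`)
  bold <- structure(list(signal = sig, TR = 720), class = "bold_series")
  b1 <- window_resample_mmf(bold, emp, window_min = 10, mode = "bootstrap",
                            n_resamples = 200, seed = 9, step_min = 3)
  b2 <- window_resample_mmf(bold, emp, window_min = 10, mode = "bootstrap",
                            n_resamples = 200, seed = 9, step_min = 3)
  expect_identical(b1$boot_means, b2$boot_means)
  expect_true(b1$ci[1] <= b1$mean && b1$mean <= b1$ci[2])
  # identical conditions: permutation difference is not significant
  pm <- window_resample_mmf(bold, emp, window_min = 10,
                            mode = "permutation", n_resamples = 400,
                            seed = 9, bold2 = bold, step_min = 3)
  expect_equal(pm$observed_diff, 0)
  expect_gt(pm$p_value, 0.5)
})
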