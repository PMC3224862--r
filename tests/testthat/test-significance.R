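test_that("colored noise has exact variance, in-band spectrum and seeded independence", {
  fs <- 200
  band <- freq_band("beta", 13, 30)
  x <- colored_noise_source(band, 3.3, 30, fs, 61)
  expect_equal(stats::var(x), 3.3, tolerance = 1e-12)
  # out-of-band power fraction < 1% (periodogram oracle); "band" includes
  # the filter's documented transition skirt tw = min(f_lo/2, width/2)
  tw <- min(band$f_lo / 2, (band$f_hi - band$f_lo) / 2)
  lo <- band$f_lo - tw; hi <- band$f_hi + tw
  sp <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  inband <- (f >= lo & f <= hi) | (f >= fs - hi & f <= fs - lo)
  expect_lt(sum(sp[!inband]) / sum(sp), 0.01)
  # independent seeds: small correlation; same seed: identical
  y <- colored_noise_source(band, 3.3, 30, fs, 62)
  expect_lt(abs(stats::cor(x, y)), 4 / sqrt(length(x)))
  expect_identical(x, colored_noise_source(band, 3.3, 30, fs, 61))
})

test_that("synthetic sensor noise has the requested spatial structure", {
  arr <- fix_array16
  # pure white floor: near-diagonal covariance
  nw <- synth_sensor_noise(arr, 60, 100, 63, floor_fraction = 1)
  Cw <- stats::cov(t(nw$data))
  expect_lt(max(abs(Cw[upper.tri(Cw)])) / mean(diag(Cw)), 0.1)
  # rank-1 + floor: one dominant eigenvalue (eigensolve oracle)
  n1 <- synth_sensor_noise(arr, 60, 100, 64, spatial_rank = 1,
                           floor_fraction = 0.2)
  ev <- eigen(stats::cov(t(n1$data)), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / ev[2], 3)
  expect_gt(ev[length(ev)], 0)
  # reproducible bit-for-bit
  expect_identical(n1$data, synth_sensor_noise(arr, 60, 100, 64,
                                               spatial_rank = 1,
                                               floor_fraction = 0.2)$data)
  expect_error(synth_sensor_noise(arr, 1, 100, 1, spatial_rank = 99), "exceed")
})

test_that("simulated pair datasets have the stated structure", {
  arr <- fix_array16
  band <- freq_band("beta", 13, 30)
  fs <- 200
  d1 <- dipole_spec(c(0.035, -0.01, 0.05), 0.3, moment = 2e-8)
  d2 <- dipole_spec(c(-0.035, -0.01, 0.05), 1.2, moment = 2e-8)
  zero_noise <- sensor_ts(matrix(0, arr$M, 20 * fs), fs)
  sim0 <- simulate_pair_dataset(d1, d2, zero_noise, band, 65, arr, fix_cond)
  expect_lte(qr(sim0$data)$rank, 2)
  src <- attr(sim0, "sources")
  expect_lt(abs(stats::cor(src[, 1], src[, 2])), 0.1)
  # with noise: beamformer projection at the seed recovers s1
  noise <- synth_sensor_noise(arr, 20, fs, 66)
  sim <- simulate_pair_dataset(d1, d2, noise, band, 65, arr, fix_cond)
  Xb <- fir_bandpass(sim$data, band, fs)
  C <- estimate_covariance(sensor_ts(Xb, fs))
  L1 <- lead_field(arr, fix_cond, d1)
  W1 <- compute_weights(L1, C)
  p1 <- as.numeric(crossprod(W1, Xb))
  expect_gt(stats::cor(p1, attr(sim, "sources")[, 1]), 0.9)
  expect_error(simulate_pair_dataset(d1, d2, sensor_ts(matrix(0, 3, 10), fs),
                                     band, 1, arr, fix_cond), "channel count")
})

test_that("percentile threshold follows the linear-interpolation convention", {
  dec <- percentile_threshold(c(50.5, 96.5), 1:100, 0.95)
  # threshold 95.05 leaves exactly the 5 largest null values above it
  expect_equal(dec$threshold, 95.05)
  expect_equal(sum((1:100) > dec$threshold), 5)
  expect_identical(dec$mask, c(FALSE, TRUE))
  # calibration identity: real == null flags ~5%
  set.seed(67)
  nv <- rnorm(4000)
  dec2 <- percentile_threshold(nv, nv, 0.95)
  expect_equal(mean(dec2$mask), 0.05, tolerance = 0.005)
  expect_error(percentile_threshold(1, 1:100, 1.2), "quantile")
  expect_warning(percentile_threshold(1, 1:10, 0.95), "fewer than 20")
})

test_that("binned correction zeroes null bin means and preserves in-bin order", {
  grid <- make_grid(25, fix_cond)
  n <- nrow(grid$centers)
  set.seed(68)
  wc <- fc_map(runif(n), grid)
  real <- fc_map(rnorm(n, mean = 2 * wc$values), grid)
  null <- fc_map(rnorm(n, mean = 2 * wc$values), grid)
  bc <- binned_correction(real, null, wc, bin_width = 0.05)
  bin <- findInterval(wc$values, bc$bin_edges, rightmost.closed = TRUE)
  for (b in unique(bin)) {
    expect_equal(mean(bc$null$values[bin == b]), 0, tolerance = 1e-12)
    ord0 <- order(real$values[bin == b])
    ord1 <- order(bc$real$values[bin == b])
    expect_identical(ord0, ord1)
  }
  # bin width 1 degenerates to global null-mean subtraction
  bc1 <- binned_correction(real, null, wc, bin_width = 1)
  expect_equal(bc1$real$values, real$values - mean(null$values),
               tolerance = 1e-12)
  # injected distal coupling survives correction
  far <- which.max(rowSums(sweep(grid$centers, 2, grid$centers[1, ])^2))
  real2 <- real; real2$values[far] <- real2$values[far] + 5
  bc2 <- binned_correction(real2, null, wc)
  expect_gt(bc2$real$values[far], 3)
})

test_that("exact Wilcoxon matches brute-force enumeration and the n=6 floor", {
  # n = 6, all positive: the attainable floor
  p6 <- exact_wilcoxon_signed_rank(c(0.3, 1.2, 0.7, 2.2, 0.1, 0.9))
  expect_equal(as.numeric(p6), 2 / 64, tolerance = 1e-12)
  expect_equal(signif(as.numeric(p6), 3), 0.0312)
  # n = 5, all positive
  expect_equal(as.numeric(exact_wilcoxon_signed_rank(rep(1, 5) * (1:5))),
               0.0625, tolerance = 1e-12)
  # random cases incl. ties vs the 2^n enumeration oracle
  set.seed(69)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE) +
      round(rnorm(n), 1)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(as.numeric(exact_wilcoxon_signed_rank(d)),
                 oracle_wilcoxon_enum(d), tolerance = 1e-12)
  }
  # sign-flip symmetry
  d <- c(0.4, -1.1, 2.2, 0.6, -0.2, 1.4)
  expect_equal(as.numeric(exact_wilcoxon_signed_rank(d)),
               as.numeric(exact_wilcoxon_signed_rank(-d)), tolerance = 1e-12)
  # agreement with stats::wilcox.test in the tie-free exact regime
  set.seed(70)
  d2 <- rnorm(8)
  expect_equal(as.numeric(exact_wilcoxon_signed_rank(d2)),
               stats::wilcox.test(d2, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_warning(p0 <- exact_wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_equal(as.numeric(p0), 1)
  expect_warning(exact_wilcoxon_signed_rank(rnorm(30)), "approximation")
})

test_that("group significance map applies the exact test voxelwise", {
  grid <- make_grid(40, fix_cond)
  n <- nrow(grid$centers)
  set.seed(71)
  nulls <- lapply(1:6, function(i) fc_map(rnorm(n), grid))
  reals <- lapply(1:6, function(i) fc_map(rnorm(n), grid))
  # voxel 1: real == null for every subject -> p = 1
  for (i in 1:6) reals[[i]]$values[1] <- nulls[[i]]$values[1]
  # voxel 2: real > null for all subjects -> p = 0.03125 (floor)
  for (i in 1:6) reals[[i]]$values[2] <- nulls[[i]]$values[2] + 1
  suppressWarnings(g <- group_significance_map(reals, nulls))
  expect_equal(g$p$values[1], 1)
  expect_equal(g$p$values[2], 2 / 64, tolerance = 1e-12)
  expect_true(g$mask[2])
  gb <- suppressWarnings(group_significance_map(reals, nulls, bonferroni = TRUE))
  expect_false(any(gb$mask))   # floor 0.03125 > 0.05 / n
  expect_lte(sum(gb$mask), sum(g$mask))
})

test_that("pair confidence limit pools 6 x 100 mean-corrected points", {
  set.seed(72)
  nulls <- lapply(1:6, function(i) rnorm(100, mean = i / 10))
  real <- vapply(nulls, mean, 0) + 3
  dec <- pair_confidence_limit(real, nulls, 0.95)
  expect_length(dec$pooled_null, 600)
  expect_lt(abs(mean(dec$pooled_null)), 1e-12)
  expect_equal(dec$corrected_mean, 3, tolerance = 1e-12)
  expect_true(dec$significant)
  dec90 <- pair_confidence_limit(real, nulls, 0.90)
  expect_lt(dec90$limit, dec$limit)
  # calibration: real drawn from the null exceeds the limit ~5% of the time
  hits <- replicate(300, {
    ens <- lapply(1:6, function(i) rnorm(40))
    rv <- vapply(ens, function(v) sample(v, 1), 0)
    pair_confidence_limit(rv, ens, 0.95)$corrected_mean >
      pair_confidence_limit(rv, ens, 0.95)$limit
  })
  expect_lt(mean(hits), 0.12)
  expect_error(pair_confidence_limit(1, nulls[1], 0.95), "2 subjects")
})

test_that("spectrum-matched surrogates keep the target envelope spectrum and no coupling", {
  fs <- 200
  band <- freq_band("beta", 13, 30)
  ref <- data.frame(freq = seq(0.02, 2, by = 0.02))
  ref$power <- 1 / ref$freq     # 1/f envelope spectrum
  x1 <- spectrum_matched_envelope_source(ref, band, 60, fs, 73)
  x2 <- spectrum_matched_envelope_source(ref, band, 60, fs, 74)
  # measured envelope spectrum is 1/f-like: power at 0.1 Hz >> at 1 Hz
  env <- hilbert_envelope(x1) - mean(hilbert_envelope(x1))
  sp <- Mod(stats::fft(env))^2
  f <- (seq_along(env) - 1) * fs / length(env)
  pw_band <- function(lo, hi) mean(sp[f >= lo & f <= hi])
  expect_gt(pw_band(0.05, 0.2) / pw_band(0.8, 1.2), 3)
  # independent draws: null-level AEC
  e1 <- trim_edges(hilbert_envelope(x1), fs)
  e2 <- trim_edges(hilbert_envelope(x2), fs)
  expect_lt(abs(aec(e1, e2, 5, fs)$value), 0.25)
  expect_error(spectrum_matched_envelope_source(
    data.frame(freq = 1, power = -1), band, 10, fs, 1), "negative")
})
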