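test_that("covariance estimation removes means and matches sampling theory", {
  set.seed(31)
  M <- 12; n <- 5000
  X <- matrix(rnorm(M * n), M, n)
  C <- estimate_covariance(sensor_ts(X, 100))
  expect_equal(C$C, t(C$C), tolerance = 1e-14)
  expect_equal(diag(C$C), rep(1, M), tolerance = 0.1)
  offd <- C$C[upper.tri(C$C)]
  expect_lt(max(abs(offd)), 4 / sqrt(n))
  # constant channel -> zero row/col after mean removal
  X[3, ] <- 7
  C2 <- estimate_covariance(sensor_ts(X, 100))$C
  expect_equal(C2[3, ], rep(0, M), tolerance = 1e-15)
  # windowing equals covariance of the concatenated window
  w <- c(1:1000, 3001:4000)
  C3 <- estimate_covariance(sensor_ts(X, 100), w)$C
  C4 <- estimate_covariance(sensor_ts(X[, w], 100))$C
  expect_equal(C3, C4, tolerance = 1e-15)
  expect_error(estimate_covariance(sensor_ts(X, 100), integer(0)), "empty")
  expect_warning(estimate_covariance(sensor_ts(X, 100), 1:5), "rank-deficient")
})

test_that("noise floor is the minimum singular value", {
  expect_equal(noise_floor(diag(c(1, 2, 3))), 1)
  expect_equal(noise_floor(4.2 * diag(5)), 4.2)
  set.seed(32)
  for (i in 1:5) {
    C <- rand_spd(10)
    expect_equal(noise_floor(C),
                 min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
                 tolerance = 1e-10)
  }
})

test_that("weights satisfy unit gain and the closed form for isotropic covariance", {
  set.seed(33)
  cfg <- beamformer_config()
  for (i in 1:25) {
    M <- sample(6:24, 1)
    C <- rand_spd(M)
    L <- rnorm(M)
    W <- compute_weights(L, C, cfg)
    expect_lt(abs(sum(W * L) - 1), 1e-10)
  }
  # C + mu*sigma*I = c*I  =>  W = L / (L.L)
  M <- 10; L <- rnorm(M)
  W <- compute_weights(L, 2.5 * diag(M), cfg)
  expect_equal(as.numeric(W), L / sum(L * L), tolerance = 1e-10)
  expect_error(compute_weights(rnorm(4), matrix(0, 4, 4),
                               beamformer_config(mu = 0)), "singular")
})

test_that("weights equal the brute-force constrained-minimization oracle", {
  set.seed(34)
  cfg <- beamformer_config()
  for (i in 1:20) {
    M <- 8
    C <- rand_spd(M)
    L <- rnorm(M)
    sigma <- noise_floor(C)
    Creg <- C + cfg$mu * sigma * diag(M)
    W <- compute_weights(L, C, cfg)
    Wo <- oracle_constrained_min(L, Creg)
    expect_equal(as.numeric(W), Wo, tolerance = 1e-8)
    # minimality among random unit-gain competitors
    vW <- sum(W * (Creg %*% W))
    for (k in 1:10) {
      Z <- rnorm(M); Z <- Z / sum(Z * L)
      expect_gte(sum(Z * (Creg %*% Z)) + 1e-12, vW)
    }
  }
})

test_that("orientation solver matches a 0.1-degree grid-search oracle", {
  set.seed(35)
  arr <- fix_array16
  cfg <- beamformer_config()
  step <- pi / 1800
  for (i in 1:30) {
    dp <- rand_tangential_dipole()
    Lb <- lead_field_pair(arr, fix_cond, dp$location)
    C <- rand_spd(arr$M)
    d <- optimal_orientation(Lb, C, cfg)
    expect_gte(d, 0); expect_lt(d, pi)
    sigma <- noise_floor(C)
    Creg <- C + cfg$mu * sigma * diag(arr$M)
    vf <- function(dd) {
      L <- Lb %*% c(cos(dd), sin(dd))
      W <- solve(Creg, L); W <- W / sum(W * L)
      sum(W * (C %*% W))
    }
    grid_d <- seq(0, pi - step, by = step)
    vg <- vapply(grid_d, vf, 0)
    expect_lt(abs(vf(d) - max(vg)) / max(vg), 1e-5)
  }
  # isotropic covariance: degenerate case flagged
  Lb <- lead_field_pair(arr, fix_cond, c(0.02, 0.01, 0.04))
  expect_warning(optimal_orientation(Lb, diag(arr$M), cfg), "no source structure")
  expect_error(optimal_orientation(matrix(0, arr$M, 2), diag(arr$M), cfg),
               "degenerate")
})

test_that("orientation of a strong simulated source is recovered within 2 degrees", {
  set.seed(36)
  arr <- fix_array32
  band <- freq_band("beta", 13, 30)
  fs <- 200
  for (i in 1:5) {
    dp <- rand_tangential_dipole(rmax = 0.6)
    L <- lead_field(arr, fix_cond, dipole_spec(dp$location, dp$delta))
    s <- colored_noise_source(band, (2e-8)^2, 30, fs, 1000 + i)
    noise <- synth_sensor_noise(arr, 30, fs, 2000 + i, noise_sd = 1e-14)
    X <- outer(as.numeric(L), s) + noise$data
    C <- estimate_covariance(sensor_ts(fir_bandpass(X, band, fs), fs))
    Lb <- lead_field_pair(arr, fix_cond, dp$location)
    dhat <- optimal_orientation(Lb, C)
    err <- min(abs(dhat - dp$delta), pi - abs(dhat - dp$delta))
    expect_lt(err, 2 * pi / 180)
  }
})

test_that("projection is the stated inner product and achieves unit gain", {
  set.seed(37)
  arr <- fix_array16
  X <- matrix(rnorm(16 * 500), 16, 500)
  data <- sensor_ts(X, 100)
  W <- numeric(16); W[5] <- 1
  expect_equal(project(W, data), X[5, ])
  # noise-free single source, matched voxel: exact reconstruction
  L <- lead_field(arr, fix_cond, dipole_spec(c(0.03, 0, 0.04), 0.9))
  s <- sin(seq_len(500) / 10)
  Xs <- outer(as.numeric(L), s)
  W <- compute_weights(L, rand_spd(16), beamformer_config())
  expect_equal(project(W, sensor_ts(Xs, 100)), s, tolerance = 1e-8)
  expect_error(project(rnorm(8), data), "mismatch")
})

test_that("grid scan localizes a dipole and orders weights vs lead-field leakage", {
  ex <- quick_experiment(seed = 41, resting_s = 40, task_blocks = 1,
                         block_s = 10)
  # grid commensurate with the recipe's source lattice: off-lattice
  # sources are sampled off-peak and background activity can out-score
  # them on the noise-normalized map
  grid <- make_grid(20, fix_cond)
  scan <- scan_grid(grid, ex$data, ex$array, fix_cond, band = ex$recipe$band)
  # pseudo-Z peak within one grid step of a true source
  pk <- peak_location(fc_map(scan$pseudo_z, grid))
  dmin <- min(sqrt(rowSums(sweep(ex$recipe$source_locations, 2,
                                 pk$center)^2)))
  expect_lt(dmin * 1000, 20 * sqrt(3))
  # unit gain everywhere
  gains <- rowSums(scan$weights * scan$leadfields)
  expect_lt(max(abs(gains - 1)), 1e-8)
  # weights-correlation leakage is tighter than lead-field correlation
  seed_v <- nearest_voxel(grid, ex$recipe$source_locations[1, ])
  wc <- weights_correlation_map(scan, seed_v)
  lc <- lead_field_correlation_map(scan, seed_v)
  expect_equal(wc$values[seed_v], 1, tolerance = 1e-12)
  expect_equal(lc$values[seed_v], 1, tolerance = 1e-12)
  expect_true(all(wc$values <= 1 + 1e-12))
  expect_lt(volume_above(wc, 0.25), volume_above(lc, 0.25))
  # profile decays with distance on average (lead-field correlation:
  # at a 20 mm grid the adaptive weights decorrelate already at the
  # first neighbor, leaving no gradient to measure)
  prof <- correlation_vs_distance(lc, seed_v)
  expect_equal(prof$distance_mm[1], 0)
  expect_equal(prof$value[1], 1)
  near <- prof$value[prof$distance_mm > 0 & prof$distance_mm < 40]
  far <- prof$value[prof$distance_mm > 80]
  expect_gt(mean(near), mean(far))
})

test_that("resting-only and all-data covariance windows give different weights", {
  ex <- quick_experiment(seed = 42, resting_s = 30, task_blocks = 2,
                         block_s = 8)
  grid <- make_grid(25, fix_cond)
  s_all <- scan_grid(grid, ex$data, ex$array, fix_cond,
                     band = ex$recipe$band)
  s_rest <- scan_grid(grid, ex$data, ex$array, fix_cond,
                      beamformer_config(window_policy = "resting_only"),
                      band = ex$recipe$band, window = ex$truth$resting_idx)
  expect_gt(max(abs(s_all$weights - s_rest$weights)) /
              max(abs(s_all$weights)), 1e-3)
})

test_that("pseudo-T contrast is zero for identical windows and localizes suppression", {
  ex <- quick_experiment(seed = 43, resting_s = 30, task_blocks = 2,
                         block_s = 8, n_channels = 32)
  grid <- make_grid(15, fix_cond)
  scan <- scan_grid(grid, ex$data, ex$array, fix_cond, band = ex$recipe$band)
  w <- ex$truth$control_idx
  pt0 <- pseudo_t_map(scan, ex$data, w, w)
  expect_equal(pt0$values, rep(0, length(pt0$values)), tolerance = 1e-12)
  # beta suppression during "movement": map minimum near a true source
  pt <- pseudo_t_map(scan, ex$data, ex$truth$active_idx, ex$truth$control_idx)
  mn <- which.min(pt$values)
  dmin <- min(sqrt(rowSums(sweep(ex$recipe$source_locations, 2,
                                 grid$centers[mn, ])^2)))
  expect_lt(dmin * 1000, 15 * sqrt(3))
  # invariance to a global gain on the data
  data2 <- sensor_ts(ex$data$data * 3.2, ex$data$fs)
  scan2 <- scan_grid(grid, data2, ex$array, fix_cond, band = ex$recipe$band)
  pt2 <- pseudo_t_map(scan2, data2, ex$truth$active_idx, ex$truth$control_idx)
  expect_equal(pt2$values, pt$values, tolerance = 1e-6)
  expect_error(pseudo_t_map(scan, ex$data, integer(0), w), "non-empty")
})

test_that("volume_above counts voxels times voxel volume and is monotone", {
  grid <- make_grid(50, fix_cond)
  n <- nrow(grid$centers)
  expect_equal(volume_above(fc_map(rep(0, n), grid), 0.25), 0)
  expect_equal(volume_above(fc_map(rep(1, n), grid), 0.25), n * 0.125 * 1000)
  set.seed(44)
  m <- fc_map(runif(n), grid)
  vols <- vapply(seq(0, 1, by = 0.1), function(th) volume_above(m, th), 0)
  expect_true(all(diff(vols) <= 0))
})
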