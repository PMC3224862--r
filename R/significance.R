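# Simulation-based null framework: simulated dipole pairs with
# uncorrelated timecourses, null FC values/images, binned
# weights-correlation correction, percentile thresholds, confidence
# limits and exact Wilcoxon group statistics.

#' Band-limited Gaussian noise source
#'
#' Gaussian white noise colored by band-pass filtering, rescaled so the
#' sample variance equals `target_variance` exactly.
#'
#' @param band a [freq_band()].
#' @param target_variance variance of the returned series.
#' @param duration seconds.
#' @param fs Hz.
#' @param rng_seed integer seed (the caller's RNG stream is untouched).
#' @return numeric timecourse of length `round(duration * fs)`.
#' @export
colored_noise_source <- function(band, target_variance, duration, fs, rng_seed) {
  n <- round(duration * fs)
  x <- with_seed(rng_seed, stats::rnorm(n))
  x <- fir_bandpass(x, band, fs)
  x <- x - mean(x)
  x * sqrt(target_variance / stats::var(x))
}

#' Synthetic spatially correlated sensor noise
#'
#' Surrogate for an empty-room recording: Gaussian noise with a
#' low-rank spatial mixing plus a white floor, giving a full-rank
#' channel covariance. `floor_fraction` is the fraction of per-channel
#' variance carried by the white floor.
#'
#' @param array a [sensor_array()].
#' @param duration seconds.
#' @param fs Hz.
#' @param rng_seed integer seed.
#' @param spatial_rank rank of the correlated component (<= M).
#' @param floor_fraction in `[0, 1]`; 1 gives white noise.
#' @param noise_sd per-channel noise standard deviation in tesla
#'   (default 5e-14, i.e. 50 fT RMS: a ~5 fT/sqrt(Hz) magnetometer
#'   noise density integrated over a ~100 Hz acquisition band).
#' @return a [sensor_ts()].
#' @export
synth_sensor_noise <- function(array, duration, fs, rng_seed,
                               spatial_rank = 8, floor_fraction = 0.3,
                               noise_sd = 5e-14) {
  M <- array$M
  if (spatial_rank > M) stop("'spatial_rank' cannot exceed the channel count")
  n <- round(duration * fs)
  X <- with_seed(rng_seed, {
    A <- matrix(stats::rnorm(M * spatial_rank), M, spatial_rank)
    A <- A / sqrt(rowSums(A^2))          # unit spatial gain per channel
    Z <- matrix(stats::rnorm(spatial_rank * n), spatial_rank, n)
    W <- matrix(stats::rnorm(M * n), M, n)
    sqrt(1 - floor_fraction) * (A %*% Z) + sqrt(floor_fraction) * W
  })
  sensor_ts(X * noise_sd, fs)
}

#' Simulated two-dipole MEG dataset
#'
#' Two dipolar sources with independent band-limited Gaussian
#' timecourses (no built-in coupling), multiplied by their lead fields
#' and added to sensor noise. Each spec's `moment` is used as the
#' standard deviation of its source moment timecourse (A m), so the
#' simulated source variances can be matched to values estimated from
#' data.
#'
#' @param seed_spec,test_spec [dipole_spec()] objects.
#' @param noise a [sensor_ts()] of sensor noise (sets duration and fs).
#' @param band a [freq_band()].
#' @param rng_seed integer seed.
#' @param array a [sensor_array()].
#' @param conductor a [conductor_model()].
#' @return a [sensor_ts()] with attribute `sources` holding the two
#'   source timecourses.
#' @export
simulate_pair_dataset <- function(seed_spec, test_spec, noise, band, rng_seed,
                                  array, conductor) {
  fs <- noise$fs
  if (noise$M != array$M)
    stop("noise channel count does not match the sensor array")
  duration <- noise$n / fs
  s1 <- colored_noise_source(band, seed_spec$moment^2, duration, fs,
                             child_seed(rng_seed, 1))
  s2 <- colored_noise_source(band, test_spec$moment^2, duration, fs,
                             child_seed(rng_seed, 2))
  L1 <- lead_field(array, conductor, dipole_spec(seed_spec$location, seed_spec$delta))
  L2 <- lead_field(array, conductor, dipole_spec(test_spec$location, test_spec$delta))
  X <- outer(as.numeric(L1), s1) + outer(as.numeric(L2), s2) + noise$data
  out <- sensor_ts(X, fs)
  attr(out, "sources") <- cbind(s1, s2)
  out
}

# evaluate one FC metric between two projected source series
eval_metric <- function(metric, ts_seed, ts_test, delta, band, fs,
                        edge_trim = 1) {
  if (metric %in% c("AEC", "CAE")) {
    e1 <- trim_edges(hilbert_envelope(ts_seed), fs, edge_trim)
    e2 <- trim_edges(hilbert_envelope(ts_test), fs, edge_trim)
    if (metric == "AEC") aec(e1, e2, delta, fs)$value
    else cae(e1, e2, delta, fs)$value
  } else {
    t1 <- trim_edges(ts_seed, fs, edge_trim)
    t2 <- trim_edges(ts_test, fs, edge_trim)
    if (metric == "Coh") band_coherence(t1, t2, delta, band, fs)$value
    else band_icoh(t1, t2, delta, band, fs)$value
  }
}

#' Null FC values for a fixed voxel pair
#'
#' Repeats the two-dipole simulation `n_iter` times with fresh
#' uncorrelated source timecourses, projects each dataset through the
#' supplied beamformer weights (band-filtered first) and evaluates the
#' FC metric. This is the per-pair null ensemble used for confidence
#' limits.
#'
#' @param W_seed,W_test weight M-vectors used for the real data.
#' @param seed_spec,test_spec [dipole_spec()] objects (moment = source
#'   timecourse sd in A m).
#' @param noise a [sensor_ts()] sensor-noise dataset (re-used across
#'   iterations, as a fixed empty-room recording would be).
#' @param band a [freq_band()].
#' @param metric `"AEC"`, `"CAE"`, `"Coh"` or `"ICoh"`.
#' @param delta segment length (s).
#' @param n_iter iterations.
#' @param rng_seed integer seed.
#' @param array,conductor geometry.
#' @param edge_trim seconds trimmed per end after projection.
#' @return An object of class `null_ensemble`: values, metric, seeds.
#' @export
null_fc_pair <- function(W_seed, W_test, seed_spec, test_spec, noise, band,
                         metric, delta, n_iter, rng_seed, array, conductor,
                         edge_trim = 1) {
  fs <- noise$fs
  duration <- noise$n / fs
  Xn <- fir_bandpass(noise$data, band, fs)
  np_seed <- as.numeric(crossprod(W_seed, Xn))
  np_test <- as.numeric(crossprod(W_test, Xn))
  L1 <- lead_field(array, conductor, dipole_spec(seed_spec$location, seed_spec$delta))
  L2 <- lead_field(array, conductor, dipole_spec(test_spec$location, test_spec$delta))
  g <- c(s11 = sum(W_seed * L1), s12 = sum(W_seed * L2),
         t21 = sum(W_test * L1), t22 = sum(W_test * L2))
  seeds <- vapply(seq_len(n_iter), function(k) child_seed(rng_seed, k), 0L)
  vals <- vapply(seq_len(n_iter), function(k) {
    s1 <- colored_noise_source(band, seed_spec$moment^2, duration, fs,
                               child_seed(seeds[k], 1))
    s2 <- colored_noise_source(band, test_spec$moment^2, duration, fs,
                               child_seed(seeds[k], 2))
    ts_seed <- g["s11"] * s1 + g["s12"] * s2 + np_seed
    ts_test <- g["t21"] * s1 + g["t22"] * s2 + np_test
    eval_metric(metric, ts_seed, ts_test, delta, band, fs, edge_trim)
  }, 0)
  structure(list(values = vals, metric = metric, seeds = seeds,
                 n_iter = n_iter), class = "null_ensemble")
}

#' Null FC image
#'
#' For every test voxel, a fresh two-dipole dataset is simulated (seed
#' dipole fixed, test dipole at that voxel, uncorrelated timecourses),
#' projected through the same beamformer weights as the real data, and
#' the FC metric between seed and test voxel is evaluated. One dataset
#' per voxel by default, as in the single-subject procedure; the sensor
#' noise dataset is shared across voxels like a fixed empty-room
#' recording.
#'
#' @param scan a `beam_scan` (weights for the real data).
#' @param seed_index seed voxel index.
#' @param metric,delta,band,edge_trim as in [null_fc_pair()].
#' @param noise a [sensor_ts()].
#' @param rng_seed integer seed.
#' @param source_sd standard deviations (A m) of the simulated seed and
#'   test source moment timecourses (length-2, recycled).
#' @param array,conductor geometry.
#' @param n_iter datasets per voxel (values averaged when > 1).
#' @return An [fc_map()] of null FC values with attribute `seeds`.
#' @export
null_fc_image <- function(scan, seed_index, metric, delta, band, noise,
                          rng_seed, source_sd, array, conductor,
                          n_iter = 1, edge_trim = 1) {
  fs <- noise$fs
  duration <- noise$n / fs
  source_sd <- rep(source_sd, length.out = 2)
  Xn <- fir_bandpass(noise$data, band, fs)
  noise_p <- scan$weights %*% Xn            # projected noise, all voxels
  W_seed <- scan$weights[seed_index, ]
  L_seed <- scan$leadfields[seed_index, ]
  V <- nrow(scan$weights)
  vals <- numeric(V)
  for (v in seq_len(V)) {
    L_test <- scan$leadfields[v, ]
    W_test <- scan$weights[v, ]
    g11 <- sum(W_seed * L_seed); g12 <- sum(W_seed * L_test)
    g21 <- sum(W_test * L_seed); g22 <- sum(W_test * L_test)
    acc <- 0
    for (it in seq_len(n_iter)) {
      sk <- child_seed(rng_seed, v * 131L + it)
      s1 <- colored_noise_source(band, source_sd[1]^2, duration, fs,
                                 child_seed(sk, 1))
      s2 <- colored_noise_source(band, source_sd[2]^2, duration, fs,
                                 child_seed(sk, 2))
      ts_seed <- g11 * s1 + g12 * s2 + noise_p[seed_index, ]
      ts_test <- g21 * s1 + g22 * s2 + noise_p[v, ]
      acc <- acc + eval_metric(metric, ts_seed, ts_test, delta, band, fs,
                               edge_trim)
    }
    vals[v] <- acc / n_iter
  }
  out <- fc_map(vals, scan$grid, paste0("null_", metric))
  attr(out, "rng_seed") <- rng_seed
  out
}

#' Binned weights-correlation correction
#'
#' Voxels are binned by their weights correlation with the seed (bin
#' width 0.05 by default); the mean simulated (null) FC within each bin
#' is subtracted from both the real and the null map. Empty bins fall
#' back to the nearest populated bin (reported via attribute
#' `empty_bins`). Within each bin the correction is a constant shift,
#' so voxel rank order within a bin is preserved.
#'
#' @param fc_real,fc_null [fc_map()] objects on the same grid.
#' @param wc_map weights-correlation [fc_map()].
#' @param bin_width default 0.05.
#' @return list with corrected `real` and `null` maps, `bin_means`,
#'   `bin_edges`.
#' @export
binned_correction <- function(fc_real, fc_null, wc_map, bin_width = 0.05) {
  if (!same_grid(fc_real, fc_null) || !same_grid(fc_real, wc_map))
    stop("maps must share one grid")
  edges <- seq(0, 1 + bin_width, by = bin_width)
  bin <- findInterval(wc_map$values, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  means <- rep(NA_real_, nb)
  for (b in unique(bin)) means[b] <- mean(fc_null$values[bin == b])
  empty <- which(is.na(means))
  if (all(is.na(means))) stop("all weights-correlation bins are empty")
  if (length(empty) > 0) {
    filled <- which(!is.na(means))
    for (b in empty) means[b] <- means[filled[which.min(abs(filled - b))]]
  }
  corr <- means[bin]
  list(real = fc_map(fc_real$values - corr, fc_real$grid,
                     paste0(fc_real$label, "_corrected")),
       null = fc_map(fc_null$values - corr, fc_null$grid,
                     paste0(fc_null$label, "_corrected")),
       bin_means = means, bin_edges = edges,
       empty_bins = empty)
}

#' Upper-percentile significance threshold
#'
#' Thresholds the corrected real map at the given quantile of the
#' corrected null distribution (linear interpolation between order
#' statistics, `stats::quantile` type 7).
#'
#' @param corrected_real numeric vector or [fc_map()].
#' @param corrected_null numeric vector or [fc_map()] of null values.
#' @param quantile upper quantile, default 0.95 (the upper fifth
#'   percentile criterion).
#' @return An object of class `significance_decision`: `threshold`,
#'   logical `mask`, `procedure`.
#' @export
percentile_threshold <- function(corrected_real, corrected_null,
                                 quantile = 0.95) {
  if (!(quantile > 0 && quantile < 1)) stop("'quantile' must be in (0,1)")
  rv <- if (inherits(corrected_real, "fc_map")) corrected_real$values else corrected_real
  nv <- if (inherits(corrected_null, "fc_map")) corrected_null$values else corrected_null
  if (length(nv) < 20)
    warning("null distribution has fewer than 20 values; threshold unstable")
  thr <- unname(stats::quantile(nv, quantile, type = 7))
  structure(list(threshold = thr, mask = rv > thr,
                 procedure = "percentile_single_subject",
                 quantile = quantile),
            class = "significance_decision")
}

#' Group confidence limit for a voxel pair
#'
#' Subject-wise null means are subtracted from the real values
#' (corrected FC); the mean-corrected null ensembles are concatenated
#' across subjects into one pooled distribution whose upper `level`
#' quantile is the confidence limit. With 6 subjects and 100 iterations
#' each, the pool has 600 points.
#'
#' @param real_values numeric vector, one FC value per subject.
#' @param null_ensembles list of per-subject `null_ensemble` objects or
#'   numeric vectors.
#' @param level confidence level, default 0.95 (0.90 supported for the
#'   weak-effect variant).
#' @return list with `corrected_mean`, `se`, `limit`, `significant`,
#'   `pooled_null`, class `significance_decision`.
#' @export
pair_confidence_limit <- function(real_values, null_ensembles, level = 0.95) {
  nsub <- length(real_values)
  if (length(null_ensembles) != nsub)
    stop("one null ensemble per subject is required")
  if (nsub < 2)
    stop("standard error across subjects needs at least 2 subjects")
  nulls <- lapply(null_ensembles, function(e)
    if (inherits(e, "null_ensemble")) e$values else as.numeric(e))
  null_means <- vapply(nulls, mean, 0)
  corrected <- real_values - null_means
  pooled <- unlist(lapply(nulls, function(v) v - mean(v)))
  limit <- unname(stats::quantile(pooled, level, type = 7))
  structure(list(corrected_mean = mean(corrected),
                 se = stats::sd(corrected) / sqrt(nsub),
                 corrected = corrected,
                 limit = limit, level = level,
                 significant = mean(corrected) > limit,
                 pooled_null = pooled,
                 procedure = "confidence_limit_pair"),
            class = "significance_decision")
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided p-value for paired differences by exact enumeration of all
#' 2^n sign assignments (computed by convolution over the tied-rank
#' generating function, which is equivalent to full enumeration and
#' handles ties in |d| exactly). Zero differences are dropped first, the
#' standard convention. For n > 25 a normal approximation with
#' continuity correction is used and flagged with a warning.
#'
#' @param differences numeric vector of paired differences.
#' @return two-sided p-value with attributes `statistic` (W+) and `n`.
#' @export
exact_wilcoxon_signed_rank <- function(differences) {
  d <- differences[differences != 0]
  if (length(d) == 0) {
    warning("all differences are zero; p = 1")
    return(structure(1, statistic = NA_real_, n = 0L))
  }
  n <- length(d)
  r <- rank(abs(d))               # average ranks under ties
  w <- sum(r[d > 0])
  if (n > 25) {
    warning("n > 25: using normal approximation")
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (abs(w - mu) - 0.5) / sig
    p <- 2 * stats::pnorm(-z)
    return(structure(min(1, p), statistic = w, n = n))
  }
  # exact null distribution of 2*W+ over integer support
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1)      # index = value of 2*W+ + 1
  dist[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(total + 1 - ri)])
    dist <- (dist + shifted) / 2
  }
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  p <- min(1, 2 * min(p_le, p_ge))
  structure(p, statistic = w, n = n)
}

#' Group-level Wilcoxon significance map
#'
#' Per voxel, the exact two-sided Wilcoxon signed-rank p for the paired
#' (real - null) FC values across subjects, with a p < `alpha` mask.
#' Functional images are not corrected for multiple comparisons by
#' default; `bonferroni = TRUE` divides alpha by the voxel count.
#'
#' @param real_maps,null_maps lists of per-subject [fc_map()] objects on
#'   a common grid.
#' @param alpha significance level (default 0.05).
#' @param bonferroni logical.
#' @return list of class `significance_decision` with `p` ([fc_map()]),
#'   `mask`, `alpha_used`.
#' @export
group_significance_map <- function(real_maps, null_maps, alpha = 0.05,
                                   bonferroni = FALSE) {
  if (length(real_maps) != length(null_maps))
    stop("equal numbers of real and null maps are required")
  for (m in c(real_maps, null_maps))
    if (!same_grid(m, real_maps[[1]])) stop("maps must share one grid")
  R <- do.call(rbind, lapply(real_maps, function(m) m$values))
  N <- do.call(rbind, lapply(null_maps, function(m) m$values))
  D <- R - N
  p <- apply(D, 2, function(dv) as.numeric(exact_wilcoxon_signed_rank(dv)))
  V <- ncol(D)
  a <- if (bonferroni) alpha / V else alpha
  grid <- real_maps[[1]]$grid
  structure(list(p = fc_map(p, grid, "wilcoxon_p"),
                 mask = p < a, alpha_used = a,
                 procedure = "wilcoxon_group"),
            class = "significance_decision")
}

#' Envelope-spectrum-matched surrogate source
#'
#' Band-limited carrier amplitude-modulated so that the Hilbert envelope
#' of the result has (approximately) a prescribed power spectrum, with
#' randomized envelope phases so no coupling is introduced. Used to
#' check that FC results are not driven by univariate envelope spectral
#' content.
#'
#' @param reference_envelope_spectrum data.frame with columns `freq`
#'   (Hz) and `power` (nonnegative); interpreted as the target envelope
#'   power spectral density up to scale. Interpolated onto the FFT grid.
#' @param band carrier [freq_band()].
#' @param duration seconds.
#' @param fs Hz.
#' @param rng_seed integer seed.
#' @param mod_depth modulation depth in (0, 1); default 0.5.
#' @return numeric timecourse with attribute `envelope` (the target
#'   modulator).
#' @export
spectrum_matched_envelope_source <- function(reference_envelope_spectrum,
                                             band, duration, fs, rng_seed,
                                             mod_depth = 0.5) {
  spec <- reference_envelope_spectrum
  if (any(spec$power < 0)) stop("infeasible reference spectrum: negative power")
  n <- round(duration * fs)
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  pw <- stats::approx(spec$freq, spec$power, xout = freqs, rule = 2)$y
  pw[1] <- 0
  mod <- with_seed(child_seed(rng_seed, 1), {
    ph <- stats::runif(length(freqs), 0, 2 * pi)
    amp <- sqrt(pw)
    half <- amp * exp(1i * ph)
    full <- complex(real = numeric(n))
    full[seq_along(half)] <- half
    if (n %% 2 == 0) {
      full[(n / 2 + 2):n] <- Conj(half[(n / 2):2])
      full[n / 2 + 1] <- Re(half[n / 2 + 1])
    } else {
      full[((n + 1) / 2 + 1):n] <- Conj(half[((n + 1) / 2):2])
    }
    Re(stats::fft(full, inverse = TRUE))
  })
  sdm <- stats::sd(mod)
  mod <- if (sdm > 0) mod / sdm else mod * 0
  env <- 1 + mod_depth * mod
  clipped <- env < 0.05
  if (any(clipped)) env[clipped] <- 0.05
  carrier <- unit_envelope_carrier(band, duration, fs, child_seed(rng_seed, 2))
  out <- env * carrier
  attr(out, "envelope") <- env
  attr(out, "clipped_fraction") <- mean(clipped)
  out
}

# band-limited carrier whose analytic-signal modulus is exactly 1
unit_envelope_carrier <- function(band, duration, fs, rng_seed) {
  x <- colored_noise_source(band, 1, duration, fs, rng_seed)
  a <- analytic_signal(x)
  m <- Mod(a)
  m[m == 0] <- 1
  Re(a / m)
}
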