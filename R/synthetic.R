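# Synthetic-data generators: sensor helmets, coupled dipole pairs with
# known envelope coupling, full resting + localizer experiments, and
# matched "hemodynamic" 4-D volumes. Every generator is a pure function
# of (parameters, seed).

#' Quasi-uniform sensor helmet
#'
#' Deterministic Fibonacci-lattice points on a spherical cap of the
#' given radius, radially oriented; an abstract stand-in for a
#' whole-head magnetometer helmet.
#'
#' @param n_channels number of sensors (>= 8).
#' @param helmet_radius sphere radius in meters (default 0.12).
#' @param coverage fraction of the full sphere covered by the cap,
#'   starting from the top (default 0.6).
#' @param center helmet center (conductor center), meters.
#' @return a [sensor_array()].
#' @export
make_sensor_array <- function(n_channels = 64, helmet_radius = 0.12,
                              coverage = 0.6, center = c(0, 0, 0)) {
  if (n_channels < 8) stop("need at least 8 channels")
  i <- seq_len(n_channels) - 0.5
  # z from top of sphere down through the cap
  z <- 1 - 2 * coverage * i / n_channels
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(1 - z^2)
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  pos <- sweep(dirs * helmet_radius, 2, center, "+")
  sensor_array(pos, dirs)
}

# positive slow modulator: low-pass filtered Gaussian noise, rectified
# and re-smoothed, normalized to mean 1. Bandwidth <= `bw` Hz.
slow_modulator <- function(n, fs, bw, rng_seed) {
  x <- with_seed(rng_seed, stats::rnorm(n + 4 * round(fs / bw)))
  sigma <- fs / (2 * pi * bw)
  half <- ceiling(4 * sigma)
  k <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  k <- k / sum(k)
  sm <- conv_same(x, k)
  sm <- abs(sm)
  sm <- conv_same(sm, k)
  sm <- sm[(length(sm) - n + 1):length(sm)]
  sm / mean(sm)
}

#' Band-limited source pair with controllable envelope coupling
#'
#' Each source is band-limited Gaussian carrier noise multiplied by a
#' positive slow modulator; the two modulators share a common component
#' with weight `alpha` (`envelope_i = alpha * shared + (1 - alpha) *
#' private_i`). The carriers are always independent, so at `alpha = 1`
#' the slow envelopes are identical while zero-lag carrier correlation
#' stays near zero: envelope metrics see coupling, phase metrics do
#' not. Because the carrier contributes its own fast envelope jitter,
#' the measurable AEC at `alpha = 1` is well below 1; the achievable
#' ceiling is quantified by [calibrate_coupling()].
#'
#' @param band a [freq_band()].
#' @param alpha envelope coupling in `[0, 1]`.
#' @param duration seconds.
#' @param fs Hz.
#' @param variances length-2 variances of the two source timecourses
#'   (A m)^2; default `(2e-8)^2` each (tens of nA m amplitude).
#' @param rng_seed integer seed.
#' @param mod_bw modulator bandwidth in Hz (default 0.5, consistent with
#'   envelope power concentrated below ~1 Hz).
#' @return list `s1`, `s2` (timecourses) and `truth` (envelopes, alpha,
#'   parameters).
#' @export
make_coupled_pair <- function(band, alpha, duration, fs,
                              variances = c(4e-16, 4e-16), rng_seed = 1,
                              mod_bw = 0.5) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  n <- round(duration * fs)
  shared <- slow_modulator(n, fs, mod_bw, child_seed(rng_seed, 1))
  p1 <- slow_modulator(n, fs, mod_bw, child_seed(rng_seed, 2))
  p2 <- slow_modulator(n, fs, mod_bw, child_seed(rng_seed, 3))
  e1 <- alpha * shared + (1 - alpha) * p1
  e2 <- alpha * shared + (1 - alpha) * p2
  c1 <- colored_noise_source(band, 1, duration, fs, child_seed(rng_seed, 4))
  c2 <- colored_noise_source(band, 1, duration, fs, child_seed(rng_seed, 5))
  s1 <- e1 * c1; s2 <- e2 * c2
  s1 <- (s1 - mean(s1)) * sqrt(variances[1] / stats::var(s1))
  s2 <- (s2 - mean(s2)) * sqrt(variances[2] / stats::var(s2))
  list(s1 = s1, s2 = s2,
       truth = list(envelope1 = e1, envelope2 = e2, alpha = alpha,
                    band = band, fs = fs, rng_seed = rng_seed,
                    mod_bw = mod_bw))
}

#' Coupling-to-AEC calibration curve
#'
#' Monte-Carlo mapping from the generator's envelope-coupling parameter
#' `alpha` to the expected AEC measured on the source timecourses
#' themselves (no sensors, no beamformer): the ceiling an ideal
#' reconstruction could reach. Returns per-alpha means and standard
#' errors.
#'
#' @param band,delta,duration,fs as elsewhere.
#' @param alpha_grid numeric vector of coupling values.
#' @param n_rep Monte-Carlo repetitions per alpha (>= 10).
#' @param rng_seed integer seed.
#' @param edge_trim seconds trimmed from the envelopes.
#' @param local_background ratio of co-located uncoupled broadband
#'   activity to source amplitude (0 = pure coupled pair, the ideal
#'   ceiling; 1 matches the default [experiment_recipe()] world). The
#'   in-band part of this local activity dilutes the measurable AEC,
#'   and the calibration must reflect it when the generated experiments
#'   contain it.
#' @param bp_band band used by the calibration's measurement filter;
#'   defaults to `band`.
#' @return data.frame with columns `alpha`, `aec`, `se`.
#' @export
calibrate_coupling <- function(band, delta, duration, fs,
                               alpha_grid = seq(0, 1, by = 0.25),
                               n_rep = 20, rng_seed = 1, edge_trim = 1,
                               local_background = 0, bp_band = band) {
  if (n_rep < 10) stop("'n_rep' must be >= 10")
  bg_band <- freq_band("background", 1, min(70, 0.45 * fs))
  rows <- lapply(seq_along(alpha_grid), function(i) {
    a <- alpha_grid[i]
    vals <- vapply(seq_len(n_rep), function(k) {
      p <- make_coupled_pair(band, a, duration, fs,
                             rng_seed = child_seed(rng_seed, i * 1000L + k))
      s1 <- p$s1; s2 <- p$s2
      if (local_background > 0) {
        lb_var <- local_background^2 * stats::var(p$s1)
        s1 <- s1 + colored_noise_source(bg_band, lb_var, duration, fs,
                                        child_seed(rng_seed, i * 1000L + k + 500000L))
        s2 <- s2 + colored_noise_source(bg_band, lb_var, duration, fs,
                                        child_seed(rng_seed, i * 1000L + k + 600000L))
        s1 <- fir_bandpass(s1, bp_band, fs)
        s2 <- fir_bandpass(s2, bp_band, fs)
      }
      e1 <- trim_edges(hilbert_envelope(s1), fs, edge_trim)
      e2 <- trim_edges(hilbert_envelope(s2), fs, edge_trim)
      aec(e1, e2, delta, fs)$value
    }, 0)
    data.frame(alpha = a, aec = mean(vals),
               se = stats::sd(vals) / sqrt(n_rep))
  })
  do.call(rbind, rows)
}

#' Experiment recipe
#'
#' The stated world for a synthetic resting + localizer experiment. The
#' desk-scale defaults (64 channels, 100 s resting, 300 Hz, 10 mm grid)
#' keep full pipelines tractable; [paper_scale_recipe()] gives the
#' full-scale variant (275 channels, 300 s, 600 Hz, 5 mm).
#'
#' @param resting_s resting-phase duration (s).
#' @param task_blocks number of task blocks; each is `block_s` of
#'   "movement" (band power suppressed) followed by `block_s` of rest.
#' @param block_s block half-length (s).
#' @param fs sampling rate (Hz).
#' @param band oscillation [freq_band()] of the simulated pair.
#' @param alpha envelope coupling in the resting phase.
#' @param source_locations 2 x 3 matrix (m); defaults to left/right
#'   "sensorimotor" positions.
#' @param source_sd source moment sd (A m) per source.
#' @param task_suppression multiplicative amplitude factor during task
#'   blocks (default 0.4: a beta-power decrease during movement).
#' @param n_background number of uncoupled broadband background dipoles
#'   at random locations (default 8). Resting cortex is active in every
#'   band; without this background, analysis bands away from the coupled
#'   band would contain nothing but filter-skirt leak-through of the
#'   coupled pair, which no real recording looks like.
#' @param background_sd moment sd (A m) of each background dipole
#'   (default 1e-8, half the coupled-source amplitude).
#' @param local_background_sd moment sd (A m) of the uncoupled broadband
#'   activity co-located with each source of interest (default equal to
#'   `source_sd`): the sites of interest are themselves active in every
#'   band, not only in the coupled band.
#' @param noise_args list passed to [synth_sensor_noise()].
#' @param grid_spacing_mm reconstruction grid spacing.
#' @param rng_seed integer seed.
#' @return list of class `experiment_recipe`.
#' @export
experiment_recipe <- function(resting_s = 100, task_blocks = 2, block_s = 15,
                              fs = 300, band = freq_band("beta", 13, 30),
                              alpha = 0.8,
                              source_locations = rbind(c(0.04, 0, 0.04),
                                                       c(-0.04, 0, 0.04)),
                              source_sd = c(2e-8, 2e-8),
                              task_suppression = 0.4,
                              n_background = 8, background_sd = 1e-8,
                              local_background_sd = NULL,
                              noise_args = list(spatial_rank = 8,
                                                floor_fraction = 0.3,
                                                noise_sd = 5e-14),
                              grid_spacing_mm = 10, rng_seed = 1) {
  structure(as.list(environment()), class = "experiment_recipe")
}

#' Full-scale experiment recipe
#' @param ... overrides passed to [experiment_recipe()].
#' @export
paper_scale_recipe <- function(...) {
  args <- list(resting_s = 300, task_blocks = 10, block_s = 30, fs = 600,
               grid_spacing_mm = 5, ...)
  do.call(experiment_recipe, args)
}

#' Generate a synthetic experiment
#'
#' Resting phase: the coupled pair at the recipe's `alpha`. Task phase:
#' alternating "movement" / rest blocks in which the sources' band
#' amplitude is multiplied by `task_suppression` during movement
#' (emulating a task-induced beta power decrease). Spatially correlated
#' sensor noise is added throughout. Ground truth (timecourses,
#' envelopes, phase windows, geometry) is attached.
#'
#' @param recipe an [experiment_recipe()].
#' @param array a [sensor_array()].
#' @param conductor a [conductor_model()].
#' @return a [sensor_ts()] with attribute `truth`.
#' @export
make_experiment <- function(recipe, array, conductor) {
  r <- recipe
  fs <- r$fs
  task_s <- 2 * r$block_s * r$task_blocks
  total_s <- r$resting_s + task_s
  n_rest <- round(r$resting_s * fs)
  n_total <- round(total_s * fs)
  pair <- make_coupled_pair(r$band, r$alpha, total_s, fs,
                            variances = r$source_sd^2,
                            rng_seed = child_seed(r$rng_seed, 1))
  gain <- rep(1, n_total)
  if (r$task_blocks > 0 && task_s > 0) {
    nb <- round(r$block_s * fs)
    for (b in seq_len(r$task_blocks)) {
      from <- n_rest + (b - 1) * 2 * nb + 1
      gain[from:(from + nb - 1)] <- r$task_suppression
    }
  }
  s1 <- pair$s1 * gain
  s2 <- pair$s2 * gain
  B1 <- tangential_basis(r$source_locations[1, ], conductor$center)
  B2 <- tangential_basis(r$source_locations[2, ], conductor$center)
  d1 <- dipole_spec(r$source_locations[1, ], delta = 0.3)
  d2 <- dipole_spec(r$source_locations[2, ], delta = 1.2)
  L1 <- lead_field(array, conductor, d1)
  L2 <- lead_field(array, conductor, d2)
  noise <- do.call(synth_sensor_noise,
                   c(list(array = array, duration = total_s, fs = fs,
                          rng_seed = child_seed(r$rng_seed, 2)),
                     r$noise_args))
  X <- outer(as.numeric(L1), s1) + outer(as.numeric(L2), s2) + noise$data
  # uncoupled broadband background activity across the brain
  bg <- list()
  bg_band <- freq_band("background", 1, min(70, 0.45 * fs))
  lb_sd <- if (is.null(r$local_background_sd)) r$source_sd else
    rep(r$local_background_sd, length.out = 2)
  local_bg <- matrix(0, n_total, 2)
  for (i in 1:2) {
    if (lb_sd[i] > 0) {
      sb <- colored_noise_source(bg_band, lb_sd[i]^2, total_s, fs,
                                 child_seed(r$rng_seed, 50L + i))
      L <- if (i == 1) L1 else L2
      X <- X + outer(as.numeric(L), sb)
      local_bg[, i] <- sb
    }
  }
  if (r$n_background > 0) {
    for (k in seq_len(r$n_background)) {
      sk <- child_seed(r$rng_seed, 100L + k)
      loc <- with_seed(sk, {
        u <- stats::rnorm(3)
        u / sqrt(sum(u^2)) * stats::runif(1, 0.25, 0.65) * conductor$radius
      }) + conductor$center
      db <- dipole_spec(loc, with_seed(child_seed(sk, 1), stats::runif(1, 0, pi)))
      sb <- colored_noise_source(bg_band, r$background_sd^2, total_s, fs,
                                 child_seed(sk, 2))
      X <- X + outer(as.numeric(lead_field(array, conductor, db)), sb)
      bg[[k]] <- db
    }
  }
  out <- sensor_ts(X, fs)
  attr(out, "truth") <- list(
    s1 = s1, s2 = s2, local_bg = local_bg, envelopes = pair$truth,
    gain = gain, dipoles = list(d1, d2), background = bg, recipe = r,
    resting_idx = seq_len(n_rest),
    task_idx = if (task_s > 0) (n_rest + 1):n_total else integer(0),
    active_idx = which(gain < 1),
    control_idx = which(gain == 1 & seq_len(n_total) > n_rest))
  out
}

#' Synthetic "hemodynamic" 4-D volume
#'
#' Two Gaussian-profile blobs centered on the source locations whose
#' timecourses share a slow common component weighted by `coupling`,
#' plus spatially smooth background noise: a stand-in for a resting
#' fcMRI acquisition co-localized with the simulated MEG sources.
#'
#' @param grid a [make_grid()] grid.
#' @param source_locations 2 x 3 matrix (m).
#' @param coupling in `[0, 1]`.
#' @param TR sampling interval (s), default 1.5.
#' @param duration seconds, default 300.
#' @param blob_fwhm_mm spatial extent of the blobs (default 15).
#' @param noise_sd background noise sd relative to blob amplitude 1
#'   (default 0.5).
#' @param rng_seed integer seed.
#' @return a [fourd_volume()] with attribute `truth`.
#' @export
make_hemodynamic_volume <- function(grid, source_locations, coupling,
                                    TR = 1.5, duration = 300,
                                    blob_fwhm_mm = 15, noise_sd = 0.5,
                                    rng_seed = 1) {
  if (TR <= 0) stop("'TR' must be positive")
  nt <- round(duration / TR)
  fs_eff <- 1 / TR
  shared <- slow_modulator(nt, fs_eff, 0.05, child_seed(rng_seed, 1))
  p1 <- slow_modulator(nt, fs_eff, 0.05, child_seed(rng_seed, 2))
  p2 <- slow_modulator(nt, fs_eff, 0.05, child_seed(rng_seed, 3))
  t1 <- coupling * shared + (1 - coupling) * p1
  t2 <- coupling * shared + (1 - coupling) * p2
  scale01 <- function(x) (x - mean(x)) / stats::sd(x)
  t1 <- scale01(t1); t2 <- scale01(t2)
  sig2 <- (blob_fwhm_mm / 1000 / 2.3548)^2
  w1 <- exp(-rowSums(sweep(grid$centers, 2, source_locations[1, ])^2) / (2 * sig2))
  w2 <- exp(-rowSums(sweep(grid$centers, 2, source_locations[2, ])^2) / (2 * sig2))
  V <- nrow(grid$centers)
  noise <- with_seed(child_seed(rng_seed, 4),
                     matrix(stats::rnorm(V * nt), V, nt))
  # spatial smoothing of the noise for realistic smoothness
  nmap_grid <- grid
  for (tt in seq_len(nt)) {
    m <- gaussian_smooth(fc_map(noise[, tt], nmap_grid), blob_fwhm_mm / 2)
    noise[, tt] <- m$values
  }
  noise <- noise / stats::sd(noise)
  data <- outer(w1, t1) + outer(w2, t2) + noise_sd * noise
  out <- fourd_volume(data, grid, TR)
  attr(out, "truth") <- list(t1 = t1, t2 = t2, w1 = w1, w2 = w2,
                             coupling = coupling, rng_seed = rng_seed)
  out
}
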