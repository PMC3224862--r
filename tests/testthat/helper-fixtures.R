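# Shared small fixtures, built in code at load time.

fix_cond <- conductor_model()

fix_array16 <- make_sensor_array(16)
fix_array32 <- make_sensor_array(32)

# array with non-radial sensing directions: on radially oriented sensors
# the volume-current field contribution vanishes identically, so oracle
# comparisons must use tilted sensors to exercise it
fix_array_tilted <- local({
  base <- make_sensor_array(16)
  radial <- base$orientations
  tang <- t(vapply(seq_len(base$M), function(i)
    tangential_basis(base$positions[i, ])[, 1], numeric(3)))
  ori <- radial + 0.8 * tang
  sensor_array(base$positions, ori / sqrt(rowSums(ori^2)))
})

# random SPD matrix with a controllable condition
rand_spd <- function(m, n_obs = 4 * m) {
  A <- matrix(stats::rnorm(m * n_obs), m, n_obs)
  tcrossprod(A) / n_obs
}

# random tangential dipole inside the conductor
rand_tangential_dipole <- function(cond = fix_cond, rmin = 0.2, rmax = 0.65) {
  r0 <- stats::rnorm(3)
  r0 <- r0 / sqrt(sum(r0^2)) * stats::runif(1, rmin, rmax) * cond$radius
  B <- tangential_basis(r0, cond$center)
  list(location = r0 + cond$center, delta = stats::runif(1, 0, pi), basis = B)
}

# small resting-only experiment used by several tests
quick_experiment <- function(seed = 1, resting_s = 40, fs = 200,
                             n_channels = 32, task_blocks = 0, ...) {
  arr <- make_sensor_array(n_channels)
  recipe <- experiment_recipe(resting_s = resting_s, task_blocks = task_blocks,
                              fs = fs, rng_seed = seed, ...)
  data <- make_experiment(recipe, arr, fix_cond)
  list(array = arr, recipe = recipe, data = data,
       truth = attr(data, "truth"))
}

nearest_voxel <- function(grid, location) {
  which.min(rowSums(sweep(grid$centers, 2, location)^2))
}
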