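# Volumetric-map comparison: smoothing, spatial correlation, overlap,
# seed-based correlation volumes and Bonferroni thresholding.

gauss_kernel_1d <- function(fwhm_mm, spacing_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  if (sigma == 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  k / sum(k)
}

conv_axis <- function(arr, k, axis) {
  if (length(k) == 1) return(arr)
  d <- dim(arr)
  half <- (length(k) - 1) / 2
  out <- array(0, d)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, da[1], da[2] * da[3])
  padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  res <- matrix(0, da[1], ncol(m))
  for (i in seq_along(k))
    res <- res + k[i] * padded[i:(i + da[1] - 1), , drop = FALSE]
  out <- array(res, da)
  aperm(out, order(perm))
}

#' Gaussian smoothing of a volumetric map
#'
#' Separable Gaussian convolution with the given full width at half
#' maximum. Out-of-mask voxels are treated as zero-valued with weight
#' renormalization at the mask boundary, so a constant map stays
#' constant and values away from the edge conserve their local sum.
#' `fwhm_mm = 0` is the identity.
#'
#' @param map an [fc_map()].
#' @param fwhm_mm kernel FWHM in millimeters.
#' @return a smoothed [fc_map()].
#' @export
gaussian_smooth <- function(map, fwhm_mm) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(map)
  k <- gauss_kernel_1d(fwhm_mm, map$grid$spacing_mm)
  vals <- map_to_array(map, fill = 0)
  mask <- map_to_array(fc_map(rep(1, length(map$values)), map$grid), fill = 0)
  for (ax in 1:3) {
    vals <- conv_axis(vals, k, ax)
    mask <- conv_axis(mask, k, ax)
  }
  sm <- vals
  nz <- mask > 1e-12
  sm[nz] <- vals[nz] / mask[nz]
  array_to_map(sm, map$grid, paste0(map$label, "_smoothed"))
}

#' Spatial correlation between two maps
#'
#' Pearson correlation between the vectorized in-mask voxel values of
#' two maps on a common grid. Optionally voxels within
#' `exclude_radius_mm` of a seed voxel are dropped first: close to the
#' seed both maps are dominated by point-spread/leakage rather than by
#' connectivity, and the exclusion variant compares only the distal
#' structure.
#'
#' @param map_a,map_b [fc_map()] objects on the same grid.
#' @param seed_index optional seed voxel index (required when
#'   `exclude_radius_mm > 0`).
#' @param exclude_radius_mm radius of the excluded seed neighborhood
#'   (default 0: whole-brain comparison).
#' @return scalar correlation.
#' @export
spatial_correlation <- function(map_a, map_b, seed_index = NULL,
                                exclude_radius_mm = 0) {
  if (!same_grid(map_a, map_b)) stop("maps are not on the same grid")
  keep <- rep(TRUE, length(map_a$values))
  if (exclude_radius_mm > 0) {
    if (is.null(seed_index))
      stop("'seed_index' is required when excluding a seed neighborhood")
    ctr <- map_a$grid$centers
    d <- sqrt(rowSums((ctr - matrix(ctr[seed_index, ], nrow(ctr), 3,
                                    byrow = TRUE))^2)) * 1000
    keep <- d > exclude_radius_mm
  }
  stats::cor(map_a$values[keep], map_b$values[keep])
}

#' Overlap volume of two thresholded masks
#'
#' @param mask_a,mask_b logical vectors (or [fc_map()]s of 0/1) on the
#'   same grid.
#' @param spacing_mm voxel spacing (taken from the map when available).
#' @return list with `volume_cm3` (intersection), `fraction`
#'   (Jaccard: intersection / union), `volume_a_cm3`, `volume_b_cm3`.
#' @export
overlap_volume <- function(mask_a, mask_b, spacing_mm = NULL) {
  get_mask <- function(m) if (inherits(m, "fc_map")) m$values > 0 else as.logical(m)
  if (inherits(mask_a, "fc_map") && is.null(spacing_mm))
    spacing_mm <- mask_a$grid$spacing_mm
  a <- get_mask(mask_a); b <- get_mask(mask_b)
  if (length(a) != length(b)) stop("masks differ in length")
  vv <- (spacing_mm / 10)^3
  inter <- sum(a & b); uni <- sum(a | b)
  list(volume_cm3 = inter * vv,
       fraction = if (uni == 0) 0 else inter / uni,
       volume_a_cm3 = sum(a) * vv, volume_b_cm3 = sum(b) * vv)
}

#' Seed-based correlation volume
#'
#' The seed timecourse is the average over the seed voxel and its up to
#' 26 lattice neighbors inside the mask (fewer at the boundary; count
#' reported); the map is the Pearson correlation between this seed
#' timecourse and every voxel's timecourse. Zero-variance voxels get 0.
#'
#' @param vol a [fourd_volume()].
#' @param seed_index voxel index of the seed.
#' @return an [fc_map()] with attributes `n_seed_voxels`,
#'   `n_zero_variance`.
#' @export
seed_correlation_volume <- function(vol, seed_index) {
  ijk <- vol$grid$ijk
  d <- abs(ijk - matrix(ijk[seed_index, ], nrow(ijk), 3, byrow = TRUE))
  nb <- which(apply(d, 1, max) <= 1)        # 27-cell neighborhood incl. seed
  seed_tc <- colMeans(vol$data[nb, , drop = FALSE])
  sds <- apply(vol$data, 1, stats::sd)
  vals <- rep(0, nrow(vol$data))
  ok <- sds > 0 & stats::sd(seed_tc) > 0
  vals[ok] <- apply(vol$data[ok, , drop = FALSE], 1, stats::cor, y = seed_tc)
  out <- fc_map(vals, vol$grid, "seed_correlation")
  attr(out, "n_seed_voxels") <- length(nb)
  attr(out, "n_zero_variance") <- sum(!ok)
  out
}

#' Bonferroni-corrected correlation threshold
#'
#' Converts a correlation map to a significance mask: the critical
#' correlation is obtained from the two-sided t-transform
#' `t = r sqrt(df / (1 - r^2))` with `df = n_timepoints - 2` at level
#' `alpha / n_tests`, and voxels with `|r|` at or above it are flagged.
#'
#' @param map correlation [fc_map()].
#' @param n_timepoints timecourse length behind the correlations.
#' @param n_tests number of comparisons (e.g. voxel count).
#' @param alpha family-wise level, default 0.05.
#' @return logical mask with attribute `r_critical`.
#' @export
bonferroni_threshold <- function(map, n_timepoints, n_tests, alpha = 0.05) {
  if (n_tests <= 0) stop("'n_tests' must be positive")
  df <- n_timepoints - 2
  if (df < 1) stop("need at least 3 timepoints")
  tcrit <- stats::qt(1 - (alpha / n_tests) / 2, df)
  rcrit <- tcrit / sqrt(df + tcrit^2)
  mask <- abs(map$values) >= rcrit
  attr(mask, "r_critical") <- rcrit
  mask
}

#' Peak voxel of a map
#'
#' @param map an [fc_map()].
#' @param region_mask optional logical vector restricting the search.
#' @return list with `index`, `center` (m), `value`; ties are broken by
#'   the smallest linear voxel index (reported via message).
#' @export
peak_location <- function(map, region_mask = NULL) {
  v <- map$values
  idx <- seq_along(v)
  if (!is.null(region_mask)) {
    if (!any(region_mask)) stop("region mask is empty")
    idx <- idx[region_mask]
    v <- v[region_mask]
  }
  mx <- max(v)
  hits <- idx[v == mx]
  if (length(hits) > 1)
    message(sprintf("peak tie among %d voxels; smallest index %d chosen",
                    length(hits), hits[1]))
  i <- hits[1]
  list(index = i, center = map$grid$centers[i, ], value = mx)
}
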