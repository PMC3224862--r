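# Voxel grids and volumetric maps.

#' Regular voxel grid inside the conductor
#'
#' A regular lattice (spacing in mm) clipped to an inner "brain" sphere
#' of radius `conductor$radius - margin`. Internally voxel indices are
#' 0-based `ijk` on the enclosing lattice; world coordinates are meters
#' relative to the conductor center (exported to NIfTI in mm).
#'
#' @param spacing_mm lattice spacing in millimeters.
#' @param conductor a [conductor_model()].
#' @param margin clearance between the grid sphere and the conductor
#'   surface, meters (default 0.015).
#' @return An object of class `voxel_grid`: `centers` (V x 3, m), `ijk`
#'   (V x 3, 0-based), `dims`, `spacing_mm`, `origin` (m, world position
#'   of voxel (0,0,0)), `radius` (m).
#' @export
make_grid <- function(spacing_mm, conductor, margin = 0.015) {
  stopifnot_scalar(spacing_mm, "spacing_mm")
  if (spacing_mm <= 0) stop("'spacing_mm' must be positive")
  r <- conductor$radius - margin
  if (r <= 0) stop("margin leaves no room for a grid")
  sp <- spacing_mm / 1000
  half <- floor(r / sp)
  ax <- seq(-half, half) * sp
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rn <- sqrt(rowSums(g^2))
  # the lattice point at the sphere center is excluded: a dipole there has
  # an identically zero lead field and is not reconstructable
  inside <- rn < r & rn > 1e-9
  g <- g[inside, , drop = FALSE]
  centers <- sweep(g, 2, conductor$center, "+")
  ijk <- round(sweep(g, 2, -half * sp) / sp)
  structure(list(centers = centers, ijk = ijk,
                 dims = rep(2L * half + 1L, 3), spacing_mm = spacing_mm,
                 origin = conductor$center - half * sp, radius = r),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d voxels, %g mm spacing, radius %g mm\n",
              nrow(x$centers), x$spacing_mm, x$radius * 1000))
  invisible(x)
}

#' Volumetric scalar map on a voxel grid
#'
#' @param values numeric vector, one value per grid voxel.
#' @param grid a [make_grid()] voxel grid.
#' @param label provenance tag (metric, band, ...).
#' @return An object of class `fc_map`.
#' @export
fc_map <- function(values, grid, label = "") {
  values <- as.numeric(values)
  if (length(values) != nrow(grid$centers))
    stop("value count does not match the grid")
  structure(list(values = values, grid = grid, label = label),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> '%s': %d voxels, range [%.4g, %.4g]\n", x$label,
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$grid$centers), dim(b$grid$centers)) &&
    isTRUE(all.equal(a$grid$centers, b$grid$centers, tolerance = 1e-12))
}

# scatter map values into a dense 3-D array (NA outside the mask)
map_to_array <- function(map, fill = NA_real_) {
  arr <- array(fill, map$grid$dims)
  idx <- map$grid$ijk + 1L
  arr[cbind(idx[, 1], idx[, 2], idx[, 3])] <- map$values
  arr
}

array_to_map <- function(arr, grid, label = "") {
  idx <- grid$ijk + 1L
  fc_map(arr[cbind(idx[, 1], idx[, 2], idx[, 3])], grid, label)
}

#' 4-D volume (voxel timecourses on a grid)
#'
#' @param data V x T matrix of per-voxel timecourses.
#' @param grid a [make_grid()] voxel grid.
#' @param TR sampling interval in seconds.
#' @return An object of class `fourd_volume`.
#' @export
fourd_volume <- function(data, grid, TR) {
  data <- as.matrix(data)
  if (nrow(data) != nrow(grid$centers))
    stop("row count does not match the grid")
  stopifnot_scalar(TR, "TR")
  structure(list(data = data, grid = grid, TR = TR), class = "fourd_volume")
}
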