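# Forward model: dipolar sources in a spherically symmetric conductor,
# sensed by point magnetometers.

#' Sensor array
#'
#' A set of M point magnetometers, each with a position (m) and a unit
#' sensing orientation. Real MEG hardware (gradiometer coil pairs,
#' reference channels) is deliberately not modeled; noise is injected
#' directly at the sensor level instead.
#'
#' @param positions M x 3 matrix of sensor positions in meters.
#' @param orientations M x 3 matrix of unit sensing directions.
#' @return An object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L)
    stop("positions and orientations must have 3 columns")
  if (nrow(positions) != nrow(orientations))
    stop("positions and orientations must have the same number of rows")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-12))
    orientations <- orientations / nrm
  structure(list(positions = positions, orientations = orientations,
                 M = nrow(positions)), class = "sensor_array")
}

#' Spherical conductor model
#'
#' Single-sphere volume conductor (Sarvas closed form). The multi-sphere
#' variant is realized through per-channel sphere centers re-using the
#' same closed form. The field outside the sphere depends only on the
#' center; the radius is bookkeeping used to validate source and sensor
#' placement and to clip reconstruction grids.
#'
#' @param center 3-vector, sphere center in meters.
#' @param radius sphere radius in meters (default 0.09).
#' @param channel_centers optional M x 3 matrix of per-channel centers.
#' @return An object of class `conductor_model`.
#' @export
conductor_model <- function(center = c(0, 0, 0), radius = 0.09,
                            channel_centers = NULL) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("'center' must be a 3-vector")
  stopifnot_scalar(radius, "radius")
  if (!is.null(channel_centers)) channel_centers <- as.matrix(channel_centers)
  structure(list(center = center, radius = radius,
                 channel_centers = channel_centers),
            class = "conductor_model")
}

#' Dipole specification
#'
#' A current dipole at location `location` (m) whose moment lies in the
#' tangential plane at angle `delta` (radians, in `[0, pi)`) from the
#' azimuthal direction, with moment magnitude `moment` (A m).
#'
#' @param location 3-vector, meters; must lie strictly inside the conductor.
#' @param delta orientation angle within the tangential plane, radians.
#' @param moment dipole moment magnitude in A m (default 1).
#' @return An object of class `dipole_spec`.
#' @export
dipole_spec <- function(location, delta = 0, moment = 1) {
  location <- as.numeric(location)
  if (length(location) != 3L) stop("'location' must be a 3-vector")
  stopifnot_scalar(delta, "delta")
  delta <- delta %% pi
  structure(list(location = location, delta = delta, moment = moment),
            class = "dipole_spec")
}

#' Tangential basis at a source location
#'
#' Returns the ordered orthonormal pair spanning the plane tangential to
#' the conductor sphere at `location`. The first vector is the azimuthal
#' direction, fixed deterministically as `normalize(z x radial)`; when the
#' radial direction is (nearly) parallel to z the fallback
#' `normalize(x x radial)` is used. The second vector is
#' `radial x azimuthal`.
#'
#' @param location 3-vector (m).
#' @param center conductor center 3-vector (m).
#' @return 3 x 2 matrix; columns are the azimuthal and polar directions.
#' @export
tangential_basis <- function(location, center = c(0, 0, 0)) {
  radial <- as.numeric(location) - as.numeric(center)
  if (vnorm(radial) < 1e-14)
    stop("degenerate geometry: source location coincides with sphere center")
  radial <- unit(radial)
  zc <- cross3(c(0, 0, 1), radial)
  if (vnorm(zc) < 1e-8) zc <- cross3(c(1, 0, 0), radial)
  e1 <- unit(zc)
  e2 <- cross3(radial, e1)
  cbind(azimuthal = e1, polar = e2)
}

# Sarvas closed-form magnetic field of a current dipole in a spherical
# conductor, projected onto sensor orientations. Vectorized over sensors.
# q: moment 3-vector (A m); r0: dipole location; all relative to a common
# origin; centers: n x 3 sphere centers (one row per sensor).
sarvas_project <- function(q, r0, positions, orientations, centers) {
  mu0 <- 4e-7 * pi
  rr <- positions - centers
  r0r <- matrix(r0, nrow(positions), 3, byrow = TRUE) - centers
  a_vec <- rr - r0r
  a <- sqrt(rowSums(a_vec^2))
  Rn <- sqrt(rowSums(rr^2))
  r0dotr <- rowSums(r0r * rr)
  F <- a * (Rn * a + Rn^2 - r0dotr)
  adotr <- rowSums(a_vec * rr)
  c1 <- a^2 / Rn + adotr / a + 2 * a + 2 * Rn
  c2 <- a + 2 * Rn + adotr / a
  gradF <- c1 * rr - c2 * r0r
  # Q x r0 varies per sensor in the multi-sphere case (r0 is re-expressed
  # relative to each channel's sphere center).
  Qx <- cbind(q[2] * r0r[, 3] - q[3] * r0r[, 2],
              q[3] * r0r[, 1] - q[1] * r0r[, 3],
              q[1] * r0r[, 2] - q[2] * r0r[, 1])
  Qxdotr <- rowSums(Qx * rr)
  B <- (F * Qx - Qxdotr * gradF) * (mu0 / (4 * pi * F^2))
  rowSums(B * orientations)
}

conductor_centers <- function(conductor, M) {
  if (!is.null(conductor$channel_centers)) {
    if (nrow(conductor$channel_centers) != M)
      stop("per-channel sphere centers must match the channel count")
    conductor$channel_centers
  } else {
    matrix(conductor$center, M, 3, byrow = TRUE)
  }
}

#' Lead field of a dipole
#'
#' Magnetic field per unit dipole moment at each sensor, for a tangential
#' dipole parametrized by `theta = [r, delta]`. Uses the spherical-conductor
#' closed form; exactly zero for radial dipoles and for a dipole at the
#' sphere center.
#'
#' @param array a [sensor_array()].
#' @param conductor a [conductor_model()].
#' @param dipole a [dipole_spec()].
#' @return numeric M-vector (tesla per A m), with the dipole spec attached
#'   as attribute `source`.
#' @export
lead_field <- function(array, conductor, dipole) {
  loc <- dipole$location
  if (vnorm(loc - conductor$center) >= conductor$radius)
    stop("dipole location must lie strictly inside the conductor sphere")
  B <- tangential_basis(loc, conductor$center)
  u <- cos(dipole$delta) * B[, 1] + sin(dipole$delta) * B[, 2]
  centers <- conductor_centers(conductor, array$M)
  lf <- sarvas_project(u * dipole$moment, loc, array$positions,
                       array$orientations, centers)
  attr(lf, "source") <- dipole
  lf
}

#' Lead fields for the two tangential basis orientations
#'
#' Any tangential orientation delta has lead field
#' `cos(delta) * L[,1] + sin(delta) * L[,2]`.
#'
#' @inheritParams lead_field
#' @param location source location 3-vector (m).
#' @return M x 2 matrix of lead fields for the azimuthal and polar
#'   basis orientations.
#' @export
lead_field_pair <- function(array, conductor, location) {
  if (vnorm(location - conductor$center) >= conductor$radius)
    stop("dipole location must lie strictly inside the conductor sphere")
  B <- tangential_basis(location, conductor$center)
  centers <- conductor_centers(conductor, array$M)
  cbind(sarvas_project(B[, 1], location, array$positions,
                       array$orientations, centers),
        sarvas_project(B[, 2], location, array$positions,
                       array$orientations, centers))
}
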