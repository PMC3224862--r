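# Scalar LCMV beamformer: covariance, regularized weights, orientation
# optimization, projection, leakage diagnostics and localizer contrasts.

#' Beamformer configuration
#'
#' @param mu unitless Tikhonov regularization scalar (default 4, the
#'   standard operating point for this pipeline).
#' @param window_policy which data window feeds the covariance:
#'   `"all_data"` (default; better spatial resolution when a task phase
#'   modulates power) or `"resting_only"`.
#' @return An object of class `beamformer_config`.
#' @export
beamformer_config <- function(mu = 4, window_policy = c("all_data", "resting_only")) {
  stopifnot_scalar(mu, "mu")
  if (mu < 0) stop("'mu' must be >= 0")
  window_policy <- match.arg(window_policy)
  structure(list(mu = mu, window_policy = window_policy),
            class = "beamformer_config")
}

#' Sensor covariance over a sample window
#'
#' Channel means are removed over the window before outer-product
#' averaging (denominator `n - 1`).
#'
#' @param data a [sensor_ts()] or channels x samples matrix.
#' @param window integer vector of sample indices (default: all samples).
#' @return An object of class `cov_estimate`: list with the M x M matrix
#'   `C`, the window used, and `n_samples`.
#' @export
estimate_covariance <- function(data, window = NULL) {
  X <- as_sensor_matrix(data)
  if (is.null(window)) window <- seq_len(ncol(X))
  if (length(window) == 0) stop("empty covariance window")
  X <- X[, window, drop = FALSE]
  n <- ncol(X)
  if (n < nrow(X))
    warning(sprintf("covariance window (%d samples) shorter than channel count (%d); estimate will be rank-deficient", n, nrow(X)))
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / max(n - 1, 1)
  C <- (C + t(C)) / 2
  structure(list(C = C, window = range(window), n_samples = n),
            class = "cov_estimate")
}

cov_matrix <- function(C) if (inherits(C, "cov_estimate")) C$C else as.matrix(C)

#' Uncorrelated-noise power estimate
#'
#' The minimum singular value of the covariance matrix.
#'
#' @param C a `cov_estimate` or symmetric matrix.
#' @return scalar noise power (same units as the covariance).
#' @export
noise_floor <- function(C) {
  C <- cov_matrix(C)
  min(svd(C, nu = 0, nv = 0)$d)
}

regularized_cov <- function(C, cfg, sigma = NULL) {
  C <- cov_matrix(C)
  if (is.null(sigma)) sigma <- noise_floor(C)
  Creg <- C + cfg$mu * sigma * diag(nrow(C))
  rc <- rcond(Creg)
  if (rc < 1e-14)
    stop(sprintf("regularized covariance is numerically singular (reciprocal condition number %.2e)", rc))
  Creg
}

#' Unit-gain minimum-variance weights
#'
#' `W = (C + mu*sigma*I)^-1 L / (L' (C + mu*sigma*I)^-1 L)`: the weight
#' vector minimizing projected variance among all vectors with unit gain
#' on the lead field `L`.
#'
#' @param L lead-field M-vector.
#' @param C a `cov_estimate` or M x M matrix.
#' @param cfg a [beamformer_config()].
#' @param sigma noise power; recomputed from `C` when `NULL`.
#' @return numeric M-vector with attribute `source` carried over from `L`.
#' @export
compute_weights <- function(L, C, cfg = beamformer_config(), sigma = NULL) {
  Creg <- regularized_cov(C, cfg, sigma)
  W <- solve(Creg, as.numeric(L))
  g <- sum(W * L)
  if (abs(g) < .Machine$double.xmin * 1e10)
    stop("lead field is (numerically) zero; cannot form unit-gain weights")
  W <- W / g
  attr(W, "source") <- attr(L, "source")
  W
}

# Closed-form orientation of maximal projected variance.
#
# With L(delta) = Lb %*% c(cos d, sin d) and Eq.-2 weights, the projected
# variance is V(d) = (u'Pu) / (u'Qu)^2 where P = Lb' Ci C Ci Lb,
# Q = Lb' Ci Lb, Ci = (C + mu sigma I)^-1, u = (cos d, sin d).
# Writing phi = 2d both quadratic forms are first-order trig polynomials
# in phi, and dV/dphi = 0 reduces to a quartic in tan(phi/2), solved
# exactly with polyroot.
solve_orientation <- function(P, Q) {
  a0 <- (P[1, 1] + P[2, 2]) / 2; a1 <- (P[1, 1] - P[2, 2]) / 2; a2 <- P[1, 2]
  b0 <- (Q[1, 1] + Q[2, 2]) / 2; b1 <- (Q[1, 1] - Q[2, 2]) / 2; b2 <- Q[1, 2]
  k0 <- 1.5 * (a2 * b1 - a1 * b2)
  k1 <- a2 * b0 - 2 * a0 * b2
  k2 <- 2 * a0 * b1 - a1 * b0
  k3 <- -(a1 * b2 + a2 * b1) / 2
  k4 <- (a1 * b1 - a2 * b2) / 2
  coef <- c(k0 + k1 + k3,           # t^0
            2 * k2 + 4 * k4,        # t^1
            2 * k0 - 6 * k3,        # t^2
            2 * k2 - 4 * k4,        # t^3
            k0 - k1 + k3)           # t^4
  cand <- pi / 2  # phi = pi (t = infinity) is always a candidate
  nz <- which(abs(coef) > max(abs(coef)) * 1e-14)
  if (length(nz) > 1) {
    deg <- max(nz)
    rts <- polyroot(coef[seq_len(deg)])
    real <- Re(rts[abs(Im(rts)) < 1e-8 * (1 + abs(rts))])
    cand <- c(cand, (2 * atan(real) / 2) %% pi)
  } else {
    # derivative identically zero: variance independent of delta
    cand <- c(0, cand)
  }
  vfun <- function(d) {
    u <- c(cos(d), sin(d))
    num <- sum(u * (P %*% u)); den <- sum(u * (Q %*% u))
    num / den^2
  }
  vals <- vapply(cand, vfun, 0)
  best <- max(vals)
  # ties (within numerical noise) broken toward smaller delta
  sel <- cand[vals >= best * (1 - 1e-12)]
  min(sel)
}

#' Source orientation of maximal projected variance
#'
#' Finds `delta` in `[0, pi)` maximizing the beamformer output variance
#' `W(delta)' C W(delta)` under the unit-gain constraint, in closed form
#' (quartic stationarity condition; see the methods vignette). When the
#' covariance carries no source structure (C proportional to I) the
#' maximizer is the minimum-norm-lead-field direction, a known artifact;
#' it is returned with a warning.
#'
#' @param Lb M x 2 matrix of tangential basis lead fields
#'   (see [lead_field_pair()]).
#' @param C a `cov_estimate` or M x M matrix.
#' @param cfg a [beamformer_config()].
#' @param sigma optional noise power.
#' @return delta in `[0, pi)`.
#' @export
optimal_orientation <- function(Lb, C, cfg = beamformer_config(), sigma = NULL) {
  Cm <- cov_matrix(C)
  if (max(sqrt(colSums(Lb^2))) == 0)
    stop("degenerate source: both tangential lead fields are zero")
  ev <- eigen(Cm, symmetric = TRUE, only.values = TRUE)$values
  if ((ev[1] - ev[length(ev)]) <= 1e-10 * max(abs(ev[1]), .Machine$double.xmin))
    warning("covariance has no source structure (C ~ c*I); returning the minimum-lead-field-norm orientation")
  if (is.null(sigma)) sigma <- noise_floor(Cm)
  Creg <- regularized_cov(Cm, cfg, sigma)
  CiL <- solve(Creg, Lb)
  Q <- crossprod(Lb, CiL)
  P <- crossprod(CiL, Cm %*% CiL)
  solve_orientation(P, Q)
}

#' Project sensor data through beamformer weights
#'
#' @param W weight M-vector (or V x M matrix for many voxels).
#' @param data a [sensor_ts()] or channels x samples matrix.
#' @return numeric vector (or V x T matrix) of source amplitude estimates.
#' @export
project <- function(W, data) {
  X <- as_sensor_matrix(data)
  if (is.matrix(W)) {
    if (ncol(W) != nrow(X)) stop("channel count mismatch between weights and data")
    W %*% X
  } else {
    if (length(W) != nrow(X)) stop("channel count mismatch between weights and data")
    as.numeric(crossprod(W, X))
  }
}

#' Beamformer scan over a voxel grid
#'
#' Computes, per voxel: tangential basis lead fields, the orientation of
#' maximal variance, unit-gain weights and projected variance. The data
#' are band-filtered first when `band` is given (weights are then
#' band-specific, matching the per-band covariance).
#'
#' @param grid a [make_grid()] voxel grid.
#' @param data a [sensor_ts()].
#' @param array a [sensor_array()].
#' @param conductor a [conductor_model()].
#' @param cfg a [beamformer_config()].
#' @param band optional [freq_band()].
#' @param window optional sample-index vector for the covariance window
#'   (e.g. the resting phase when `cfg$window_policy == "resting_only"`).
#' @return An object of class `beam_scan`: weights (V x M), delta (V),
#'   variance (V, raw projected variance), pseudo_z (V, projected
#'   variance normalized by projected noise power `sigma * W'W` --
#'   the depth-bias-free quantity used for localization), lead fields at
#'   the optimal orientation (V x M), the covariance, sigma, cfg, band
#'   and grid.
#' @export
scan_grid <- function(grid, data, array, conductor,
                      cfg = beamformer_config(), band = NULL, window = NULL) {
  X <- as_sensor_matrix(data)
  fs <- if (inherits(data, "sensor_ts")) data$fs else
    stop("scan_grid needs a sensor_ts to know the sampling rate")
  if (!is.null(band)) X <- fir_bandpass(X, band, fs)
  Cest <- estimate_covariance(sensor_ts(X, fs), window)
  Cm <- Cest$C
  sigma <- noise_floor(Cm)
  Creg <- Cm + cfg$mu * sigma * diag(nrow(Cm))
  Ui <- chol(Creg)
  V <- nrow(grid$centers)
  M <- array$M
  Wmat <- matrix(0, V, M)
  Lmat <- matrix(0, V, M)
  delta <- numeric(V)
  variance <- numeric(V)
  pseudo_z <- numeric(V)
  for (v in seq_len(V)) {
    Lb <- lead_field_pair(array, conductor, grid$centers[v, ])
    CiL <- backsolve(Ui, forwardsolve(t(Ui), Lb))
    Q <- crossprod(Lb, CiL)
    P <- crossprod(CiL, Cm %*% CiL)
    d <- solve_orientation(P, Q)
    L <- Lb %*% c(cos(d), sin(d))
    W <- backsolve(Ui, forwardsolve(t(Ui), L))
    W <- W / sum(W * L)
    delta[v] <- d
    Wmat[v, ] <- W
    Lmat[v, ] <- L
    variance[v] <- sum(W * (Cm %*% W))
    pseudo_z[v] <- variance[v] / (sigma * sum(W * W))
  }
  structure(list(weights = Wmat, delta = delta, variance = variance,
                 pseudo_z = pseudo_z,
                 leadfields = Lmat, cov = Cest, sigma = sigma, cfg = cfg,
                 band = band, grid = grid, fs = fs),
            class = "beam_scan")
}

#' Pseudo-T localizer contrast
#'
#' Per voxel, `(P_active - P_control) / (sigma * W'W)` where `P` is the
#' projected band variance in each window. The normalization makes the
#' map invariant to a global gain on the data; only the peak location is
#' interpreted, not the magnitude.
#'
#' @param scan a `beam_scan`.
#' @param data the [sensor_ts()] the scan was built from.
#' @param active,control sample-index vectors for the two windows.
#' @return An [fc_map()] of pseudo-T values.
#' @export
pseudo_t_map <- function(scan, data, active, control) {
  if (length(active) == 0 || length(control) == 0)
    stop("active and control windows must be non-empty")
  X <- as_sensor_matrix(data)
  if (!is.null(scan$band)) X <- fir_bandpass(X, scan$band, scan$fs)
  Ca <- estimate_covariance(X, active)$C
  Cc <- estimate_covariance(X, control)$C
  W <- scan$weights
  Pa <- rowSums((W %*% Ca) * W)
  Pc <- rowSums((W %*% Cc) * W)
  wnorm <- rowSums(W * W)
  fc_map((Pa - Pc) / (scan$sigma * wnorm), scan$grid, "pseudo_t")
}

abs_cor_to_seed <- function(mat, seed_index, label) {
  seedv <- mat[seed_index, ]
  v <- rep(0, nrow(mat))
  sds <- apply(mat, 1, stats::sd)
  if (sds[seed_index] == 0) {
    warning("seed vector has zero variance; map set to 0")
  } else {
    ok <- sds > 0
    if (any(!ok)) warning(sprintf("%d zero-variance vectors set to 0", sum(!ok)))
    v[ok] <- abs(apply(mat[ok, , drop = FALSE], 1, stats::cor, y = seedv))
  }
  v
}

#' Weights-correlation leakage map
#'
#' Absolute Pearson correlation between the beamformer weight vector at
#' the seed voxel and at every other voxel: the signal-leakage
#' diagnostic. Value 1 at the seed.
#'
#' @param scan a `beam_scan`.
#' @param seed_index voxel index of the seed.
#' @return An [fc_map()].
#' @export
weights_correlation_map <- function(scan, seed_index) {
  fc_map(abs_cor_to_seed(scan$weights, seed_index, "weights_correlation"),
         scan$grid, "weights_correlation")
}

#' Lead-field-correlation map
#'
#' As [weights_correlation_map()] but using the lead fields at each
#' voxel's optimized orientation: the leakage profile a non-adaptive
#' (lead-field based) reconstruction would have.
#'
#' @inheritParams weights_correlation_map
#' @return An [fc_map()].
#' @export
lead_field_correlation_map <- function(scan, seed_index) {
  fc_map(abs_cor_to_seed(scan$leadfields, seed_index, "leadfield_correlation"),
         scan$grid, "leadfield_correlation")
}

#' Map values against distance from a seed voxel
#'
#' @param map an [fc_map()].
#' @param seed_index voxel index of the seed.
#' @return data.frame with columns `distance_mm` and `value`, ordered by
#'   distance (ties by voxel index).
#' @export
correlation_vs_distance <- function(map, seed_index) {
  ctr <- map$grid$centers
  d <- sqrt(rowSums((ctr - matrix(ctr[seed_index, ], nrow(ctr), 3, byrow = TRUE))^2))
  ord <- order(d, seq_along(d))
  data.frame(distance_mm = d[ord] * 1000, value = map$values[ord])
}

#' Volume of voxels above a threshold
#'
#' @param map an [fc_map()].
#' @param threshold scalar; voxels with value strictly above it count.
#' @return volume in cm^3.
#' @export
volume_above <- function(map, threshold) {
  sum(map$values > threshold) * (map$grid$spacing_mm / 10)^3
}
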