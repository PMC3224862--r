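# Independent oracles. Each implements the quantity under test by a
# different route than the package code and is deliberately kept free of
# package internals.

# ---- forward model: primary Biot-Savart + Geselowitz surface integral ----
# The conductor surface potential is obtained numerically: the
# infinite-medium dipole potential plus the harmonic Neumann correction,
# computed degree-by-degree via the Legendre addition theorem on a
# Fibonacci surface grid. Entirely independent of the closed-form field.

oracle_fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

oracle_v_inf <- function(pts, q, r0) {
  d <- sweep(pts, 2, r0)
  dn <- sqrt(rowSums(d^2))
  (d %*% q) / (4 * pi * dn^3)
}

# H: applied to the surface Neumann data g gives the harmonic correction
oracle_make_H <- function(y, Rsph, nmax = 50) {
  nq <- nrow(y)
  cosG <- tcrossprod(y)
  cosG[cosG > 1] <- 1; cosG[cosG < -1] <- -1
  Pprev <- matrix(1, nq, nq)
  Pcur <- cosG
  H <- (Rsph * 3 / (4 * pi)) * Pcur
  for (n in 2:nmax) {
    Pnext <- ((2 * n - 1) * cosG * Pcur - (n - 1) * Pprev) / n
    H <- H + (Rsph * (2 * n + 1) / (4 * pi * n)) * Pnext
    Pprev <- Pcur; Pcur <- Pnext
  }
  H
}

oracle_surface_potential <- function(q, r0, Rsph, y, H) {
  h <- 1e-6
  g <- -(oracle_v_inf(y * (Rsph + h), q, r0) -
           oracle_v_inf(y * (Rsph - h), q, r0)) / (2 * h)
  vh <- (H %*% g) * (4 * pi / nrow(y))
  as.vector(oracle_v_inf(y * Rsph, q, r0) + vh)
}

# field of dipole q at r0 projected on one sensor (pos rs, orientation o)
oracle_field <- function(q, r0, rs, o, vs, y, Rsph) {
  mu0 <- 4e-7 * pi
  d <- rs - r0
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  Bp <- mu0 / (4 * pi) * cr(q, d) / sqrt(sum(d^2))^3
  pts <- y * Rsph
  dvec <- matrix(rs, nrow(y), 3, byrow = TRUE) - pts
  dn3 <- sqrt(rowSums(dvec^2))^3
  crm <- cbind(y[, 2] * dvec[, 3] - y[, 3] * dvec[, 2],
               y[, 3] * dvec[, 1] - y[, 1] * dvec[, 3],
               y[, 1] * dvec[, 2] - y[, 2] * dvec[, 1])
  dS <- 4 * pi * Rsph^2 / nrow(y)
  Bv <- -(mu0 / (4 * pi)) * colSums(crm * vs / dn3) * dS
  sum((Bp + Bv) * o)
}

# ---- beamformer: constrained minimization by null-space elimination ----
# minimize W' Creg W subject to W'L = 1, solved by eliminating the
# constraint with a QR null-space basis and solving the reduced normal
# equations; shares no code path with the closed-form weights.
oracle_constrained_min <- function(L, Creg) {
  m <- length(L)
  W0 <- L / sum(L * L)
  N <- qr.Q(qr(cbind(L)), complete = TRUE)[, -1, drop = FALSE]
  Hm <- crossprod(N, Creg %*% N)
  b <- -crossprod(N, Creg %*% W0)
  z <- solve(Hm, b)
  as.numeric(W0 + N %*% z)
}

# ---- coherence: direct per-bin FFT oracle (loops, no pooling helper) ----
oracle_band_coh_icoh <- function(x, y, delta, f_lo, f_hi, fs) {
  ns <- round(delta * fs)
  nseg <- floor(length(x) / ns)
  cohs <- numeric(nseg); icohs <- numeric(nseg)
  for (k in seq_len(nseg)) {
    xi <- x[((k - 1) * ns + 1):(k * ns)]
    yi <- y[((k - 1) * ns + 1):(k * ns)]
    X <- stats::fft(xi); Y <- stats::fft(yi)
    sxy <- 0 + 0i; sxx <- 0; syy <- 0
    for (j in seq_len(ns)) {
      f <- (j - 1) * fs / ns
      if (f >= f_lo && f <= f_hi && f <= fs / 2) {
        sxy <- sxy + X[j] * Conj(Y[j])
        sxx <- sxx + Mod(X[j])^2
        syy <- syy + Mod(Y[j])^2
      }
    }
    cohs[k] <- Mod(sxy) / sqrt(sxx * syy)
    icohs[k] <- abs(Im(sxy)) / sqrt(sxx * syy)
  }
  list(coh = mean(cohs), icoh = mean(icohs),
       coh_k = cohs, icoh_k = icohs)
}

# ---- Wilcoxon: literal enumeration of all 2^n sign assignments ----
oracle_wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, 0)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
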