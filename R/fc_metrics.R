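# Functional-connectivity metrics between two source timecourses:
# envelope correlation (AEC, CAE) and band coherence (Coh, ICoh).

fc_result <- function(metric, value, segments = NULL, delta = NA,
                      n_dropped = 0L, band = NULL) {
  structure(list(metric = metric, value = value, segments = segments,
                 delta = delta, n_dropped = n_dropped,
                 band = if (!is.null(band)) band$name else NULL),
            class = "fc_metric")
}

#' @export
print.fc_metric <- function(x, ...) {
  cat(sprintf("<fc_metric> %s = %.4f (%s%s)\n", x$metric, x$value,
              if (is.null(x$segments)) "no per-segment timecourse"
              else paste(length(x$segments), "segments"),
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Averaged envelope correlation (AEC)
#'
#' Pearson correlation between the two Hilbert envelopes within each
#' `delta`-second segment, averaged across segments. Segments in which
#' either envelope has zero variance are undefined and are dropped from
#' the mean (count reported in the result).
#'
#' @param env_seed,env_test equal-length envelope timecourses.
#' @param delta segment length, seconds.
#' @param fs sampling rate, Hz.
#' @return An `fc_metric` with per-segment values retained.
#' @export
aec <- function(env_seed, env_test, delta, fs) {
  if (length(env_seed) != length(env_test))
    stop("envelopes must have equal length")
  if (round(delta * fs) < 3)
    stop("need at least 3 samples per segment for a correlation")
  a <- segment(env_seed, delta, fs)
  b <- segment(env_test, delta, fs)
  r <- vapply(seq_len(ncol(a)), function(k) {
    if (stats::sd(a[, k]) == 0 || stats::sd(b[, k]) == 0) NA_real_
    else stats::cor(a[, k], b[, k])
  }, 0)
  dropped <- sum(is.na(r))
  fc_result("AEC", mean(r, na.rm = TRUE), segments = r, delta = delta,
            n_dropped = dropped)
}

#' Correlation of averaged envelopes (CAE)
#'
#' Each envelope is collapsed to one mean value per `delta`-second
#' segment; the single Pearson correlation between the two n-point
#' averaged envelopes is the metric. Collapsing acts as a low-pass
#' filter on the envelope, so CAE emphasizes slow co-modulation.
#'
#' @inheritParams aec
#' @return An `fc_metric` (no per-segment timecourse exists for CAE).
#' @export
cae <- function(env_seed, env_test, delta, fs) {
  if (length(env_seed) != length(env_test))
    stop("envelopes must have equal length")
  a <- averaged_envelope(env_seed, delta, fs)
  b <- averaged_envelope(env_test, delta, fs)
  if (length(a) < 3)
    stop("CAE needs at least 3 segments; shorten delta or lengthen the data")
  fc_result("CAE", stats::cor(a, b), delta = delta)
}

# pooled in-band cross/auto spectra per segment; shared by Coh and ICoh
band_cross_spectra <- function(ts_seed, ts_test, delta, band, fs,
                               taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  if (length(ts_seed) != length(ts_test))
    stop("timecourses must have equal length")
  a <- segment(ts_seed, delta, fs)
  b <- segment(ts_test, delta, fs)
  ns <- nrow(a)
  f <- (seq_len(ns) - 1) * fs / ns
  sel <- which(f >= band$f_lo & f <= band$f_hi & f <= fs / 2)
  if (length(sel) == 0)
    stop(sprintf(
      "segment too short: no frequency bin inside [%g, %g] Hz; need delta >= %.3g s",
      band$f_lo, band$f_hi, 1 / band$f_hi))
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ns) - 1) / (ns - 1))
    a <- a * w; b <- b * w
  }
  A <- stats::mvfft(a)[sel, , drop = FALSE]
  B <- stats::mvfft(b)[sel, , drop = FALSE]
  list(Sxy = colSums(A * Conj(B)),
       Sxx = colSums(Mod(A)^2),
       Syy = colSums(Mod(B)^2))
}

#' Band coherence (Coh)
#'
#' Per segment, the modulus of the band-pooled normalized cross-spectrum
#' `|sum_f X Y*| / sqrt(sum |X|^2 sum |Y|^2)`; the summary value is the
#' mean across segments. Pooling the auto- and cross-spectra over the
#' in-band bins before normalizing is essential: a single bin is always
#' unit-modulus.
#'
#' @inheritParams aec
#' @param ts_seed,ts_test band-limited source timecourses (not envelopes).
#' @param band a [freq_band()].
#' @param taper `"rect"` (default, the bare DFT) or `"hann"`.
#' @return An `fc_metric` with per-segment values.
#' @export
band_coherence <- function(ts_seed, ts_test, delta, band, fs,
                           taper = c("rect", "hann")) {
  s <- band_cross_spectra(ts_seed, ts_test, delta, band, fs, taper)
  ck <- Mod(s$Sxy) / sqrt(s$Sxx * s$Syy)
  fc_result("Coh", mean(ck), segments = ck, delta = delta, band = band)
}

#' Band imaginary coherence (ICoh)
#'
#' Per segment, `|Im(sum_f X Y*)| / sqrt(sum |X|^2 sum |Y|^2)` pooled
#' over in-band bins; mean across segments. The imaginary part excludes
#' zero-lag correlation, making ICoh insensitive to signal leakage. The
#' absolute value is taken per segment because the phase of coherent
#' bursts may flip between windows; set `signed = TRUE` for the signed
#' variant.
#'
#' @inheritParams band_coherence
#' @param signed keep the per-segment sign (default FALSE).
#' @return An `fc_metric` with per-segment values.
#' @export
band_icoh <- function(ts_seed, ts_test, delta, band, fs,
                      taper = c("rect", "hann"), signed = FALSE) {
  s <- band_cross_spectra(ts_seed, ts_test, delta, band, fs, taper)
  ik <- Im(s$Sxy) / sqrt(s$Sxx * s$Syy)
  if (!signed) ik <- abs(ik)
  fc_result("ICoh", mean(ik), segments = ik, delta = delta, band = band)
}

#' Per-segment FC timecourse
#'
#' Temporal sequence of per-segment metric values; the temporal
#' resolution is `delta`. CAE has no per-segment values by construction
#' and is rejected.
#'
#' @param metric one of `"AEC"`, `"Coh"`, `"ICoh"`.
#' @param seed,test inputs in the form the metric expects (envelopes for
#'   AEC, band-limited timecourses for Coh/ICoh).
#' @inheritParams band_coherence
#' @return An object of class `fc_timecourse`: per-segment values plus
#'   segment midpoints in seconds.
#' @export
fc_timecourse <- function(metric = c("AEC", "Coh", "ICoh", "CAE"),
                          seed, test, delta, fs, band = NULL) {
  metric <- match.arg(metric)
  if (metric == "CAE")
    stop("CAE collapses each segment to one point; it has no per-segment FC timecourse (use AEC)")
  res <- switch(metric,
    AEC = aec(seed, test, delta, fs),
    Coh = band_coherence(seed, test, delta, band, fs),
    ICoh = band_icoh(seed, test, delta, band, fs))
  v <- res$segments
  structure(list(values = v, delta = delta,
                 time = (seq_along(v) - 0.5) * delta, metric = metric),
            class = "fc_timecourse")
}

#' Correlation between two FC timecourses
#'
#' @param tc1,tc2 `fc_timecourse` objects with identical segmentation.
#' @return Pearson correlation (scalar).
#' @export
metric_timecourse_correlation <- function(tc1, tc2) {
  if (length(tc1$values) != length(tc2$values) || tc1$delta != tc2$delta)
    stop("FC timecourses have mismatched segmentation")
  if (length(tc1$values) < 3)
    stop("need at least 3 segments")
  stats::cor(tc1$values, tc2$values)
}
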