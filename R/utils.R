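#' @keywords internal
"_PACKAGE"

# vector helpers ---------------------------------------------------------

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a parent seed and an index,
# staying inside the 32-bit integer range R requires.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483562) + 1L
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
}

#' Multichannel sensor time series
#'
#' Container for an M-channel MEG recording: a numeric matrix with one row
#' per channel and one column per sample, plus the sampling rate.
#'
#' @param data numeric matrix, channels x samples (tesla).
#' @param fs sampling rate in Hz.
#' @return An object of class `sensor_ts`.
#' @export
sensor_ts <- function(data, fs) {
  data <- as.matrix(data)
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive")
  structure(list(data = data, fs = fs, M = nrow(data), n = ncol(data)),
            class = "sensor_ts")
}

#' @export
print.sensor_ts <- function(x, ...) {
  cat(sprintf("<sensor_ts> %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$M, x$n, x$fs, x$n / x$fs))
  invisible(x)
}

as_sensor_matrix <- function(data) {
  if (inherits(data, "sensor_ts")) data$data else as.matrix(data)
}
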