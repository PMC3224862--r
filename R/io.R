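# Plain-text serialization of geometry (JSON sidecars) and the
# binary run container (RDS; no HDF5 bindings are assumed).

#' Write sensor array and conductor model as a JSON sidecar
#'
#' @param array a [sensor_array()].
#' @param conductor a [conductor_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(array, conductor, path) {
  obj <- list(
    sensor_array = list(positions = array$positions,
                        orientations = array$orientations),
    conductor = list(center = conductor$center, radius = conductor$radius,
                     channel_centers = conductor$channel_centers))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a geometry JSON sidecar
#'
#' @param path file written by [write_geometry_json()].
#' @return list with `array` and `conductor`.
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- obj$conductor$channel_centers
  if (!is.null(cc) && length(cc) == 0) cc <- NULL
  list(array = sensor_array(obj$sensor_array$positions,
                            obj$sensor_array$orientations),
       conductor = conductor_model(obj$conductor$center,
                                   obj$conductor$radius, cc))
}

#' Archive a run (weights, covariance, seeds, results) to disk
#'
#' One hierarchical container per run, stored as RDS with a JSON-style
#' manifest entry recording seeds and parameters.
#'
#' @param path output file (`.rds`).
#' @param ... named objects to store.
#' @param manifest named list of parameters/seeds recorded alongside.
#' @return `path`, invisibly.
#' @export
save_run <- function(path, ..., manifest = list()) {
  saveRDS(list(manifest = manifest, objects = list(...)), path)
  invisible(path)
}

#' Load a run container
#' @param path file written by [save_run()].
#' @return list with `manifest` and `objects`.
#' @export
load_run <- function(path) readRDS(path)

#' Tidy FC results table
#'
#' One row per metric x band x delta x pair x segment, ready for CSV.
#'
#' @param results list of `fc_metric` objects.
#' @param pair identifier for the voxel pair.
#' @return data.frame.
#' @export
fc_results_table <- function(results, pair = "seed-test") {
  rows <- lapply(results, function(r) {
    segs <- if (is.null(r$segments)) NA_real_ else r$segments
    data.frame(metric = r$metric,
               band = if (is.null(r$band)) NA_character_ else r$band,
               delta = r$delta, pair = pair,
               segment = if (is.null(r$segments)) NA_integer_ else seq_along(segs),
               value = segs, summary = r$value)
  })
  do.call(rbind, rows)
}
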