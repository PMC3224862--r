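# Minimal NIfTI-1 reader/writer (single-file .nii, float32, diagonal
# affine). No NIfTI package is assumed; the format subset written here is
# the 348-byte header + sform affine, which any neuroimaging tool reads.
# Voxel indices are 0-based internally; the sform maps them to mm world
# coordinates.

#' Write a volumetric map or array as NIfTI-1
#'
#' Data are written as float32 with a diagonal sform affine built from
#' the grid spacing and origin (mm). 3-D maps ([fc_map()]) and 4-D
#' volumes ([fourd_volume()]) are supported; out-of-mask voxels are
#' written as 0.
#'
#' @param x an [fc_map()], [fourd_volume()], or 3-D/4-D numeric array.
#' @param path output filename (`.nii`).
#' @param spacing_mm,origin_mm affine parameters; taken from the grid
#'   when `x` carries one.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing_mm = NULL, origin_mm = NULL) {
  if (inherits(x, "fc_map")) {
    arr <- map_to_array(x, fill = 0)
    spacing_mm <- x$grid$spacing_mm
    origin_mm <- x$grid$origin * 1000
  } else if (inherits(x, "fourd_volume")) {
    tdim <- ncol(x$data)
    arr <- array(0, c(x$grid$dims, tdim))
    idx <- x$grid$ijk + 1L
    for (tt in seq_len(tdim))
      arr[cbind(idx[, 1], idx[, 2], idx[, 3], tt)] <- x$data[, tt]
    spacing_mm <- x$grid$spacing_mm
    origin_mm <- x$grid$origin * 1000
  } else {
    arr <- x
    if (is.null(spacing_mm)) spacing_mm <- 1
    if (is.null(origin_mm)) origin_mm <- c(0, 0, 0)
  }
  dims <- dim(arr)
  ndim <- length(dims)
  if (!ndim %in% c(3L, 4L)) stop("only 3-D or 4-D volumes are supported")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused legacy fields
  wi(c(ndim, dims, rep(1L, 7 - ndim)), 2)       # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(16L, 2)                                    # datatype = float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, rep(spacing_mm, 3), rep(1, 4)))       # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 10L)), con)  # slice_end, slice_code, xyzt_units (mm|s)
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 2L), 2)                              # qform_code = 0, sform_code = 2
  wf(rep(0, 6))                                 # quatern_b/c/d + qoffset_x/y/z
  wf(c(spacing_mm, 0, 0, origin_mm[1]))         # srow_x
  wf(c(0, spacing_mm, 0, origin_mm[2]))         # srow_y
  wf(c(0, 0, spacing_mm, origin_mm[3]))         # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.double(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports the subset this package writes: single-file, float32 or
#' common integer/double datatypes, no compression.
#'
#' @param path filename.
#' @return list with `data` (array), `spacing_mm`, `origin_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (hdr_size != 348) stop("not a little-endian NIfTI-1 file")
  readBin(con, "raw", 36)
  dims <- ri(8, 2)
  rf(3); ri(1, 2)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  readBin(con, "raw", 2 + 2)
  rf(4); ri(2, 4)
  readBin(con, "raw", 104)
  ri(2, 2)
  rf(6)
  srow <- matrix(rf(12), 3, 4, byrow = TRUE)
  readBin(con, "raw", 16 + 4 + 4)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  nvox <- prod(shape)
  data <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n = nvox, size = 1, signed = FALSE, endian = "little"),
    "4" = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n = nvox, size = 4, endian = "little"),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = "little"),
    stop(sprintf("unsupported NIfTI datatype %d", datatype)))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, shape),
       spacing_mm = pixdim[2:4],
       origin_mm = srow[, 4])
}
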