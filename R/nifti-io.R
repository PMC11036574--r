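# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format this package needs: 3D scalar images,
# datatypes uint8 / int16 / int32 / float32 / float64, scl_slope/scl_inter
# rescaling, little- or big-endian files (detected from sizeof_hdr).
# Orientation is carried as a plain voxel-to-mm scaling + translation
# (sform code 1, diagonal matrix); oblique sforms are rejected.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`). Only a minimal,
#' strictly-validated subset of the standard is supported: see Details.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (array), `dim` (integer vector), `spacing`
#'   (numeric, mm per voxel along each axis), and `origin` (numeric, mm).
#' @details Voxel values are rescaled by `scl_slope` / `scl_inter` when set.
#'   Byte order is detected from the `sizeof_hdr` field. Files with
#'   non-diagonal sform matrices are rejected.
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != NIFTI_HDR_SIZE)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  readBin(con, "raw", 36L)                      # data_type..dim_info
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                      # intent_p1..intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)   # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)   # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 123L)                     # slice_end .. intent_name end
  # offset so far: 4+36+16+14+2+2+2+32+4+4+4+123 = 243; srow_x starts at 280
  readBin(con, "raw", 37L)                      # qform/quatern block remainder
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                      # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)

  ndim <- dims[1L]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI dim[0]: ", ndim)
  shape <- dims[2L:(1L + ndim)]
  # trailing singleton dims are tolerated (common exporter quirk)
  while (length(shape) > 3L && shape[length(shape)] == 1L)
    shape <- shape[-length(shape)]

  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)

  skip <- round(vox_offset) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  spacing <- abs(pixdim[2L:min(4L, 1L + ndim)])
  offdiag <- srow[1L:3L, 1L:3L]
  diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6))
    stop("oblique sform matrices are not supported: ", path)
  origin <- srow[, 4L]

  list(data = array(vals, dim = shape), dim = as.integer(shape),
       spacing = spacing, origin = origin)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array as a little-endian single-file NIfTI-1 image with a
#' diagonal sform. `.gz` suffix triggers gzip compression.
#'
#' @param data 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Numeric length-3, voxel spacing in mm.
#' @param origin Numeric length-3, position of voxel (1,1,1) in mm.
#' @param datatype `"float64"`, `"float32"` or `"uint8"` (masks).
#' @return `path`, invisibly.
#' @keywords internal
write_nifti <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        datatype = c("float64", "float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  dt_code <- switch(datatype, float64 = 64L, float32 = 16L, uint8 = 2L)
  bitpix <- switch(datatype, float64 = 64L, float32 = 32L, uint8 = 8L)

  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw0 <- function(n) writeBin(raw(n), con)

  w_i32(NIFTI_HDR_SIZE)
  w_raw0(36L)                                   # data_type, db_name, extents...
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))       # dim[8]
  w_raw0(14L)
  w_i16(dt_code); w_i16(bitpix); w_i16(0L)
  w_f32(c(1, spacing, 0, 0, 0, 0))              # pixdim[8] (qfac = 1)
  w_f32(NIFTI_VOX_OFFSET)                       # vox_offset
  w_f32(1); w_f32(0)                            # scl_slope, scl_inter
  w_raw0(132L)                                  # slice_end .. aux_file (-> 252)
  w_i16(0L); w_i16(1L)                          # qform_code 0, sform_code 1
  w_f32(rep(0, 6))                              # quaterns b,c,d + offsets x,y,z
  w_f32(c(spacing[1], 0, 0, origin[1]))         # srow_x
  w_f32(c(0, spacing[2], 0, origin[2]))         # srow_y
  w_f32(c(0, 0, spacing[3], origin[3]))         # srow_z
  w_raw0(16L)                                   # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)
  w_raw0(4L)                                    # extension flag

  if (datatype == "uint8") {
    writeBin(as.integer(round(data)), con, size = 1L)
  } else {
    writeBin(as.numeric(data), con,
             size = if (datatype == "float32") 4L else 8L, endian = "little")
  }
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}
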