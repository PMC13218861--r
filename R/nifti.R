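#' Read a NIfTI-1 volume
#'
#' Minimal NIfTI-1 reader covering the files this package writes and the
#' common single-file datatypes (uint8, int16, int32, float32, float64).
#' Handles `.nii` and gzip-compressed `.nii.gz`, both endiannesses, and
#' applies `scl_slope`/`scl_inter` rescaling when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric array with the image dimensions.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop_param("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop_param("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_param("unsupported NIfTI magic '", magic, "'")
  dim_raw <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim_raw[1]
  if (ndim < 1 || ndim > 7) stop_param("invalid NIfTI dim[0]: ", ndim)
  dims <- dim_raw[2:(1 + ndim)]
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "numeric", size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "numeric", size = 4, endian = endian)
  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2" = as.double(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4" = as.double(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "8" = as.double(readBin(con, "integer", n = n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop_param("unsupported NIfTI datatype code ", datatype)
  )
  if (length(vals) != n) stop_param("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(vals, dim = dims)
}

#' Write a NIfTI-1 volume
#'
#' Writes a numeric array as a single-file little-endian NIfTI-1 image
#' (float32 by default), gzip-compressed when the path ends in `.gz`.
#'
#' @param vol Numeric array (2D or 3D).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(vol)
  if (is.null(dims)) dims <- length(vol)
  if (length(dims) > 7) stop_param("too many dimensions for NIfTI")
  code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348)                                   # sizeof_hdr
  w_raw(36)                                    # data_type..dim_info
  w_i16(c(length(dims), dims, rep(1L, 7 - length(dims))))  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)                   # intent_p1..3, intent_code
  w_i16(c(code, bitpix, 0))                     # datatype, bitpix, slice_start
  w_f32(c(0, rep(1, length(dims)), rep(0, 7 - length(dims))))  # pixdim[8]
  w_f32(352)                                    # vox_offset
  w_f32(c(1, 0))                                # scl_slope, scl_inter
  w_i16(0); w_raw(2)                            # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
  w_i32(c(0, 0))                                # glmax, glmin
  w_raw(80 + 24)                                # descrip, aux_file
  w_i16(c(0, 0))                                # qform_code, sform_code
  w_f32(rep(0, 18))                             # quatern/srow
  w_raw(16)                                     # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  w_raw(4)                                      # extension flag
  if (datatype == "float32") w_f32(as.double(vol))
  else writeBin(as.double(vol), con, size = 8, endian = "little")
  invisible(path)
}
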