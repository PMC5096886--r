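# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O in base R.
# Covers the dtypes this pipeline writes: uint8, int16, int32, float32,
# float64. Affine stored/read through the sform (srow_x/y/z, sform_code 1).

.nifti_dtypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 volume
#'
#' @param data numeric/logical array, 3D or 4D.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-mm matrix (RAS); defaults to a scaled identity
#'   from `voxel_size`.
#' @param voxel_size mm per voxel along each spatial axis.
#' @param dtype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @param tr repetition time in seconds, stored in `pixdim[4]` for 4D data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL, voxel_size = c(1, 1, 1),
                        dtype = "float32", tr = 0) {
  dt <- .nifti_dtypes[[dtype]]
  if (is.null(dt)) stop_hv("unsupported NIfTI dtype '%s'", dtype)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop_hv("write_nifti expects a 3D or 4D array, got %dD", nd)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  dims <- dim(data)

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raws <- charToRaw(s)
    writeBin(c(raws, raw(len - length(raws))), con)
  }

  wi(348L, 4L)                       # sizeof_hdr
  writeBin(raw(36L), con)            # data_type[10], db_name[18], extents, session_error, regular, dim_info
  wi(c(nd, dims, rep(1L, 7 - nd)), 2L)  # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(0L, 2L)                         # intent_code
  wi(dt$code, 2L)                    # datatype
  wi(dt$bitpix, 2L)                  # bitpix
  wi(0L, 2L)                         # slice_start
  wf(c(1, voxel_size, if (nd == 4L) tr else 1, 1, 1, 1)[1:8])  # pixdim[8]
  wf(352)                            # vox_offset
  wf(1)                              # scl_slope
  wf(0)                              # scl_inter
  wi(0L, 2L); wi(0L, 1L); wi(0L, 1L) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  writeBin(raw(104L), con)           # descrip[80], aux_file[24]
  wi(0L, 2L)                         # qform_code
  wi(1L, 2L)                         # sform_code
  wf(rep(0, 6))                      # quatern b,c,d, qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  writeBin(raw(16L), con)            # intent_name
  wc("n+1", 4L)                      # magic
  writeBin(raw(4L), con)             # extender

  if (dt$what == "integer") {
    writeBin(as.integer(data), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file written by [write_nifti()] or any
#'   NIfTI-1 writer using one of the supported dtypes.
#' @return list with `data` (array), `affine` (4x4), `voxel_size`, `tr`,
#'   `dtype`.
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed, endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4L, endian = "little")

  sizeof_hdr <- ri(1L, 4L)
  if (!identical(sizeof_hdr, 348L)) stop_hv("not a NIfTI-1 file (sizeof_hdr=%d): %s", sizeof_hdr, path)
  invisible(readBin(con, "raw", n = 36L))
  dim8 <- ri(8L, 2L)
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  rf(3L); ri(1L, 2L)
  datatype <- ri(1L, 2L)
  bitpix <- ri(1L, 2L); ri(1L, 2L)
  pixdim <- rf(8L)
  vox_offset <- rf(1L)
  scl_slope <- rf(1L); scl_inter <- rf(1L)
  ri(1L, 2L); ri(1L, 1L); ri(1L, 1L)
  rf(4L); ri(2L, 4L)
  invisible(readBin(con, "raw", n = 104L))
  ri(1L, 2L)  # qform_code
  sform_code <- ri(1L, 2L)
  rf(6L)
  srow <- rbind(rf(4L), rf(4L), rf(4L))
  invisible(readBin(con, "raw", n = 16L))
  magic <- rawToChar(readBin(con, "raw", n = 4L))
  if (!grepl("^n\\+1", magic)) stop_hv("unsupported NIfTI magic '%s'", magic)
  invisible(readBin(con, "raw", n = 4L))

  idx <- which(vapply(.nifti_dtypes, function(d) d$code == datatype, logical(1)))
  if (!length(idx)) stop_hv("unsupported NIfTI datatype code %d", datatype)
  dt <- .nifti_dtypes[[idx]]
  nvox <- prod(dims)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (!isTRUE(all.equal(scl_slope, 0)) && !isTRUE(all.equal(scl_slope, 1))) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code == 0L) affine <- diag(c(pixdim[2:4], 1))
  list(data = array(vals, dim = dims),
       affine = affine,
       voxel_size = pixdim[2:4],
       tr = if (nd >= 4L) pixdim[5] else NA_real_,
       dtype = names(.nifti_dtypes)[idx])
}

#' Check that two NIfTI affines agree
#'
#' Orientation mismatches between a mask and a BOLD series are a hard error:
#' voxelwise operations silently misalign otherwise.
#'
#' @param affine_a,affine_b 4x4 matrices.
#' @param tol absolute tolerance.
#' @return `TRUE` invisibly, or an error naming both affines.
#' @export
check_affines <- function(affine_a, affine_b, tol = 1e-4) {
  if (max(abs(affine_a - affine_b)) > tol) {
    stop_hv("affine mismatch:\nA = %s\nB = %s",
            paste(signif(affine_a, 5), collapse = " "),
            paste(signif(affine_b, 5), collapse = " "))
  }
  invisible(TRUE)
}
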