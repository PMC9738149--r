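# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, float32 on write).
#
# No NIfTI package ships with this environment, so the format support the
# pipeline needs is implemented directly against the NIfTI-1 header layout
# (348-byte header, vox_offset 352, x-fastest column-major data, which matches
# R array ordering).  Reading supports the common scalar datatypes; writing
# always emits float32 with an identity-scaled sform.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Write a 3D or 4D array as a NIfTI-1 image
#'
#' @param data numeric array with 3 or 4 dimensions.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_size_mm in-plane and through-plane voxel sizes (mm), length 3.
#' @param tr_seconds repetition time stored in `pixdim[4]` (seconds).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(1, 1, 1),
                        tr_seconds = 1) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    abort2("write_nifti() expects a 3D or 4D array", "boldvar_bad_field")
  }
  chk_num(voxel_size_mm, "voxel_size_mm", len = 3L, lower = 1e-6)
  chk_num(tr_seconds, "tr_seconds", lower = 0)
  dims <- c(nd, dim(data), rep(1L, 7L - nd))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wchr <- function(n) writeBin(raw(n), con)

  wint(348L, 4L)                    # sizeof_hdr
  wchr(10L); wchr(18L)              # data_type, db_name (unused)
  wint(0L, 4L); wint(0L, 2L)        # extents, session_error
  writeBin(charToRaw("r"), con)     # regular
  wchr(1L)                          # dim_info
  wint(dims, 2L)                    # dim[8]
  wflt(c(0, 0, 0))                  # intent_p1..p3
  wint(0L, 2L)                      # intent_code
  wint(16L, 2L)                     # datatype = float32
  wint(32L, 2L)                     # bitpix
  wint(0L, 2L)                      # slice_start
  wflt(c(1, voxel_size_mm, tr_seconds, 0, 0, 0))  # pixdim[8]
  wflt(352)                         # vox_offset
  wflt(1); wflt(0)                  # scl_slope, scl_inter
  wint(0L, 2L); wchr(1L)            # slice_end, slice_code
  wint(10L, 1L)                     # xyzt_units: mm | sec
  wflt(c(0, 0, 0, 0))               # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4L)               # glmax, glmin
  wchr(80L); wchr(24L)              # descrip, aux_file
  wint(0L, 2L); wint(1L, 2L)        # qform_code, sform_code
  wflt(c(0, 0, 0, 0, 0, 0))         # quatern b/c/d, qoffset x/y/z
  wflt(c(voxel_size_mm[1], 0, 0, 0))  # srow_x
  wflt(c(0, voxel_size_mm[2], 0, 0))  # srow_y
  wflt(c(0, 0, voxel_size_mm[3], 0))  # srow_z
  wchr(16L)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wchr(4L)                          # pad to vox_offset = 352
  wflt(as.numeric(data))
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return list with `data` (array), `voxel_size_mm`, `tr_seconds`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    abort2(sprintf("NIfTI file not found: %s", path), "boldvar_missing_file")
  }
  magic2 <- readBin(path, "raw", n = 2L)
  gz <- length(magic2) == 2L && magic2[1] == as.raw(0x1f) &&
    magic2[2] == as.raw(0x8b)
  con <- if (gz) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (bitwAnd(bitwShiftR(sizeof_hdr, 24L), 255L) != 92L) {
      # 348 byte-swapped = 0x5C010000
      abort2(sprintf("not a NIfTI-1 file: %s", path), "boldvar_bad_file")
    }
  }
  readBin(con, "raw", 36L)                                    # skip to dim
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                    # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 2L, size = 2L, endian = endian)     # bitpix, start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 348L - 120L)                            # rest of header
  if (vox_offset > 348) readBin(con, "raw", as.integer(vox_offset - 348L))

  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    abort2(sprintf("unsupported NIfTI datatype code %d", datatype),
           "boldvar_bad_file")
  }
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) {
    abort2(sprintf("truncated NIfTI data in %s", path), "boldvar_bad_file")
  }
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(
    data = array(as.numeric(vals), dim = shape),
    voxel_size_mm = pixdim[2:4],
    tr_seconds = if (nd >= 4L) pixdim[5] else NA_real_
  )
}
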