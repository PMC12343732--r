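# Minimal NIfTI-1 reader/writer. No R NIfTI package is available in this
# stack, so the subset of the format the package needs is implemented here:
# single-file .nii / .nii.gz, 3D or 4D, common datatypes on read, float64 on
# write (lossless round-trips of SH coefficients), sform affine. Headers are
# validated against nibabel in the test suite.

NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE))    # float64

nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as a NIfTI-1 image
#'
#' Data are stored as float64 so that coefficient volumes round-trip
#' bit-exactly. The affine goes into the sform (code 1); pixdim is derived
#' from the affine's column norms.
#'
#' @param data numeric array, 3 or 4 dimensional.
#' @param path output path (.nii or .nii.gz).
#' @param affine 4 x 4 voxel-to-world transform.
#' @return the path, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4)) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  dims <- dim(data)
  con <- nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.numeric(x), con, size = size,
                                        endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)   # data_type..dim_info (unused/zero)
  dim8 <- c(nd, dims, rep(1L, 7L - length(dims)))
  wi(dim8, 2L)                                   # dim[8]
  wf(rep(0, 3))                                  # intent_p1..p3
  wi(0L, 2L)                                     # intent_code
  wi(64L, 2L)                                    # datatype = float64
  wi(64L, 2L)                                    # bitpix
  wi(0L, 2L)                                     # slice_start
  pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)), rep(1, 4))
  wf(pixdim)                                     # pixdim[8]
  wf(352L)                                       # vox_offset
  wf(1)                                          # scl_slope
  wf(0)                                          # scl_inter
  wi(0L, 2L); writeBin(raw(2L), con)             # slice_end, slice_code, xyzt
  wf(0); wf(0)                                   # cal_max, cal_min
  wf(0); wi(0L, 4L); wi(0L, 4L)                  # slice_duration, toffset, glmax
  wi(0L, 4L)                                     # glmin
  writeBin(raw(80L + 24L), con)                  # descrip, aux_file
  wi(0L, 2L)                                     # qform_code
  wi(1L, 2L)                                     # sform_code
  wf(rep(0, 6))                                  # quatern b,c,d + offsets
  wf(t(affine[1:3, ]))                           # srow_x/y/z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag
  writeBin(as.numeric(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Supports uint8/int16/int32/float32/float64, little or big endian,
#' single-file .nii/.nii.gz; applies scl_slope/scl_inter when set.
#'
#' @param path file path.
#' @return list with `data` (array), `affine` (4 x 4), `dim`, `pixdim`,
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd_i <- function(off, size, n = 1L, endian = "little")
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  sizeof <- rd_i(0L, 4L)
  endian <- if (sizeof == 348L) "little" else "big"
  if (sizeof != 348L &&
      rd_i(0L, 4L, endian = "big") != 348L)
    stop(path, " is not a NIfTI-1 file")
  rd_i <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  rd_f <- function(off, n = 1L, size = 4L)
    readBin(hdr[(off + 1L):(off + size * n)], "double", n = n, size = size,
            endian = endian)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": unsupported magic '", magic, "'")
  dim8 <- rd_i(40L, 2L, 8L)
  nd <- dim8[1L]
  dims <- dim8[2L:(1L + nd)]
  datatype <- rd_i(70L, 2L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd_f(76L, 8L)
  vox_offset <- rd_f(108L)
  scl_slope <- rd_f(112L); scl_inter <- rd_f(116L)
  srow <- matrix(rd_f(280L, 12L), 3L, 4L, byrow = TRUE)
  sform_code <- rd_i(254L, 2L)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code == 0L) affine <- diag(c(pixdim[2:4], 1))
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n_vals <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vals, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vals) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(as.numeric(vals), dims), affine = affine, dim = dims,
       pixdim = pixdim[2L:(1L + nd)], datatype = datatype)
}
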