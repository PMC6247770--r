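# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Implemented in-package because no NIfTI library is available in the target
# R environment. Covers the common scalar datatypes, both endiannesses, and
# preserves the voxel grid (pixdim + sform affine). Data are written as
# float64, so write -> read round-trips are bit-exact.

#' In-memory image volume
#'
#' @param data numeric array (3-D or 4-D).
#' @param pixdim voxel dimensions, mm (length 3; a 4th entry is the time
#'   step for 4-D data).
#' @param affine optional 4 x 4 voxel-to-world matrix (NIfTI sform, 0-based
#'   voxel indices); defaults to `diag(pixdim)`.
#' @export
nifti_volume <- function(data, pixdim = c(1, 1, 1), affine = NULL) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array")
  if (length(d) < 3) { dim(data) <- c(d, rep(1L, 3 - length(d))); d <- dim(data) }
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- pixdim[1:3]
  }
  structure(list(data = data, pixdim = as.numeric(pixdim), affine = affine),
            class = "nifti_volume")
}

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [nifti_volume()] or a plain array.
#' @param path output path, `.nii` or `.nii.gz`.
#' @param pixdim,affine used when `vol` is a plain array.
#' @export
write_volume <- function(vol, path, pixdim = c(1, 1, 1), affine = NULL) {
  if (!inherits(vol, "nifti_volume")) vol <- nifti_volume(vol, pixdim, affine)
  d <- dim(vol$data)
  ndim <- length(d)
  dim8 <- rep(1L, 8); dim8[1] <- ndim; dim8[1 + seq_len(ndim)] <- as.integer(d)
  pd8 <- rep(0, 8); pd8[1] <- 1
  pd8[2:4] <- vol$pixdim[1:3]
  if (ndim >= 4) pd8[5] <- if (length(vol$pixdim) >= 4) vol$pixdim[4] else 1
  con <- .nii_con(path, "wb")
  on.exit(close(con))
  w_i <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i(348L, 4)                       # sizeof_hdr
  w_raw(10 + 18); w_i(0L, 4); w_i(0L, 2); w_raw(2)  # unused + regular/dim_info
  w_i(dim8, 2)                       # dim[8]
  w_f(c(0, 0, 0)); w_i(0L, 2)        # intent
  w_i(64L, 2); w_i(64L, 2); w_i(0L, 2)  # datatype float64, bitpix, slice_start
  w_f(pd8)                           # pixdim[8]
  w_f(352); w_f(1); w_f(0)           # vox_offset, scl_slope, scl_inter
  w_i(0L, 2); w_raw(2)               # slice_end, slice_code, xyzt_units
  w_f(c(0, 0, 0, 0)); w_i(c(0L, 0L), 4)  # cal_max/min, slice_dur, toffset, gl
  desc <- charToRaw(sprintf("%-80s", "mpcasl"))[1:80]
  writeBin(desc, con); w_raw(24)     # descrip, aux_file
  w_i(0L, 2); w_i(2L, 2)             # qform_code 0, sform_code 2
  w_f(c(0, 0, 0, 0, 0, 0))           # quaternion + qoffset
  A <- vol$affine
  w_f(A[1, ]); w_f(A[2, ]); w_f(A[3, ])
  w_raw(16)                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  w_raw(4)                           # extension flag
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return a [nifti_volume()].
#' @export
read_volume <- function(path) {
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("malformed NIfTI header: file too short")
  rd_i <- function(off, size, n = 1, endian)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  rd_f <- function(off, n = 1, endian)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  endian <- "little"
  if (rd_i(0, 4, 1, endian) != 348) {
    endian <- "big"
    if (rd_i(0, 4, 1, endian) != 348) stop("malformed NIfTI header")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file")
  dim8 <- rd_i(40, 2, 8, endian)
  ndim <- dim8[1]
  if (ndim < 1 || ndim > 7) stop("malformed NIfTI header: bad ndim")
  d <- dim8[1 + seq_len(ndim)]
  datatype <- rd_i(70, 2, 1, endian)
  pixdim <- rd_f(76, 8, endian)[2:5]
  vox_offset <- rd_f(108, 1, endian)
  scl_slope <- rd_f(112, 1, endian)
  scl_inter <- rd_f(116, 1, endian)
  sform <- rd_i(254, 2, 1, endian)
  affine <- diag(4)
  if (sform > 0) {
    affine[1, ] <- rd_f(280, 4, endian)
    affine[2, ] <- rd_f(296, 4, endian)
    affine[3, ] <- rd_f(312, 4, endian)
  } else diag(affine)[1:3] <- pixdim[1:3]
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "16" = readBin(con, "double", n, size = 4, endian = endian),
    "64" = readBin(con, "double", n, size = 8, endian = endian),
    "512" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = endian)),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(data) < n) stop("malformed NIfTI: truncated data")
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- d
  nifti_volume(data, pixdim = pixdim[seq_len(min(ndim, 4))], affine = affine)
}
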