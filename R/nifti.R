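# Minimal single-file NIfTI-1 I/O (.nii / .nii.gz).
#
# Only what the pipeline needs: 3D volumes, the common numeric datatypes,
# sform/qform affines, scl_slope/scl_inter scaling, both endiannesses.
# The offline R stack ships no NIfTI package, so this is carried in-tree.

.nifti_datatypes <- list(
  `2`   = list(name = "uint8",   what = "integer", size = 1L, signed = FALSE),
  `4`   = list(name = "int16",   what = "integer", size = 2L, signed = TRUE),
  `8`   = list(name = "int32",   what = "integer", size = 4L, signed = TRUE),
  `16`  = list(name = "float32", what = "double",  size = 4L, signed = TRUE),
  `64`  = list(name = "float64", what = "double",  size = 8L, signed = TRUE),
  `256` = list(name = "int8",    what = "integer", size = 1L, signed = TRUE),
  `512` = list(name = "uint16",  what = "integer", size = 2L, signed = FALSE)
)

.nifti_code_for <- function(datatype) {
  codes <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
             float64 = 64L, int8 = 256L, uint16 = 512L)
  code <- codes[[datatype]]
  if (is.null(code)) stop("unsupported NIfTI datatype: ", datatype)
  code
}

.quaternion_to_affine <- function(b, c, d, qx, qy, qz, pixdim) {
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c
  ), nrow = 3, byrow = TRUE)
  qfac <- if (is.na(pixdim[1]) || pixdim[1] >= 0) 1 else -1
  R[, 3] <- R[, 3] * qfac
  R <- R %*% diag(abs(pixdim[2:4]))
  affine <- diag(4)
  affine[1:3, 1:3] <- R
  affine[1:3, 4] <- c(qx, qy, qz)
  affine
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), applying
#' `scl_slope`/`scl_inter` scaling when present. Only 3D volumes are used by
#' this package; trailing singleton dimensions are dropped.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `dim` (integer grid
#'   shape), `pixdim` (voxel size in mm), `affine` (4x4 grid-to-world
#'   transform, 0-based voxel indices), and `datatype` (storage type name).
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(offset, what, n, size) {
    readBin(hdr_raw[(offset + 1):(offset + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  ndim <- dim_field[1]
  if (ndim < 1L || ndim > 7L) stop("bad dim[0] in NIfTI header: ", path)
  dims <- dim_field[2:(1 + ndim)]
  datatype_code <- rd(70L, "integer", 1L, 2L)
  dt <- .nifti_datatypes[[as.character(datatype_code)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype_code, ": ", path)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  quatern <- rd(256L, "double", 6L, 4L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3, byrow = TRUE)

  # skip bytes between header end and data start (extensions)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  values <- readBin(con, dt$what, n = n_vox, size = dt$size,
                    signed = dt$signed, endian = endian)
  if (length(values) < n_vox) stop("truncated NIfTI data: ", path)
  values <- as.double(values)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    values <- values * scl_slope + scl_inter
  }
  keep <- max(which(dims > 1L), 1L)
  dims <- dims[seq_len(max(keep, min(3L, ndim)))]
  data <- array(values, dim = dims)

  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    .quaternion_to_affine(quatern[1], quatern[2], quatern[3],
                          quatern[4], quatern[5], quatern[6], pixdim)
  } else {
    a <- diag(4)
    diag(a)[1:3] <- abs(pixdim[2:4])
    a
  }
  list(data = data, dim = as.integer(dim(data)),
       pixdim = abs(pixdim[2:(1 + length(dim(data)))]),
       affine = affine, datatype = dt$name)
}

#' Write a NIfTI-1 volume
#'
#' Writes a numeric array as a single-file NIfTI-1 image. `float64` storage
#' preserves doubles bit-for-bit (used for Jacobian maps); `int32`/`int16`
#' suit label maps.
#'
#' @param data Numeric 3D array.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param affine 4x4 grid-to-world transform (written as sform, code 2).
#' @param datatype One of `"float64"`, `"float32"`, `"int32"`, `"int16"`,
#'   `"uint8"`.
#' @param description Free-text header field (max 79 characters).
#' @return `path`, invisibly.
#' @export
nifti_write <- function(data, path, affine = NULL, datatype = "float64",
                        description = "hierseg") {
  dims <- dim(data)
  if (is.null(dims)) stop("`data` must be an array")
  if (length(dims) > 7L) stop("too many dimensions for NIfTI-1")
  if (is.null(affine)) affine <- diag(4)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  code <- .nifti_code_for(datatype)
  dt <- .nifti_datatypes[[as.character(code)]]
  voxsz <- sqrt(colSums(affine[1:3, 1:3]^2))

  endian <- "little"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = endian)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = endian)
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = endian)
  w_chr <- function(x, n) {
    raw_x <- charToRaw(x)
    if (length(raw_x) >= n) raw_x <- raw_x[seq_len(n - 1L)]
    writeBin(c(raw_x, raw(n - length(raw_x))), con)
  }
  w_i32(348L)                      # sizeof_hdr
  writeBin(raw(35L), con)          # data_type, db_name, extents, session_error, regular
  writeBin(raw(1L), con)           # dim_info
  dim_field <- rep(1L, 8L)
  dim_field[1] <- length(dims)
  dim_field[2:(1 + length(dims))] <- dims
  w_i16(dim_field)
  w_f32(c(0, 0, 0))                # intent_p1..3
  w_i16(c(0L, code, dt$size * 8L, 0L))  # intent_code, datatype, bitpix, slice_start
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:(1 + length(voxsz))] <- voxsz
  w_f32(pixdim)
  w_f32(352)                       # vox_offset
  w_f32(c(1, 0))                   # scl_slope, scl_inter
  w_i16(0L); writeBin(raw(2L), con)  # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_chr(description, 80L)
  w_chr("", 24L)                   # aux_file
  w_i16(c(0L, 2L))                 # qform_code, sform_code
  w_f32(rep(0, 6))                 # quatern_b..d, qoffset_x..z
  w_f32(t(affine[1:3, , drop = FALSE]))  # srow_x, srow_y, srow_z
  w_chr("", 16L)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  writeBin(raw(4L), con)           # extension flag
  values <- as.vector(data)
  if (dt$what == "integer") {
    values <- as.integer(round(values))
    writeBin(values, con, size = dt$size, endian = endian)
  } else {
    writeBin(as.double(values), con, size = dt$size, endian = endian)
  }
  invisible(path)
}
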