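#' Image volume container
#'
#' A `acm_volume` holds a 3D (or 4D, volume series) numeric grid together
#' with its voxel-to-world affine. Voxel indexing is 0-based: continuous
#' voxel coordinate `v` maps to world position `affine %*% c(v, 1)`, and
#' voxel centers sit at integer coordinates. `space` tags the grid as
#' `"subject"` or `"atlas"` so pipeline stages can assert they are combining
#' co-registered inputs.
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param affine 4x4 voxel-to-world matrix (mm). Must be invertible.
#' @param space label, `"subject"` or `"atlas"`.
#' @return An object of class `acm_volume` with fields `data`, `affine`,
#'   `voxel_size` (mm per axis, derived from the affine) and `space`.
#' @export
as_volume <- function(data, affine = diag(4), space = "subject") {
  data <- as.array(data)
  if (!(length(dim(data)) %in% c(3L, 4L)))
    stop("volume data must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (!all(is.finite(affine))) stop("affine contains non-finite values")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(!is.finite(vs)) || any(vs <= 0)) stop("voxel sizes must be positive")
  structure(list(data = data, affine = affine, voxel_size = vs,
                 space = space),
            class = "acm_volume")
}

#' @export
print.acm_volume <- function(x, ...) {
  cat(sprintf("<acm_volume> %s grid, space=%s, voxel=%s mm\n",
              paste(dim(x$data), collapse = "x"), x$space,
              paste(sprintf("%.3g", x$voxel_size), collapse = "x")))
  invisible(x)
}

#' @export
dim.acm_volume <- function(x) dim(x$data)

#' Spatial (i, j, k) dimensions of a volume
#' @param volume an `acm_volume`.
#' @export
grid_dim <- function(volume) dim(volume$data)[1:3]

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) && max(abs(a$affine - b$affine)) < tol
}

#' Binary mask constructor
#'
#' Validates that the grid holds only 0/1 values and wraps it as a volume.
#'
#' @param data 3D array of 0/1 (logical accepted).
#' @inheritParams as_volume
#' @export
as_mask <- function(data, affine = diag(4), space = "subject") {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  as_volume(data, affine, space)
}

## ---- NIfTI-1 I/O -----------------------------------------------------------
## Minimal single-file .nii support (optionally gzipped). Only the fields the
## pipeline needs are honoured: dim, datatype, pixdim, vox_offset, scl_*,
## sform/qform. No R NIfTI package is available in the target environment,
## so the format is handled here directly.

.nii_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Read a NIfTI-1 volume
#'
#' Reads an uncompressed or gzipped single-file NIfTI-1 image. The affine is
#' taken from the sform when `sform_code > 0`, else from the qform, else
#' from `pixdim`. Data are returned as doubles with `scl_slope`/`scl_inter`
#' applied when set.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param space space tag attached to the returned volume.
#' @return An [as_volume()] object.
#' @export
read_volume <- function(path, space = "subject") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  rd <- function(raw, what, n, size, endian, signed = TRUE)
    readBin(raw, what, n = n, size = size, endian = endian, signed = signed)
  endian <- "little"
  sizeof_hdr <- rd(hdr_raw, "integer", 1L, 4L, endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- rd(hdr_raw, "integer", 1L, 4L, endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  at <- function(off, what, n, size, signed = TRUE)
    rd(hdr_raw[(off + 1L):(off + n * size)], what, n, size, endian, signed)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  dim_field <- at(40L, "integer", 8L, 2L)
  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 4L) stop("only 3D/4D NIfTI volumes are supported")
  dims <- dim_field[2:(1 + ndim)]
  datatype <- at(70L, "integer", 1L, 2L)
  pixdim <- at(76L, "double", 8L, 4L)
  if (any(!is.finite(pixdim[2:4]))) stop("NaN voxel sizes in header")
  vox_offset <- at(108L, "double", 1L, 4L)
  scl_slope <- at(112L, "double", 1L, 4L)
  scl_inter <- at(116L, "double", 1L, 4L)
  qform_code <- at(252L, "integer", 1L, 2L)
  sform_code <- at(254L, "integer", 1L, 2L)
  srow <- matrix(at(280L, "double", 12L, 4L), nrow = 3, byrow = TRUE)

  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- at(256L, "double", 6L, 4L)
    b <- q[1]; c_ <- q[2]; d <- q[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
                  2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
                  2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2),
                nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    A <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    rbind(cbind(A, q[4:6]), c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }

  dt <- .nii_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  # skip to the data (4-byte extension flag sits between header and data)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n_vox) stop("truncated NIfTI data section: ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  as_volume(array(vals, dim = dims), affine, space = space)
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file uncompressed `.nii` (or gzipped when the path ends
#' in `.gz`) with the volume's affine stored in the sform (code 2). The
#' round trip through [read_volume()] is lossless for `float32` payloads
#' whose values are representable in single precision, and bit-exact for
#' `int32`/`float64`.
#'
#' @param volume an `acm_volume`.
#' @param path output path.
#' @param dtype one of `"float32"`, `"float64"`, `"int32"`, `"uint8"`.
#' @export
write_volume <- function(volume, path, dtype = "float32") {
  stopifnot(inherits(volume, "acm_volume"))
  code <- switch(dtype, uint8 = 2L, int32 = 8L, float32 = 16L, float64 = 64L,
                 stop("unsupported dtype: ", dtype))
  bitpix <- switch(dtype, uint8 = 8L, int32 = 32L, float32 = 32L, float64 = 64L)
  dims <- dim(volume$data)
  ndim <- length(dims)
  dim_field <- rep(1L, 8L); dim_field[1] <- ndim
  dim_field[2:(1 + ndim)] <- as.integer(dims)
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- volume$voxel_size
  if (ndim == 4L) pixdim[5] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                  # sizeof_hdr
  w(raw(36L), 1L)                              # data_type..dim_info
  w(dim_field, 2L)                             # dim
  w(c(0, 0, 0), 4L)                            # intent_p1..p3
  w(c(0L, code, bitpix, 0L), 2L)               # intent_code, datatype, bitpix, slice_start
  w(pixdim, 4L)                                # pixdim
  w(c(352, 1, 0), 4L)                          # vox_offset, scl_slope, scl_inter
  w(0L, 2L); w(raw(2L), 1L)                    # slice_end, slice_code, xyzt_units
  w(c(0, 0, 0, 0), 4L)                         # cal_max..toffset
  w(c(0L, 0L), 4L)                             # glmax, glmin
  w(raw(104L), 1L)                             # descrip, aux_file
  w(c(0L, 2L), 2L)                             # qform_code, sform_code
  w(rep(0, 6), 4L)                             # quatern/qoffset
  w(as.vector(t(volume$affine[1:3, ])), 4L)    # srow_x/y/z
  w(raw(16L), 1L)                              # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w(raw(1L), 1L)
  w(raw(4L), 1L)                               # extension flag
  vals <- as.vector(volume$data)
  if (dtype %in% c("int32", "uint8")) {
    writeBin(as.integer(round(vals)), con, size = bitpix %/% 8L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}
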