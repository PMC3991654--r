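#' Tensor field container
#'
#' Array-backed grid of multi-tensor voxel models over a binary mask.
#' Internally: `n_fibers` (integer, 0 outside the mask), `d6` components
#' `[i, j, k, fiber, 6]` in (xx, yy, zz, xy, xz, yz) order, `frac`
#' `[i, j, k, fiber]`, `s0`, plus grid geometry.
#'
#' @param dim length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @param space `"subject"` or `"atlas"`.
#' @export
tensor_field <- function(dim, affine = diag(4), space = "subject") {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L)
  structure(list(
    dim = dim, affine = as.matrix(affine),
    voxel_size = sqrt(colSums(as.matrix(affine)[1:3, 1:3]^2)),
    space = space,
    n_fibers = array(0L, dim),
    d6 = array(0, c(dim, 2L, 6L)),
    frac = array(0, c(dim, 2L)),
    s0 = array(0, dim)
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s, space=%s, %d voxels (%d two-fiber)\n",
              paste(x$dim, collapse = "x"), x$space, sum(x$n_fibers > 0),
              sum(x$n_fibers == 2L)))
  invisible(x)
}

#' Set one voxel of a tensor field
#' @param field a [tensor_field()]; `i,j,k` 1-based indices;
#'   `model` a [multi_tensor_voxel()] or NULL to clear.
#' @export
set_field_voxel <- function(field, i, j, k, model) {
  if (is.null(model)) {
    field$n_fibers[i, j, k] <- 0L
    field$frac[i, j, k, ] <- 0
    field$s0[i, j, k] <- 0
    return(field)
  }
  field$n_fibers[i, j, k] <- model$n_fibers
  for (f in seq_len(model$n_fibers)) {
    field$d6[i, j, k, f, ] <- mat_to_d6(model$tensors[[f]])
    field$frac[i, j, k, f] <- model$fractions[f]
  }
  if (model$n_fibers == 1L) field$frac[i, j, k, 2] <- 0
  field$s0[i, j, k] <- model$s0
  field
}

#' Extract one voxel of a tensor field
#' @inheritParams set_field_voxel
#' @return A [multi_tensor_voxel()], or NULL for background voxels.
#' @export
field_voxel <- function(field, i, j, k) {
  n <- field$n_fibers[i, j, k]
  if (n == 0L) return(NULL)
  tensors <- lapply(seq_len(n), function(f) d6_to_mat(field$d6[i, j, k, f, ]))
  fr <- field$frac[i, j, k, seq_len(n)]
  multi_tensor_voxel(tensors, fr / sum(fr), field$s0[i, j, k])
}

#' Mask of defined (in-model) voxels
#' @param field a [tensor_field()].
#' @export
field_mask <- function(field) {
  as_mask(array(as.numeric(field$n_fibers > 0L), field$dim),
          field$affine, field$space)
}

#' Per-voxel FA and MD maps of a tensor field
#'
#' Scalar maps computed from the largest-fraction tensor of each voxel;
#' background voxels are 0.
#'
#' @param field a [tensor_field()].
#' @return An [as_volume()].
#' @export
fa_map <- function(field) scalar_map(field, compute_fa)

#' @rdname fa_map
#' @export
md_map <- function(field) scalar_map(field, compute_md)

scalar_map <- function(field, fun) {
  out <- array(0, field$dim)
  idx <- which(field$n_fibers > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    f <- which.max(field$frac[i, j, k, ])
    out[i, j, k] <- fun(d6_to_mat(field$d6[i, j, k, f, ]))
  }
  as_volume(out, field$affine, field$space)
}

#' Fit a tensor field from a diffusion-weighted volume series
#'
#' Runs [fit_single_tensor()] in every mask voxel; where `max_fibers = 2`,
#' voxels whose single-tensor model is rejected by
#' [classify_fibre_count()] get the two-tensor fit.
#'
#' @param dwi 4D `acm_volume` (one 3D volume per gradient entry).
#' @param gtab a [gradient_table()].
#' @param mask binary `acm_volume`; only mask voxels are fitted.
#' @param max_fibers 1 or 2.
#' @param alpha model-selection F-test level.
#' @param refine nonlinear refinement of single-tensor fits.
#' @export
fit_tensor_field <- function(dwi, gtab, mask, max_fibers = 2, alpha = 0.05,
                             refine = TRUE) {
  stopifnot(inherits(dwi, "acm_volume"), length(dim(dwi$data)) == 4L)
  if (dim(dwi$data)[4] != length(gtab$bvals))
    stop("4th DWI axis does not match gradient table")
  field <- tensor_field(grid_dim(dwi), dwi$affine, dwi$space)
  idx <- which(mask$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    sig <- dwi$data[i, j, k, ]
    single <- fit_single_tensor(sig, gtab, refine = refine)
    model <- multi_tensor_voxel(list(single$tensor), 1, single$s0)
    if (max_fibers >= 2) {
      energy <- sum(sig^2)
      if (single$rss > 1e-12 * energy) {
        two <- fit_two_tensor(sig, gtab, single = single)
        if (classify_fibre_count(sig, gtab, alpha, single = single,
                                 two = two) == 2L)
          model <- two
      }
    }
    field <- set_field_voxel(field, i, j, k, model)
  }
  field
}

#' Serialize / deserialize a tensor field as multi-volume NIfTI
#'
#' Writes `<prefix>_d1.nii`, `<prefix>_d2.nii` (6-component 4D tensor
#' volumes), `<prefix>_frac.nii`, `<prefix>_nfib.nii` and `<prefix>_s0.nii`.
#' Values are stored as float64 so the round trip is bit-exact.
#'
#' @param field a [tensor_field()]; `prefix` output path prefix.
#' @export
write_tensor_field <- function(field, prefix) {
  aff <- field$affine
  wr <- function(arr, name, dtype = "float64")
    write_volume(as_volume(arr, aff, field$space),
                 paste0(prefix, "_", name, ".nii"), dtype)
  wr(array(field$d6[, , , 1, ], c(field$dim, 6L)), "d1")
  wr(array(field$d6[, , , 2, ], c(field$dim, 6L)), "d2")
  wr(field$frac, "frac")
  wr(array(as.numeric(field$n_fibers), field$dim), "nfib", "int32")
  wr(field$s0, "s0")
  invisible(prefix)
}

#' @rdname write_tensor_field
#' @param space space tag for the loaded field.
#' @export
read_tensor_field <- function(prefix, space = "subject") {
  rd <- function(name) read_volume(paste0(prefix, "_", name, ".nii"))
  d1 <- rd("d1"); d2 <- rd("d2"); fr <- rd("frac"); nf <- rd("nfib")
  s0 <- rd("s0")
  field <- tensor_field(grid_dim(d1), d1$affine, space)
  field$d6[, , , 1, ] <- d1$data
  field$d6[, , , 2, ] <- d2$data
  field$frac <- fr$data
  field$n_fibers <- array(as.integer(round(nf$data)), field$dim)
  field$s0 <- s0$data
  field
}
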