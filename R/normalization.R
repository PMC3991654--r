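## Spatial normalization of tensor fields. A deformation field stores, on
## the atlas grid, the displacement (mm) that maps each atlas position to
## its corresponding subject position (pull-back convention). Warping pulls
## the subject-space multi-tensor model back onto the atlas grid and
## reorients every component tensor with the preservation-of-principal-
## direction (PPD) rule, which leaves eigenvalues (hence FA/MD) untouched.

#' Deformation field constructors
#'
#' `deformation_from_function` evaluates an analytic atlas-to-subject world
#' map on the atlas grid and stores its displacement; `deformation_identity`
#' and `deformation_affine` are the obvious specializations, and
#' `deformation_radial_bump` adds a localized Gaussian radial expansion
#' (an atrophy-like volume change) for tests. All constructors are
#' download-free so every warp test can be run from code.
#'
#' @param dim atlas grid dimensions (length 3).
#' @param affine atlas voxel-to-world matrix.
#' @param fn function taking a 3 x n matrix of world positions and
#'   returning the mapped 3 x n subject positions.
#' @return A `deformation_field` with fields `disp` (`[i,j,k,3]`, mm),
#'   `affine`, `dim`, `voxel_size`.
#' @export
deformation_from_function <- function(dim, affine = diag(4), fn) {
  dim <- as.integer(dim)
  idx <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                               k = 0:(dim[3] - 1)))
  W <- affine %*% rbind(t(idx), 1)
  mapped <- fn(W[1:3, , drop = FALSE])
  disp <- array(0, c(dim, 3L))
  for (c_ in 1:3) disp[, , , c_] <- array(mapped[c_, ] - W[c_, ], dim)
  if (any(!is.finite(disp))) stop("non-finite displacement")
  structure(list(disp = disp, affine = as.matrix(affine), dim = dim,
                 voxel_size = sqrt(colSums(as.matrix(affine)[1:3, 1:3]^2))),
            class = "deformation_field")
}

#' @rdname deformation_from_function
#' @export
deformation_identity <- function(dim, affine = diag(4))
  deformation_from_function(dim, affine, function(W) W)

#' @rdname deformation_from_function
#' @param A 4x4 world-to-world affine (atlas position to subject position).
#' @export
deformation_affine <- function(dim, affine = diag(4), A)
  deformation_from_function(dim, affine, function(W)
    (A %*% rbind(W, 1))[1:3, , drop = FALSE])

#' @rdname deformation_from_function
#' @param center world-space bump center; `amplitude` peak displacement
#'   (mm); `sigma` Gaussian radius (mm).
#' @export
deformation_radial_bump <- function(dim, affine = diag(4), center,
                                    amplitude = 1, sigma = 5)
  deformation_from_function(dim, affine, function(W) {
    d <- W - center
    r <- sqrt(colSums(d^2))
    scale <- amplitude * exp(-r^2 / (2 * sigma^2))
    W + sweep(d, 2, ifelse(r > 0, scale / pmax(r, 1e-12), 0), "*")
  })

#' Map atlas voxel indices to subject world positions
#' @param def a deformation field; `idx` n x 3 matrix of 0-based voxel
#'   indices.
#' @export
deformation_map <- function(def, idx) {
  idx <- matrix(idx, ncol = 3)
  W <- def$affine %*% rbind(t(idx), 1)
  lin <- idx[, 1] + def$dim[1] * (idx[, 2] + def$dim[2] * idx[, 3]) + 1
  n <- prod(def$dim)
  d <- cbind(def$disp[lin], def$disp[lin + n], def$disp[lin + 2 * n])
  t(W[1:3, , drop = FALSE]) + d
}

## displacement gradient d(disp_c)/d(voxel_a), central differences inside,
## one-sided at the grid edges -> array [i,j,k,comp,axis]
disp_gradient <- function(def) {
  d <- def$dim
  G <- array(0, c(d, 3L, 3L))
  for (a in 1:3) {
    n <- d[a]
    if (n < 2) stop("grid too small for finite differences")
    hi <- c(2:n, n); lo <- c(1, 1:(n - 1))
    den <- rep(2, n); den[1] <- 1; den[n] <- 1
    for (c_ in 1:3) {
      x <- def$disp[, , , c_]
      if (a == 1) diffq <- (x[hi, , ] - x[lo, , ]) / den
      if (a == 2) diffq <- (x[, hi, ] - x[, lo, ]) / rep(den, each = d[1])
      if (a == 3) diffq <- sweep(x[, , hi] - x[, , lo], 3, den, "/")
      G[, , , c_, a] <- diffq
    }
  }
  G
}

#' Local affine of a deformation at an atlas voxel
#'
#' Returns `F = d(subject position) / d(atlas position)` at the given
#' 0-based voxel index, from central finite differences of the mapping at
#' voxel spacing. Positions on the grid boundary are an error unless
#' `one_sided = TRUE` (then one-sided differences are used there).
#'
#' @param def a deformation field; `pos` integer 0-based voxel index
#'   (length 3).
#' @param one_sided allow boundary voxels via one-sided differences.
#' @export
local_affine <- function(def, pos, one_sided = FALSE) {
  pos <- as.integer(round(pos))
  if (any(pos < 0) || any(pos > def$dim - 1L)) stop("position outside grid")
  if (!one_sided && (any(pos < 1L) || any(pos > def$dim - 2L)))
    stop("position on grid boundary")
  A3 <- def$affine[1:3, 1:3]
  Dd <- matrix(0, 3, 3)
  get_disp <- function(p) {
    lin <- p[1] + def$dim[1] * (p[2] + def$dim[2] * p[3]) + 1
    n <- prod(def$dim)
    c(def$disp[lin], def$disp[lin + n], def$disp[lin + 2 * n])
  }
  for (a in 1:3) {
    hi <- pos; lo <- pos
    hi[a] <- min(pos[a] + 1L, def$dim[a] - 1L)
    lo[a] <- max(pos[a] - 1L, 0L)
    Dd[, a] <- (get_disp(hi) - get_disp(lo)) / (hi[a] - lo[a])
  }
  (A3 + Dd %*% diag(1, 3)) %*% solve(A3) # d/dworld = d/dvoxel * dvoxel/dworld
}

#' PPD tensor reorientation
#'
#' Preservation of principal direction: the principal eigenvector is mapped
#' through `F` and renormalized; the second eigenvector is mapped, made
#' orthogonal to the new principal axis and renormalized; the third
#' completes the right-handed frame. The original eigenvalues are laid on
#' the new frame, so FA and MD are exactly preserved.
#'
#' @param tensor symmetric 3x3 diffusion tensor.
#' @param Fmat invertible local affine (3x3).
#' @export
ppd_reorient <- function(tensor, Fmat) {
  if (abs(det(Fmat)) < 1e-12) stop("singular local affine")
  e <- eigen(tensor, symmetric = TRUE)
  lam <- e$values
  v1 <- Fmat %*% e$vectors[, 1]
  n1l <- sqrt(sum(v1^2))
  if (n1l < 1e-12) stop("principal direction maps to zero")
  n1 <- v1 / n1l
  v2 <- Fmat %*% e$vectors[, 2]
  v2 <- v2 - sum(v2 * n1) * n1
  n2l <- sqrt(sum(v2^2))
  n2 <- if (n2l < 1e-12) {
    # degenerate image of e2: any unit vector orthogonal to n1
    cand <- diag(3)[, which.min(abs(n1))]
    w <- cand - sum(cand * n1) * n1
    w / sqrt(sum(w^2))
  } else v2 / n2l
  n3 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  V <- cbind(n1, n2, n3)
  V %*% diag(lam) %*% t(V)
}

#' Warp a subject-space tensor field onto the atlas grid
#'
#' For each atlas mask voxel the mapped subject position is looked up by
#' nearest neighbour in the subject field (no interpolation of model
#' parameters across voxels with possibly different fiber counts), and
#' every component tensor is PPD-reoriented with the deformation's local
#' affine. Fractions and S0 are carried over. Atlas voxels mapping outside
#' the subject grid, or onto subject background, become background.
#'
#' @param field subject-space [tensor_field()].
#' @param def deformation field on the atlas grid (atlas -> subject).
#' @param atlas_mask binary `acm_volume` on the atlas grid.
#' @export
warp_tensor_field <- function(field, def, atlas_mask) {
  stopifnot(inherits(field, "tensor_field"),
            inherits(def, "deformation_field"))
  if (!all(grid_dim(atlas_mask) == def$dim))
    stop("atlas mask and deformation grids differ")
  out <- tensor_field(def$dim, def$affine, space = "atlas")
  idx <- which(atlas_mask$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty atlas mask")
  sub_pos <- deformation_map(def, idx - 1L)
  V <- solve(field$affine) %*% rbind(t(sub_pos), 1)
  svox <- round(t(V[1:3, , drop = FALSE]))
  n_used <- 0L
  for (r in seq_len(nrow(idx))) {
    sv <- svox[r, ]
    if (any(sv < 0) || any(sv > field$dim - 1L)) next
    model <- field_voxel(field, sv[1] + 1L, sv[2] + 1L, sv[3] + 1L)
    if (is.null(model)) next
    Floc <- local_affine(def, idx[r, ] - 1L, one_sided = TRUE)
    tensors <- lapply(model$tensors, ppd_reorient, Fmat = Floc)
    out <- set_field_voxel(out, idx[r, 1], idx[r, 2], idx[r, 3],
                           multi_tensor_voxel(tensors, model$fractions,
                                              model$s0))
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    warning("all atlas voxels mapped outside the subject field")
  out
}

#' Jacobian determinant map of a deformation
#'
#' det of [local_affine()] per atlas voxel (one-sided differences at grid
#' edges). Values > 1 mean the local subject tissue is larger than the
#' atlas (the stored map is atlas -> subject).
#'
#' @param def a deformation field.
#' @return An [as_volume()] of det(J), dimensionless.
#' @export
jacobian_map <- function(def) {
  G <- disp_gradient(def)
  A3 <- def$affine[1:3, 1:3]
  A3inv <- solve(A3)
  n <- prod(def$dim)
  # F = (A3 + Dd) %*% A3inv, vectorized over voxels
  Fv <- array(0, c(n, 3, 3))
  Gm <- array(G, c(n, 3, 3))
  for (r in 1:3) for (c_ in 1:3) {
    acc <- 0
    for (m in 1:3) acc <- acc + (A3[r, m] + Gm[, r, m]) * A3inv[m, c_]
    Fv[, r, c_] <- acc
  }
  detv <- Fv[, 1, 1] * (Fv[, 2, 2] * Fv[, 3, 3] - Fv[, 2, 3] * Fv[, 3, 2]) -
    Fv[, 1, 2] * (Fv[, 2, 1] * Fv[, 3, 3] - Fv[, 2, 3] * Fv[, 3, 1]) +
    Fv[, 1, 3] * (Fv[, 2, 1] * Fv[, 3, 2] - Fv[, 2, 2] * Fv[, 3, 1])
  as_volume(array(detv, def$dim), def$affine, space = "atlas")
}

#' Voxel-based atrophy covariate
#'
#' White-matter mask modulated by the Jacobian determinant of the
#' atlas-to-subject deformation and divided by the subject's intracranial
#' volume, giving a per-subject volume on the atlas grid whose voxels
#' reflect local tissue quantity relative to head size.
#'
#' @param wm_mask binary atlas-space mask volume.
#' @param def deformation field (atlas grid).
#' @param icv intracranial volume (mm^3), positive.
#' @export
atrophy_covariate <- function(wm_mask, def, icv) {
  if (!is.numeric(icv) || icv <= 0) stop("icv must be positive")
  if (!all(grid_dim(wm_mask) == def$dim)) stop("mask/deformation grid mismatch")
  J <- jacobian_map(def)
  as_volume(wm_mask$data * J$data / icv, def$affine, space = "atlas")
}

#' Deformation field NIfTI I/O
#'
#' Stored as a 4D displacement volume (3 components, mm, pull-back
#' convention: atlas position + displacement = subject position).
#'
#' @param def a deformation field; `path` a `.nii` path.
#' @export
write_deformation_field <- function(def, path) {
  write_volume(as_volume(def$disp, def$affine, "atlas"), path, "float64")
}

#' @rdname write_deformation_field
#' @export
read_deformation_field <- function(path) {
  v <- read_volume(path)
  d <- dim(v$data)
  if (length(d) != 4L || d[4] != 3L)
    stop("deformation volume must be 4D with 3 components")
  structure(list(disp = v$data, affine = v$affine, dim = d[1:3],
                 voxel_size = v$voxel_size),
            class = "deformation_field")
}
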