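## Resampling onto a target grid. "tricubic" is Keys cubic convolution
## (a = -1/2) with mirror boundary handling; it reproduces linear ramps
## exactly, which is the property the pipeline's re-slicing relies on.
## "nearest" never invents values, so label/mask volumes stay valid.

keys_weights <- function(t, a = -0.5) {
  # weights for source offsets (-1, 0, 1, 2) at fractional position t in [0,1)
  w_near <- function(x) (a + 2) * x^3 - (a + 3) * x^2 + 1        # |x| <= 1
  w_far  <- function(x) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a # 1 < |x| < 2
  list(w_far(1 + t), w_near(t), w_near(1 - t), w_far(2 - t))
}

mirror_index <- function(i, d) {
  # reflect 0-based index into [0, d-1], symmetric about edge voxel centers
  if (d == 1L) return(rep(0L, length(i)))
  period <- 2L * (d - 1L)
  m <- ((i %% period) + period) %% period
  ifelse(m >= d, period - m, m)
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: each target voxel center is mapped through both
#' affines into the source grid and interpolated there. `nearest` preserves
#' the input value set; `tricubic` is cubic-convolution interpolation with
#' mirror boundaries. Target positions mapping outside the source grid get
#' 0 (nearest) or mirrored values (tricubic stays defined via reflection
#' only within one voxel of the edge; farther out it returns 0).
#'
#' @param volume source `acm_volume` (3D).
#' @param target an `acm_volume` or a list with `dim` (length 3) and
#'   `affine` (4x4) describing the output grid.
#' @param method `"tricubic"` or `"nearest"`.
#' @export
resample <- function(volume, target, method = c("tricubic", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "acm_volume"))
  tdim <- if (inherits(target, "acm_volume")) grid_dim(target) else target$dim
  taff <- if (inherits(target, "acm_volume")) target$affine else target$affine
  taff <- as.matrix(taff)
  if (abs(det(taff)) < 1e-12) stop("degenerate target affine")
  sdim <- grid_dim(volume)
  src <- volume$data
  if (length(dim(src)) != 3L) stop("resample expects a 3D volume")

  M <- solve(volume$affine) %*% taff      # target voxel -> source voxel
  idx <- as.matrix(expand.grid(i = 0:(tdim[1] - 1), j = 0:(tdim[2] - 1),
                               k = 0:(tdim[3] - 1)))
  P <- M %*% rbind(t(idx), 1)             # 4 x n source voxel coords
  px <- P[1, ]; py <- P[2, ]; pz <- P[3, ]

  if (method == "nearest") {
    ri <- round(px); rj <- round(py); rk <- round(pz)
    inside <- ri >= 0 & ri <= sdim[1] - 1 & rj >= 0 & rj <= sdim[2] - 1 &
      rk >= 0 & rk <= sdim[3] - 1
    out <- numeric(length(px))
    lin <- ri[inside] + sdim[1] * (rj[inside] + sdim[2] * rk[inside]) + 1
    out[inside] <- src[lin]
  } else {
    inside <- px > -1 & px < sdim[1] & py > -1 & py < sdim[2] &
      pz > -1 & pz < sdim[3]
    bx <- floor(px); by <- floor(py); bz <- floor(pz)
    wx <- keys_weights(px - bx); wy <- keys_weights(py - by)
    wz <- keys_weights(pz - bz)
    out <- numeric(length(px))
    for (dz in 0:3) {
      kz <- mirror_index(bz + dz - 1, sdim[3])
      for (dy in 0:3) {
        ky <- mirror_index(by + dy - 1, sdim[2])
        wyz <- wy[[dy + 1]] * wz[[dz + 1]]
        for (dx in 0:3) {
          kx <- mirror_index(bx + dx - 1, sdim[1])
          lin <- kx + sdim[1] * (ky + sdim[2] * kz) + 1
          out <- out + wx[[dx + 1]] * wyz * src[lin]
        }
      }
    }
    out[!inside] <- 0
  }
  as_volume(array(out, dim = tdim), taff, space = volume$space)
}
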