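## Synthetic data: fiber phantoms with known geometry, simulated DWI with
## Rician noise, and multi-subject cohorts with focal lesions and a
## disability score coupled to tract damage. Defaults emulate the target protocol's
## stated world: 10 b0 + 61 diffusion directions at b = 1200 s/mm^2,
## SNR 16, group sizes 20 / 19 / 15 with matching per-group age distributions.

#' Default single-shell acquisition scheme
#'
#' 10 b0 volumes followed by 61 diffusion-weighted directions
#' (deterministic Fibonacci-hemisphere set shipped with the package) at
#' the given b-factor.
#'
#' @param n_b0 number of b0 volumes.
#' @param bval shell b-factor, s/mm^2.
#' @export
default_gradients <- function(n_b0 = 10, bval = 1200) {
  dirs <- as.matrix(read.table(
    system.file("extdata", "dirs61.txt", package = "acmap")))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bvals <- c(rep(0, n_b0), rep(bval, nrow(dirs)))
  bvecs <- cbind(matrix(0, 3, n_b0), t(dirs))
  gradient_table(bvals, bvecs)
}

#' Phantom specification
#'
#' @param geometry `"straight_tube"`, `"crossing"` or `"curved_arc"`.
#' @param dims grid dimensions.
#' @param radius tube radius in voxels.
#' @param eigenvalues fiber tensor eigenvalues (mm^2/s), decreasing.
#' @param background_diffusivity isotropic background diffusivity
#'   (mm^2/s); background voxels have FA exactly 0.
#' @param s0 non-diffusion-weighted signal.
#' @param voxel_size_mm isotropic voxel size.
#' @export
phantom_spec <- function(geometry = c("straight_tube", "crossing",
                                      "curved_arc"),
                         dims = c(24, 16, 16), radius = 2,
                         eigenvalues = c(1.7e-3, 3e-4, 3e-4),
                         background_diffusivity = 7e-4, s0 = 1,
                         voxel_size_mm = 2) {
  geometry <- match.arg(geometry)
  eigenvalues <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  if (any(eigenvalues <= 0)) stop("eigenvalues must be positive")
  if (2 * radius >= min(dims)) stop("tube does not fit inside the grid")
  structure(list(geometry = geometry, dims = as.integer(dims),
                 radius = radius, eigenvalues = eigenvalues,
                 background_diffusivity = background_diffusivity,
                 s0 = s0, voxel_size_mm = voxel_size_mm),
            class = "phantom_spec")
}

tensor_from_axis <- function(axis, lam) {
  axis <- axis / sqrt(sum(axis^2))
  # complete an orthonormal frame around the tangent
  h <- diag(3)[, which.min(abs(axis))]
  u2 <- h - sum(h * axis) * axis; u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(axis[2] * u2[3] - axis[3] * u2[2],
          axis[3] * u2[1] - axis[1] * u2[3],
          axis[1] * u2[2] - axis[2] * u2[1])
  V <- cbind(axis, u2, u3)
  V %*% diag(lam) %*% t(V)
}

#' Build a tensor phantom
#'
#' In-tube voxels carry a prolate tensor aligned with the local tract
#' tangent; the crossing geometry yields two-tensor voxels (equal
#' fractions, orthogonal modes) in the overlap; everything else carries an
#' isotropic background tensor, so the FA > 0 rule reproduces the tube as
#' the brain/seed mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with `field` (a [tensor_field()]) and `mask` (tube voxels,
#'   an `acm_volume`).
#' @export
make_tensor_phantom <- function(spec) {
  d <- spec$dims
  affine <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  field <- tensor_field(d, affine)
  mask <- array(0, d)
  cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2; cx <- (d[1] - 1) / 2
  lam <- spec$eigenvalues
  bg <- diag(rep(spec$background_diffusivity, 3))
  Dx <- tensor_from_axis(c(1, 0, 0), lam)
  Dy <- tensor_from_axis(c(0, 1, 0), lam)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    x <- i - 1; y <- j - 1; z <- k - 1
    in_x_tube <- (y - cy)^2 + (z - cz)^2 <= spec$radius^2
    model <- NULL
    if (spec$geometry == "straight_tube") {
      if (in_x_tube) model <- multi_tensor_voxel(list(Dx), 1, spec$s0)
    } else if (spec$geometry == "crossing") {
      in_y_tube <- (x - cx)^2 + (z - cz)^2 <= spec$radius^2
      if (in_x_tube && in_y_tube)
        model <- multi_tensor_voxel(list(Dx, Dy), c(0.5, 0.5), spec$s0)
      else if (in_x_tube) model <- multi_tensor_voxel(list(Dx), 1, spec$s0)
      else if (in_y_tube) model <- multi_tensor_voxel(list(Dy), 1, spec$s0)
    } else { # curved_arc: quarter circle in the xy plane around (0, 0)
      R <- 0.7 * min(d[1], d[2])
      r2d <- sqrt(x^2 + y^2)
      if (abs(r2d - R) <= spec$radius && abs(z - cz) <= spec$radius &&
          r2d > 0) {
        tangent <- c(-y, x, 0) / r2d
        model <- multi_tensor_voxel(list(tensor_from_axis(tangent, lam)),
                                    1, spec$s0)
      }
    }
    if (is.null(model)) {
      field <- set_field_voxel(field, i, j, k,
                               multi_tensor_voxel(list(bg), 1, spec$s0))
    } else {
      field <- set_field_voxel(field, i, j, k, model)
      mask[i, j, k] <- 1
    }
  }
  list(field = field, mask = as_mask(mask, affine))
}

#' Seed/brain mask from an FA map (FA > 0 rule)
#' @param field a [tensor_field()] (its FA map defines the mask).
#' @param threshold FA threshold (default 0: strictly positive FA).
#' @export
acm_seed_mask <- function(field, threshold = 0) {
  fa <- fa_map(field)
  as_mask(array(as.numeric(fa$data > threshold), field$dim),
          field$affine, field$space)
}

#' Simulate a DWI series from a tensor field
#'
#' Per-voxel noise-free signals from the multi-tensor model, corrupted
#' with Rician noise of `sigma = s0 / snr` (`snr = Inf` for noise-free).
#'
#' @param field a [tensor_field()].
#' @param gtab a [gradient_table()].
#' @param snr signal-to-noise ratio of the b0 signal.
#' @return 4D `acm_volume`.
#' @export
simulate_dwi <- function(field, gtab, snr = 16) {
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive (or Inf)")
  d <- field$dim
  nmeas <- length(gtab$bvals)
  out <- array(0, c(d, nmeas))
  idx <- which(field$n_fibers > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    out[i, j, k, ] <- predict_signal(field_voxel(field, i, j, k), gtab)
  }
  if (is.finite(snr)) {
    s0ref <- max(field$s0)
    out <- array(add_rician_noise(as.vector(out), s0ref / snr), dim(out))
  }
  as_volume(out, field$affine, field$space)
}

#' Cohort specification
#'
#' Defaults state the emulated population: three groups of
#' 20 / 19 / 15 subjects (healthy / RR-like / SP-like), matching per-group age
#' distributions, Bernoulli(0.5) gender, lesions only in patients with the
#' SP-like group receiving more and larger blobs, and a disability score
#' (EDSS-like, 0-10 in half steps) generated linearly from total tract
#' damage plus Gaussian noise.
#'
#' @param n_healthy,n_rr,n_sp group sizes.
#' @param lesion_count_rr,lesion_count_sp lesion blobs per patient.
#' @param lesion_radius_rr,lesion_radius_sp blob radius (voxels).
#' @param effect_rr,effect_sp fractional blend of lesioned tensors toward
#'   isotropy, in [0, 1).
#' @param edss_scale slope of EDSS on the damaged tract fraction.
#' @param edss_noise_sd EDSS noise SD before rounding.
#' @param age_mean,age_sd per-group age distributions (years).
#' @export
cohort_spec <- function(n_healthy = 20, n_rr = 19, n_sp = 15,
                        lesion_count_rr = 2, lesion_count_sp = 4,
                        lesion_radius_rr = 1.5, lesion_radius_sp = 2,
                        effect_rr = 0.2, effect_sp = 0.4,
                        edss_scale = 30, edss_noise_sd = 0.5,
                        age_mean = c(healthy = 44.60, rr = 39.45, sp = 49.34),
                        age_sd = c(healthy = 9.87, rr = 8.98, sp = 11.31)) {
  if (any(c(effect_rr, effect_sp) < 0) || any(c(effect_rr, effect_sp) >= 1))
    stop("lesion effect must be in [0, 1)")
  if (min(n_healthy, n_rr, n_sp) < 2) stop("need n >= 2 per group")
  structure(as.list(environment()), class = "cohort_spec")
}

blend_voxel_toward_isotropy <- function(field, i, j, k, effect) {
  model <- field_voxel(field, i, j, k)
  if (is.null(model)) return(field)
  tensors <- lapply(model$tensors, function(D) {
    e <- eigen(D, symmetric = TRUE)
    lam <- (1 - effect) * e$values + effect * mean(e$values)
    e$vectors %*% diag(lam) %*% t(e$vectors)
  })
  set_field_voxel(field, i, j, k,
                  multi_tensor_voxel(tensors, model$fractions, model$s0))
}

#' Generate a synthetic cohort
#'
#' Every subject starts from the same phantom tensor field. Patients
#' receive lesion blobs centered on random tract voxels, inside which the
#' tensor eigenvalues are blended toward the isotropic tensor of equal
#' trace (MD roughly preserved, FA reduced). Total damage (sum of the
#' applied effect over lesioned tract voxels, as a fraction of the tract
#' size) drives the EDSS score. Healthy subjects are lesion-free with EDSS
#' NA. Seeded generation is reproducible via `set.seed()` before the call.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom a [phantom_spec()].
#' @return list with `subjects` (per-subject list: `field`, `lesion_mask`,
#'   `damage`), `covariates` (data.frame: subject_id, group, age, gender,
#'   icv, edss), `template` (the lesion-free phantom), `tract_mask`.
#' @export
make_cohort <- function(cohort = cohort_spec(), phantom = phantom_spec()) {
  base <- make_tensor_phantom(phantom)
  tube_idx <- which(base$mask$data > 0, arr.ind = TRUE)
  n_tube <- nrow(tube_idx)
  groups <- c(rep("healthy", cohort$n_healthy), rep("RR", cohort$n_rr),
              rep("SP", cohort$n_sp))
  subjects <- vector("list", length(groups))
  cov <- data.frame(subject_id = sprintf("sub-%02d", seq_along(groups)),
                    group = groups,
                    age = NA_real_, gender = NA_integer_,
                    icv = NA_real_, edss = NA_real_,
                    stringsAsFactors = FALSE)
  grp_key <- c(healthy = "healthy", RR = "rr", SP = "sp")
  for (s in seq_along(groups)) {
    g <- groups[s]
    key <- grp_key[[g]]
    cov$age[s] <- rnorm(1, cohort$age_mean[[key]], cohort$age_sd[[key]])
    cov$gender[s] <- rbinom(1, 1, 0.5)
    cov$icv[s] <- rnorm(1, 1.5e6, 1e5)
    field <- base$field
    lesion <- array(0, phantom$dims)
    damage <- 0
    if (g != "healthy") {
      n_les <- if (g == "RR") cohort$lesion_count_rr else cohort$lesion_count_sp
      r_les <- if (g == "RR") cohort$lesion_radius_rr else cohort$lesion_radius_sp
      effect <- if (g == "RR") cohort$effect_rr else cohort$effect_sp
      if (n_les > 0 && effect > 0) {
        centers <- tube_idx[sample.int(n_tube, n_les, replace = TRUE), ,
                            drop = FALSE]
        for (l in seq_len(n_les)) {
          ctr <- centers[l, ]
          for (r in seq_len(n_tube)) {
            v <- tube_idx[r, ]
            if (sum((v - ctr)^2) <= r_les^2 && lesion[v[1], v[2], v[3]] == 0) {
              lesion[v[1], v[2], v[3]] <- 1
              field <- blend_voxel_toward_isotropy(field, v[1], v[2], v[3],
                                                   effect)
              damage <- damage + effect
            }
          }
        }
      }
      damage <- damage / n_tube
      edss <- cohort$edss_scale * damage + rnorm(1, 0, cohort$edss_noise_sd)
      cov$edss[s] <- min(10, max(0, round(edss * 2) / 2))
    }
    subjects[[s]] <- list(field = field,
                          lesion_mask = as_mask(lesion, base$field$affine),
                          damage = damage)
  }
  list(subjects = subjects, covariates = cov, template = base$field,
       tract_mask = base$mask)
}
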