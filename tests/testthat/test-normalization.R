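test_that("local_affine recovers analytic transforms", {
  dims <- c(10, 10, 10)
  def_id <- deformation_identity(dims)
  expect_equal(local_affine(def_id, c(5, 5, 5)), diag(3), tolerance = 1e-12)

  def_sc <- deformation_affine(dims, diag(4), diag(c(1.1, 1.1, 1.1, 1)))
  expect_equal(local_affine(def_sc, c(5, 5, 5)), diag(rep(1.1, 3)),
               tolerance = 1e-6)

  R <- rot_z(0.4)
  A <- diag(4); A[1:3, 1:3] <- R
  def_rot <- deformation_affine(dims, diag(4), A)
  Floc <- local_affine(def_rot, c(5, 5, 5))
  expect_equal(crossprod(Floc), diag(3), tolerance = 1e-6)
  expect_equal(Floc, R, tolerance = 1e-6)

  expect_error(local_affine(def_id, c(0, 5, 5)), "boundary")
  expect_error(local_affine(def_id, c(5, 5, 20)), "outside")
})

test_that("PPD reorientation follows the hand-computed rule", {
  D <- diag(c(1.7e-3, 3e-4, 3e-4))
  expect_equal(ppd_reorient(D, diag(3)), D, tolerance = 1e-12)

  # rotation equivariance, eigenvalues untouched
  set.seed(21)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    lam <- sort(runif(3, 1e-4, 2e-3), decreasing = TRUE)
    V <- qr.Q(qr(matrix(rnorm(9), 3)))
    D0 <- V %*% diag(lam) %*% t(V)
    Dr <- ppd_reorient(D0, Q)
    expect_equal(sort(eigen(Dr)$values), sort(lam), tolerance = 1e-12)
    expect_equal(Dr, Q %*% D0 %*% t(Q), tolerance = 1e-9)
    expect_equal(compute_fa(Dr), compute_fa(D0), tolerance = 1e-9)
    expect_equal(compute_md(Dr), compute_md(D0), tolerance = 1e-12)
  }

  # shear on a z-stick leaves e1 = (0,0,1); on an x-stick e1 = (1,0,0)
  Fsh <- rbind(c(1, 0.3, 0), c(0, 1, 0), c(0, 0, 1))
  Dz <- diag(c(3e-4, 3e-4, 1.7e-3))
  ez <- eigen(ppd_reorient(Dz, Fsh), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(ez), c(0, 0, 1), tolerance = 1e-9)
  Dx <- diag(c(1.7e-3, 3e-4, 3e-4))
  ex <- eigen(ppd_reorient(Dx, Fsh), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(ex), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(sort(eigen(ppd_reorient(Dx, Fsh))$values),
               sort(c(1.7e-3, 3e-4, 3e-4)), tolerance = 1e-12)

  expect_error(ppd_reorient(D, matrix(0, 3, 3)), "singular")
})

test_that("warp_tensor_field: identity copy, rotation equivariance, empty", {
  ph <- fx_tube()
  dims <- ph$field$dim
  amask <- as_mask(array(1, dims), ph$field$affine, "atlas")

  w_id <- warp_tensor_field(ph$field, deformation_identity(dims,
                                                           ph$field$affine),
                            amask)
  expect_identical(w_id$n_fibers, ph$field$n_fibers)
  expect_equal(w_id$d6, ph$field$d6, tolerance = 1e-9)
  expect_equal(w_id$frac, ph$field$frac, tolerance = 1e-12)

  # global rotation about the grid center: compare the warped FA map with
  # the independently rotated-resampled FA map (nearest-neighbour oracle)
  th <- pi / 7
  R <- rot_z(th)
  ctr <- (ph$field$affine %*% c((dims - 1) / 2, 1))[1:3]
  A <- diag(4); A[1:3, 1:3] <- R; A[1:3, 4] <- ctr - R %*% ctr
  def <- deformation_affine(dims, ph$field$affine, A)
  warped <- warp_tensor_field(ph$field, def, amask)
  fa_in <- fa_map(ph$field)
  fa_w <- fa_map(warped)
  M <- solve(ph$field$affine) %*% A %*% ph$field$affine
  idx <- which(warped$n_fibers > 0, arr.ind = TRUE)
  err <- 0
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    s <- round((M %*% c(v - 1, 1))[1:3]) + 1
    err <- max(err, abs(fa_w$data[v[1], v[2], v[3]] -
                          fa_in$data[s[1], s[2], s[3]]))
  }
  expect_lte(err, 1e-9)
  # e1 rotated by R where the source voxel was in the tube
  v <- idx[which.max(fa_w$data[idx])[1], ]
  e1 <- eigen(d6_to_mat_test(warped$d6[v[1], v[2], v[3], 1, ]))$vectors[, 1]
  expect_angle_le(e1, R %*% c(1, 0, 0), 1e-4)

  # deformation mapping everything outside -> empty field + warning
  far <- diag(4); far[1:3, 4] <- 1e4
  def_out <- deformation_affine(dims, ph$field$affine, far)
  expect_warning(w_out <- warp_tensor_field(ph$field, def_out, amask),
                 "outside")
  expect_true(all(w_out$n_fibers == 0L))
})

test_that("jacobian map matches analytic determinants", {
  dims <- c(10, 10, 10)
  expect_equal(jacobian_map(deformation_identity(dims))$data,
               array(1, dims), tolerance = 1e-12)
  Jsc <- jacobian_map(deformation_affine(dims, diag(4),
                                         diag(c(1.1, 1.1, 1.1, 1))))
  expect_equal(Jsc$data[5, 5, 5], 1.331, tolerance = 1e-3)
  A <- diag(4); A[1:3, 1:3] <- rot_z(0.5)
  Jr <- jacobian_map(deformation_affine(dims, diag(4), A))
  expect_equal(Jr$data, array(1, dims), tolerance = 1e-6)

  # composition of analytic affines: det multiplies
  B <- diag(c(1.2, 0.9, 1.05, 1)); B[1, 4] <- 0.3
  C <- diag(4); C[1:3, 1:3] <- rot_z(0.3) %*% diag(c(1.1, 1, 0.95))
  JB <- jacobian_map(deformation_affine(dims, diag(4), B))$data[5, 5, 5]
  JC <- jacobian_map(deformation_affine(dims, diag(4), C))$data[5, 5, 5]
  JBC <- jacobian_map(deformation_affine(dims, diag(4), C %*% B))$data[5, 5, 5]
  expect_equal(JBC, JB * JC, tolerance = 1e-6)
})

test_that("atrophy covariate is mask x det(J) / ICV", {
  dims <- c(8, 8, 8)
  mask <- as_mask(array(rbinom(prod(dims), 1, 0.5), dims), diag(4), "atlas")
  cov_id <- atrophy_covariate(mask, deformation_identity(dims), 1)
  expect_equal(cov_id$data, mask$data, tolerance = 1e-9)
  def_sc <- deformation_affine(dims, diag(4), diag(c(1.1, 1.1, 1.1, 1)))
  cov_sc <- atrophy_covariate(mask, def_sc, 1)
  inner <- mask$data[3:6, 3:6, 3:6]
  expect_equal(cov_sc$data[3:6, 3:6, 3:6], 1.331 * inner, tolerance = 1e-3)
  cov_half <- atrophy_covariate(mask, def_sc, 2)
  expect_equal(cov_half$data, cov_sc$data / 2, tolerance = 1e-12)
  expect_error(atrophy_covariate(mask, def_sc, -1), "positive")
})
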