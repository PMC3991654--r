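lam_wm <- c(1.7e-3, 3e-4, 3e-4)

test_that("predict_signal matches the closed-form model", {
  gt <- fx_gtab()
  iso <- multi_tensor_voxel(diag(rep(7e-4, 3)), 1, 50)
  S <- predict_signal(iso, gt)
  expect_equal(S[gt$b0], rep(50, sum(gt$b0)))
  expect_equal(S[!gt$b0], rep(50 * exp(-1200 * 7e-4), sum(!gt$b0)))

  # two orthogonal sticks, hand-evaluated sum
  Dx <- diag(lam_wm); Dy <- diag(lam_wm[c(2, 1, 3)])
  m2 <- multi_tensor_voxel(list(Dx, Dy), c(0.5, 0.5), 1)
  g <- c(1, 0, 0)
  hand <- 0.5 * exp(-1200 * lam_wm[1]) + 0.5 * exp(-1200 * lam_wm[2])
  expect_equal(predict_signal(m2, 1200, matrix(g)), hand)
  expect_error(predict_signal(m2, -5, matrix(g)), "negative")
})

test_that("single-tensor fit recovers noise-free generators", {
  gt <- fx_gtab()
  R <- rot_z(0.6)
  D <- R %*% diag(lam_wm) %*% t(R)
  S <- predict_signal(multi_tensor_voxel(D, 1, 120), gt)
  fit <- fit_single_tensor(S, gt)
  expect_equal(fit$eig$values, lam_wm, tolerance = 1e-6)
  expect_equal(fit$s0, 120, tolerance = 1e-6)

  # isotropic symmetry
  Si <- predict_signal(multi_tensor_voxel(diag(rep(7e-4, 3)), 1, 1), gt)
  fi <- fit_single_tensor(Si, gt)
  expect_equal(fi$eig$values, rep(7e-4, 3), tolerance = 1e-6)

  bad <- S; bad[5] <- -1
  expect_error(fit_single_tensor(bad, gt), "negative")
  expect_error(fit_single_tensor(rep(0, length(S)), gt), "zero")
  g7 <- gradient_table(c(0, 1200), cbind(0, c(1, 0, 0)))
  expect_error(fit_single_tensor(c(1, 0.5), g7), "7 measurements")
})

test_that("two-tensor fit resolves a 90-degree crossing", {
  gt <- fx_gtab()
  Dx <- diag(lam_wm); Dy <- diag(lam_wm[c(2, 1, 3)])
  S <- predict_signal(multi_tensor_voxel(list(Dx, Dy), c(0.5, 0.5), 1), gt)
  fit <- fit_two_tensor(S, gt)
  e1 <- eigen(fit$tensors[[1]], symmetric = TRUE)$vectors[, 1]
  e2 <- eigen(fit$tensors[[2]], symmetric = TRUE)$vectors[, 1]
  axes <- list(c(1, 0, 0), c(0, 1, 0))
  # each recovered axis matches one truth axis within 2 degrees
  match1 <- which.max(c(abs(e1[1]), abs(e1[2])))
  expect_angle_le(e1, axes[[match1]], 2)
  expect_angle_le(e2, axes[[3 - match1]], 2)
  expect_equal(fit$fractions, c(0.5, 0.5), tolerance = 0.05)

  # label symmetry: swapping the init axes gives the same canonical model
  f_ab <- fit_two_tensor(S, gt, init = list(c(1, 0, 0), c(0, 1, 0)))
  f_ba <- fit_two_tensor(S, gt, init = list(c(0, 1, 0), c(1, 0, 0)))
  expect_equal(sort(sapply(f_ab$tensors, function(D) D[1, 1])),
               sort(sapply(f_ba$tensors, function(D) D[1, 1])),
               tolerance = 0.01)
})

test_that("two-tensor fit degrades gracefully on one-fiber data", {
  gt <- fx_gtab()
  S <- predict_signal(multi_tensor_voxel(diag(lam_wm), 1, 1), gt)
  single <- fit_single_tensor(S, gt)
  two <- fit_two_tensor(S, gt, single = single)
  # either one dominant fraction or negligible RSS improvement
  expect_true(max(two$fractions) >= 0.9 ||
                (single$rss - attr(two, "rss")) < 1e-10 * sum(S^2))
  expect_lte(attr(two, "rss"), single$rss + 1e-15)
})

test_that("fiber-count classification separates the regimes", {
  gt <- fx_gtab()
  S1 <- predict_signal(multi_tensor_voxel(diag(lam_wm), 1, 1), gt)
  expect_identical(classify_fibre_count(S1, gt), 1L)
  Siso <- predict_signal(multi_tensor_voxel(diag(rep(7e-4, 3)), 1, 1), gt)
  expect_identical(classify_fibre_count(Siso, gt), 1L)
  Dx <- diag(lam_wm); Dy <- diag(lam_wm[c(2, 1, 3)])
  S2 <- predict_signal(multi_tensor_voxel(list(Dx, Dy), c(0.5, 0.5), 1), gt)
  expect_identical(classify_fibre_count(S2, gt), 2L)
})

test_that("FA and MD follow the eigenvalue formulas", {
  expect_equal(compute_fa(diag(rep(7e-4, 3))), 0)
  expect_equal(compute_md(diag(rep(7e-4, 3))), 7e-4)
  expect_equal(compute_fa(c(1, 0, 0)), 1)
  expect_equal(compute_fa(matrix(0, 3, 3)), 0)

  # direct evaluation of the formula for (2.0, 0.2, 0.2) x 1e-3
  lam <- c(2.0e-3, 2e-4, 2e-4)
  oracle <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(compute_fa(lam), oracle)
  expect_equal(round(oracle, 3), 0.891)

  # rotation and scale invariance (property over random tensors)
  set.seed(11)
  for (i in 1:10) {
    lam <- sort(abs(rnorm(3, 1e-3, 5e-4)) + 1e-5, decreasing = TRUE)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- Q %*% diag(lam) %*% t(Q)
    expect_equal(compute_fa(D), compute_fa(lam), tolerance = 1e-9)
    expect_equal(compute_fa(3.7 * lam), compute_fa(lam), tolerance = 1e-12)
  }
})

test_that("simulate -> fit -> simulate closes on noise-free data", {
  gt <- fx_gtab()
  set.seed(3)
  for (i in 1:5) {
    lam <- sort(runif(3, 2e-4, 2e-3), decreasing = TRUE)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- Q %*% diag(lam) %*% t(Q)
    S <- predict_signal(multi_tensor_voxel(D, 1, 100), gt)
    fit <- fit_single_tensor(S, gt)
    S2 <- predict_signal(multi_tensor_voxel(fit$tensor, 1, fit$s0), gt)
    expect_equal(S2, S, tolerance = 1e-6)
  }
})

test_that("two-tensor RSS never exceeds single-tensor RSS (noisy data)", {
  gt <- fx_gtab()
  set.seed(4)
  for (i in 1:4) {
    S <- predict_signal(multi_tensor_voxel(diag(lam_wm), 1, 1), gt)
    S <- add_rician_noise(S, 1 / 16)
    single <- fit_single_tensor(S, gt)
    two <- fit_two_tensor(S, gt, single = single)
    expect_lte(attr(two, "rss"), single$rss + 1e-12)
  }
})

test_that("fit_tensor_field fits and classifies a crossing phantom", {
  ph <- make_tensor_phantom(phantom_spec("crossing", dims = c(11, 11, 7),
                                         radius = 1))
  gt <- fx_gtab()
  dwi <- simulate_dwi(ph$field, gt, snr = Inf)
  fitted <- fit_tensor_field(dwi, gt, ph$mask, max_fibers = 2)
  truth2 <- ph$field$n_fibers == 2L
  expect_true(all(fitted$n_fibers[truth2] == 2L))
  one_true <- ph$field$n_fibers == 1L & ph$mask$data > 0
  expect_true(mean(fitted$n_fibers[one_true] == 1L) > 0.9)
  fa_t <- fa_map(ph$field); fa_f <- fa_map(fitted)
  expect_equal(fa_f$data[one_true], fa_t$data[one_true], tolerance = 1e-5)
})

test_that("tensor field NIfTI serialization round trips", {
  ph <- fx_tube()
  pre <- file.path(withr::local_tempdir(), "f")
  write_tensor_field(ph$field, pre)
  back <- read_tensor_field(pre)
  expect_identical(back$n_fibers, ph$field$n_fibers)
  expect_identical(back$d6, ph$field$d6)
  expect_identical(back$frac, ph$field$frac)
})
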