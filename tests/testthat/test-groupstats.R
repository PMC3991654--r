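test_that("Gaussian smoothing: identity, kernel width, mass, translation", {
  v <- as_volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)))
  expect_identical(smooth_volume(v, 0)$data, v$data)

  # fully interior voxels (kernel radius 4 voxels at 2 mm / FWHM 4 mm)
  const <- as_volume(array(5, c(12, 12, 12)), diag(c(2, 2, 2, 1)))
  sc <- smooth_volume(const, 4)
  expect_equal(sc$data[5:8, 5:8, 5:8], array(5, c(4, 4, 4)), tolerance = 1e-9)

  # delta at 1 mm voxels: half maximum reached 2 mm from the center
  delta <- as_volume(array(0, c(21, 21, 21)))
  delta$data[11, 11, 11] <- 1
  sd4 <- smooth_volume(delta, 4)
  expect_equal(sum(sd4$data), 1, tolerance = 1e-6)
  prof <- sd4$data[, 11, 11] / sd4$data[11, 11, 11]
  sigma <- 4 / 2.3548200450309493
  expect_equal(prof[13], exp(-2^2 / (2 * sigma^2)), tolerance = 1e-3)
  expect_equal(prof[13], 0.5, tolerance = 0.02)

  # commutes with translation (interior)
  sh <- delta; sh$data <- array(0, c(21, 21, 21)); sh$data[14, 11, 11] <- 1
  ssh <- smooth_volume(sh, 4)
  expect_equal(ssh$data[4:18 + 3, 11, 11], sd4$data[4:18, 11, 11],
               tolerance = 1e-12)

  expect_error(smooth_volume(v, -1), "non-negative")
})

test_that("voxel-wise GLM equals the scalar regression oracle", {
  set.seed(80)
  n <- 24; v <- 40
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n, 45, 9), rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * v), n, v) + 2 * X[, 2]
  ctr <- c(0, 1, 0, 0)
  fit <- fit_glm(Y, X, ctr)
  expect_equal(mean(fit$beta[2, ]), 2, tolerance = 0.2)
  for (j in c(1, 17, v)) {
    lmfit <- lm(Y[, j] ~ 0 + X)
    sm <- summary(lmfit)$coefficients
    expect_equal(fit$t[j], sm[2, "t value"], tolerance = 1e-10)
    expect_equal(fit$beta[, j], unname(coef(lmfit)), tolerance = 1e-10)
  }
  # two groups with identical data -> t = 0 everywhere
  half <- matrix(rnorm(n / 2 * v), n / 2, v)
  Y0 <- rbind(half, half)
  X0 <- cbind(1, rep(c(0, 1), each = n / 2))
  expect_equal(fit_glm(Y0, X0, c(0, 1))$t, rep(0, v), tolerance = 1e-8)
  # one-voxel degeneracy equals a scalar regression
  f1 <- fit_glm(Y[, 1, drop = FALSE], X, ctr)
  expect_equal(f1$t, summary(lm(Y[, 1] ~ 0 + X))$coefficients[2, "t value"],
               tolerance = 1e-10)
  expect_error(fit_glm(Y, cbind(X, X[, 2]), c(ctr, 0)), "rank")
})

test_that("voxel-wise covariate column matches a per-voxel lm oracle", {
  set.seed(81)
  n <- 20; v <- 6
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  VC <- matrix(rnorm(n * v), n, v)
  Y <- matrix(rnorm(n * v), n, v) + X[, 2] + 0.5 * VC
  fit <- fit_glm(Y, X, c(0, 1, 0), voxel_covariate = VC)
  for (j in 1:v) {
    sm <- summary(lm(Y[, j] ~ 0 + X + VC[, j]))$coefficients
    expect_equal(fit$t[j], sm[2, "t value"], tolerance = 1e-10)
  }
})

test_that("Welch voxel test matches t.test on adjusted residuals", {
  set.seed(82)
  n <- 30
  g <- rep(c("a", "b"), c(14, 16))
  Z <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * 5), n, 5)
  res <- welch_voxel_ttest(Y, g, nuisance = Z)
  R <- Y - Z %*% solve(crossprod(Z), crossprod(Z, Y))
  for (j in 1:5) {
    tt <- t.test(R[g == "a", j], R[g == "b", j])
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df[j], unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("summary t-test: conventions and degenerate input", {
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  r <- ttest_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # pooled vs welch differ when variances do
  p <- ttest_from_summary(10, 1, 10, 8, 4, 12, "pooled")
  w <- ttest_from_summary(10, 1, 10, 8, 4, 12, "welch")
  expect_lt(w$df, p$df)
  expect_false(isTRUE(all.equal(p$p, w$p)))
  # one-tailed halves the two-tailed p for positive t
  t2 <- ttest_from_summary(10, 2, 10, 8, 2, 10, tails = 2)
  t1 <- ttest_from_summary(10, 2, 10, 8, 2, 10, tails = 1)
  expect_equal(t1$p, t2$p / 2)
})

test_that("permutation SVC: self-contrast yields nothing; effects are found", {
  set.seed(83)
  n <- 24; v <- 50
  X <- cbind(1, rep(c(0, 1), each = n / 2), rnorm(n))
  roi <- rep(TRUE, v)
  # one population split into two arbitrary labels: nothing to find
  Y <- matrix(rnorm(n * v), n, v)
  rs <- svc_fwe(Y, X, c(0, 1, 0), roi, n_permutations = 199)
  expect_false(any(rs$significant))
  # painted effect inside a sub-ROI is recovered there
  Yeff <- Y; Yeff[X[, 2] == 1, 1:10] <- Yeff[X[, 2] == 1, 1:10] + 3
  re <- svc_fwe(Yeff, X, c(0, 1, 0), roi, n_permutations = 199)
  expect_true(any(re$significant[1:10]))
  expect_false(any(re$significant[11:v]))
  expect_error(svc_fwe(Y, X, c(0, 1, 0), roi, n_permutations = 50), "100")
})

test_that("ROI median conventions and brute-force agreement", {
  aff <- diag(4)
  lab <- as_volume(array(0, c(4, 4, 4)), aff)
  lab$data[1:4, 1, 1] <- 1
  vol <- as_volume(array(0, c(4, 4, 4)), aff)
  vol$data[1:4, 1, 1] <- c(1, 2, 3, 100)
  expect_equal(roi_median(vol, lab, 1), 2.5)
  const <- as_volume(array(7, c(4, 4, 4)), aff)
  expect_equal(roi_median(const, lab, 1), 7)
  expect_error(roi_median(vol, lab, 9), "empty ROI")
  set.seed(84)
  for (i in 1:5) {
    vol$data <- array(rnorm(64), c(4, 4, 4))
    vals <- sort(vol$data[lab$data == 1])
    brute <- mean(vals[c(2, 3)])  # n = 4: midpoint of the central pair
    expect_equal(roi_median(vol, lab, 1), brute)
  }
})

test_that("disability correlation: exact, generative and null cases", {
  set.seed(85)
  n <- 30
  age <- rnorm(n, 45, 9); gender <- rbinom(n, 1, 0.5)
  med <- rnorm(n)
  # perfectly linear
  r <- correlate_disability(med, 2 * med + 1, age, gender)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  # generative recovery: known signal fraction
  a <- 1.5; b <- 0.05
  edss <- a * med + b * age + rnorm(n, 0, 0.3)
  rg <- correlate_disability(med, edss, age, gender)
  sig_var <- var(a * med + b * age)
  expect_equal(rg$r2, sig_var / (sig_var + 0.09), tolerance = 0.15)
  # null calibration of the Pearson p
  hits <- 0
  for (i in 1:1000) {
    x <- rnorm(12); y <- rnorm(12)
    if (cor.test(x, y)$p.value < 0.05) hits <- hits + 1
  }
  expect_gt(hits, 25); expect_lt(hits, 80)
  expect_error(correlate_disability(rep(1, n), med, age, gender), "constant")
  expect_error(correlate_disability(med[1:3], med[1:3], age[1:3], gender[1:3]),
               "4 subjects")
})

test_that("lesion maps, proportion test and dice", {
  aff <- diag(4)
  mk <- function(vox) {
    m <- array(0, c(5, 5, 5))
    for (v in vox) m[v[1], v[2], v[3]] <- 1
    as_mask(m, aff)
  }
  shared <- list(c(2, 2, 2))
  masks <- lapply(1:4, function(i) mk(shared))
  lp <- lesion_probability_map(masks)
  expect_equal(lp$data[2, 2, 2], 1)
  expect_equal(sum(lp$data), 1)

  one_of_four <- lesion_probability_map(list(mk(shared), mk(list()),
                                             mk(list()), mk(list())))
  expect_equal(one_of_four$data[2, 2, 2], 0.25)

  expect_equal(lesion_difference(lp, lp)$data, array(0, c(5, 5, 5)))
  tmap <- proportion_test(masks, masks)
  expect_true(all(tmap$data == 0))

  a <- mk(lapply(1:8, function(i) c(i %% 5 + 1, 1, 1)))
  expect_equal(dice(a, a), 1)
  b <- mk(list(c(1, 5, 5)))
  expect_equal(dice(a, b), 0)
  A <- mk(lapply(1:2, function(i) c(i, 1, 1))); A$data[1:4, 2, 1] <- 1
  A <- as_mask(A$data, aff)
  B <- array(0, c(5, 5, 5)); B[1:4, 2, 1] <- 1; B[1:4, 3, 1] <- 1
  B <- as_mask(B, aff)
  expect_equal(dice(A, B), 2 * 4 / (6 + 8))
  expect_equal(dice(mk(list()), mk(list())), 0)

  # brute-force property on random masks
  set.seed(86)
  for (i in 1:5) {
    x <- as_mask(array(rbinom(125, 1, 0.3), c(5, 5, 5)), aff)
    y <- as_mask(array(rbinom(125, 1, 0.3), c(5, 5, 5)), aff)
    inter <- sum(x$data == 1 & y$data == 1)
    brute <- if (sum(x$data) + sum(y$data) == 0) 0 else
      2 * inter / (sum(x$data) + sum(y$data))
    expect_equal(dice(x, y), brute)
  }
})

test_that("study design builds the documented coding and contrasts", {
  cov <- data.frame(group = c("healthy", "RR", "SP", "healthy"),
                    age = c(40, 38, 52, 47), gender = c(0, 1, 1, 0))
  d <- study_design(cov)
  expect_equal(colnames(d$X),
               c("intercept", "groupRR", "groupSP", "age", "gender"))
  expect_equal(d$X[, "groupRR"], c(0, 1, 0, 0))
  expect_equal(sum(d$X[, "age"]), 0)  # centered
  expect_equal(d$contrasts$sp_gt_rr, c(0, -1, 1, 0, 0))
  expect_error(study_design(data.frame(group = "PP", age = 1, gender = 0)),
               "unknown group")
})
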