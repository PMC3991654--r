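# Shared fixtures, built once per test run (lazily) and cached.

.fx <- new.env(parent = emptyenv())

fx_gtab <- function() {
  if (is.null(.fx$gtab)) .fx$gtab <- default_gradients()
  .fx$gtab
}

# small straight-tube phantom (shared by tracking/acm tests)
fx_tube <- function() {
  if (is.null(.fx$tube))
    .fx$tube <- make_tensor_phantom(phantom_spec("straight_tube",
                                                 dims = c(20, 12, 12),
                                                 radius = 1.5))
  .fx$tube
}

# calibration table for the tube phantom at SNR 16
fx_tube_calib <- function() {
  if (is.null(.fx$tube_calib)) {
    set.seed(100)
    .fx$tube_calib <- build_calibration_table(fx_tube()$field, snr = 16,
                                              gtab = fx_gtab(),
                                              n_trials = 300, seed = 100)
  }
  .fx$tube_calib
}

fx_tube_fodf <- function() {
  if (is.null(.fx$tube_fodf))
    .fx$tube_fodf <- build_fodf_field(fx_tube()$field, fx_tube_calib())
  .fx$tube_fodf
}

# synthetic calibration table: every shape maps to a fixed kappa pair
fixed_kappa_table <- function(k1, k2) {
  structure(list(bins = data.frame(r1 = 1, r2 = 1, k1 = k1, k2 = k2),
                 snr = Inf, bin_width = 0.5,
                 meta = list(n_trials = 0, seed = 0, scheme_id = "fixed")),
            class = "calibration_table")
}

# fODF field over a tensor field with constant concentrations
fodf_with_kappa <- function(field, k1, k2)
  build_fodf_field(field, fixed_kappa_table(k1, k2))

# (xx, yy, zz, xy, xz, yz) -> symmetric 3x3 (mirrors the field layout)
d6_to_mat_test <- function(d6)
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)

# rotation matrix about z
rot_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)

expect_angle_le <- function(u, v, deg) {
  a <- acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  expect_lte(a, deg)
}
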