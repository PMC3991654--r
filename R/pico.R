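## Fiber-orientation uncertainty as Bingham distributions on the sphere:
## density proportional to exp(k1 (x.u1)^2 + k2 (x.u2)^2) with k1 <= k2 <= 0
## and mode axis u3 (antipodally symmetric). Concentrations are calibrated
## per tensor shape and SNR by Monte-Carlo simulation (PICo): corrupt the
## noise-free tensor signals with Rician noise, refit, collect principal
## axes, and moment-match a Bingham lobe to the axis scatter.

KAPPA_FLOOR <- -1e4

#' Bingham lobe
#'
#' @param frame 3x3 orthonormal matrix with columns (u1, u2, u3); u3 is the
#'   mode axis.
#' @param kappa concentrations `c(k1, k2)` with `k1 <= k2 <= 0`.
#' @export
bingham_lobe <- function(frame, kappa) {
  frame <- as.matrix(frame)
  if (max(abs(crossprod(frame) - diag(3))) > 1e-9)
    stop("frame not orthonormal")
  kappa <- as.numeric(kappa)
  if (length(kappa) != 2 || kappa[1] > kappa[2] + 1e-12 || kappa[2] > 1e-12)
    stop("need k1 <= k2 <= 0")
  structure(list(frame = frame, kappa = pmin(kappa, 0)),
            class = "bingham_lobe")
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

## second moments tau_j = E[(x.u_j)^2], j = 1, 2, of the Bingham density,
## by Gauss-Legendre (cos theta, 64 nodes) x midpoint (phi, 128 points)
## quadrature of the normalizing integral.
.bingham_quad <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gl <- gauss_legendre(64)
      phi <- (seq_len(128) - 0.5) * 2 * pi / 128
      st2 <- 1 - gl$nodes^2                   # sin^2 theta
      cache <<- list(
        x1sq = outer(st2, cos(phi)^2),        # (x.u1)^2 on the grid
        x2sq = outer(st2, sin(phi)^2),
        w = outer(gl$weights, rep(2 * pi / 128, 128)))
    }
    cache
  }
})

bingham_tau <- function(k1, k2) {
  q <- .bingham_quad()
  f <- exp(k1 * q$x1sq + k2 * q$x2sq) * q$w
  c_ <- sum(f)
  c(sum(q$x1sq * f), sum(q$x2sq * f)) / c_
}

## invert the moment equations tau(k1, k2) = target
invert_bingham_moments <- function(tau_hat) {
  if (sum(tau_hat) < 5e-4)  # delta-like scatter: quadrature floor
    return(c(KAPPA_FLOOR, KAPPA_FLOOR))
  p0 <- log(pmin(pmax(1 / (2 * pmax(tau_hat, 1e-4)), 1e-3), 5e3))
  obj <- function(p) {
    tau <- bingham_tau(-exp(p[1]), -exp(p[2]))
    sum((tau - tau_hat)^2)
  }
  fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = log(1e-4), upper = log(abs(KAPPA_FLOOR)))
  k <- -exp(fit$par)
  sort(pmax(k, KAPPA_FLOOR))  # enforce k1 <= k2
}

#' Fit a Bingham lobe to a set of axes by moment matching
#'
#' The frame is the eigenframe of the scatter matrix `T = mean(x x')`
#' (mode = largest-eigenvalue direction; axes are treated antipodally, so
#' the sign of each input is irrelevant). Concentrations are found by
#' numerically inverting the Bingham second-moment equations with
#' quadrature of the normalizing constant. Nearly-degenerate scatter (all
#' axes equal) returns the documented floor `kappa = -1e4`.
#'
#' @param axes n x 3 matrix of unit axes, n >= 10.
#' @export
fit_bingham_to_axes <- function(axes) {
  axes <- as.matrix(axes)
  if (ncol(axes) != 3) stop("axes must be n x 3")
  if (nrow(axes) < 10) stop("need at least 10 axes")
  nrm <- sqrt(rowSums(axes^2))
  axes <- axes / nrm
  T_ <- crossprod(axes) / nrow(axes)
  e <- eigen(T_, symmetric = TRUE)        # values decreasing
  frame <- e$vectors[, 3:1]               # u1 = smallest, u3 = mode
  if (det(frame) < 0) frame[, 1] <- -frame[, 1]
  tau_hat <- e$values[3:2]                # scatter along u1, u2
  kappa <- invert_bingham_moments(tau_hat)
  bingham_lobe(frame, kappa)
}

#' Sample axes from a Bingham lobe
#'
#' Rejection sampling from the uniform sphere (acceptance
#' `exp(k1 t1^2 + k2 t2^2)`, always <= 1). Floor-concentration lobes return
#' the mode axis deterministically (random antipodal sign); after
#' `max_rej` rejected proposals the mode is returned as a guard. Driven by
#' R's RNG, so `set.seed()` fixes the sequence.
#'
#' @param lobe a [bingham_lobe()].
#' @param n number of axes.
#' @param max_rej rejection guard.
#' @return n x 3 matrix of unit axes.
#' @export
sample_axis <- function(lobe, n = 1, max_rej = 5000) {
  stopifnot(inherits(lobe, "bingham_lobe"))
  cpp_sample_bingham(lobe$frame, lobe$kappa[1], lobe$kappa[2], n, max_rej)
}

#' Rician-corrupt signals
#'
#' Magnitude-MRI noise model: `sqrt((S + e1)^2 + e2^2)` with independent
#' `e ~ N(0, sigma^2)` channels.
#'
#' @param signals noise-free signal vector/matrix.
#' @param sigma Gaussian channel SD.
#' @export
add_rician_noise <- function(signals, sigma) {
  if (sigma == 0) return(signals)
  n <- length(signals)
  out <- sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (is.matrix(signals)) matrix(out, nrow(signals)) else out
}

#' PICo concentration calibration for one tensor shape
#'
#' Monte-Carlo: noise-free signals of a single tensor with the given
#' eigenvalues (S0 = 1) are corrupted with Rician noise of
#' `sigma = S0 / snr`, a single tensor is refit per trial (log-linear
#' least squares; `refine = TRUE` adds the nonlinear polish) and the
#' principal axes are collected; the returned concentrations are the
#' [fit_bingham_to_axes()] moment fit over those axes. `snr = Inf` is the
#' noise-free limit and returns the floor concentrations.
#'
#' @param eigenvalues three tensor eigenvalues (mm^2/s), any order.
#' @param snr signal-to-noise ratio of the b0 signal, > 0.
#' @param gtab a [gradient_table()].
#' @param n_trials Monte-Carlo trials, >= 100.
#' @param refine nonlinear refinement of each trial's fit (slow; off by
#'   default).
#' @return `c(k1, k2)`, with the fitted [bingham_lobe()] as attribute
#'   `"lobe"`.
#' @export
calibrate <- function(eigenvalues, snr, gtab, n_trials = 500,
                      refine = FALSE) {
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  if (n_trials < 100) stop("need at least 100 trials")
  lam <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  D <- diag(lam)                       # e1 along x in the canonical frame
  model <- multi_tensor_voxel(list(D), 1, 1)
  S <- predict_signal(model, gtab)
  if (!is.finite(snr)) {
    lobe <- bingham_lobe(cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)),
                         c(KAPPA_FLOOR, KAPPA_FLOOR))
    out <- lobe$kappa
    attr(out, "lobe") <- lobe
    return(out)
  }
  sigma <- 1 / snr
  Sm <- matrix(S, length(S), n_trials)
  noisy <- add_rician_noise(Sm, sigma)
  axes <- matrix(0, n_trials, 3)
  if (refine) {
    for (t in seq_len(n_trials))
      axes[t, ] <- fit_single_tensor(noisy[, t], gtab)$eig$vectors[, 1]
  } else {
    X <- loglinear_design(gtab)
    P <- solve(crossprod(X), t(X))
    beta <- P %*% log(pmax(noisy, 1e-12))
    for (t in seq_len(n_trials)) {
      e <- eigen(d6_to_mat(beta[2:7, t]), symmetric = TRUE)
      axes[t, ] <- e$vectors[, 1]
    }
  }
  lobe <- fit_bingham_to_axes(axes)
  out <- lobe$kappa
  attr(out, "lobe") <- lobe
  out
}

## ---- calibration table -----------------------------------------------------

shape_ratios <- function(lam) {
  lam <- sort(lam, decreasing = TRUE)
  lo <- max(lam[3], 1e-12)
  c(r1 = lam[1] / max(lam[2], 1e-12), r2 = lam[2] / lo)
}

#' Build a PICo calibration table for the shapes present in a tensor field
#'
#' Tensor shapes are binned by the eigenvalue ratios (lambda1/lambda2,
#' lambda2/lambda3), rounded to `bin_width`; one [calibrate()] run per
#' occupied bin (using the first-encountered eigenvalues of that bin).
#'
#' @param field a [tensor_field()], or a list of them (e.g. a cohort): the
#'   table then covers the union of their shape bins.
#' @param snr assumed signal-to-noise ratio (protocol default 16).
#' @param gtab acquisition [gradient_table()].
#' @param n_trials Monte-Carlo trials per bin.
#' @param bin_width shape-ratio bin width.
#' @param seed RNG seed recorded in the metadata and applied per bin.
#' @return A `calibration_table`: data.frame of bins plus metadata.
#' @export
build_calibration_table <- function(field, snr = 16, gtab,
                                    n_trials = 500, bin_width = 0.5,
                                    seed = 1L) {
  fields <- if (inherits(field, "tensor_field")) list(field) else field
  keys <- character(0)
  rows <- list()
  for (fld in fields) {
    idx <- which(fld$n_fibers > 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      for (f in seq_len(fld$n_fibers[i, j, k])) {
        lam <- tensor_eigenvalues(d6_to_mat(fld$d6[i, j, k, f, ]))
        rr <- shape_ratios(lam)
        b1 <- round(rr[1] / bin_width) * bin_width
        b2 <- round(rr[2] / bin_width) * bin_width
        key <- paste(b1, b2, sep = "_")
        if (!(key %in% keys)) {
          keys <- c(keys, key)
          rows[[key]] <- list(r1 = b1, r2 = b2, lam = lam)
        }
      }
    }
  }
  bins <- do.call(rbind, lapply(rows, function(x) {
    set.seed(seed + round(1000 * (x$r1 + 31 * x$r2)) %% 100000L)
    kap <- calibrate(x$lam, snr, gtab, n_trials)
    data.frame(r1 = x$r1, r2 = x$r2, k1 = kap[1], k2 = kap[2])
  }))
  rownames(bins) <- NULL
  structure(list(bins = bins, snr = snr, bin_width = bin_width,
                 meta = list(n_trials = n_trials, seed = seed,
                             scheme_id = sprintf("b%g_n%d", max(gtab$bvals),
                                                 length(gtab$bvals)))),
            class = "calibration_table")
}

#' Serialize a calibration table to / from JSON
#' @param table a `calibration_table`; `path` file path.
#' @export
write_calibration_table <- function(table, path) {
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$bins <- as.data.frame(x$bins)
  structure(x, class = "calibration_table")
}

lookup_kappa <- function(table, lam, extrapolate = TRUE) {
  rr <- shape_ratios(lam)
  d2 <- (table$bins$r1 - rr[1])^2 + (table$bins$r2 - rr[2])^2
  i <- which.min(d2)
  if (!extrapolate && sqrt(d2[i]) > table$bin_width)
    stop("tensor shape not covered by the calibration table")
  c(table$bins$k1[i], table$bins$k2[i])
}

## ---- fODF field ------------------------------------------------------------

#' Build the fODF field from a tensor field and a calibration table
#'
#' One Bingham lobe per fitted tensor: mode axis = tensor principal
#' eigenvector, lobe frame completed by the second/third eigenvectors
#' (dispersion assignment: u2 = e2, u1 = e3), concentrations looked up in
#' the calibration table by nearest shape bin, and lobe weights equal to
#' the volume fractions.
#'
#' @param field a [tensor_field()].
#' @param calibration a `calibration_table` (must match the intended SNR).
#' @param extrapolate allow nearest-bin lookup beyond one bin width.
#' @return A `fodf_field`.
#' @export
build_fodf_field <- function(field, calibration, extrapolate = TRUE) {
  dim <- field$dim
  fodf <- structure(list(
    dim = dim, affine = field$affine, voxel_size = field$voxel_size,
    space = field$space, snr = calibration$snr,
    nlobes = array(0L, dim),
    weights = array(0, c(dim, 2L)),
    axes = array(0, c(dim, 2L, 9L)),
    kappa = array(0, c(dim, 2L, 2L))
  ), class = "fodf_field")
  idx <- which(field$n_fibers > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nf <- field$n_fibers[i, j, k]
    fodf$nlobes[i, j, k] <- nf
    for (f in seq_len(nf)) {
      e <- eigen(d6_to_mat(field$d6[i, j, k, f, ]), symmetric = TRUE)
      kap <- lookup_kappa(calibration, e$values, extrapolate)
      frame <- cbind(e$vectors[, 3], e$vectors[, 2], e$vectors[, 1])
      fodf$axes[i, j, k, f, ] <- as.vector(frame)
      fodf$kappa[i, j, k, f, ] <- kap
      fodf$weights[i, j, k, f] <- field$frac[i, j, k, f]
    }
  }
  fodf
}

#' @export
print.fodf_field <- function(x, ...) {
  cat(sprintf("<fodf_field> %s, %d voxels with lobes (snr=%g)\n",
              paste(x$dim, collapse = "x"), sum(x$nlobes > 0), x$snr))
  invisible(x)
}

## flatten an fODF field + tracking mask into the list the C++ core reads
fodf_cstruct <- function(fodf, mask) {
  stopifnot(inherits(fodf, "fodf_field"))
  if (!all(grid_dim(mask) == fodf$dim)) stop("field/mask grid mismatch")
  n <- prod(fodf$dim)
  axes <- aperm(array(fodf$axes, c(n, 2, 9)), c(3, 2, 1))   # 9 x 2 x n
  kap <- aperm(array(fodf$kappa, c(n, 2, 2)), c(3, 2, 1))   # 2 x 2 x n
  list(dim = as.integer(fodf$dim),
       nlobes = as.integer(fodf$nlobes),
       weights = as.numeric(aperm(array(fodf$weights, c(n, 2)), c(2, 1))),
       axes = as.numeric(axes),
       kappa = as.numeric(kap),
       mask = as.integer(mask$data > 0),
       voxel_size = as.numeric(fodf$voxel_size))
}
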