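## Multi-tensor diffusion model: S(g, b) = S0 * sum_i f_i exp(-b g' D_i g),
## at most two tensors per voxel. Fits use a log-linear least-squares start
## and a Levenberg-Marquardt refinement with the tensors parameterized by
## their Cholesky factors (positive semidefinite by construction) and the
## fraction by a logistic transform (simplex by construction).

d6_order <- c("xx", "yy", "zz", "xy", "xz", "yz")

d6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

mat_to_d6 <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])

chol_to_mat <- function(l6) {
  # lower-triangular factor packed (L11, L21, L22, L31, L32, L33)
  L <- matrix(0, 3, 3)
  L[1, 1] <- l6[1]; L[2, 1] <- l6[2]; L[2, 2] <- l6[3]
  L[3, 1] <- l6[4]; L[3, 2] <- l6[5]; L[3, 3] <- l6[6]
  L %*% t(L)
}

mat_to_chol <- function(D, floor_frac = 1e-8) {
  e <- eigen(D, symmetric = TRUE)
  lam <- pmax(e$values, floor_frac * max(abs(e$values), 1e-12))
  Dp <- e$vectors %*% diag(lam) %*% t(e$vectors)
  L <- t(chol(Dp))
  c(L[1, 1], L[2, 1], L[2, 2], L[3, 1], L[3, 2], L[3, 3])
}

#' Multi-tensor voxel model
#'
#' @param tensors list of 1 or 2 symmetric 3x3 diffusion tensors (mm^2/s).
#' @param fractions volume fractions, non-negative, summing to 1.
#' @param s0 non-diffusion-weighted signal, positive.
#' @export
multi_tensor_voxel <- function(tensors, fractions = 1, s0 = 1) {
  if (is.matrix(tensors)) tensors <- list(tensors)
  n <- length(tensors)
  if (!(n %in% 1:2)) stop("1 or 2 tensors per voxel")
  if (length(fractions) != n) stop("fractions length must match tensor count")
  if (any(fractions < -1e-12)) stop("negative fraction")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (s0 <= 0) stop("s0 must be positive")
  for (D in tensors)
    if (max(abs(D - t(D))) > 1e-10 * max(1, max(abs(D))))
      stop("tensor not symmetric")
  structure(list(n_fibers = n, tensors = tensors,
                 fractions = as.numeric(fractions), s0 = s0),
            class = "multi_tensor_voxel")
}

#' Predict diffusion-weighted signals from a voxel model
#'
#' Evaluates `S0 * sum_i f_i exp(-b g' D_i g)` for each (b, g) pair. b = 0
#' entries return exactly `S0`.
#'
#' @param model a [multi_tensor_voxel()].
#' @param bval numeric vector of b-factors (s/mm^2), or a
#'   [gradient_table()] (then `bvec` is ignored).
#' @param bvec 3 x N matrix of unit gradients.
#' @export
predict_signal <- function(model, bval, bvec = NULL) {
  if (inherits(bval, "gradient_table")) {
    bvec <- bval$bvecs; bval <- bval$bvals
  }
  if (any(bval < 0)) stop("negative b-value")
  bvec <- as.matrix(bvec)
  out <- numeric(length(bval))
  for (i in seq_len(model$n_fibers)) {
    D <- model$tensors[[i]]
    q <- colSums(bvec * (D %*% bvec))     # g' D g per column
    out <- out + model$fractions[i] * exp(-bval * q)
  }
  model$s0 * out
}

## Levenberg-Marquardt with forward-difference Jacobian. Small and generic;
## used by both tensor fits.
lm_minimize <- function(par, resid_fn, max_iter = 200, tol = 1e-10) {
  r <- resid_fn(par)
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    np <- length(par)
    J <- matrix(0, length(r), np)
    h <- 1e-7 * (abs(par) + 1e-7)
    for (j in seq_len(np)) {
      pj <- par; pj[j] <- pj[j] + h[j]
      J[, j] <- (resid_fn(pj) - r) / h[j]
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (k in 1:12) {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12, np)
      step <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      par_new <- par + as.vector(step)
      r_new <- resid_fn(par_new)
      rss_new <- sum(r_new^2)
      if (is.finite(rss_new) && rss_new <= rss) {
        rel <- (rss - rss_new) / max(rss, .Machine$double.xmin)
        par <- par_new; r <- r_new; rss <- rss_new
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (rel < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) { converged <- converged || !improved; break }
  }
  list(par = par, rss = rss, converged = converged, iter = iter)
}

check_dwi_signals <- function(signals, gtab) {
  if (length(signals) != length(gtab$bvals))
    stop("signal count does not match gradient table")
  if (all(signals == 0)) stop("all-zero signals")
  if (any(signals < 0)) stop("negative signal value")
  if (any(signals == 0)) stop("zero signal value (log-linear fit undefined)")
  if (length(signals) < 7) stop("need at least 7 measurements")
  if (!any(gtab$b0)) stop("need at least one b0 measurement")
}

loglinear_design <- function(gtab) {
  b <- gtab$bvals; g <- gtab$bvecs
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Fit a single diffusion tensor to one voxel's signals
#'
#' Log-linear least squares on `log S` provides the starting estimate; a
#' Levenberg-Marquardt refinement on the nonlinear signal model, with the
#' tensor parameterized by its Cholesky factor, enforces positive
#' semidefiniteness. On noise-free data the log-linear step is already
#' exact.
#'
#' @param signals positive signal vector, one per gradient entry.
#' @param gtab a [gradient_table()] with at least 7 entries and one b0.
#' @param refine run the nonlinear refinement (default TRUE).
#' @param max_iter,tol LM convergence controls (relative RSS change).
#' @return list with `tensor` (3x3), `s0`, `rss`, `eig`
#'   (eigen decomposition, values sorted decreasing), `converged`.
#' @export
fit_single_tensor <- function(signals, gtab, refine = TRUE,
                              max_iter = 200, tol = 1e-10) {
  check_dwi_signals(signals, gtab)
  X <- loglinear_design(gtab)
  beta <- qr.solve(X, log(signals))
  s0 <- exp(beta[1])
  D <- d6_to_mat(beta[2:7])
  l6 <- mat_to_chol(D)
  par <- c(log(s0), l6)
  if (refine) {
    fit <- lm_minimize(par, function(p) {
      m <- multi_tensor_voxel(list(chol_to_mat(p[2:7])), 1, exp(p[1]))
      predict_signal(m, gtab) - signals
    }, max_iter = max_iter, tol = tol)
    par <- fit$par
    rss <- fit$rss
    converged <- fit$converged
  } else {
    m <- multi_tensor_voxel(list(chol_to_mat(par[2:7])), 1, exp(par[1]))
    rss <- sum((predict_signal(m, gtab) - signals)^2)
    converged <- TRUE
  }
  D <- chol_to_mat(par[2:7])
  e <- eigen(D, symmetric = TRUE)
  list(tensor = D, s0 = exp(par[1]), rss = rss, eig = e,
       converged = converged)
}

prolate_tensor <- function(axis, lam_par = 1.2e-3, lam_perp = 3e-4) {
  axis <- axis / sqrt(sum(axis^2))
  lam_perp * diag(3) + (lam_par - lam_perp) * tcrossprod(axis)
}

two_tensor_pack <- function(p) {
  f1 <- 1 / (1 + exp(-p[2]))
  multi_tensor_voxel(list(chol_to_mat(p[3:8]), chol_to_mat(p[9:14])),
                     c(f1, 1 - f1), exp(p[1]))
}

canonical_order <- function(model) {
  if (model$n_fibers < 2) return(model)
  e1 <- lapply(model$tensors, function(D) {
    v <- eigen(D, symmetric = TRUE)$vectors[, 1]
    if (v[which.max(abs(v))] < 0) -v else v
  })
  f <- model$fractions
  swap <- if (abs(f[1] - f[2]) > 1e-6) f[1] < f[2] else {
    # fraction tie: order by principal axis, lexicographically
    a <- round(e1[[1]], 6); b <- round(e1[[2]], 6)
    d <- a - b
    nz <- which(abs(d) > 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  if (swap)
    multi_tensor_voxel(model$tensors[2:1], f[2:1], model$s0)
  else model
}

#' Fit a two-tensor model to one voxel's signals
#'
#' Shared S0, two positive-semidefinite tensors (Cholesky parameterized) and
#' a logistic-parameterized mixing fraction, refined by Levenberg-Marquardt
#' from two starting strategies: (a) the single-tensor principal axis plus
#' the direction of strongest residual apparent diffusivity, and (b) the
#' two most diffusive, mutually separated gradient directions. The better
#' converged fit is kept; if neither improves on the single-tensor fit, a
#' duplicated single tensor is returned (so the two-tensor residual never
#' exceeds the single-tensor residual). Components are returned in a
#' canonical order (descending fraction, axis-lexicographic tie-break).
#'
#' @inheritParams fit_single_tensor
#' @param init optional list of two unit 3-vectors to use as starting axes
#'   instead of the automatic strategies.
#' @param single optional precomputed [fit_single_tensor()] result.
#' @return A [multi_tensor_voxel()] with attributes `rss` and `converged`.
#' @export
fit_two_tensor <- function(signals, gtab, init = NULL, single = NULL,
                           max_iter = 200, tol = 1e-10) {
  check_dwi_signals(signals, gtab)
  if (is.null(single)) single <- fit_single_tensor(signals, gtab)
  s0 <- single$s0
  w <- !gtab$b0
  adc_obs <- -log(pmax(signals[w], 1e-12) / s0) / gtab$bvals[w]
  gw <- gtab$bvecs[, w, drop = FALSE]

  inits <- list()
  if (!is.null(init)) {
    inits <- list(init)
  } else {
    # (a) single-tensor e1 + strongest residual-ADC direction away from it
    e1 <- single$eig$vectors[, 1]
    adc_pred <- colSums(gw * (single$tensor %*% gw))
    resid_adc <- adc_obs - adc_pred
    away <- abs(colSums(gw * e1)) < cos(20 * pi / 180)
    a2 <- if (any(away)) gw[, which(away)[which.max(resid_adc[away])]] else
      gw[, which.max(resid_adc)]
    inits[[1]] <- list(e1, a2)
    # (b) two ADC peaks separated by > 30 degrees
    i1 <- which.max(adc_obs)
    sep <- abs(colSums(gw * gw[, i1])) < cos(30 * pi / 180)
    if (any(sep)) {
      i2 <- which(sep)[which.max(adc_obs[sep])]
      inits[[2]] <- list(gw[, i1], gw[, i2])
    }
  }

  mean_lam <- mean(pmax(single$eig$values, 1e-5))
  best <- NULL
  for (ini in inits) {
    lam_par <- max(3 * mean_lam / 1.6, 1e-5)
    t1 <- prolate_tensor(ini[[1]], lam_par, lam_par / 4)
    t2 <- prolate_tensor(ini[[2]], lam_par, lam_par / 4)
    par0 <- c(log(s0), 0, mat_to_chol(t1), mat_to_chol(t2))
    fit <- lm_minimize(par0, function(p)
      predict_signal(two_tensor_pack(p), gtab) - signals,
      max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }

  if (best$rss <= single$rss) {
    model <- canonical_order(two_tensor_pack(best$par))
    attr(model, "rss") <- best$rss
    attr(model, "converged") <- best$converged
  } else {
    # fall back: duplicated single tensor, identical residual
    model <- multi_tensor_voxel(list(single$tensor, single$tensor),
                                c(0.5, 0.5), s0)
    attr(model, "rss") <- single$rss
    attr(model, "converged") <- TRUE
  }
  model
}

#' Classify the number of fibers in a voxel
#'
#' Nested-model F-test on the residual sums of squares of the single-tensor
#' (7 parameters) and two-tensor (14 parameters) fits: the voxel is called
#' two-fiber iff the single-tensor model is rejected at level `alpha`.
#' Voxels whose single-tensor residual is already negligible relative to
#' the signal energy are called single-fiber without the second fit.
#'
#' @inheritParams fit_two_tensor
#' @param alpha significance level of the nested F-test (default 0.05).
#' @param two optional precomputed [fit_two_tensor()] result.
#' @return integer, 1 or 2.
#' @export
classify_fibre_count <- function(signals, gtab, alpha = 0.05,
                                 single = NULL, two = NULL) {
  check_dwi_signals(signals, gtab)
  if (is.null(single)) single <- fit_single_tensor(signals, gtab)
  energy <- sum(signals^2)
  if (single$rss <= 1e-12 * energy) return(1L)
  if (is.null(two)) two <- fit_two_tensor(signals, gtab, single = single)
  rss1 <- single$rss; rss2 <- attr(two, "rss")
  n <- length(signals); p1 <- 7; p2 <- 14
  if (n <= p2) stop("too few measurements for the nested F-test")
  if (rss2 <= 1e-14 * energy) return(2L)
  Fstat <- ((rss1 - rss2) / (p2 - p1)) / (rss2 / (n - p2))
  p <- pf(Fstat, p2 - p1, n - p2, lower.tail = FALSE)
  if (is.finite(Fstat) && Fstat > 0 && p < alpha) 2L else 1L
}

tensor_eigenvalues <- function(x) {
  if (is.matrix(x)) sort(eigen(x, symmetric = TRUE, only.values = TRUE)$values,
                         decreasing = TRUE)
  else sort(as.numeric(x), decreasing = TRUE)
}

#' Fractional anisotropy of a diffusion tensor
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`,
#' in [0, 1]. The all-zero tensor returns 0 by convention.
#'
#' @param x a symmetric 3x3 tensor or its three eigenvalues.
#' @export
compute_fa <- function(x) {
  lam <- tensor_eigenvalues(x)
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  min(1, sqrt(1.5 * sum((lam - mean(lam))^2) / ss))
}

#' Mean diffusivity (mm^2/s)
#' @inheritParams compute_fa
#' @export
compute_md <- function(x) mean(tensor_eigenvalues(x))
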