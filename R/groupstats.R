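## Group-level statistical layer: Gaussian smoothing, voxel-wise GLM,
## summary t-tests, permutation maxT small-volume FWE correction
## (Freedman-Lane), ROI medians, disability correlations, lesion maps and
## Dice overlap.

FWHM_TO_SIGMA <- 2.3548200450309493  # 2 * sqrt(2 * log(2))

#' Gaussian smoothing of a volume
#'
#' Separable convolution with per-axis `sigma = fwhm / (2.3548 * voxel)`,
#' kernel truncated at 4 sigma, zero padding at the boundary. The total
#' image mass is preserved for interior support. `fwhm = 0` is the
#' identity.
#'
#' @param volume a 3D `acm_volume`.
#' @param fwhm_mm kernel full width at half maximum, mm (protocol default 4).
#' @export
smooth_volume <- function(volume, fwhm_mm = 4) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(volume)
  arr <- volume$data
  d <- dim(arr)
  for (a in 1:3) {
    sigma <- fwhm_mm / (FWHM_TO_SIGMA * volume$voxel_size[a])
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    k <- k / sum(k)
    n <- d[a]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    perm <- c(a, setdiff(1:3, a))
    A <- aperm(arr, perm)
    M <- K %*% matrix(A, n)
    arr <- aperm(array(M, d[perm]), order(perm))
  }
  as_volume(arr, volume$affine, volume$space)
}

#' Stack volumes into a subjects x voxels matrix
#' @param volumes list of co-registered `acm_volume`s.
#' @param mask optional binary mask restricting the voxel set.
#' @export
volumes_matrix <- function(volumes, mask = NULL) {
  ref <- volumes[[1]]
  for (v in volumes)
    if (!same_grid(v, ref)) stop("volumes are not on one grid")
  sel <- if (is.null(mask)) rep(TRUE, prod(grid_dim(ref))) else mask$data > 0
  t(vapply(volumes, function(v) v$data[sel], numeric(sum(sel))))
}

#' Voxel-wise ordinary least squares GLM
#'
#' Per voxel: `beta = (X'X)^-1 X' y`, residual variance with `n - p`
#' degrees of freedom, and `t = c' beta / sqrt(sigma2 c'(X'X)^-1 c)` for
#' the requested contrast. `voxel_covariate` (a subjects x voxels matrix,
#' e.g. the atrophy covariate) appends one per-voxel column to the design;
#' its contrast weight is 0.
#'
#' @param Y subjects x voxels response matrix (see [volumes_matrix()]).
#' @param X design matrix (subjects x p), full rank, including the
#'   intercept.
#' @param contrast length-p numeric contrast vector.
#' @param voxel_covariate optional subjects x voxels matrix.
#' @return list with `beta` (p x v), `t`, `se`, `sigma2` (length v), `df`.
#' @export
fit_glm <- function(Y, X, contrast, voxel_covariate = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("Y and X disagree on subject count")
  if (qr(X)$rank < p) stop("rank-deficient design")
  if (n <= p + !is.null(voxel_covariate)) stop("fewer subjects than columns")
  contrast <- as.numeric(contrast)
  if (length(contrast) != p) stop("contrast length must match design columns")
  if (is.null(voxel_covariate)) {
    XtXi <- solve(crossprod(X))
    beta <- XtXi %*% crossprod(X, Y)
    resid <- Y - X %*% beta
    df <- n - p
    sigma2 <- colSums(resid^2) / df
    cvar <- drop(t(contrast) %*% XtXi %*% contrast)
    se <- sqrt(sigma2 * cvar)
    tstat <- drop(crossprod(contrast, beta)) / se
    # exact-fit voxels (zero residual variance up to float noise) get t = 0
    tstat[se == 0 | sigma2 <= 1e-20 * colMeans(Y * Y)] <- 0
    list(beta = beta, t = tstat, se = se, sigma2 = sigma2, df = df)
  } else {
    voxel_covariate <- as.matrix(voxel_covariate)
    if (!all(dim(voxel_covariate) == dim(Y)))
      stop("voxel_covariate must match Y")
    v <- ncol(Y)
    df <- n - p - 1L
    tstat <- se <- sigma2 <- numeric(v)
    beta <- matrix(0, p + 1L, v)
    cfull <- c(contrast, 0)
    for (j in seq_len(v)) {
      Xj <- cbind(X, voxel_covariate[, j])
      XtXi <- tryCatch(solve(crossprod(Xj)), error = function(e) NULL)
      if (is.null(XtXi)) { tstat[j] <- 0; next }
      bj <- XtXi %*% crossprod(Xj, Y[, j])
      rj <- Y[, j] - Xj %*% bj
      sigma2[j] <- sum(rj^2) / df
      se[j] <- sqrt(sigma2[j] * drop(t(cfull) %*% XtXi %*% cfull))
      tstat[j] <- if (se[j] > 0) sum(cfull * bj) / se[j] else 0
      beta[, j] <- bj
    }
    list(beta = beta, t = tstat, se = se, sigma2 = sigma2, df = df)
  }
}

#' Welch two-group voxel test on covariate-adjusted residuals
#'
#' Regresses the nuisance design out of every voxel (one common OLS fit),
#' then runs an unequal-variance (Welch) two-sample t-test between the two
#' groups' residuals per voxel.
#'
#' @param Y subjects x voxels matrix.
#' @param groups factor/vector with exactly two levels; the t statistic is
#'   mean(level1) - mean(level2).
#' @param nuisance optional nuisance design (intercept added if absent).
#' @return list with `t`, `df` (per voxel, Satterthwaite).
#' @export
welch_voxel_ttest <- function(Y, groups, nuisance = NULL) {
  Y <- as.matrix(Y)
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  Z <- if (is.null(nuisance)) matrix(1, nrow(Y), 1) else as.matrix(nuisance)
  R <- Y - Z %*% solve(crossprod(Z), crossprod(Z, Y))
  a <- g == levels(g)[1]
  nA <- sum(a); nB <- sum(!a)
  mA <- colMeans(R[a, , drop = FALSE]); mB <- colMeans(R[!a, , drop = FALSE])
  vA <- apply(R[a, , drop = FALSE], 2, var)
  vB <- apply(R[!a, , drop = FALSE], 2, var)
  seq2 <- vA / nA + vB / nB
  tstat <- ifelse(seq2 > 0, (mA - mB) / sqrt(seq2), 0)
  df <- ifelse(seq2 > 0,
               seq2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               nA + nB - 2)
  list(t = tstat, df = df)
}

#' Two-sample t-test from group summaries
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (n >= 2, sd >= 0).
#' @param variant `"pooled"` (equal variance, df = nA + nB - 2) or
#'   `"welch"` (Satterthwaite df).
#' @param tails 1 or 2.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(meanA, sdA, nA, meanB, sdB, nB,
                               variant = c("pooled", "welch"), tails = 2) {
  variant <- match.arg(variant)
  if (nA < 2 || nB < 2) stop("need n >= 2 per group")
  if (sdA < 0 || sdB < 0) stop("negative sd")
  if (sdA == 0 && sdB == 0 && meanA == meanB)
    return(list(t = 0, df = nA + nB - 2, p = 1))
  if (variant == "pooled") {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    se2 <- sdA^2 / nA + sdB^2 / nB
    se <- sqrt(se2)
    df <- se2^2 / ((sdA^2 / nA)^2 / (nA - 1) + (sdB^2 / nB)^2 / (nB - 1))
  }
  tstat <- (meanA - meanB) / se
  p <- if (tails == 2) 2 * pt(abs(tstat), df, lower.tail = FALSE)
       else pt(tstat, df, lower.tail = FALSE)
  list(t = tstat, df = df, p = min(p, 1))
}

#' Permutation small-volume FWE correction (maxT, Freedman-Lane)
#'
#' Restricted to the voxels of `roi`: the observed contrast t-map is
#' compared against the permutation null of the maximum in-ROI t.
#' Covariates are handled with the Freedman-Lane scheme: the reduced
#' (nuisance-only) model residuals are permuted, the nuisance fit is added
#' back, and the full model is refit. The one-tailed test rejects for
#' large positive `c' beta`; FWE p-values use the (1 + count) / (1 + n)
#' estimator.
#'
#' @param Y subjects x voxels matrix restricted to (or indexable by) the
#'   analysis voxels.
#' @param X full design matrix; `contrast` picks the effect of interest
#'   (nuisance columns are those with zero contrast weight).
#' @param roi logical/0-1 vector selecting the in-ROI columns of `Y`.
#' @param n_permutations number of label permutations, >= 100.
#' @param alpha FWE significance level (protocol default 0.05).
#' @return list with `t` (in-ROI observed t), `p_fwe`, `significant`
#'   (logical), `max_null`, `threshold` (the alpha-quantile of the null).
#' @export
svc_fwe <- function(Y, X, contrast, roi = NULL, n_permutations = 1000,
                    alpha = 0.05) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (n_permutations < 100) stop("need at least 100 permutations")
  if (1 / (n_permutations + 1) > alpha)
    stop("too few permutations for the requested alpha")
  roi <- if (is.null(roi)) rep(TRUE, ncol(Y)) else as.logical(roi > 0)
  Yr <- Y[, roi, drop = FALSE]
  contrast <- as.numeric(contrast)
  nuis <- which(abs(contrast) < 1e-12)
  obs <- fit_glm(Yr, X, contrast)$t
  Z <- X[, nuis, drop = FALSE]
  gamma <- solve(crossprod(Z), crossprod(Z, Yr))
  fit0 <- Z %*% gamma
  R <- Yr - fit0
  n <- nrow(Yr)
  max_null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    Yb <- fit0 + R[perm, , drop = FALSE]
    max_null[b] <- max(fit_glm(Yb, X, contrast)$t)
  }
  p_fwe <- vapply(obs, function(t0) (1 + sum(max_null >= t0)) /
                    (n_permutations + 1), numeric(1))
  list(t = obs, p_fwe = p_fwe, significant = p_fwe <= alpha,
       max_null = max_null,
       threshold = stats::quantile(max_null, 1 - alpha, names = FALSE))
}

#' Median of a volume within one ROI label
#'
#' Even voxel counts use the midpoint of the central pair.
#'
#' @param volume an `acm_volume`; `roi_labels` integer label volume on the
#'   same grid; `roi_id` label value.
#' @export
roi_median <- function(volume, roi_labels, roi_id) {
  if (!same_grid(volume, roi_labels)) stop("grid mismatch")
  vals <- volume$data[roi_labels$data == roi_id]
  if (length(vals) == 0) stop("empty ROI: ", roi_id)
  median(vals)
}

#' Correlate a regional median statistic with disability
#'
#' Pearson correlation (two-tailed) between the ROI medians and EDSS, a
#' multiple regression `EDSS ~ median + age + gender` whose
#' fitted-vs-observed correlation R and coefficient of determination r^2
#' summarize the model fit, and a Bonferroni-adjusted Pearson p across
#' `n_rois` examined regions.
#'
#' @param medians per-subject ROI medians; `edss`, `age`, `gender`
#'   per-subject covariates.
#' @param n_rois number of ROIs examined (Bonferroni divisor, default 10).
#' @return list with `pearson_r`, `pearson_p`, `pearson_p_bonferroni`,
#'   `glm_R`, `r2`.
#' @export
correlate_disability <- function(medians, edss, age, gender, n_rois = 10) {
  if (length(medians) < 4) stop("need at least 4 subjects")
  if (sd(medians) == 0 || sd(edss) == 0) stop("constant input vector")
  ct <- cor.test(medians, edss)
  fit <- lm(edss ~ medians + age + gender)
  R <- if (sd(fitted(fit)) == 0) 0 else cor(fitted(fit), edss)
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       pearson_p_bonferroni = min(1, ct$p.value * n_rois),
       glm_R = R, r2 = R^2)
}

#' Lesion probability map and group comparisons
#'
#' `lesion_probability_map` averages spatially normalized binary lesion
#' masks, voxel-wise: the fraction of subjects lesioned at each voxel.
#' `lesion_difference` subtracts two such maps. `proportion_test` runs a
#' per-voxel two-sample t-test on the subjects' binary lesion indicators.
#'
#' @param lesion_masks list of binary `acm_volume`s on one grid.
#' @export
lesion_probability_map <- function(lesion_masks) {
  if (length(lesion_masks) == 0) stop("empty subject list")
  ref <- lesion_masks[[1]]
  acc <- array(0, grid_dim(ref))
  for (m in lesion_masks) {
    if (!same_grid(m, ref)) stop("grid mismatch")
    if (!all(m$data %in% c(0, 1))) stop("masks must be binary")
    acc <- acc + m$data
  }
  as_volume(acc / length(lesion_masks), ref$affine, ref$space)
}

#' @rdname lesion_probability_map
#' @param mapA,mapB lesion probability maps on one grid.
#' @export
lesion_difference <- function(mapA, mapB) {
  if (!same_grid(mapA, mapB)) stop("grid mismatch")
  as_volume(mapA$data - mapB$data, mapA$affine, mapA$space)
}

#' @rdname lesion_probability_map
#' @param masksA,masksB per-group lists of binary masks.
#' @param variant pooled or welch per-voxel t.
#' @return `proportion_test`: an `acm_volume` t-map (0 where both groups
#'   have zero variance and equal proportions).
#' @export
proportion_test <- function(masksA, masksB, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  ref <- masksA[[1]]
  A <- t(vapply(masksA, function(m) as.numeric(m$data), numeric(prod(grid_dim(ref)))))
  B <- t(vapply(masksB, function(m) as.numeric(m$data), numeric(prod(grid_dim(ref)))))
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, var); vB <- apply(B, 2, var)
  if (variant == "pooled") {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    se <- sqrt(vA / nA + vB / nB)
  }
  tstat <- ifelse(se > 0, (mA - mB) / se, 0)
  as_volume(array(tstat, grid_dim(ref)), ref$affine, ref$space)
}

#' Dice overlap of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`, in [0, 1]; defined as 0 when both masks
#' are empty.
#'
#' @param maskA,maskB binary `acm_volume`s on one grid.
#' @export
dice <- function(maskA, maskB) {
  if (!same_grid(maskA, maskB)) stop("grid mismatch")
  a <- maskA$data > 0; b <- maskB$data > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
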