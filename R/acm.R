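#' Compute an anatomical connectivity map
#'
#' Probabilistic tractography is repeated from every seed-mask voxel
#' (`n_per_seed` streamlines each, seeded at voxel centers) and each
#' streamline increments the count of every voxel it visits. With the
#' default unique-visit counting a streamline contributes at most 1 to any
#' voxel, making counts step-size invariant; `count_mode = "entry"`
#' increments once per voxel entry instead. Deterministic under a fixed
#' RNG seed (`set.seed()` before the call).
#'
#' @param fodf a `fodf_field`.
#' @param seed_mask binary `acm_volume`; also used as the tracking /
#'   termination mask unless `track_mask` is given.
#' @param n_per_seed streamlines per seed voxel (protocol default 500).
#' @param params a [tracking_params()].
#' @param count_mode `"unique"` or `"entry"`.
#' @param track_mask optional separate stopping mask.
#' @return An `acm_volume` of integer visit counts with metadata attribute
#'   `acm_meta` (n_per_seed, count mode, seed count).
#' @export
compute_acm <- function(fodf, seed_mask, n_per_seed, params = tracking_params(),
                        count_mode = c("unique", "entry"),
                        track_mask = NULL) {
  count_mode <- match.arg(count_mode)
  if (is.null(track_mask)) track_mask <- seed_mask
  if (!all(grid_dim(seed_mask) == fodf$dim))
    stop("field/mask grid mismatch")
  n_seeds <- sum(seed_mask$data > 0)
  if (n_seeds == 0) stop("empty seed mask")
  cs <- fodf_cstruct(fodf, track_mask)
  counts <- cpp_compute_acm(cs, as.integer(seed_mask$data > 0),
                            as.integer(n_per_seed), params$step_fraction,
                            params$max_steps, params$curvature_limit_deg,
                            params$max_rej, params$bidirectional,
                            count_mode == "unique")
  out <- as_volume(array(as.numeric(counts), fodf$dim), fodf$affine,
                   space = fodf$space)
  attr(out, "acm_meta") <- list(n_per_seed = n_per_seed,
                                count_mode = count_mode, n_seeds = n_seeds)
  out
}

#' ACM precision as a function of streamline number
#'
#' Repeats the ACM estimation `repeats` times (independent RNG streams)
#' for each requested streamline count and reports, per count, the
#' mask-average voxel-wise coefficient of variation (sample SD over mean,
#' n - 1 denominator; zero-mean voxels excluded) and the mask-average SNR
#' (mean over SD). The emulated protocol uses five repeats over
#' N in {10, 50, 100, 150, 300, 500, 700} and selected N = 500.
#'
#' @param fodf a `fodf_field`.
#' @param seed_mask binary seed mask.
#' @param n_values ascending streamline counts.
#' @param repeats number of repeated estimations, >= 2 (protocol default 5).
#' @param params a [tracking_params()].
#' @return data.frame with columns `n`, `avg_cv`, `avg_snr`.
#' @export
acm_precision <- function(fodf, seed_mask, n_values, repeats = 5,
                          params = tracking_params()) {
  if (repeats < 2) stop("need at least 2 repeats")
  n_values <- as.integer(n_values)
  if (is.unsorted(n_values)) stop("n_values must be ascending")
  mvox <- seed_mask$data > 0
  res <- lapply(n_values, function(N) {
    stack <- vapply(seq_len(repeats), function(r) {
      acm <- compute_acm(fodf, seed_mask, N, params)
      acm$data[mvox]
    }, numeric(sum(mvox)))
    mu <- rowMeans(stack)
    sdv <- apply(stack, 1, sd)
    ok <- mu > 0
    data.frame(n = N, avg_cv = mean(sdv[ok] / mu[ok]),
               avg_snr = mean(mu[ok & sdv > 0] / sdv[ok & sdv > 0]))
  })
  do.call(rbind, res)
}
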