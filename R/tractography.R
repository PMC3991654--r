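#' Tracking parameters
#'
#' Defaults follow the emulated acquisition protocol: step size 1/10 of the voxel size,
#' bidirectional seeding, termination on mask exit or on more than 180
#' degrees of cumulative turning within the extent of one voxel. The
#' `max_steps` cap (2000) is plumbing that guarantees termination and is
#' flagged in the output when hit.
#'
#' @param step_fraction step length as a fraction of the voxel size,
#'   in (0, 0.5].
#' @param max_steps per-direction step cap, >= 1.
#' @param bidirectional launch both half-tracks from the seed.
#' @param curvature_limit_deg intra-voxel cumulative turning limit.
#' @param max_rej Bingham rejection-sampling guard.
#' @export
tracking_params <- function(step_fraction = 0.1, max_steps = 2000,
                            bidirectional = TRUE,
                            curvature_limit_deg = 180, max_rej = 5000) {
  if (step_fraction <= 0 || step_fraction > 0.5)
    stop("step_fraction must be in (0, 0.5]")
  if (max_steps < 1) stop("max_steps must be >= 1")
  structure(list(step_fraction = step_fraction,
                 max_steps = as.integer(max_steps),
                 bidirectional = isTRUE(bidirectional),
                 curvature_limit_deg = curvature_limit_deg,
                 max_rej = as.integer(max_rej)),
            class = "tracking_params")
}

.term_labels <- c("mask_exit", "curvature", "max_steps")

#' Sample the fODF at a continuous position (probabilistic nearest)
#'
#' One of the 8 voxels surrounding the position is selected with
#' probability equal to its trilinear weight; the selected voxel's lobes
#' are returned (`n = 0` for background selections).
#'
#' @param fodf a `fodf_field`; `position` continuous 0-based voxel
#'   coordinate; `mask` optional tracking mask (defaults to voxels with
#'   lobes).
#' @return list with `voxel` (0-based index of the selected voxel) and
#'   `n_lobes`.
#' @export
fodf_at <- function(fodf, position, mask = NULL) {
  position <- as.numeric(position)
  if (any(position < -0.5) || any(position > fodf$dim - 0.5))
    stop("position outside field bounds")
  pick <- integer(3)
  for (a in 1:3) {
    base <- floor(position[a])
    frac <- position[a] - base
    pick[a] <- base + (runif(1) < frac)
    if (pick[a] < 0 || pick[a] > fodf$dim[a] - 1)
      return(list(voxel = NULL, n_lobes = 0L))
  }
  list(voxel = pick,
       n_lobes = fodf$nlobes[pick[1] + 1, pick[2] + 1, pick[3] + 1])
}

#' Propagate one probabilistic streamline
#'
#' Two half-tracks are launched from the seed voxel center along the
#' positive and negative directions of an axis sampled from a
#' weight-chosen lobe; at every step the fODF is sampled
#' (probabilistic-nearest), the lobe most aligned with the heading is
#' chosen, an axis is drawn from it and oriented into the heading's
#' hemisphere, and the position advances by `step_fraction` of a voxel.
#'
#' @param seed_voxel 0-based integer voxel index (length 3), inside the
#'   mask.
#' @param fodf a `fodf_field`.
#' @param mask binary tracking mask (`acm_volume`).
#' @param params a [tracking_params()].
#' @return A `streamline`: list with `points` (m x 3, continuous voxel
#'   coords) and `term` (two labels from mask_exit / curvature /
#'   max_steps).
#' @export
propagate <- function(seed_voxel, fodf, mask, params = tracking_params()) {
  cs <- fodf_cstruct(fodf, mask)
  res <- cpp_propagate(cs, as.integer(seed_voxel), params$step_fraction,
                       params$max_steps, params$curvature_limit_deg,
                       params$max_rej, params$bidirectional)
  structure(list(points = res$points, term = .term_labels[res$term]),
            class = "streamline")
}

#' Streamline set I/O (plain-text TSV)
#'
#' Lossless round trip: coordinates are written with full precision
#' (`%.17g`), one point per row, with the streamline id and the two
#' termination labels. An empty set writes a header-only file.
#'
#' @param streamlines list of `streamline` objects.
#' @param path file path.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("id\tx\ty\tz\tterm_start\tterm_end", con)
  for (s in seq_along(streamlines)) {
    sl <- streamlines[[s]]
    P <- sl$points
    lines <- sprintf("%d\t%.17g\t%.17g\t%.17g\t%s\t%s",
                     s, P[, 1], P[, 2], P[, 3], sl$term[1], sl$term[2])
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("malformed streamline file: ", conditionMessage(e)))
  if (nrow(tab) == 0) return(list())
  if (!all(c("id", "x", "y", "z", "term_start", "term_end") %in% names(tab)))
    stop("malformed streamline file (missing columns)")
  if (any(is.na(tab$x)) || any(is.na(tab$y)) || any(is.na(tab$z)))
    stop("malformed streamline file (truncated record)")
  lapply(split(tab, tab$id), function(d) {
    structure(list(points = unname(as.matrix(d[, c("x", "y", "z")])),
                   term = c(d$term_start[1], d$term_end[1])),
              class = "streamline")
  })
}
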