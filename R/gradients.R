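#' Gradient table
#'
#' Holds one b-factor and one unit gradient direction per acquired volume,
#' in FSL bval/bvec convention. Entries with `bval < b0_threshold` are
#' flagged as non-diffusion-weighted (b0); their direction is ignored.
#' The threshold defaults to 50 s/mm^2 so that small header noise on
#' nominally-zero b-values is tolerated.
#'
#' @param bvals numeric vector of b-factors (s/mm^2).
#' @param bvecs 3 x N matrix of gradient directions; weighted entries must
#'   have unit norm within 1e-6.
#' @param b0_threshold b-value below which an entry counts as b0.
#' @return A `gradient_table` with fields `bvals`, `bvecs`, `b0` (logical).
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- unname(as.matrix(bvecs))
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x N matrix")
  if (length(bvals) != ncol(bvecs))
    stop("bvals length (", length(bvals), ") != bvec count (", ncol(bvecs), ")")
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("non-numeric token in gradient table")
  if (any(bvals < 0)) stop("negative b-value")
  b0 <- bvals < b0_threshold
  if (!any(b0)) stop("gradient table has no b0 entry")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop("non-unit bvec on weighted entry (norm ",
         paste(sprintf("%.4f", nrm[bad]), collapse = ", "), ")")
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0,
                 b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table> %d entries (%d b0, %d weighted), b in [%g, %g]\n",
              length(x$bvals), sum(x$b0), sum(!x$b0),
              min(x$bvals), max(x$bvals)))
  invisible(x)
}

#' Read FSL-style bval/bvec files
#'
#' Both files are whitespace-separated text: the bval file one row of N
#' b-factors, the bvec file 3 rows of N direction components.
#'
#' @param bval_path,bvec_path file paths.
#' @inheritParams gradient_table
#' @export
read_gradients <- function(bval_path, bvec_path, b0_threshold = 50) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bvals <- scan(bval_path, what = double(), quiet = TRUE)
  raw <- readLines(bvec_path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) != 3L) stop("bvec file must have 3 rows, got ", length(raw))
  rows <- lapply(raw, function(l) {
    toks <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) stop("non-numeric token in bvec file")
    vals
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged bvec file (unequal row lengths)")
  bvecs <- do.call(rbind, rows)
  gradient_table(bvals, bvecs, b0_threshold)
}

#' Rotation factor of the polar decomposition
#'
#' For an invertible `A = R P` (R orthogonal, P symmetric positive
#' definite), returns `R = U t(V)` from the SVD `A = U S t(V)`. Pure
#' scalings therefore map to the identity.
#'
#' @param A invertible 3x3 matrix.
#' @export
polar_rotation <- function(A) {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(3L, 3L)))
  if (abs(det(A)) < 1e-12) stop("singular matrix")
  s <- svd(A)
  s$u %*% t(s$v)
}

#' Rotate gradient directions by the rotational part of an affine
#'
#' After co-registering diffusion volumes with an affine transform, the
#' gradient directions must be updated with the rotation factor of that
#' transform's polar decomposition. b-values are unchanged; rotated bvecs
#' are renormalized; b0 entries keep their (zero) direction.
#'
#' @param table a [gradient_table()].
#' @param affine_3x3 invertible 3x3 matrix.
#' @export
rotate_gradients <- function(table, affine_3x3) {
  stopifnot(inherits(table, "gradient_table"))
  R <- polar_rotation(affine_3x3)
  bvecs <- R %*% table$bvecs
  nrm <- sqrt(colSums(bvecs^2))
  w <- !table$b0 & nrm > 0
  bvecs[, w] <- sweep(bvecs[, w, drop = FALSE], 2, nrm[w], "/")
  bvecs[, table$b0] <- table$bvecs[, table$b0]
  gradient_table(table$bvals, bvecs, table$b0_threshold)
}
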