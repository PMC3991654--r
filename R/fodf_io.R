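#' Serialize / deserialize an fODF field as multi-volume NIfTI
#'
#' Writes `<prefix>_nlobes.nii`, `<prefix>_weights.nii`,
#' `<prefix>_axes.nii` (18 components: two 3x3 lobe frames) and
#' `<prefix>_kappa.nii`; float64 storage, bit-exact round trip.
#'
#' @param fodf a `fodf_field`; `prefix` output path prefix.
#' @export
write_fodf_field <- function(fodf, prefix) {
  aff <- fodf$affine
  wr <- function(arr, name, dtype = "float64")
    write_volume(as_volume(arr, aff, fodf$space),
                 paste0(prefix, "_", name, ".nii"), dtype)
  d <- fodf$dim
  wr(array(as.numeric(fodf$nlobes), d), "nlobes", "int32")
  wr(array(fodf$weights, c(d, 2L)), "weights")
  wr(array(fodf$axes, c(d, 18L)), "axes")
  wr(array(fodf$kappa, c(d, 4L)), "kappa")
  con <- file(paste0(prefix, "_meta.json"), "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(snr = fodf$snr, space = fodf$space),
                              auto_unbox = TRUE), con)
  invisible(prefix)
}

#' @rdname write_fodf_field
#' @export
read_fodf_field <- function(prefix) {
  rd <- function(name) read_volume(paste0(prefix, "_", name, ".nii"))
  nl <- rd("nlobes"); w <- rd("weights"); ax <- rd("axes"); kp <- rd("kappa")
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  d <- grid_dim(nl)
  structure(list(
    dim = d, affine = nl$affine, voxel_size = nl$voxel_size,
    space = meta$space, snr = meta$snr,
    nlobes = array(as.integer(round(nl$data)), d),
    weights = array(w$data, c(d, 2L)),
    axes = array(ax$data, c(d, 2L, 9L)),
    kappa = array(kp$data, c(d, 2L, 2L))
  ), class = "fodf_field")
}
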