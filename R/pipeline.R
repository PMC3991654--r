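## Reproducible pipeline runner. A run config (JSON or list) names the
## stages in order; each stage draws its RNG stream from the run seed and
## its position, writes its outputs under out_dir, and the manifest
## records parameters, seeds and output checksums so any stage can be
## re-run bit-identically.

.pipeline_stage_deps <- list(
  phantom = character(0),
  fit_tensors = c("dwi", "mask"),
  calibrate = "field",
  build_fodf = c("field", "calibration"),
  acm = c("fodf", "seed_mask"),
  acm_precision = c("fodf", "seed_mask")
)

#' Run the ACM pipeline from a config
#'
#' Stages (`phantom`, `fit_tensors`, `calibrate`, `build_fodf`, `acm`,
#' `acm_precision`) execute in the order given; each consumes the state
#' produced by its dependencies and fails with a dependency error if a
#' required upstream stage is missing. Every stochastic stage is seeded
#' from the run seed plus its stage index, and the manifest records all
#' parameters, seeds and MD5 checksums of the written outputs. Paper
#' constants (step 1/10 voxel, SNR 16, N = 500, 4 mm FWHM, alpha 0.05,
#' 5 repeats) are stage defaults, never hard-coded downstream.
#'
#' @param config a list, or a path to a JSON file, with fields `version`
#'   (1), `seed`, `out_dir` and `stages` (list of named-stage parameter
#'   lists).
#' @return The manifest (list), also written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (is.null(config$version) || config$version != 1)
    stop("config schema violation: version must be 1")
  for (fld in c("seed", "out_dir", "stages"))
    if (is.null(config[[fld]])) stop("config schema violation: missing ", fld)
  stages <- config$stages
  if (is.data.frame(stages)) stages <- split(stages, seq_len(nrow(stages)))
  if (length(stages) == 0) stop("config schema violation: empty stages")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list(version = 1, seed = config$seed, stages = list())
  p <- function(...) file.path(out_dir, paste0(...))

  for (si in seq_along(stages)) {
    st <- as.list(stages[[si]])
    name <- st$name
    if (is.null(name) || !name %in% names(.pipeline_stage_deps))
      stop("config schema violation: unknown stage ", name)
    missing_deps <- setdiff(.pipeline_stage_deps[[name]], ls(state))
    if (length(missing_deps))
      stop("dependency error: stage '", name, "' needs upstream output(s): ",
           paste(missing_deps, collapse = ", "))
    stage_seed <- (config$seed + si * 1000L) %% .Machine$integer.max
    set.seed(stage_seed)
    files <- character(0)

    if (name == "phantom") {
      spec <- phantom_spec(
        geometry = st$geometry %||% "straight_tube",
        dims = unlist(st$dims %||% c(24, 16, 16)),
        radius = st$radius %||% 2)
      ph <- make_tensor_phantom(spec)
      state$field <- ph$field
      state$mask <- ph$mask
      state$seed_mask <- acm_seed_mask(ph$field)
      gtab <- default_gradients()
      state$gtab <- gtab
      state$dwi <- simulate_dwi(ph$field, gtab, snr = st$snr %||% 16)
      write_tensor_field(ph$field, p("phantom_field"))
      write_volume(ph$mask, p("phantom_mask.nii"), "uint8")
      write_volume(state$dwi, p("phantom_dwi.nii"))
      files <- p(c("phantom_field_d1.nii", "phantom_mask.nii",
                   "phantom_dwi.nii"))
    } else if (name == "fit_tensors") {
      state$field <- fit_tensor_field(state$dwi, state$gtab, state$mask,
                                      max_fibers = st$max_fibers %||% 1,
                                      refine = isTRUE(st$refine))
      state$seed_mask <- acm_seed_mask(state$field)
      write_tensor_field(state$field, p("fitted_field"))
      files <- p("fitted_field_d1.nii")
    } else if (name == "calibrate") {
      state$calibration <- build_calibration_table(
        state$field, snr = st$snr %||% 16, gtab = state$gtab %||%
          default_gradients(),
        n_trials = st$n_trials %||% 500, seed = stage_seed)
      write_calibration_table(state$calibration, p("calibration.json"))
      files <- p("calibration.json")
    } else if (name == "build_fodf") {
      state$fodf <- build_fodf_field(state$field, state$calibration)
      write_fodf_field(state$fodf, p("fodf"))
      files <- p("fodf_nlobes.nii")
    } else if (name == "acm") {
      acm <- compute_acm(state$fodf, state$seed_mask,
                         n_per_seed = st$n_per_seed %||% 500,
                         params = tracking_params(
                           step_fraction = st$step_fraction %||% 0.1))
      state$acm <- acm
      write_volume(acm, p("acm.nii"), "int32")
      files <- p("acm.nii")
    } else if (name == "acm_precision") {
      prec <- acm_precision(state$fodf, state$seed_mask,
                            n_values = unlist(st$n_values %||%
                                                c(10, 50, 150, 300, 500, 700)),
                            repeats = st$repeats %||% 5)
      write.table(prec, p("precision.tsv"), sep = "\t", row.names = FALSE,
                  quote = FALSE)
      files <- p("precision.tsv")
    }

    manifest$stages[[si]] <- list(
      name = name, seed = stage_seed, params = st[setdiff(names(st), "name")],
      outputs = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
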