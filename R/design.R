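#' Study design matrix and standard contrasts
#'
#' Builds the group/age/gender design used by the voxel-wise GLM: an
#' intercept, indicator columns for the non-reference groups (the
#' reference is the first of healthy / RR / SP present in the data),
#' mean-centered age, and gender passed through as given (0/1 coding, 0 is
#' the reference). One-tailed contrasts follow the directional
#' hypotheses — patients are expected to have *lower* connectivity, so
#' "healthy > RR" is the positive direction of `healthy_gt_rr`, etc.;
#' contrasts are generated for every ordered pair of groups present.
#'
#' @param covariates data.frame with columns `group` (healthy / RR / SP),
#'   `age`, `gender` (0/1).
#' @return list with `X` (design matrix), `contrasts` (named list of
#'   contrast vectors), `columns`, `reference`.
#' @export
study_design <- function(covariates) {
  req <- c("group", "age", "gender")
  if (!all(req %in% names(covariates)))
    stop("covariates must contain: ", paste(req, collapse = ", "))
  if (any(is.na(covariates[req]))) stop("missing values in used columns")
  g <- as.character(covariates$group)
  levels_all <- c("healthy", "RR", "SP")
  bad <- setdiff(unique(g), levels_all)
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  present <- intersect(levels_all, unique(g))
  if (length(present) < 2) stop("need at least two groups")
  ref <- present[1]
  ind <- sapply(present[-1], function(lv) as.numeric(g == lv))
  colnames(ind) <- paste0("group", present[-1])
  X <- cbind(intercept = 1, ind,
             age = covariates$age - mean(covariates$age),
             gender = as.numeric(covariates$gender))
  p <- ncol(X)
  con <- function(a, b) {
    v <- numeric(p)
    if (a != ref) v[match(paste0("group", a), colnames(X))] <- 1
    if (b != ref) v[match(paste0("group", b), colnames(X))] <- -1
    v
  }
  contrasts <- list()
  for (a in present) for (b in setdiff(present, a))
    contrasts[[paste0(tolower(a), "_gt_", tolower(b))]] <- con(a, b)
  list(X = X, contrasts = contrasts, columns = colnames(X), reference = ref)
}
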