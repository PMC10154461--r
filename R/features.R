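#' Radiomics feature registry
#'
#' The 104-feature registry: 18 first-order (FF), 14 morphological (MF)
#' and 72 texture (TF) features, the latter split into GLCM (21), GLRLM
#' (16), GLSZM (16), GLDM (14) and NGTDM (5). Stored as a data file so
#' the set can be inspected or swapped without code changes.
#'
#' @return Data frame with columns `name`, `class`, `family`.
#' @export
feature_registry <- function() {
  read.csv(system.file("extdata", "feature_registry.csv", package = "rimshrink"),
           stringsAsFactors = FALSE)
}

#' Extract the full radiomics feature vector for one ROI
#'
#' Runs the extraction chain on a volume/mask pair: optional window/level
#' clamp, nearest-neighbour resampling of image and mask to the target
#' spacing, first-order statistics, 3D shape features, fixed-bin-width
#' discretization and the five texture families. No filtered image
#' channels are used: features are computed on the raw (windowed) image
#' only. Extraction is fully deterministic.
#'
#' @param values 3D numeric array of attenuation (HU).
#' @param mask binary 3D array aligned with `values`.
#' @param spacing voxel spacing in mm.
#' @param config a [preprocess_config()].
#' @return Named numeric vector of 104 finite values, in registry order.
#' @export
extract_features <- function(values, mask, spacing,
                             config = preprocess_config()) {
  check_mask(mask, dim(values))
  if (!is.null(config$window))
    values <- apply_window(values, config$window[1], config$window[2])
  rs <- resample_nn(values, mask, spacing, config$target_spacing)
  if (sum(rs$mask != 0) == 0L)
    .stop2("rimshrink_empty_roi_error", "ROI empty after resampling to ",
           paste(config$target_spacing, collapse = "x"), " mm")
  x <- rs$values[rs$mask != 0]
  ff <- first_order_features(x, prod(rs$spacing), config$bin_width)
  mf <- shape_features(rs$mask, rs$spacing)
  gl <- discretize(rs$values, rs$mask, config$bin_width)
  tf <- texture_features(gl)
  out <- c(ff, mf, tf)
  reg <- feature_registry()
  if (!identical(names(out), reg$name)) out <- out[reg$name]
  stopifnot(length(out) == 104L, all(is.finite(out)))
  out
}

#' Extract feature vectors for every case and ROI method
#'
#' Derives the four ROI variants per case and extracts the 104-feature
#' vector for each, returning a long feature table. Cases whose eroded
#' ROI is empty are excluded jointly from all four methods so the paired
#' design is preserved; exclusions are reported via a message and the
#' `excluded` attribute.
#'
#' @param cases list of `lesion_case` objects.
#' @param radius_mm erosion radius in mm.
#' @param config a [preprocess_config()].
#' @param rater which mask to use, 1 or 2 (cases without a second-rater
#'   mask are skipped when `rater = 2`).
#' @return Data frame with columns `case_id`, `roi_method`, `label` and
#'   the 104 features; attribute `excluded` lists dropped case ids.
#' @export
extract_cohort_features <- function(cases, radius_mm = 3.0,
                                    config = preprocess_config(), rater = 1) {
  rows <- list()
  excluded <- character()
  for (cs in cases) {
    mask <- if (rater == 1) cs$mask_rater1 else cs$mask_rater2
    if (is.null(mask)) next
    rois <- tryCatch(derive_rois(mask, cs$volume$spacing, radius_mm, cs$case_id),
                     rimshrink_empty_roi_error = function(e) {
                       .msg("excluding case ", cs$case_id, ": ", conditionMessage(e))
                       NULL
                     })
    if (is.null(rois)) { excluded <- c(excluded, cs$case_id); next }
    ok <- TRUE
    fvs <- list()
    for (m in .roi_methods) {
      fv <- tryCatch(extract_features(cs$volume$values, rois$masks[[m]],
                                      cs$volume$spacing, config),
                     rimshrink_empty_roi_error = function(e) NULL)
      if (is.null(fv)) { ok <- FALSE; break }
      fvs[[m]] <- fv
    }
    if (!ok) {
      .msg("excluding case ", cs$case_id, ": ROI empty after preprocessing")
      excluded <- c(excluded, cs$case_id)
      next
    }
    for (m in .roi_methods)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cs$case_id, roi_method = m, label = cs$label,
        as.list(fvs[[m]]), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
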