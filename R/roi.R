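#' Slice with the largest cross-sectional lesion area
#'
#' Returns the z index (0-based) of the slice with the largest foreground
#' area in mm^2 (voxel count times dx*dy, so for a single mask the voxel
#' count itself decides). Ties are broken toward the smallest z.
#'
#' @param mask binary 3D array.
#' @param spacing voxel spacing in mm.
#' @return Integer 0-based slice index.
#' @export
largest_area_slice <- function(mask, spacing = c(1, 1, 1)) {
  if (sum(mask != 0) == 0L)
    .stop2("rimshrink_empty_roi_error", "empty mask: no slice to select")
  counts <- apply(mask != 0, 3, sum)
  area <- counts * spacing[1] * spacing[2]
  which.max(area) - 1L   # which.max takes the first maximum: smallest z
}

#' Millimetre-calibrated binary erosion
#'
#' A voxel is retained iff its Euclidean distance (in mm, using the voxel
#' spacing) to the nearest background voxel centre exceeds `radius_mm`.
#' With `mode = "in_plane_2d"` distances are computed within each fixed-z
#' slice; with `mode = "full_3d"` in three dimensions. Radius 0 is the
#' identity. Computed by thresholding the exact Euclidean distance
#' transform.
#'
#' @param mask binary 3D array.
#' @param spacing voxel spacing in mm (dx, dy, dz).
#' @param radius_mm erosion radius in mm, >= 0.
#' @param mode `"full_3d"` or `"in_plane_2d"`.
#' @param case_id optional identifier used in error messages.
#' @return Eroded binary array of the same shape.
#' @export
erode_mm <- function(mask, spacing, radius_mm,
                     mode = c("full_3d", "in_plane_2d"), case_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(radius_mm >= 0)
  m <- binarize_mask(mask)
  if (radius_mm == 0) return(m)
  dsq <- cpp_edt_sq(as.integer(m), dim(m), as.numeric(spacing),
                    mode == "in_plane_2d")
  out <- array(0L, dim(m))
  out[m == 1L & dsq > radius_mm^2] <- 1L
  if (sum(out) == 0L)
    .stop2("rimshrink_empty_roi_error",
           "erosion (", mode, ", ", radius_mm, " mm) emptied the mask",
           if (!is.null(case_id)) paste0(" for case ", case_id) else "")
  out
}

#' Derive the four ROI variants from a full-volume lesion mask
#'
#' * `ALL`: the input full-volume mask.
#' * `MAX`: the mask restricted to its maximum-area slice.
#' * `MAX_E`: `MAX` eroded in-plane by `radius_mm` (x and y only).
#' * `ALL_E`: `ALL` eroded in 3D by `radius_mm`.
#'
#' The single-slice ROIs occupy exactly one z slice; the maximum-area
#' slice is selected before erosion and kept.
#'
#' @inheritParams erode_mm
#' @param radius_mm erosion radius in mm (default 3).
#' @return Object of class `roi_set`: list with `masks` (named list of the
#'   four binary arrays), `max_slice_index` (0-based), `erosion_radius_mm`.
#' @export
derive_rois <- function(mask, spacing, radius_mm = 3.0, case_id = NULL) {
  all_m <- binarize_mask(mask)
  check_mask(all_m, dim(all_m))
  z0 <- largest_area_slice(all_m, spacing)
  max_m <- array(0L, dim(all_m))
  max_m[, , z0 + 1L] <- all_m[, , z0 + 1L]
  fail <- function(method, e)
    .stop2("rimshrink_empty_roi_error", "ROI '", method, "' is empty",
           if (!is.null(case_id)) paste0(" for case ", case_id) else "",
           ": ", conditionMessage(e))
  max_e <- tryCatch(erode_mm(max_m, spacing, radius_mm, "in_plane_2d", case_id),
                    rimshrink_empty_roi_error = function(e) fail("MAX_E", e))
  all_e <- tryCatch(erode_mm(all_m, spacing, radius_mm, "full_3d", case_id),
                    rimshrink_empty_roi_error = function(e) fail("ALL_E", e))
  structure(list(masks = list(MAX = max_m, MAX_E = max_e,
                              ALL = all_m, ALL_E = all_e),
                 max_slice_index = z0, erosion_radius_mm = radius_mm),
            class = "roi_set")
}

#' @exportS3Method base::print
print.roi_set <- function(x, ...) {
  v <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<roi_set> erosion %.1f mm, max slice z=%d; voxels: %s\n",
              x$erosion_radius_mm, x$max_slice_index,
              paste(sprintf("%s=%d", names(v), v), collapse = ", ")))
  invisible(x)
}
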