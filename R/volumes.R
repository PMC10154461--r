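#' CT volume container
#'
#' A CT volume is a 3D array of attenuation values in Hounsfield units (HU)
#' together with the voxel spacing in millimetres. The third array axis is
#' the slice (z) axis. Orientation information beyond spacing is ignored:
#' the ROI derivation and feature extraction depend on spacing only.
#'
#' @param values 3D numeric array of attenuation values (HU).
#' @param spacing numeric length-3 vector, voxel spacing in mm (dx, dy, dz).
#' @return An object of class `ct_volume`: a list with elements `values`
#'   and `spacing`.
#' @export
ct_volume <- function(values, spacing) {
  if (length(dim(values)) != 3L || any(dim(values) == 0L))
    .stop2("rimshrink_geometry_error", "volume must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    .stop2("rimshrink_header_error", "spacing must be three finite positive values (mm)")
  if (any(!is.finite(values)))
    .stop2("rimshrink_geometry_error", "volume values must be finite")
  structure(list(values = values, spacing = spacing), class = "ct_volume")
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# binarize an integer-labelled mask array: any non-zero label -> 1
binarize_mask <- function(labels) {
  m <- array(0L, dim(labels))
  m[labels != 0] <- 1L
  m
}

check_mask <- function(mask, vol_dim, require_nonempty = TRUE) {
  if (!identical(dim(mask), as.integer(vol_dim)) &&
      !identical(as.integer(dim(mask)), as.integer(vol_dim)))
    .stop2("rimshrink_geometry_error",
           "mask shape (", paste(dim(mask), collapse = "x"),
           ") does not match volume shape (", paste(vol_dim, collapse = "x"), ")")
  if (require_nonempty && sum(mask != 0) == 0L)
    .stop2("rimshrink_empty_roi_error", "mask has no foreground voxels")
  invisible(TRUE)
}

#' Read and write CT volumes and masks as NIfTI
#'
#' Volumes and masks are stored as NIfTI (`.nii` / `.nii.gz`). Spacing is
#' taken from the header `pixdim`; orientation matrices are ignored (the
#' pipeline is spacing-covariant and phantoms are generated in canonical
#' orientation).
#'
#' @param path file path.
#' @return `read_ct_volume()` returns a [ct_volume]; `read_mask_nifti()`
#'   returns a binarized 3D integer array.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    .stop2("rimshrink_header_error", "non-positive pixdim in ", path)
  ct_volume(array(as.numeric(img), dim(img)[1:3]), sp)
}

#' @param vol a [ct_volume].
#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ct_volume
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  binarize_mask(array(as.integer(round(as.numeric(img))), dim(img)[1:3]))
}

#' @param mask 3D integer array (0 background, non-zero foreground).
#' @param spacing voxel spacing in mm, written to the header.
#' @rdname read_ct_volume
#' @export
write_mask_nifti <- function(mask, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Load a lesion case from NIfTI files
#'
#' Reads a CT volume and one or two aligned lesion masks. Masks are
#' binarized (any non-zero label becomes foreground); a mask whose grid
#' does not match the volume is a geometry error, an all-background mask
#' an empty-ROI error.
#'
#' @param volume_path,mask_path NIfTI paths for the volume and the
#'   (first-rater) mask.
#' @param label class label, `"adenoma"` or `"non_adenoma"`.
#' @param case_id case identifier.
#' @param mask_rater2_path optional second-rater mask path.
#' @param institution free-text institution tag.
#' @return An object of class `lesion_case`.
#' @export
read_case <- function(volume_path, mask_path, label,
                      case_id = basename(volume_path),
                      mask_rater2_path = NULL, institution = "") {
  label <- match.arg(label, .rimshrink_labels)
  vol <- read_ct_volume(volume_path)
  m1 <- read_mask_nifti(mask_path)
  check_mask(m1, dim(vol$values))
  m2 <- NULL
  if (!is.null(mask_rater2_path) && nzchar(mask_rater2_path)) {
    m2 <- read_mask_nifti(mask_rater2_path)
    check_mask(m2, dim(vol$values))
  }
  lesion_case(case_id, vol, m1, label, mask_rater2 = m2, institution = institution)
}

#' @param volume a [ct_volume].
#' @param mask_rater1,mask_rater2 binary 3D arrays aligned to `volume`
#'   (`mask_rater2` may be `NULL`).
#' @rdname read_case
#' @export
lesion_case <- function(case_id, volume, mask_rater1, label,
                        mask_rater2 = NULL, institution = "") {
  stopifnot(inherits(volume, "ct_volume"))
  label <- match.arg(label, .rimshrink_labels)
  mask_rater1 <- binarize_mask(mask_rater1)
  check_mask(mask_rater1, dim(volume$values))
  if (!is.null(mask_rater2)) {
    mask_rater2 <- binarize_mask(mask_rater2)
    check_mask(mask_rater2, dim(volume$values))
  }
  structure(list(case_id = as.character(case_id), volume = volume,
                 mask_rater1 = mask_rater1, mask_rater2 = mask_rater2,
                 label = label, institution = institution),
            class = "lesion_case")
}

#' @exportS3Method base::print
print.lesion_case <- function(x, ...) {
  cat(sprintf("<lesion_case> %s [%s] %s voxels foreground, rater2 %s\n",
              x$case_id, x$label, sum(x$mask_rater1),
              if (is.null(x$mask_rater2)) "absent" else "present"))
  invisible(x)
}

#' Load a cohort manifest
#'
#' The manifest is a CSV with columns `case_id`, `volume`, `mask_rater1`,
#' optional `mask_rater2`, `label` and `institution`; file paths are
#' resolved relative to the manifest location.
#'
#' @param path manifest CSV path.
#' @return A list of `lesion_case` objects, in manifest order.
#' @export
load_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "volume", "mask_rater1", "label")
  if (!all(need %in% names(man)))
    .stop2("rimshrink_integrity_error", "manifest must have columns: ",
           paste(need, collapse = ", "))
  if (anyDuplicated(man$case_id))
    .stop2("rimshrink_integrity_error", "duplicated case_id in manifest: ",
           paste(unique(man$case_id[duplicated(man$case_id)]), collapse = ", "))
  bad <- setdiff(unique(man$label), .rimshrink_labels)
  if (length(bad))
    .stop2("rimshrink_vocabulary_error", "unknown label(s): ",
           paste(bad, collapse = ", "), " (accepted: ",
           paste(.rimshrink_labels, collapse = ", "), ")")
  root <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  lapply(seq_len(nrow(man)), function(i) {
    r2 <- if ("mask_rater2" %in% names(man) && nzchar(man$mask_rater2[i] %||% ""))
      resolve(man$mask_rater2[i]) else NULL
    read_case(resolve(man$volume[i]), resolve(man$mask_rater1[i]),
              label = man$label[i], case_id = man$case_id[i],
              mask_rater2_path = r2,
              institution = if ("institution" %in% names(man)) man$institution[i] else "")
  })
}

#' Read and write feature tables
#'
#' A feature table is a data frame keyed by (`case_id`, `roi_method`) with
#' one column per radiomics feature. Values round-trip through CSV at full
#' double precision.
#'
#' @param table feature table data frame.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(table[, c("case_id", "roi_method")]))
    .stop2("rimshrink_integrity_error",
           "duplicate (case_id, roi_method) rows in feature table")
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(tab[, c("case_id", "roi_method")]))
    .stop2("rimshrink_integrity_error",
           "duplicate (case_id, roi_method) rows in ", path)
  num_cols <- setdiff(names(tab), c("case_id", "roi_method", "label", "institution"))
  for (cn in num_cols) {
    if (any(is.na(tab[[cn]]))) {
      i <- which(is.na(tab[[cn]]))[1]
      .stop2("rimshrink_integrity_error", "missing value in ", path,
             " at row ", i, ", column '", cn, "'")
    }
  }
  tab
}
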