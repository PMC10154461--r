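#' Preprocessing configuration for feature extraction
#'
#' Defaults follow the extraction protocol: optional window/level clamp
#' (abdominal 40/400 HU), nearest-neighbour resampling to an isotropic
#' 3x3x3 mm grid, and fixed 25-HU bin-width discretization.
#'
#' @param target_spacing numeric length-3, resampling target in mm.
#' @param bin_width grey-level bin width in HU.
#' @param window `c(level, width)` HU clamp, or `NULL` to disable.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(3, 3, 3), bin_width = 25,
                              window = c(40, 400)) {
  stopifnot(all(target_spacing > 0), bin_width > 0,
            is.null(window) || (length(window) == 2 && window[2] > 0))
  structure(list(target_spacing = as.numeric(target_spacing),
                 bin_width = bin_width, window = window),
            class = "preprocess_config")
}

#' Window/level intensity clamp
#'
#' Clamps attenuation values to `[level - width/2, level + width/2]`;
#' values inside the window are unchanged.
#'
#' @param values numeric array or vector of HU values.
#' @param level,width window centre and width in HU (`width > 0`).
#' @export
apply_window <- function(values, level = 40, width = 400) {
  stopifnot(width > 0)
  lo <- level - width / 2
  hi <- level + width / 2
  pmin(pmax(values, lo), hi)
}

#' Nearest-neighbour resampling of a volume and its mask
#'
#' The output grid covers the same physical extent: its dimension per axis
#' is `ceiling(n_in * spacing / target)`. Each output voxel takes the
#' value (and mask label) of the input voxel whose centre is nearest to
#' the output voxel centre; exact ties go to the smaller index. Voxel
#' centres sit at `(i - 0.5) * spacing` for 1-based index i.
#'
#' @param values 3D numeric array.
#' @param mask binary 3D array aligned with `values` (or `NULL`).
#' @param spacing input voxel spacing in mm.
#' @param target target spacing in mm.
#' @return List with `values`, `mask`, `spacing` (= `target`).
#' @export
resample_nn <- function(values, mask, spacing, target = c(3, 3, 3)) {
  spacing <- as.numeric(spacing)
  target <- as.numeric(target)
  din <- dim(values)
  if (isTRUE(all.equal(spacing, target))) {
    return(list(values = values, mask = mask, spacing = spacing))
  }
  dout <- as.integer(ceiling(din * spacing / target))
  idx <- lapply(1:3, function(a) {
    centre <- (seq_len(dout[a]) - 0.5) * target[a]
    pos <- centre / spacing[a] + 0.5
    pmin(pmax(ceiling(pos - 0.5), 1L), din[a])
  })
  list(values = values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       mask = if (is.null(mask)) NULL else
         mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       spacing = target)
}

#' Fixed-bin-width grey-level discretization
#'
#' Maps ROI attenuation values to integer grey levels with bins of
#' `bin_width` HU anchored at the ROI minimum:
#' `level(x) = floor((x - min) / bin_width) + 1`. The ROI minimum maps to
#' level 1 and `ng` is the maximum level, so levels are translation
#' invariant in HU.
#'
#' @param values 3D numeric array.
#' @param mask binary 3D array; voxels outside get level 0.
#' @param bin_width bin width in HU.
#' @return List of class `grey_level_roi`: `levels` (integer array, 0
#'   outside the ROI), `ng`, `n_voxels`.
#' @export
discretize <- function(values, mask, bin_width = 25) {
  stopifnot(bin_width > 0)
  inside <- mask != 0
  if (!any(inside))
    .stop2("rimshrink_empty_roi_error", "cannot discretize an empty ROI")
  x <- values[inside]
  lev <- array(0L, dim(values))
  lev[inside] <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  structure(list(levels = lev, ng = max(lev), n_voxels = sum(inside)),
            class = "grey_level_roi")
}
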