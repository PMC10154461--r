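#' Synthetic CT lesion phantom configuration
#'
#' Defines the study conditions the phantom cohort emulates: an
#' ellipsoidal lesion of class-dependent attenuation and size embedded in
#' a uniform background, with correlated intra-lesion texture, an
#' isotropic-in-mm Gaussian point-spread blur creating mixed-attenuation
#' rim voxels (the partial-volume effect), additive white noise, and a
#' simulated second rater obtained by smooth boundary perturbation.
#'
#' Class attenuation defaults are the pooled unenhanced medians of
#' lipid-poor adenomas (20.2 HU) and non-adenomas (37.4 HU); lesion
#' diameter ranges bracket the reported class medians and respect the
#' 1-cm inclusion floor; slice spacing defaults to 3.75 mm.
#'
#' @param dim grid dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param background_mean background attenuation (HU).
#' @param case_offset_sd sd (HU) of a per-case global attenuation offset
#'   applied to lesion and background alike, emulating calibration and
#'   protocol drift between examinations.
#' @param noise_sd additive white-noise standard deviation (HU).
#' @param psf_sigma_mm point-spread Gaussian sigma in mm (>= 0).
#' @param rater_amplitude_mm maximum boundary displacement of the
#'   simulated second rater, in mm.
#' @param classes per-class parameters: mean attenuation (HU), per-case
#'   mean jitter sd (HU, matching the reported interquartile spread),
#'   lesion base diameter mean/sd (mm, truncated normal) with truncation
#'   limits, texture sd (HU), texture correlation length (mm).
#' @return List of class `phantom_config`. The RNG algorithm used for
#'   all sampling is recorded in `$rng` for reproducibility across
#'   platforms.
#' @export
phantom_config <- function(dim = c(64, 64, 18), spacing = c(1, 1, 3.75),
                           background_mean = -30, case_offset_sd = 5,
                           noise_sd = 12, psf_sigma_mm = 1.2,
                           rater_amplitude_mm = 2,
                           classes = list(
                             adenoma = list(mean = 20.2, mean_sd = 11,
                                            diam_mean = 24, diam_sd = 10,
                                            diam_limits = c(14, 48),
                                            texture_sd = 12, texture_corr_mm = 4),
                             non_adenoma = list(mean = 37.4, mean_sd = 6,
                                                diam_mean = 35, diam_sd = 14,
                                                diam_limits = c(14, 48),
                                                texture_sd = 12, texture_corr_mm = 6))) {
  stopifnot(all(spacing > 0), psf_sigma_mm >= 0, rater_amplitude_mm >= 0,
            noise_sd >= 0, all(names(classes) == .rimshrink_labels))
  for (cl in classes)
    stopifnot(cl$diam_limits[1] >= 10, diff(cl$diam_limits) >= 0,
              cl$texture_sd >= 0, cl$texture_corr_mm >= 0)
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 background_mean = background_mean,
                 case_offset_sd = case_offset_sd, noise_sd = noise_sd,
                 psf_sigma_mm = psf_sigma_mm,
                 rater_amplitude_mm = rater_amplitude_mm,
                 classes = classes,
                 rng = "Mersenne-Twister/Inversion"),
            class = "phantom_config")
}

# smooth unit-variance random field: white noise filtered by a Gaussian
# of the given correlation length (mm), then empirically standardized
smooth_field <- function(dims, spacing, corr_mm) {
  w <- array(rnorm(prod(dims)), dims)
  if (corr_mm <= 0) return(w)
  f <- cpp_gauss_blur(w, dims, corr_mm / spacing)
  f <- array(f, dims)
  (f - mean(f)) / sd(f)
}

#' Generate one synthetic lesion case
#'
#' Voxelizes an ellipsoid of class-dependent size on the grid, fills its
#' interior with the class attenuation plus a correlated texture field,
#' blurs the whole volume with the isotropic-in-mm point-spread function,
#' and adds white noise. The ground-truth mask is the pre-blur ellipsoid;
#' the second-rater mask is a seeded boundary perturbation of it. The
#' same `(config, class_label, seed)` reproduces the case bit for bit.
#'
#' @param config a [phantom_config()].
#' @param class_label `"adenoma"` or `"non_adenoma"`.
#' @param seed integer seed.
#' @param case_id case identifier.
#' @return A `lesion_case` with attribute `ground_truth`: list with
#'   `true_mean` (interior fill mean, HU), `semi_axes_mm`, `centre_mm`.
#' @export
generate_case <- function(config, class_label, seed, case_id = "phantom") {
  class_label <- match.arg(class_label, .rimshrink_labels)
  cl <- config$classes[[class_label]]
  dims <- config$dim
  sp <- config$spacing
  old <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old[1], old[2]), add = TRUE)
  set.seed(seed)

  base_diam <- pmin(pmax(rnorm(1, cl$diam_mean, cl$diam_sd),
                         cl$diam_limits[1]), cl$diam_limits[2])
  diam <- base_diam * runif(3, 0.85, 1.15)   # mild, realistic anisotropy
  semi <- diam / 2
  extent <- dims * sp
  if (any(diam + 2 >= extent))
    .stop2("rimshrink_geometry_error", "lesion (", paste(round(diam, 1), collapse = "x"),
           " mm) does not fit the grid (", paste(extent, collapse = "x"), " mm)")
  centre <- extent / 2 + runif(3, -1, 1) * sp
  offset <- rnorm(1, 0, config$case_offset_sd %||% 0)
  true_mean <- cl$mean + rnorm(1, 0, cl$mean_sd) + offset

  cx <- (seq_len(dims[1]) - 0.5) * sp[1]
  cy <- (seq_len(dims[2]) - 0.5) * sp[2]
  cz <- (seq_len(dims[3]) - 0.5) * sp[3]
  q <- outer(outer(((cx - centre[1]) / semi[1])^2,
                   ((cy - centre[2]) / semi[2])^2, `+`),
             ((cz - centre[3]) / semi[3])^2, `+`)
  mask <- array(0L, dims)
  mask[q <= 1] <- 1L
  if (sum(mask) == 0L)
    .stop2("rimshrink_empty_roi_error", "lesion voxelized to an empty mask")

  vol <- array(config$background_mean + offset, dims)
  if (cl$texture_sd > 0) {
    tex <- smooth_field(dims, sp, cl$texture_corr_mm) * cl$texture_sd
  } else tex <- array(0, dims)
  vol[mask == 1L] <- true_mean + tex[mask == 1L]

  if (config$psf_sigma_mm > 0)
    vol <- array(cpp_gauss_blur(vol, dims, config$psf_sigma_mm / sp), dims)
  if (config$noise_sd > 0)
    vol <- vol + array(rnorm(prod(dims), 0, config$noise_sd), dims)

  m2 <- if (config$rater_amplitude_mm > 0)
    perturb_mask(mask, sp, config$rater_amplitude_mm,
                 seed = sample.int(.Machine$integer.max - 1L, 1L))
  else mask

  cs <- lesion_case(case_id, ct_volume(vol, sp), mask, class_label,
                    mask_rater2 = m2, institution = "phantom")
  attr(cs, "ground_truth") <- list(true_mean = true_mean, semi_axes_mm = semi,
                                   centre_mm = centre)
  cs
}

#' Generate a balanced phantom cohort
#'
#' Per-case seeds are derived reproducibly from the master seed; two
#' cohorts generated from the same `(config, n_per_class, seed)` are
#' identical.
#'
#' @inheritParams generate_case
#' @param n_per_class cases per class (>= 1).
#' @return List of class `phantom_cohort`: `cases` (list of
#'   `lesion_case`), `ground_truth` (data frame), `config`, `seed`.
#' @export
generate_cohort <- function(config, n_per_class, seed) {
  stopifnot(n_per_class >= 1)
  old <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old[1], old[2]), add = TRUE)
  set.seed(seed)
  labels <- rep(.rimshrink_labels, each = n_per_class)
  seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
  cases <- vector("list", length(labels))
  gt <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    id <- sprintf("case%03d", i)
    cases[[i]] <- generate_case(config, labels[i], seeds[i], id)
    g <- attr(cases[[i]], "ground_truth")
    gt[[i]] <- data.frame(case_id = id, label = labels[i],
                          true_mean = g$true_mean,
                          ax = g$semi_axes_mm[1], ay = g$semi_axes_mm[2],
                          az = g$semi_axes_mm[3], seed = seeds[i])
  }
  structure(list(cases = cases, ground_truth = do.call(rbind, gt),
                 config = config, seed = seed),
            class = "phantom_cohort")
}

#' @exportS3Method base::print
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases (%s), grid %s @ %s mm, psf %.1f mm, seed %d\n",
              length(x$cases),
              paste(table(x$ground_truth$label), collapse = "/"),
              paste(x$config$dim, collapse = "x"),
              paste(x$config$spacing, collapse = "x"),
              x$config$psf_sigma_mm, x$seed))
  invisible(x)
}

#' Simulate a second rater by smooth boundary perturbation
#'
#' Displaces the mask boundary by a smooth seeded random field whose
#' maximum amplitude is `amplitude_mm`: a voxel flips label only if its
#' signed distance to the original boundary is smaller than the local
#' field value, so every voxel farther than `amplitude_mm` from the
#' boundary keeps its label. Amplitude 0 returns the mask unchanged.
#'
#' @param mask binary 3D array.
#' @param spacing voxel spacing in mm.
#' @param amplitude_mm maximum normal displacement in mm (>= 0).
#' @param seed integer seed.
#' @param corr_mm correlation length of the displacement field (mm).
#' @return Perturbed binary mask.
#' @export
perturb_mask <- function(mask, spacing, amplitude_mm, seed, corr_mm = 8) {
  stopifnot(amplitude_mm >= 0)
  m <- binarize_mask(mask)
  if (amplitude_mm == 0) return(m)
  old <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old[1], old[2]), add = TRUE)
  set.seed(seed)
  dims <- dim(m)
  # unit-variance smooth field squashed so |g| < amplitude everywhere
  # and the typical displacement is about half the amplitude
  g <- amplitude_mm * tanh(0.6 * smooth_field(dims, spacing, corr_mm))
  d_bg <- sqrt(cpp_edt_sq(as.integer(m), dims, spacing, FALSE))
  d_fg <- sqrt(cpp_edt_sq(as.integer(1L - m), dims, spacing, FALSE))
  sdf <- ifelse(m == 1L, -d_bg, d_fg)
  out <- array(0L, dims)
  out[sdf < g] <- 1L
  if (sum(out) == 0L)
    .stop2("rimshrink_empty_roi_error", "boundary perturbation emptied the mask")
  out
}
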