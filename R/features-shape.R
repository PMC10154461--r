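# 3D morphological features. The surface mesh is built by marching
# tetrahedra on a lightly mollified indicator (Gaussian, 0.8 voxel sd,
# iso-level 0.5, linear edge interpolation): the mollifier removes the
# staircase bias of meshing a raw binary field, so the surface area of a
# digitized smooth solid is recovered closely. Degenerate ROIs (fewer
# than two voxels, or a mesh the mollifier closes off) fall back to
# voxel-face closed forms.

boundary_voxel_coords <- function(mask, spacing) {
  d <- dim(mask)
  m <- array(FALSE, d)
  m[mask != 0] <- TRUE
  shift_bg <- function(ax, dir) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + dir, 1L), d[ax])
    nb <- m[src[[1]], src[[2]], src[[3]], drop = FALSE]
    edge <- idx[[ax]] + dir < 1L | idx[[ax]] + dir > d[ax]
    if (any(edge)) {
      sel <- lapply(d, seq_len)
      sel[[ax]] <- which(edge)
      nb[sel[[1]], sel[[2]], sel[[3]]] <- FALSE
    }
    nb
  }
  interior <- m
  for (ax in 1:3) for (dir in c(-1L, 1L)) interior <- interior & shift_bg(ax, dir)
  bnd <- which(m & !interior, arr.ind = TRUE)
  if (nrow(bnd) == 0L) bnd <- which(m, arr.ind = TRUE)
  sweep(bnd - 0.5, 2, spacing, `*`)
}

voxel_face_area <- function(mask, spacing) {
  d <- dim(mask)
  m <- array(0L, d)
  m[mask != 0] <- 1L
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  faces <- 0
  areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  for (ax in 1:3) {
    hi <- dim(pad)[ax]
    lo_idx <- lapply(dim(pad), seq_len)
    up_idx <- lo_idx
    lo_idx[[ax]] <- 1:(hi - 1)
    up_idx[[ax]] <- 2:hi
    diffc <- pad[lo_idx[[1]], lo_idx[[2]], lo_idx[[3]], drop = FALSE] !=
      pad[up_idx[[1]], up_idx[[2]], up_idx[[3]], drop = FALSE]
    faces <- faces + sum(diffc) * areas[ax]
  }
  faces
}

#' 3D shape (morphological) features of a binary ROI
#'
#' The 14 shape descriptors: mesh and voxel volume (mm^3), surface area
#' (mm^2), surface-to-volume ratio, sphericity, the largest pairwise
#' boundary-voxel distance in 3D and within axial/coronal/sagittal
#' planes, and the principal-axis lengths (4*sqrt(eigenvalue) of the
#' voxel-coordinate covariance) with elongation and flatness. A
#' single-slice ROI is treated as a slab one voxel thick.
#'
#' @param mask binary 3D array.
#' @param spacing voxel spacing in mm.
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing) {
  d <- dim(mask)
  n <- sum(mask != 0)
  if (n == 0L) .stop2("rimshrink_empty_roi_error", "shape: empty ROI")
  spacing <- as.numeric(spacing)
  voxvol <- n * prod(spacing)

  # mollified indicator, zero-padded so the isosurface closes
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(mask != 0)
  field <- cpp_gauss_blur(pad, dim(pad), c(0.8, 0.8, 0.8))
  av <- cpp_march_tets(field, dim(pad), spacing, 0.5)
  area <- av[1]
  meshvol <- av[2]
  if (!is.finite(area) || area <= 0 || meshvol <= 0 || n < 2) {
    area <- voxel_face_area(mask, spacing)
    meshvol <- voxvol
  }

  coords <- boundary_voxel_coords(mask, spacing)
  d3 <- cpp_max_pairwise(coords)
  plane_diam <- function(group_col, keep_cols) {
    g <- split.data.frame(coords[, keep_cols, drop = FALSE], coords[, group_col])
    max(vapply(g, function(p) cpp_max_pairwise(as.matrix(p)), numeric(1)))
  }
  d_ax <- plane_diam(3, 1:2)   # fixed z: in-plane x-y
  d_co <- plane_diam(2, c(1, 3))  # fixed y: x-z
  d_sa <- plane_diam(1, 2:3)   # fixed x: y-z

  all_xyz <- which(mask != 0, arr.ind = TRUE)
  phys <- sweep(all_xyz - 0.5, 2, spacing, `*`)
  if (n > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)

  c(mf_mesh_volume = meshvol,
    mf_voxel_volume = voxvol,
    mf_surface_area = area,
    mf_surface_volume_ratio = area / meshvol,
    mf_sphericity = (36 * pi * meshvol^2)^(1 / 3) / area,
    mf_max_3d_diameter = d3,
    mf_max_2d_diameter_axial = d_ax,
    mf_max_2d_diameter_coronal = d_co,
    mf_max_2d_diameter_sagittal = d_sa,
    mf_major_axis_length = axes[1],
    mf_minor_axis_length = axes[2],
    mf_least_axis_length = axes[3],
    mf_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    mf_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}
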