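test_that("window/level clamp follows the closed form and is identity inside", {
  expect_equal(apply_window(c(-400, 0, 100, 500), 40, 400),
               c(-160, 0, 100, 240))
  x <- seq(-150, 230, by = 10)
  expect_equal(apply_window(x, 40, 400), x)
})

test_that("nearest-neighbour resampling sizes by ceiling and matches the search oracle", {
  # identity when already at target spacing
  v <- array(rnorm(60), c(5, 4, 3))
  m <- array(rbinom(60, 1, 0.5), c(5, 4, 3))
  rs <- resample_nn(v, m, c(3, 3, 3), c(3, 3, 3))
  expect_identical(rs$values, v)

  # 60 voxels at 1 mm -> 20 voxels at 3 mm
  v2 <- array(rnorm(60 * 2 * 2), c(60, 2, 2))
  rs2 <- resample_nn(v2, NULL, c(1, 2, 2), c(3, 2, 2))
  expect_equal(dim(rs2$values)[1], 20)

  # per-voxel equality with the exhaustive nearest-centre oracle
  set.seed(21)
  vin <- array(rnorm(11 * 9 * 5), c(11, 9, 5))
  sp <- c(0.9, 1.4, 3.2)
  tg <- c(3, 3, 3)
  rs3 <- resample_nn(vin, NULL, sp, tg)
  dout <- dim(rs3$values)
  ix <- brute_resample_axis_index(11, sp[1], dout[1], tg[1])
  iy <- brute_resample_axis_index(9, sp[2], dout[2], tg[2])
  iz <- brute_resample_axis_index(5, sp[3], dout[3], tg[3])
  expect_identical(rs3$values, vin[ix, iy, iz, drop = FALSE])
})

test_that("fixed-bin-width discretization is min-anchored and shift invariant", {
  v <- array(0, c(3, 1, 1))
  v[] <- c(10, 34, 60)
  m <- array(1L, c(3, 1, 1))
  gl <- discretize(v, m, 25)
  expect_identical(as.vector(gl$levels), c(1L, 1L, 3L))
  expect_identical(gl$ng, 3L)

  gl2 <- discretize(v + 100, m, 25)
  expect_identical(gl2$levels, gl$levels)

  vc <- array(7.5, c(2, 2, 2))
  glc <- discretize(vc, array(1L, c(2, 2, 2)), 25)
  expect_true(all(glc$levels == 1L))
  expect_identical(glc$ng, 1L)
})

test_that("first-order features match hand arithmetic and an independent oracle", {
  f1 <- first_order_features(rep(5, 10), voxel_volume = 2)
  expect_equal(unname(f1[c("ff_mean", "ff_variance", "ff_entropy",
                           "ff_uniformity", "ff_skewness", "ff_kurtosis")]),
               c(5, 0, 0, 1, 0, 0))

  f2 <- first_order_features(c(0, 10), voxel_volume = 1)
  expect_equal(unname(f2[c("ff_mean", "ff_range", "ff_energy", "ff_rms")]),
               c(5, 10, 100, sqrt(50)))

  set.seed(13)
  x <- rnorm(200, 30, 20)
  f <- first_order_features(x, voxel_volume = 27, bin_width = 25)
  mu <- sum(x) / length(x)
  m2 <- sum((x - mu)^2) / length(x)
  lev <- floor((x - min(x)) / 25)
  p <- as.vector(table(lev)) / length(x)
  q <- quantile(x, c(.1, .25, .75, .9), type = 7)
  band <- x[x >= q[1] & x <= q[4]]
  expect_equal(f[["ff_energy"]], sum(x^2), tolerance = 1e-12)
  expect_equal(f[["ff_total_energy"]], 27 * sum(x^2), tolerance = 1e-12)
  expect_equal(f[["ff_entropy"]], -sum(p * log2(p)), tolerance = 1e-12)
  expect_equal(f[["ff_p10"]], unname(q[1]), tolerance = 1e-12)
  expect_equal(f[["ff_iqr"]], unname(q[3] - q[2]), tolerance = 1e-12)
  expect_equal(f[["ff_mad"]], mean(abs(x - mu)), tolerance = 1e-12)
  expect_equal(f[["ff_rmad"]], mean(abs(band - mean(band))), tolerance = 1e-12)
  expect_equal(f[["ff_skewness"]],
               mean((x - mu)^3) / m2^1.5, tolerance = 1e-12)
  expect_equal(f[["ff_kurtosis"]],
               mean((x - mu)^4) / m2^2, tolerance = 1e-12)
  expect_equal(f[["ff_uniformity"]], sum(p^2), tolerance = 1e-12)
})

test_that("shape features: exact voxel volume, near-unit ball sphericity, scaling laws", {
  cube <- array(0L, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- 1L
  sf <- shape_features(cube, c(1, 1, 1))
  expect_equal(sf[["mf_voxel_volume"]], 1000)

  ball <- ellipsoid_mask(c(56, 56, 56), c(1, 1, 1), c(25, 25, 25))
  sb <- shape_features(ball, c(1, 1, 1))
  expect_lt(abs(sb[["mf_sphericity"]] - 1), 0.05)
  expect_lt(abs(sb[["mf_max_3d_diameter"]] - 50), 2)
  # solid ball of radius R: coordinate variance R^2/5, axis length 4R/sqrt(5)
  expect_lt(abs(sb[["mf_major_axis_length"]] - 100 / sqrt(5)) / (100 / sqrt(5)), 0.05)

  # doubling the spacing: volume x8, surface x4, sphericity unchanged
  m <- ellipsoid_mask(c(24, 24, 24), c(1, 1, 1), c(8, 7, 6))
  s1 <- shape_features(m, c(1, 1, 1))
  s2 <- shape_features(m, c(2, 2, 2))
  expect_equal(s2[["mf_mesh_volume"]] / s1[["mf_mesh_volume"]], 8, tolerance = 1e-9)
  expect_equal(s2[["mf_surface_area"]] / s1[["mf_surface_area"]], 4, tolerance = 1e-9)
  expect_equal(s2[["mf_sphericity"]], s1[["mf_sphericity"]], tolerance = 1e-6)

  # single-voxel ROI falls back to the voxel closed forms
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  ss <- shape_features(single, c(2, 2, 3))
  expect_equal(ss[["mf_voxel_volume"]], 12)
  expect_equal(ss[["mf_mesh_volume"]], 12)
  expect_equal(ss[["mf_surface_area"]], 2 * (4 + 6 + 6))
})

test_that("constant ROIs give the degenerate texture limits", {
  v <- array(50, c(4, 4, 2))
  m <- array(1L, c(4, 4, 2))
  tf <- texture_features(discretize(v, m, 25))
  expect_equal(tf[["tf_glcm_contrast"]], 0)
  expect_equal(tf[["tf_glcm_correlation"]], 1)
  expect_equal(tf[["tf_ngtdm_coarseness"]], 1e6)
  expect_equal(tf[["tf_glszm_zp"]], 1 / 32)  # one zone of 32 voxels
})

test_that("run-length matrix on a 1D strip matches hand enumeration", {
  lev <- array(0L, c(5, 1, 1))
  lev[] <- c(1L, 1L, 2L, 2L, 2L)
  R <- array(rimshrink:::cpp_glrlm13(lev, dim(lev), 2L), c(2, 5, 13))
  Rx <- R[, , 1]  # direction (1,0,0)
  expect_equal(Rx[1, 2], 1)  # level 1, run length 2
  expect_equal(Rx[2, 3], 1)  # level 2, run length 3
  expect_equal(sum(Rx), 2)
})

test_that("texture matrices match naive neighbour-scan oracles", {
  set.seed(31)
  lev <- array(sample(0:4, 6 * 6 * 6, replace = TRUE, prob = c(.2, rep(.2, 4))),
               c(6, 6, 6))
  storage.mode(lev) <- "integer"
  ng <- 4L
  G <- array(rimshrink:::cpp_glcm13(lev, dim(lev), ng), c(ng, ng, 13))
  R <- array(rimshrink:::cpp_glrlm13(lev, dim(lev), ng), c(ng, 6, 13))
  for (d in 1:13) {
    expect_equal(G[, , d], glcm_oracle(lev, DIRS13[d, ], ng), info = paste("glcm dir", d))
    expect_equal(R[, , d], glrlm_oracle(lev, DIRS13[d, ], ng, 6), info = paste("glrlm dir", d))
  }
  zs <- rimshrink:::cpp_glszm_zones(lev, dim(lev))
  zo <- glszm_oracle(lev)
  expect_equal(sort(paste(zs[, 1], zs[, 2])), sort(paste(zo[, 1], zo[, 2])))
  expect_equal(rimshrink:::cpp_gldm(lev, dim(lev), ng, 0L),
               gldm_oracle(lev, ng), ignore_attr = TRUE)
  nt <- rimshrink:::cpp_ngtdm(lev, dim(lev), ng)
  no <- ngtdm_oracle(lev, ng)
  expect_equal(as.numeric(nt$n), no$n)
  expect_equal(as.numeric(nt$s), no$s, tolerance = 1e-12)
  expect_equal(nt$nvp, no$nvp)
})

test_that("all 72 texture features match an independently coded reference", {
  set.seed(37)
  for (rep in 1:3) {
    lev <- array(sample(0:5, 6 * 6 * 6, replace = TRUE), c(6, 6, 6))
    storage.mode(lev) <- "integer"
    if (all(lev == 0)) next
    gl <- structure(list(levels = lev, ng = max(lev), n_voxels = sum(lev != 0)),
                    class = "grey_level_roi")
    got <- texture_features(gl)
    want <- texture_oracle(lev, max(lev), sum(lev != 0))
    expect_equal(got[names(want)], want, tolerance = 1e-6)
  }
})

test_that("extraction returns 104 deterministic features partitioned 18/14/72", {
  cfg <- small_phantom_config()
  cs <- generate_case(cfg, "non_adenoma", 77)
  rois <- derive_rois(cs$mask_rater1, cs$volume$spacing, 3)
  reg <- feature_registry()
  expect_equal(unname(table(reg$class)[c("FF", "MF", "TF")]), c(18, 14, 72),
               ignore_attr = TRUE)
  for (m in c("MAX", "ALL_E")) {
    fv <- extract_features(cs$volume$values, rois$masks[[m]], cs$volume$spacing)
    expect_length(fv, 104)
    expect_identical(names(fv), reg$name)
    expect_true(all(is.finite(fv)))
  }
  fv1 <- extract_features(cs$volume$values, rois$masks$ALL, cs$volume$spacing)
  fv2 <- extract_features(cs$volume$values, rois$masks$ALL, cs$volume$spacing)
  expect_identical(fv1, fv2)
})

test_that("eroded single-slice ROI mean is closer to the true lesion mean under blur", {
  cfg <- small_phantom_config(psf_sigma_mm = 2)
  hits <- 0
  nrep <- 20
  for (s in seq_len(nrep)) {
    cs <- generate_case(cfg, "adenoma", 3000 + s)
    gt <- attr(cs, "ground_truth")
    rois <- tryCatch(derive_rois(cs$mask_rater1, cs$volume$spacing, 3),
                     rimshrink_empty_roi_error = function(e) NULL)
    if (is.null(rois)) next
    cfg_pp <- preprocess_config()
    f_max <- extract_features(cs$volume$values, rois$masks$MAX,
                              cs$volume$spacing, cfg_pp)
    f_maxe <- extract_features(cs$volume$values, rois$masks$MAX_E,
                               cs$volume$spacing, cfg_pp)
    if (abs(f_maxe[["ff_mean"]] - gt$true_mean) <
        abs(f_max[["ff_mean"]] - gt$true_mean)) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.9)
})
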