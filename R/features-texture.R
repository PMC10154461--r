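# Grey-level texture features over the discretized ROI.
# GLCM and GLRLM use distance 1 and the 13 unique 3D directions with
# symmetric co-occurrence; each feature is the unweighted mean over
# directions that contain at least one valid pair/run. GLSZM zones and
# GLDM dependences use 26-connectivity; NGTDM uses the 26-neighbourhood.
# Degenerate single-level ROIs yield the natural limits (zero contrast,
# capped coarseness), per the documented conventions.

glcm_features_one <- function(P) {
  s <- sum(P)
  p <- P / s
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  pd <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ps <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  da <- sum((0:(ng - 1)) * pd)
  hxy <- ent(p)
  pxy <- outer(px, px)
  nz <- p > 0 & pxy > 0
  hxy1 <- -sum(p[nz] * log2(pxy[nz]))
  hxy2 <- ent(pxy)
  hx <- ent(px)
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  offd <- abs(i - j) > 0
  c(autocorrelation = sum(i * j * p),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = ent(pd),
    difference_variance = sum(((0:(ng - 1)) - da)^2 * pd),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    id = sum(p / (1 + abs(i - j))),
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + ((i - j) / ng)^2)),
    idn = sum(p / (1 + abs(i - j) / ng)),
    inverse_variance = sum(p[offd] / (i[offd] - j[offd])^2),
    max_probability = max(p),
    sum_entropy = ent(ps))
}

# shared formula family for run-length / size-zone style matrices:
# P is levels x sizes, np the ROI voxel count
rl_family <- function(P, np, prefix, names16) {
  nz <- sum(P)
  p <- P / nz
  i <- row(P); r <- col(P)
  mi <- sum(p * i); mr <- sum(p * r)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  vals <- c(sum(P / r^2) / nz,
            sum(P * r^2) / nz,
            sum(rowSums(P)^2) / nz,
            sum(rowSums(P)^2) / nz^2,
            sum(colSums(P)^2) / nz,
            sum(colSums(P)^2) / nz^2,
            nz / np,
            sum(p * (i - mi)^2),
            sum(p * (r - mr)^2),
            ent(p),
            sum(P / i^2) / nz,
            sum(P * i^2) / nz,
            sum(P / (i^2 * r^2)) / nz,
            sum(P * i^2 / r^2) / nz,
            sum(P * r^2 / i^2) / nz,
            sum(P * i^2 * r^2) / nz)
  setNames(vals, paste0(prefix, names16))
}

ngtdm_features_one <- function(nvec, svec, nvp, ng) {
  act <- which(nvec > 0)
  pi_ <- nvec / nvp
  coarse_den <- sum(pi_ * svec)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6  # capped maximum
  ngp <- length(act)
  if (ngp > 1) {
    pr <- outer(pi_[act], pi_[act])
    dif <- outer(act, act, `-`)
    contrast <- sum(pr * dif^2) / (ngp * (ngp - 1)) * sum(svec) / nvp
    bus_den <- sum(abs(outer(act * pi_[act], act * pi_[act], `-`)))
    busyness <- if (bus_den > 0) sum(pi_ * svec) / bus_den else 0
    psum <- outer(pi_[act], pi_[act], `+`)
    snum <- outer(pi_[act] * svec[act], pi_[act] * svec[act], `+`)
    complexity <- sum(abs(dif) * snum / psum) / nvp
    strength <- if (sum(svec) > 0) sum(psum * dif^2) / sum(svec) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(tf_ngtdm_coarseness = coarseness, tf_ngtdm_contrast = contrast,
    tf_ngtdm_busyness = busyness, tf_ngtdm_complexity = complexity,
    tf_ngtdm_strength = strength)
}

#' Grey-level texture features
#'
#' Computes the 72 texture features from the five grey-level matrix
#' families: co-occurrence (GLCM, 21), run length (GLRLM, 16), size zone
#' (GLSZM, 16), dependence (GLDM, 14) and neighbourhood grey-tone
#' difference (NGTDM, 5). See the package vignette for the matrix and
#' averaging conventions.
#'
#' @param gl a `grey_level_roi` from [discretize()].
#' @param gldm_alpha dependence similarity tolerance in grey levels.
#' @return Named numeric vector of 72 features.
#' @export
texture_features <- function(gl, gldm_alpha = 0L) {
  stopifnot(inherits(gl, "grey_level_roi"))
  lev <- gl$levels
  ng <- gl$ng
  dims <- dim(lev)
  np <- gl$n_voxels

  # ---- GLCM: mean over directions with at least one pair
  Pall <- array(cpp_glcm13(as.integer(lev), dims, ng), c(ng, ng, 13))
  acc <- NULL
  nd <- 0
  for (d in 1:13) {
    Pd <- Pall[, , d, drop = TRUE]
    Pd <- matrix(Pd, ng, ng)
    if (sum(Pd) == 0) next
    f <- glcm_features_one(Pd)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  glcm <- if (nd > 0) acc / nd else
    setNames(numeric(21), names(glcm_features_one(matrix(1, 1, 1))))
  names(glcm) <- paste0("tf_glcm_", names(glcm))

  # ---- GLRLM
  maxlen <- max(dims)
  Rall <- array(cpp_glrlm13(as.integer(lev), dims, ng), c(ng, maxlen, 13))
  rl_names <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                "rv", "re", "lglre", "hglre", "srlgle", "srhgle",
                "lrlgle", "lrhgle")
  acc <- NULL
  nd <- 0
  for (d in 1:13) {
    Rd <- matrix(Rall[, , d, drop = TRUE], ng, maxlen)
    if (sum(Rd) == 0) next
    f <- rl_family(Rd, np, "tf_glrlm_", rl_names)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  glrlm <- acc / nd   # every direction has at least one run when ROI non-empty

  # ---- GLSZM
  zones <- cpp_glszm_zones(as.integer(lev), dims)
  maxz <- max(zones[, 2])
  Z <- matrix(0, ng, maxz)
  for (t in seq_len(nrow(zones))) Z[zones[t, 1], zones[t, 2]] <-
      Z[zones[t, 1], zones[t, 2]] + 1
  sz_names <- c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
                "zv", "ze", "lglze", "hglze", "salgle", "sahgle",
                "lalgle", "lahgle")
  glszm <- rl_family(Z, np, "tf_glszm_", sz_names)

  # ---- GLDM (dependence size = dependent 26-neighbours + 1, so >= 1;
  # cpp_gldm column c holds counts for c - 1 dependent neighbours)
  D <- cpp_gldm(as.integer(lev), dims, ng, as.integer(gldm_alpha))
  nzd <- sum(D)
  pD <- D / nzd
  iD <- row(D); jD <- col(D)
  miD <- sum(pD * iD); mjD <- sum(pD * jD)
  entD <- { q <- pD[pD > 0]; -sum(q * log2(q)) }
  gldm <- c(tf_gldm_sde = sum(D / jD^2) / nzd,
            tf_gldm_lde = sum(D * jD^2) / nzd,
            tf_gldm_gln = sum(rowSums(D)^2) / nzd,
            tf_gldm_dn = sum(colSums(D)^2) / nzd,
            tf_gldm_dnn = sum(colSums(D)^2) / nzd^2,
            tf_gldm_glv = sum(pD * (iD - miD)^2),
            tf_gldm_dv = sum(pD * (jD - mjD)^2),
            tf_gldm_de = entD,
            tf_gldm_lgle = sum(D / iD^2) / nzd,
            tf_gldm_hgle = sum(D * iD^2) / nzd,
            tf_gldm_sdlgle = sum(D / (iD^2 * jD^2)) / nzd,
            tf_gldm_sdhgle = sum(D * iD^2 / jD^2) / nzd,
            tf_gldm_ldlgle = sum(D * jD^2 / iD^2) / nzd,
            tf_gldm_ldhgle = sum(D * iD^2 * jD^2) / nzd)

  # ---- NGTDM
  ngt <- cpp_ngtdm(as.integer(lev), dims, ng)
  ngtdm <- if (ngt$nvp > 0)
    ngtdm_features_one(ngt$n, ngt$s, ngt$nvp, ng)
  else c(tf_ngtdm_coarseness = 1e6, tf_ngtdm_contrast = 0,
         tf_ngtdm_busyness = 0, tf_ngtdm_complexity = 0, tf_ngtdm_strength = 0)

  c(glcm, glrlm, glszm, gldm, ngtdm)
}
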