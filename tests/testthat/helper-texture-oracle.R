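# independent texture feature formulas, written with explicit scalar
# loops over matrix entries (no shared code with the package internals)

DIRS13 <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
                c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))

glcm_features_oracle <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  f <- numeric(21)
  names(f) <- c("autocorrelation", "joint_average", "cluster_prominence",
                "cluster_shade", "cluster_tendency", "contrast", "correlation",
                "difference_average", "difference_entropy", "difference_variance",
                "joint_energy", "joint_entropy", "imc1", "imc2", "id", "idm",
                "idmn", "idn", "inverse_variance", "max_probability", "sum_entropy")
  px <- rowSums(p)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  s2 <- 0
  for (i in 1:ng) s2 <- s2 + (i - mu)^2 * px[i]
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j] <- ps[i + j] + p[i, j]
  }
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    f["autocorrelation"] <- f["autocorrelation"] + i * j * v
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - 2 * mu)^4 * v
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - 2 * mu)^3 * v
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - 2 * mu)^2 * v
    f["contrast"] <- f["contrast"] + (i - j)^2 * v
    f["joint_energy"] <- f["joint_energy"] + v^2
    f["id"] <- f["id"] + v / (1 + abs(i - j))
    f["idm"] <- f["idm"] + v / (1 + (i - j)^2)
    f["idmn"] <- f["idmn"] + v / (1 + ((i - j) / ng)^2)
    f["idn"] <- f["idn"] + v / (1 + abs(i - j) / ng)
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] + v / (i - j)^2
  }
  f["joint_average"] <- mu
  f["correlation"] <- if (s2 > 0) (f[["autocorrelation"]] - mu^2) / s2 else 1
  da <- 0
  for (k in 1:ng) da <- da + (k - 1) * pd[k]
  f["difference_average"] <- da
  dv <- 0
  for (k in 1:ng) dv <- dv + (k - 1 - da)^2 * pd[k]
  f["difference_variance"] <- dv
  f["difference_entropy"] <- H(pd)
  f["sum_entropy"] <- H(ps)
  f["joint_entropy"] <- H(p)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (p[i, j] > 0 && q > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
    if (q > 0) hxy2 <- hxy2 - q * log2(q)
  }
  hx <- H(px)
  f["imc1"] <- if (hx > 0) (f[["joint_entropy"]] - hxy1) / hx else 0
  f["imc2"] <- if (hxy2 >= f[["joint_entropy"]])
    sqrt(1 - exp(-2 * (hxy2 - f[["joint_entropy"]]))) else 0
  f["max_probability"] <- max(p)
  f
}

rl_features_oracle <- function(P, np) {
  nz <- sum(P)
  ng <- nrow(P); nr <- ncol(P)
  f <- numeric(16)
  names(f) <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                "rv", "re", "lglre", "hglre", "srlgle", "srhgle",
                "lrlgle", "lrhgle")
  for (i in 1:ng) for (r in 1:nr) {
    v <- P[i, r]
    f["sre"] <- f["sre"] + v / r^2
    f["lre"] <- f["lre"] + v * r^2
    f["lglre"] <- f["lglre"] + v / i^2
    f["hglre"] <- f["hglre"] + v * i^2
    f["srlgle"] <- f["srlgle"] + v / (i * r)^2
    f["srhgle"] <- f["srhgle"] + v * i^2 / r^2
    f["lrlgle"] <- f["lrlgle"] + v * r^2 / i^2
    f["lrhgle"] <- f["lrhgle"] + v * (i * r)^2
  }
  for (i in 1:ng) f["gln"] <- f["gln"] + sum(P[i, ])^2
  for (r in 1:nr) f["rln"] <- f["rln"] + sum(P[, r])^2
  f[c("sre", "lre", "gln", "rln", "lglre", "hglre",
      "srlgle", "srhgle", "lrlgle", "lrhgle")] <-
    f[c("sre", "lre", "gln", "rln", "lglre", "hglre",
        "srlgle", "srhgle", "lrlgle", "lrhgle")] / nz
  f["glnn"] <- f[["gln"]] / nz
  f["rlnn"] <- f[["rln"]] / nz
  f["rp"] <- nz / np
  p <- P / nz
  mi <- 0; mr <- 0
  for (i in 1:ng) for (r in 1:nr) { mi <- mi + i * p[i, r]; mr <- mr + r * p[i, r] }
  for (i in 1:ng) for (r in 1:nr) {
    f["glv"] <- f["glv"] + p[i, r] * (i - mi)^2
    f["rv"] <- f["rv"] + p[i, r] * (r - mr)^2
  }
  q <- p[p > 0]
  f["re"] <- -sum(q * log2(q))
  f
}

# full 72-feature oracle from the naive matrices
texture_oracle <- function(lev, ng, np) {
  maxlen <- max(dim(lev))
  glcm_acc <- NULL; nd <- 0
  glrlm_acc <- NULL; nr <- 0
  for (d in seq_len(nrow(DIRS13))) {
    P <- glcm_oracle(lev, DIRS13[d, ], ng)
    if (sum(P) > 0) {
      v <- glcm_features_oracle(P)
      glcm_acc <- if (is.null(glcm_acc)) v else glcm_acc + v
      nd <- nd + 1
    }
    R <- glrlm_oracle(lev, DIRS13[d, ], ng, maxlen)
    if (sum(R) > 0) {
      v <- rl_features_oracle(R, np)
      glrlm_acc <- if (is.null(glrlm_acc)) v else glrlm_acc + v
      nr <- nr + 1
    }
  }
  glcm <- glcm_acc / nd
  names(glcm) <- paste0("tf_glcm_", names(glcm))
  glrlm <- glrlm_acc / nr
  names(glrlm) <- paste0("tf_glrlm_", names(glrlm))

  zs <- glszm_oracle(lev)
  Z <- matrix(0, ng, max(zs[, 2]))
  for (t in seq_len(nrow(zs))) Z[zs[t, 1], zs[t, 2]] <- Z[zs[t, 1], zs[t, 2]] + 1
  glszm <- rl_features_oracle(Z, np)
  names(glszm) <- paste0("tf_glszm_", c("sae", "lae", "gln", "glnn", "szn",
                                        "sznn", "zp", "glv", "zv", "ze",
                                        "lglze", "hglze", "salgle", "sahgle",
                                        "lalgle", "lahgle"))

  D <- gldm_oracle(lev, ng)
  nzd <- sum(D)
  pD <- D / nzd
  g <- c(sde = 0, lde = 0, gln = 0, dn = 0, dnn = 0, glv = 0, dv = 0, de = 0,
         lgle = 0, hgle = 0, sdlgle = 0, sdhgle = 0, ldlgle = 0, ldhgle = 0)
  mi <- 0; mj <- 0
  for (i in 1:ng) for (j in 1:27) { mi <- mi + i * pD[i, j]; mj <- mj + j * pD[i, j] }
  for (i in 1:ng) for (j in 1:27) {
    v <- D[i, j]
    g["sde"] <- g["sde"] + v / j^2
    g["lde"] <- g["lde"] + v * j^2
    g["lgle"] <- g["lgle"] + v / i^2
    g["hgle"] <- g["hgle"] + v * i^2
    g["sdlgle"] <- g["sdlgle"] + v / (i * j)^2
    g["sdhgle"] <- g["sdhgle"] + v * i^2 / j^2
    g["ldlgle"] <- g["ldlgle"] + v * j^2 / i^2
    g["ldhgle"] <- g["ldhgle"] + v * (i * j)^2
    g["glv"] <- g["glv"] + pD[i, j] * (i - mi)^2
    g["dv"] <- g["dv"] + pD[i, j] * (j - mj)^2
  }
  for (i in 1:ng) g["gln"] <- g["gln"] + sum(D[i, ])^2
  for (j in 1:27) g["dn"] <- g["dn"] + sum(D[, j])^2
  g[c("sde", "lde", "gln", "dn", "lgle", "hgle", "sdlgle", "sdhgle",
      "ldlgle", "ldhgle")] <-
    g[c("sde", "lde", "gln", "dn", "lgle", "hgle", "sdlgle", "sdhgle",
        "ldlgle", "ldhgle")] / nzd
  g["dnn"] <- g[["dn"]] / nzd
  q <- pD[pD > 0]
  g["de"] <- -sum(q * log2(q))
  names(g) <- paste0("tf_gldm_", names(g))

  nt <- ngtdm_oracle(lev, ng)
  pi_ <- nt$n / nt$nvp
  act <- which(nt$n > 0)
  ngp <- length(act)
  den <- sum(pi_ * nt$s)
  coarse <- if (den > 0) 1 / den else 1e6
  if (ngp > 1) {
    ctr <- 0; bden <- 0; cplx <- 0; str_num <- 0
    for (i in act) for (j in act) {
      ctr <- ctr + pi_[i] * pi_[j] * (i - j)^2
      bden <- bden + abs(i * pi_[i] - j * pi_[j])
      cplx <- cplx + abs(i - j) * (pi_[i] * nt$s[i] + pi_[j] * nt$s[j]) /
        (pi_[i] + pi_[j])
      str_num <- str_num + (pi_[i] + pi_[j]) * (i - j)^2
    }
    contrast <- ctr / (ngp * (ngp - 1)) * sum(nt$s) / nt$nvp
    busy <- if (bden > 0) sum(pi_ * nt$s) / bden else 0
    cplx <- cplx / nt$nvp
    strength <- if (sum(nt$s) > 0) str_num / sum(nt$s) else 0
  } else { contrast <- 0; busy <- 0; cplx <- 0; strength <- 0 }
  ngtdm <- c(tf_ngtdm_coarseness = coarse, tf_ngtdm_contrast = contrast,
             tf_ngtdm_busyness = busy, tf_ngtdm_complexity = cplx,
             tf_ngtdm_strength = strength)

  c(glcm, glrlm, glszm, g, ngtdm)
}
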