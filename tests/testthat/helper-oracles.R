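# independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths

# erosion oracle: scans every background voxel for every foreground voxel
brute_erode <- function(mask, spacing, radius_mm, mode) {
  d <- dim(mask)
  out <- array(0L, d)
  fg <- which(mask == 1, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  for (t in seq_len(nrow(fg))) {
    v <- fg[t, ]
    b <- if (mode == "in_plane_2d") bg[bg[, 3] == v[3], , drop = FALSE] else bg
    if (nrow(b) == 0) { out[v[1], v[2], v[3]] <- 1L; next }
    dx <- sweep(b, 2, v)
    d2 <- (dx[, 1] * spacing[1])^2 + (dx[, 2] * spacing[2])^2 +
      (dx[, 3] * spacing[3])^2
    if (min(d2) > radius_mm^2) out[v[1], v[2], v[3]] <- 1L
  }
  out
}

# nearest-centre resampling oracle: exhaustive search per output voxel,
# ties to the smaller input index
brute_resample_axis_index <- function(n_in, s_in, n_out, s_out) {
  centres_in <- (seq_len(n_in) - 0.5) * s_in
  vapply(seq_len(n_out), function(j) {
    c_out <- (j - 0.5) * s_out
    which.min(round(abs(centres_in - c_out), 12))
  }, integer(1))
}

# ICC(2,1) via explicit variance-component sums of squares
icc_oracle <- function(y1, y2) {
  x <- cbind(y1, y2)
  n <- nrow(x); k <- 2
  gm <- mean(x)
  ssr <- k * sum((rowMeans(x) - gm)^2)
  ssc <- n * sum((colMeans(x) - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# pAUC oracle for tie-free scores: dense-grid trapezoid over the
# empirical ROC staircase built by direct threshold counting; the grid
# is augmented with the exact step locations so the area is exact
pauc_grid_oracle <- function(scores, labels, fmax, ngrid = 10001) {
  stopifnot(!anyDuplicated(scores))
  y <- labels == "adenoma"
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), 1)
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), 1)
  sup_tpr <- c(0, cummax(tpr))   # staircase: best tpr at fpr <= f
  fpr_k <- c(0, fpr)
  xs <- sort(unique(c(seq(0, fmax, length.out = ngrid), fpr_k[fpr_k <= fmax], fmax)))
  mid <- (xs[-1] + xs[-length(xs)]) / 2
  yv <- sup_tpr[findInterval(mid, fpr_k)]
  sum(diff(xs) * yv)   # exact: the staircase is constant between breakpoints
}

# grey-level co-occurrence oracle for one direction: voxel-pair scan
glcm_oracle <- function(lev, dir, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- lev[i, j, k]
    if (a == 0) next
    ii <- i + dir[1]; jj <- j + dir[2]; kk <- k + dir[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    b <- lev[ii, jj, kk]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

# run-length oracle for one direction: walks every maximal line
glrlm_oracle <- function(lev, dir, ng, maxlen) {
  d <- dim(lev)
  P <- matrix(0, ng, maxlen)
  inb <- function(v) all(v >= 1) && all(v <= d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (inb(c(i, j, k) - dir)) next
    v <- c(i, j, k)
    vals <- integer()
    while (inb(v)) { vals <- c(vals, lev[v[1], v[2], v[3]]); v <- v + dir }
    r <- rle(vals)
    for (t in seq_along(r$values))
      if (r$values[t] != 0)
        P[r$values[t], r$lengths[t]] <- P[r$values[t], r$lengths[t]] + 1
  }
  P
}

# 26-connected zone sizes per grey level, by repeated flood fill in R
glszm_oracle <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (s in which(lev != 0 & !seen)) {
    if (seen[s]) next
    g <- lev[s]
    stack <- s
    seen[s] <- TRUE
    size <- 0
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1
      ijk <- arrayInd(c0, d)
      for (t in seq_len(nrow(nb))) {
        v <- ijk + nb[t, ]
        if (any(v < 1) || any(v > d)) next
        q <- v[1] + d[1] * (v[2] - 1 + d[2] * (v[3] - 1))
        if (!seen[q] && lev[q] == g) { seen[q] <- TRUE; stack <- c(stack, q) }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)
}

# dependence counts per voxel (alpha = 0), neighbour scan in R
gldm_oracle <- function(lev, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, 27)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- lev[i, j, k]
    if (a == 0) next
    dep <- 0
    for (t in seq_len(nrow(nb))) {
      v <- c(i, j, k) + nb[t, ]
      if (any(v < 1) || any(v > d)) next
      if (lev[v[1], v[2], v[3]] == a) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  P
}

# NGTDM accumulators by direct neighbourhood averaging in R
ngtdm_oracle <- function(lev, ng) {
  d <- dim(lev)
  nvec <- numeric(ng); svec <- numeric(ng); nvp <- 0
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- lev[i, j, k]
    if (a == 0) next
    vals <- integer()
    for (t in seq_len(nrow(nb))) {
      v <- c(i, j, k) + nb[t, ]
      if (any(v < 1) || any(v > d)) next
      b <- lev[v[1], v[2], v[3]]
      if (b != 0) vals <- c(vals, b)
    }
    if (length(vals)) {
      nvec[a] <- nvec[a] + 1
      svec[a] <- svec[a] + abs(a - mean(vals))
      nvp <- nvp + 1
    }
  }
  list(n = nvec, s = svec, nvp = nvp)
}

# exact Mann-Whitney P by full enumeration of group assignments
mw_exact_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pool <- c(x, y)
  u_obs <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(n, nx)
  u_all <- apply(combs, 2, function(idx)
    sum(rank(pool)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact Wilcoxon signed-rank P by sign enumeration (no ties/zeros)
wsr_exact_oracle <- function(a, b) {
  dif <- a - b
  dif <- dif[dif != 0]
  n <- length(dif)
  r <- rank(abs(dif))
  w_obs <- sum(r[dif > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
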