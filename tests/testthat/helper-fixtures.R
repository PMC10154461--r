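# shared fixture builders: all fixtures are generated in code

# digital ellipsoid mask on an (nx, ny, nz) grid; semi-axes and centre in mm
ellipsoid_mask <- function(dims, spacing, semi_mm, centre_mm = dims * spacing / 2) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  q <- outer(outer(((cx - centre_mm[1]) / semi_mm[1])^2,
                   ((cy - centre_mm[2]) / semi_mm[2])^2, `+`),
             ((cz - centre_mm[3]) / semi_mm[3])^2, `+`)
  m <- array(0L, dims)
  m[q <= 1] <- 1L
  m
}

# random connected-ish blob: union of a few random balls
random_blob <- function(dims, spacing, n_balls = 3, r_range = c(2, 5)) {
  m <- array(0L, dims)
  ctr0 <- dims * spacing / 2
  for (b in seq_len(n_balls)) {
    r <- runif(1, r_range[1], r_range[2])
    ctr <- ctr0 + runif(3, -0.2, 0.2) * dims * spacing
    m <- m | ellipsoid_mask(dims, spacing, rep(r, 3), ctr)
  }
  out <- array(0L, dims)
  out[m] <- 1L
  out
}

# tiny deterministic phantom config for fast unit tests: small grid with
# correspondingly small lesions
small_phantom_config <- function(dim = c(40, 40, 12), ...) {
  cfg <- phantom_config(dim = dim, spacing = c(1, 1, 3.75), ...)
  for (cl in names(cfg$classes)) {
    cfg$classes[[cl]]$diam_mean <- 18
    cfg$classes[[cl]]$diam_sd <- 2
    cfg$classes[[cl]]$diam_limits <- c(14, 24)
  }
  cfg
}

# random two-class feature table with a few informative columns planted
synthetic_feature_table <- function(n_per_class, n_features = 104,
                                    informative = 3, effect = 1.5) {
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * n_features), n, n_features)
  labels <- rep(c("adenoma", "non_adenoma"), each = n_per_class)
  planted <- seq_len(informative)
  x[labels == "adenoma", planted] <- x[labels == "adenoma", planted] + effect
  colnames(x) <- sprintf("feat%03d", seq_len(n_features))
  list(x = as.data.frame(x), labels = labels,
       planted = colnames(x)[planted])
}
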