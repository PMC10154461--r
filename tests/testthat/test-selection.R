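test_that("ICC(2,1) reproduces the mean-squares definition", {
  expect_equal(icc_2_1(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # absolute agreement penalizes a constant shift
  expect_lt(icc_2_1(c(1, 2, 3, 4), c(2, 3, 4, 5)), 1)

  y1 <- c(9, 6, 8, 7, 10, 6)
  y2 <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc_2_1(y1, y2), icc_oracle(y1, y2), tolerance = 1e-9)

  expect_error(icc_2_1(rep(3, 5), c(rep(3, 4), 3)), NA)
  expect_equal(icc_2_1(rep(3, 5), rep(3, 5)), 1)
})

test_that("stability filter retains agreeing features and drops noisy ones", {
  set.seed(41)
  reg <- feature_registry()
  n <- 20
  base <- matrix(rnorm(n * 104), n)
  colnames(base) <- reg$name
  t1 <- data.frame(case_id = sprintf("c%02d", 1:n), roi_method = "ALL",
                   base, check.names = FALSE)
  t2 <- t1
  rep_ <- stability_filter(t1, t2)
  expect_true(all(rep_$retained))
  expect_equal(attr(rep_, "n_cases"), n)

  t2b <- t1
  t2b$ff_mean <- rnorm(n)   # rater 2 sees pure noise for one feature
  rep2 <- stability_filter(t1, t2b)
  expect_false(rep2$retained[rep2$feature == "ff_mean"])
  expect_equal(sum(!rep2$retained), 1)

  t2c <- t1
  for (nm in reg$name) t2c[[nm]] <- t2c[[nm]] + rnorm(n, 0, 0.05)
  rep3 <- stability_filter(t1, t2c, threshold = 1.0)
  expect_true(all(!rep3$retained))
})

test_that("univariate rank filter keeps separated features, drops constants, matches exact P", {
  set.seed(43)
  x <- data.frame(sep = c(rnorm(50), rnorm(50, 3)),
                  flat = rep(1, 100),
                  noise = rnorm(100))
  labels <- rep(c("adenoma", "non_adenoma"), each = 50)
  uni <- univariate_filter(x, labels)
  expect_true(uni$retained[uni$feature == "sep"])
  expect_false(uni$retained[uni$feature == "flat"])
  expect_equal(uni$p[uni$feature == "flat"], 1)

  # identical distribution in both groups: same values -> P = 1 territory
  x2 <- data.frame(f = rep(c(1, 2, 3, 4), 2))
  l2 <- rep(c("adenoma", "non_adenoma"), each = 4)
  uni2 <- univariate_filter(x2, l2)
  expect_false(uni2$retained)

  # small-sample agreement with the exact-enumeration U oracle
  set.seed(44)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(4, 1)
    p_pkg <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(p_pkg, mw_exact_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("RFE retains ceil(30%) and keeps a perfectly separating feature", {
  set.seed(47)
  n <- 60
  x <- as.data.frame(matrix(rnorm(n * 20), n))
  names(x) <- sprintf("f%02d", 1:20)
  labels <- rep(c("adenoma", "non_adenoma"), each = n / 2)
  surv <- rfe_select(x, labels, keep_frac = 0.30)
  expect_length(surv, 6)  # ceil(0.3 * 20)

  x$sep <- ifelse(labels == "adenoma", 1, -1) + rnorm(n, 0, 0.05)
  x10 <- x[c(sprintf("f%02d", 1:9), "sep")]
  surv2 <- rfe_select(x10, labels, keep_frac = 0.10)
  expect_identical(surv2, "sep")
  expect_identical(rfe_select(x10, labels, 0.10), surv2)  # deterministic
})

test_that("LASSO 1-SE keeps the informative feature and zeroes noise", {
  set.seed(53)
  n <- 200
  x <- as.data.frame(matrix(rnorm(n * 11), n))
  names(x) <- c("inf", sprintf("n%02d", 1:10))
  labels <- rep(c("adenoma", "non_adenoma"), each = n / 2)
  x$inf <- x$inf + ifelse(labels == "adenoma", 3, 0)
  las <- lasso_1se(x, labels, folds = 10, seed = 5)
  expect_true("inf" %in% las$survivors)
  expect_gte(sum(las$coefficients[sprintf("n%02d", 1:10)] == 0), 8)

  # duplicating every row leaves the chosen-lambda survivors unchanged
  las2 <- lasso_1se(rbind(x, x), c(labels, labels), folds = 10, seed = 5)
  expect_identical(sort(las2$survivors), sort(las$survivors))

  x$flat <- 0
  las3 <- lasso_1se(x, labels, folds = 10, seed = 5)
  expect_equal(unname(las3$coefficients["flat"]), 0)
})

test_that("logistic signature scores follow the closed form and store training scores", {
  set.seed(59)
  n <- 120
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  labels <- ifelse(plogis(1.2 * x$a) > runif(n), "adenoma", "non_adenoma")
  if (length(unique(labels)) < 2) labels[1:2] <- c("adenoma", "non_adenoma")
  mod <- radiomics_signature(x, labels)
  sc <- predict(mod, x, type = "score")
  expect_equal(sc, mod$train_scores)
  expect_equal(predict(mod, x, type = "prob"), plogis(sc))

  # hand-built model: intercept 0, coefficient 1, standardized feature 2
  mod2 <- mod
  mod2$intercept <- 0
  mod2$coefficients <- c(a = 1, b = 0)
  nd <- data.frame(a = mod$centre["a"] + 2 * mod$scale["a"], b = 0)
  expect_equal(unname(predict(mod2, nd, type = "score")), 2)
  expect_equal(unname(predict(mod2, nd, type = "prob")), 1 / (1 + exp(-2)))
})

test_that("balanced symmetric problem fits a near-zero intercept", {
  set.seed(61)
  n <- 400
  x <- data.frame(f = c(rnorm(n / 2, -1), rnorm(n / 2, 1)))
  labels <- rep(c("non_adenoma", "adenoma"), each = n / 2)
  mod <- radiomics_signature(x, labels)
  expect_lt(abs(mod$intercept), 0.35)
})

test_that("stratified 8:2 split reproduces the 189/48 sizes and is seed-stable", {
  labels <- rep(c("adenoma", "non_adenoma"), c(135, 102))
  sp <- split_train_val(labels, 0.8, seed = 3)
  expect_length(sp$train, 189)
  expect_length(sp$val, 48)
  expect_setequal(c(sp$train, sp$val), seq_along(labels))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(split_train_val(labels, 0.8, seed = 3), sp)
  # stratification: class proportions preserved within one case
  expect_lt(abs(mean(labels[sp$train] == "adenoma") - 135 / 237), 0.01)
})

test_that("selection cascade yields nested survivor sets on planted data", {
  set.seed(67)
  syn <- synthetic_feature_table(60, 104, informative = 3, effect = 2)
  tr <- selection_cascade(syn$x, syn$labels, seed = 1)
  expect_true(all(tr$univariate %in% tr$stable))
  expect_true(all(tr$rfe %in% tr$univariate))
  expect_true(all(tr$lasso %in% tr$rfe))
  expect_gt(length(tr$lasso), 0)
  expect_gte(sum(syn$planted %in% tr$lasso), 2)
})
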