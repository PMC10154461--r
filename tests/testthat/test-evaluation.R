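test_that("rank AUC handles separation, the worked example, and ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c("non_adenoma", "non_adenoma",
                                             "non_adenoma", "adenoma", "adenoma"))$auc, 1)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8),
               c("non_adenoma", "non_adenoma", "adenoma", "adenoma"))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("adenoma", "non_adenoma"), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep("adenoma", 4)), class = "rimshrink_class_error")
})

test_that("AUC and DeLong CI agree with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (rep in 1:5) {
    sc <- c(rnorm(30), rnorm(25, 0.8))
    lb <- rep(c("non_adenoma", "adenoma"), c(30, 25))
    r <- roc_auc(sc, lb)
    pr <- pROC::roc(response = lb, predictor = sc, levels = c("non_adenoma", "adenoma"),
                    direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$ci, ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("pAUC at >= 95% specificity: closed forms and dense-grid oracle", {
  lb <- rep(c("non_adenoma", "adenoma"), each = 20)
  perfect <- c(rnorm(20, 0), rnorm(20, 100))
  expect_equal(unname(pauc_high_spec(perfect, lb, boot = 0)$pauc), 0.05)
  tied <- rep(1, 40)
  expect_equal(pauc_high_spec(tied, lb, boot = 0)$pauc, 0.05^2 / 2)

  set.seed(73)
  sc <- c(rnorm(30), rnorm(30, 1))
  lb2 <- rep(c("non_adenoma", "adenoma"), each = 30)
  expect_equal(pauc_high_spec(sc, lb2, boot = 0)$pauc,
               pauc_grid_oracle(sc, lb2, 0.05), tolerance = 1e-9)

  # integrating over the full FPR range reproduces the AUC
  expect_equal(rimshrink:::pauc_from_points(rimshrink:::roc_points(sc, lb2), 1),
               roc_auc(sc, lb2)$auc, tolerance = 1e-12)

  # bootstrap CI is seeded-reproducible and contains the estimate
  p1 <- pauc_high_spec(sc, lb2, boot = 200, seed = 9)
  p2 <- pauc_high_spec(sc, lb2, boot = 200, seed = 9)
  expect_identical(p1$ci, p2$ci)
})

test_that("operating points: policies, tie-breaks, and threshold scan oracle", {
  lb <- rep(c("non_adenoma", "adenoma"), c(3, 2))
  op <- operating_point(c(1, 2, 3, 4, 5), lb, "spec95")
  expect_equal(op$sens, 1)
  expect_equal(op$spec, 1)
  expect_gt(op$threshold, 3)

  perfect <- operating_point(c(1, 1, 2, 9, 9), lb, "youden")
  expect_equal(c(perfect$sens, perfect$spec, perfect$acc), c(1, 1, 1))

  set.seed(79)
  for (rep in 1:5) {
    sc <- round(rnorm(40), 1)
    lbs <- sample(rep(c("adenoma", "non_adenoma"), 20))
    op <- operating_point(sc, lbs, "youden")
    y <- lbs == "adenoma"
    cand <- c(sort(unique(sc)), Inf)
    j <- vapply(cand, function(t) mean(sc[y] >= t) + mean(sc[!y] < t) - 1, 1)
    sp <- vapply(cand, function(t) mean(sc[!y] < t), 1)
    best <- which(abs(j - max(j)) < 1e-12)
    best <- best[which.max(sp[best])]
    expect_equal(op$threshold, cand[best])
    expect_equal(op$sens + op$spec - 1, max(j), tolerance = 1e-12)
  }
})

test_that("McNemar switches between exact binomial and corrected chi-square", {
  expect_equal(mcnemar_paired(rep(TRUE, 10), rep(TRUE, 10)), 1)
  a <- c(rep(TRUE, 10), rep(TRUE, 10))
  b <- c(rep(FALSE, 10), rep(TRUE, 10))
  expect_equal(mcnemar_paired(a, b), 2 * 0.5^10, tolerance = 1e-12)
  a2 <- c(rep(TRUE, 7), rep(FALSE, 7))
  b2 <- c(rep(FALSE, 7), rep(TRUE, 7))
  expect_equal(mcnemar_paired(a2, b2), 1)
  # large discordance: continuity-corrected chi-square
  a3 <- c(rep(TRUE, 20), rep(FALSE, 10))
  b3 <- c(rep(FALSE, 20), rep(TRUE, 10))
  expect_equal(mcnemar_paired(a3, b3),
               pchisq((abs(20 - 10) - 1)^2 / 30, 1, lower.tail = FALSE))
})

test_that("pairwise score comparisons use paired signed-rank with Bonferroni cap", {
  set.seed(83)
  n <- 16
  labels <- rep(c("adenoma", "non_adenoma"), each = n / 2)
  sets <- list(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n))
  sets$B <- sets$A
  cmp <- compare_scores(sets, labels)
  ab <- cmp[cmp$method_a == "A" & cmp$method_b == "B", ]
  expect_true(all(ab$p_adj == 1))
  expect_true(all(cmp$p_adj <= 1 & cmp$p_adj > 0))
  expect_equal(nrow(cmp), 12)  # 6 pairs x 2 classes
  expect_true(all(cmp$p_adj >= cmp$p))

  # small paired sample agrees with exact signed-rank enumeration
  set.seed(84)
  a <- rnorm(8); b <- a + rnorm(8, 0.4)
  p_ref <- wsr_exact_oracle(a, b)
  p_got <- wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  expect_equal(p_got, p_ref, tolerance = 1e-9)
})

test_that("decision curves follow the net-benefit closed forms", {
  lb <- rep(c("adenoma", "non_adenoma"), each = 25)
  perfect <- c(rep(1, 25), rep(0, 25))
  dc <- decision_curve(perfect, lb)
  expect_true(all(abs(dc$nb_model - 0.5) < 1e-12))
  expect_equal(dc$nb_all[dc$threshold == 0.2], 0.5 - 0.5 * 0.25, tolerance = 1e-12)
  expect_true(all(dc$nb_none == 0))
  expect_true(all(dc$nb_model <= mean(lb == "adenoma") + 1e-12))

  set.seed(89)
  prob <- runif(50)
  lb2 <- sample(rep(c("adenoma", "non_adenoma"), 25))
  dc2 <- decision_curve(prob, lb2)
  y <- lb2 == "adenoma"
  for (t in c(0.1, 0.33, 0.8)) {
    tp <- sum(prob >= t & y); fp <- sum(prob >= t & !y)
    expect_equal(dc2$nb_model[abs(dc2$threshold - t) < 1e-9],
                 tp / 50 - fp / 50 * t / (1 - t), tolerance = 1e-12)
  }
})

test_that("evaluation report covers all methods, splits and pairwise tests", {
  set.seed(97)
  n <- 40
  lb <- rep(c("adenoma", "non_adenoma"), each = n / 2)
  mk <- function(sep) c(rnorm(n / 2, sep), rnorm(n / 2))
  scores <- list(train = list(MAX = mk(1), MAX_E = mk(1.2), ALL = mk(1.1), ALL_E = mk(1.4)),
                 val = list(MAX = mk(0.9), MAX_E = mk(1.1), ALL = mk(1), ALL_E = mk(1.3)))
  rep_ <- eval_report(scores, list(train = lb, val = lb), boot = 50, seed = 2)
  expect_equal(nrow(rep_$metrics), 8)
  expect_setequal(names(rep_$mcnemar), c("train", "val"))
  expect_equal(dim(rep_$mcnemar$val), c(4, 4))
  expect_true(all(rep_$metrics$pauc <= 0.05 + 1e-12))
  expect_true(all(rep_$metrics$auc >= rep_$metrics$auc_lo - 1e-9 &
                    rep_$metrics$auc <= rep_$metrics$auc_hi + 1e-9))
  expect_equal(nrow(rep_$pairwise$val), 12)
  rk <- compare_methods(rep_, "val")
  expect_true(rk$winner_auc %in% c("MAX", "MAX_E", "ALL", "ALL_E"))
})
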