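# Discrimination and clinical-utility metrics. The positive class is
# "adenoma" throughout; higher scores mean more adenoma-like.

check_two_class <- function(labels) {
  y <- labels == .rimshrink_labels[1]
  if (sum(y) == 0 || sum(!y) == 0)
    .stop2("rimshrink_class_error", "both classes must be present")
  y
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC by the Mann-Whitney rank estimator with tie correction (ties count
#' one half); the 95% CI uses DeLong's structural-components variance.
#'
#' @param scores numeric scores, higher = more adenoma-like.
#' @param labels class labels.
#' @return List: `auc`, `ci` (length 2), `se`.
#' @export
roc_auc <- function(scores, labels) {
  y <- check_two_class(labels)
  pos <- scores[y]
  neg <- scores[!y]
  n1 <- length(pos)
  n0 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong structural components
  psi <- function(xs, ys) outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  M <- psi(pos, neg)
  v10 <- rowMeans(M)
  v01 <- colMeans(M)
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  list(auc = auc, ci = ci, se = se)
}

# polygonal ROC through the empirical operating points, from (0,0) to
# (1,1); ties in scores merge into a single diagonal segment
roc_points <- function(scores, labels) {
  y <- check_two_class(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y)
  n0 <- sum(!y)
  tpr <- c(0, cumsum(vapply(thr, function(t) sum(y & scores == t), numeric(1))) / n1)
  fpr <- c(0, cumsum(vapply(thr, function(t) sum(!y & scores == t), numeric(1))) / n0)
  cbind(fpr = fpr, tpr = tpr)
}

pauc_from_points <- function(pts, fmax) {
  a <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    x0 <- pts[i, 1]; x1 <- pts[i + 1, 1]
    y0 <- pts[i, 2]; y1 <- pts[i + 1, 2]
    lo <- max(x0, 0); hi <- min(x1, fmax)
    if (hi <= lo) next
    yl <- if (x1 > x0) y0 + (y1 - y0) * (lo - x0) / (x1 - x0) else y0
    yh <- if (x1 > x0) y0 + (y1 - y0) * (hi - x0) / (x1 - x0) else y1
    a <- a + (hi - lo) * (yl + yh) / 2
  }
  unname(a)
}

#' Partial AUC at high specificity
#'
#' Unstandardized trapezoidal area under the polygonal ROC restricted to
#' false-positive rate in `[0, 1 - min_spec]` (so at `min_spec = 0.95`
#' the maximum is 0.05 and the all-tied-scores diagonal gives 0.00125),
#' with linear interpolation at the boundary. The 95% CI is a seeded
#' stratified bootstrap (percentile).
#'
#' @inheritParams roc_auc
#' @param min_spec minimum specificity (default 0.95).
#' @param boot bootstrap replicates for the CI (0 skips the CI).
#' @param seed bootstrap seed.
#' @return List: `pauc`, `ci`, `min_spec`.
#' @export
pauc_high_spec <- function(scores, labels, min_spec = 0.95, boot = 2000, seed = 1) {
  y <- check_two_class(labels)
  fmax <- 1 - min_spec
  est <- pauc_from_points(roc_points(scores, labels), fmax)
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(seed)
    ip <- which(y)
    in_ <- which(!y)
    bs <- vapply(seq_len(boot), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(in_, replace = TRUE))
      pauc_from_points(roc_points(scores[idx], labels[idx]), fmax)
    }, numeric(1))
    ci <- unname(quantile(bs, c(0.025, 0.975), type = 7))
  }
  list(pauc = est, ci = ci, min_spec = min_spec)
}

#' Operating point of a score
#'
#' Scans all thresholds (predict positive when `score >= t`). Policy
#' `"youden"` maximizes sensitivity + specificity - 1, breaking ties
#' toward the higher specificity; `"spec95"` takes the smallest
#' threshold with specificity at least 0.95.
#'
#' @inheritParams roc_auc
#' @param policy `"youden"` or `"spec95"`.
#' @param min_spec specificity floor for `"spec95"`.
#' @return List: `threshold`, `sens`, `spec`, `acc`.
#' @export
operating_point <- function(scores, labels, policy = c("youden", "spec95"),
                            min_spec = 0.95) {
  policy <- match.arg(policy)
  y <- check_two_class(labels)
  thr <- c(sort(unique(scores)), Inf)
  n1 <- sum(y); n0 <- sum(!y)
  sens <- vapply(thr, function(t) sum(y & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!y & scores < t) / n0, numeric(1))
  acc <- vapply(thr, function(t)
    (sum(y & scores >= t) + sum(!y & scores < t)) / length(y), numeric(1))
  if (policy == "youden") {
    j <- sens + spec - 1
    best <- which(j == max(j))
    best <- best[spec[best] == max(spec[best])][1]
  } else {
    ok <- which(spec >= min_spec)
    best <- ok[1]   # thresholds ascending; spec is non-decreasing in t
  }
  list(threshold = thr[best], sens = sens[best], spec = spec[best],
       acc = acc[best])
}

#' McNemar's test on paired correctness
#'
#' Compares two classifiers on the same cases via the discordant counts
#' b (A right, B wrong) and c (A wrong, B right): exact two-sided
#' binomial when b + c < 25, otherwise the continuity-corrected
#' chi-square. To compare sensitivities, restrict the inputs to the
#' positive cases.
#'
#' @param correct_a,correct_b logical vectors of per-case correctness.
#' @return Two-sided P value.
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0) return(1)
  if (b + cc < 25) {
    min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Pairwise radiomics-score comparisons with Bonferroni correction
#'
#' Within each class, compares the scores of every pair of ROI methods
#' on the same cases with a two-sided Wilcoxon signed-rank test, and
#' multiplies the P values by the number of pairs (capped at 1).
#'
#' @param score_sets named list (one numeric score vector per method,
#'   aligned on cases).
#' @param labels class labels of the cases.
#' @return Data frame: `class`, `method_a`, `method_b`, `p`, `p_adj`.
#' @export
compare_scores <- function(score_sets, labels) {
  stopifnot(length(score_sets) >= 2)
  meth <- names(score_sets)
  pairs <- utils::combn(meth, 2)
  out <- list()
  for (cl in .rimshrink_labels) {
    sel <- labels == cl
    if (sum(sel) < 5)
      .stop2("rimshrink_data_error", "fewer than 5 paired cases in class ", cl)
    for (p_ in seq_len(ncol(pairs))) {
      a <- score_sets[[pairs[1, p_]]][sel]
      b <- score_sets[[pairs[2, p_]]][sel]
      pv <- if (isTRUE(all.equal(a, b))) 1 else
        suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
      out[[length(out) + 1]] <- data.frame(
        class = cl, method_a = pairs[1, p_], method_b = pairs[2, p_],
        p = pv, p_adj = min(1, pv * ncol(pairs)))
    }
  }
  do.call(rbind, out)
}

#' Decision curve analysis
#'
#' Net benefit of treating cases with predicted probability at or above
#' each threshold t: `NB(t) = TP/n - FP/n * t/(1-t)`, with the treat-all
#' reference `pi - (1-pi) * t/(1-t)` (pi = prevalence) and treat-none at
#' zero.
#'
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param labels class labels.
#' @param thresholds threshold grid (t = 1 excluded).
#' @return Data frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1), all(thresholds < 1))
  y <- labels == .rimshrink_labels[1]
  n <- length(y)
  pi_ <- mean(y)
  nb <- vapply(thresholds, function(t) {
    pred <- probabilities >= t
    sum(pred & y) / n - sum(pred & !y) / n * t / (1 - t)
  }, numeric(1))
  nb_all <- pi_ - (1 - pi_) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, nb_model = nb, nb_all = nb_all,
             nb_none = 0)
}

#' Evaluation report across ROI methods and splits
#'
#' For each ROI method and data split computes AUC (DeLong 95% CI),
#' Youden operating point, pAUC at >= 95% specificity (bootstrap CI)
#' with its sensitivity/accuracy at the pooled spec-95 threshold, plus
#' pairwise McNemar tests on sensitivity at that threshold, the
#' Bonferroni-adjusted pairwise score tests, and decision curves. A pure
#' function of scores and labels, fully recomputable from the
#' serialized score table.
#'
#' @param scores_by_split named list of splits; each a named list of
#'   per-method score vectors.
#' @param labels_by_split named list of label vectors per split.
#' @param boot,seed pAUC bootstrap settings.
#' @return Object of class `eval_report`: `metrics` (data frame),
#'   `mcnemar` (per split, method-pair matrix of P values), `pairwise`
#'   (score comparisons, validation split), `dca` (per split).
#' @export
eval_report <- function(scores_by_split, labels_by_split, boot = 500, seed = 1) {
  metrics <- list()
  mcn <- list()
  dca <- list()
  pairwise <- list()
  for (sp in names(scores_by_split)) {
    sc <- scores_by_split[[sp]]
    lb <- labels_by_split[[sp]]
    y <- lb == .rimshrink_labels[1]
    correct95 <- list()
    for (m in names(sc)) {
      ra <- roc_auc(sc[[m]], lb)
      yj <- operating_point(sc[[m]], lb, "youden")
      pa <- pauc_high_spec(sc[[m]], lb, boot = boot, seed = seed)
      op95 <- operating_point(sc[[m]], lb, "spec95")
      correct95[[m]] <- ifelse(y, sc[[m]] >= op95$threshold, sc[[m]] < op95$threshold)
      metrics[[length(metrics) + 1]] <- data.frame(
        split = sp, roi_method = m,
        auc = ra$auc, auc_lo = ra$ci[1], auc_hi = ra$ci[2],
        sens = yj$sens, spec = yj$spec, acc = yj$acc,
        pauc = pa$pauc, pauc_lo = pa$ci[1], pauc_hi = pa$ci[2],
        sens95 = op95$sens, acc95 = op95$acc)
    }
    mm <- matrix(NA_real_, length(sc), length(sc),
                 dimnames = list(names(sc), names(sc)))
    for (a in names(sc)) for (b in names(sc)) if (a != b)
      mm[a, b] <- mcnemar_paired(correct95[[a]][y], correct95[[b]][y])
    mcn[[sp]] <- mm
    dca[[sp]] <- lapply(sc, function(s) decision_curve(plogis(s), lb))
    # pairwise tests need >= 5 paired cases per class; skip on tiny splits
    pairwise[[sp]] <- tryCatch(compare_scores(sc, lb),
                               rimshrink_data_error = function(e) NULL)
  }
  structure(list(metrics = do.call(rbind, metrics), mcnemar = mcn,
                 pairwise = pairwise, dca = dca),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  df <- x$metrics
  df[-(1:2)] <- lapply(df[-(1:2)], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
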