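#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' from the classical mean-squares decomposition: with n subjects and
#' k = 2 raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Absolute agreement penalizes systematic rater shifts, which is why a
#' constant offset between raters gives ICC < 1.
#'
#' @param y1,y2 paired measurements from rater 1 and rater 2 (n >= 3).
#' @return ICC value in `[-1, 1]`.
#' @export
icc_2_1 <- function(y1, y2) {
  stopifnot(length(y1) == length(y2), length(y1) >= 3)
  n <- length(y1)
  k <- 2
  x <- cbind(y1, y2)
  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den == 0) {
    if (isTRUE(all.equal(y1, y2))) return(1)
    .stop2("rimshrink_data_error", "ICC undefined: zero total variance with disagreeing raters")
  }
  (msr - mse) / den
}

#' Feature stability screening by inter-rater ICC
#'
#' Computes ICC(2,1) per feature between two feature tables extracted
#' from different raters' masks (aligned on `case_id` and `roi_method`);
#' features with ICC below the threshold are flagged for exclusion from
#' the downstream selection cascade.
#'
#' @param table_rater1,table_rater2 feature tables sharing cases and
#'   feature columns.
#' @param threshold retention threshold (default 0.75).
#' @return Data frame of class `icc_report`: `feature`, `icc`,
#'   `retained`; attribute `n_cases` records the paired subset size.
#' @export
stability_filter <- function(table_rater1, table_rater2, threshold = 0.75) {
  key1 <- paste(table_rater1$case_id, table_rater1$roi_method)
  key2 <- paste(table_rater2$case_id, table_rater2$roi_method)
  common <- intersect(key1, key2)
  if (length(common) < 3)
    .stop2("rimshrink_alignment_error",
           "fewer than 3 shared (case, roi_method) rows between raters")
  t1 <- table_rater1[match(common, key1), , drop = FALSE]
  t2 <- table_rater2[match(common, key2), , drop = FALSE]
  feats <- intersect(feature_registry()$name, names(t1))
  icc <- vapply(feats, function(f) {
    tryCatch(icc_2_1(t1[[f]], t2[[f]]),
             rimshrink_data_error = function(e) -Inf)
  }, numeric(1))
  rep_ <- data.frame(feature = feats, icc = unname(icc),
                     retained = unname(icc) >= threshold)
  attr(rep_, "n_cases") <- length(common)
  class(rep_) <- c("icc_report", "data.frame")
  rep_
}

#' Univariate feature screening (Mann-Whitney U)
#'
#' Two-sided rank-sum test of each feature between the two classes;
#' features with P below `alpha` survive. A constant feature is assigned
#' P = 1 and dropped.
#'
#' @param x numeric matrix or data frame of features (rows = cases).
#' @param labels class labels aligned with rows.
#' @param alpha significance threshold.
#' @return Data frame `feature`, `p`, `retained`.
#' @export
univariate_filter <- function(x, labels, alpha = 0.05) {
  x <- as.data.frame(x)
  g <- labels == .rimshrink_labels[1]
  stopifnot(sum(g) >= 3, sum(!g) >= 3)
  p <- vapply(x, function(v) {
    if (length(unique(v)) == 1L) return(1)
    suppressWarnings(wilcox.test(v[g], v[!g], exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(feature = names(x), p = unname(p), retained = unname(p) < alpha)
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  list(centre = ctr, scale = scl,
       z = sweep(sweep(x, 2, ctr), 2, scl, `/`))
}

#' Recursive feature elimination with an L2-regularized logistic learner
#'
#' Features are standardized, a ridge-penalized logistic model is fitted,
#' and the feature with the smallest absolute coefficient is dropped;
#' this repeats until `ceiling(keep_frac * n_in)` features remain (at
#' least one). Deterministic: the ridge fit involves no resampling.
#'
#' @param x feature matrix/data frame (>= 2 columns).
#' @param labels class labels.
#' @param keep_frac fraction of entering features to retain.
#' @param ridge_lambda penalty of the base learner.
#' @return Character vector of surviving feature names, in input order.
#' @export
rfe_select <- function(x, labels, keep_frac = 0.30, ridge_lambda = 0.01) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  y <- as.integer(labels == .rimshrink_labels[1])
  keep <- max(1L, as.integer(ceiling(keep_frac * ncol(x))))
  surv <- colnames(x)
  while (length(surv) > keep) {
    st <- standardize_fit(x[, surv, drop = FALSE])
    if (length(surv) == 1L) break
    fit <- glmnet::glmnet(st$z, y, family = "binomial", alpha = 0,
                          lambda = ridge_lambda, standardize = FALSE)
    b <- abs(as.numeric(fit$beta))
    surv <- surv[-which.min(b)]
  }
  surv
}

# stratified fold assignment: shuffles within class, cycles 1..folds
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' LASSO-penalized logistic selection with the 1-SE rule
#'
#' Standardizes the entering features, fits an L1-penalized logistic path
#' with stratified tenfold cross-validation of the binomial deviance, and
#' keeps the features with non-zero coefficients at the largest lambda
#' whose CV deviance is within one standard error of the minimum. If
#' that lambda zeroes every coefficient the minimizing lambda is used
#' instead (logged).
#'
#' @param x feature matrix/data frame (>= 2 columns).
#' @param labels class labels (both classes in every fold).
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @return List: `survivors`, `lambda`, `lambda_min`, `coefficients`
#'   (at the chosen lambda, standardized scale), `used_min_lambda`.
#' @export
lasso_1se <- function(x, labels, folds = 10, seed = 1) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  y <- as.integer(labels == .rimshrink_labels[1])
  st <- standardize_fit(x)
  foldid <- stratified_folds(labels, folds, seed)
  cv <- glmnet::cv.glmnet(st$z, y, family = "binomial", foldid = foldid,
                          standardize = FALSE, type.measure = "deviance")
  lam <- cv$lambda.1se
  b <- as.numeric(coef(cv, s = lam))[-1]
  used_min <- FALSE
  if (all(b == 0)) {
    lam <- cv$lambda.min
    b <- as.numeric(coef(cv, s = lam))[-1]
    used_min <- TRUE
    .msg("1-SE lambda zeroed all coefficients; falling back to lambda.min")
  }
  names(b) <- colnames(x)
  list(survivors = colnames(x)[b != 0], lambda = lam,
       lambda_min = cv$lambda.min, coefficients = b,
       used_min_lambda = used_min)
}

#' Stratified train/validation split
#'
#' Splits case indices into a training and validation set stratified by
#' class, with total training size `floor(ratio * n)`; per-class counts
#' are the class floors, topped up by largest fractional part. With 237
#' cases at ratio 0.8 this yields 189 training and 48 validation cases.
#'
#' @param labels class labels (n >= 5, each class >= 2).
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(labels, ratio = 0.8, seed = 1) {
  n <- length(labels)
  stopifnot(n >= 5)
  tab <- table(labels)
  if (any(tab < 2))
    .stop2("rimshrink_data_error", "each class needs >= 2 members to stratify")
  n_train <- floor(ratio * n)
  exact <- ratio * as.numeric(tab)
  base <- floor(exact)
  extra <- n_train - sum(base)
  if (extra > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  set.seed(seed)
  train <- integer()
  for (ci in seq_along(tab)) {
    idx <- which(labels == names(tab)[ci])
    train <- c(train, sample(idx, base[ci]))
  }
  train <- sort(train)
  list(train = train, val = setdiff(seq_len(n), train))
}

#' Run the full selection cascade
#'
#' Stability screening (if a second-rater table is given), univariate
#' Mann-Whitney screening, recursive feature elimination retaining 30%,
#' and LASSO with the 1-SE rule; survivor sets are nested by
#' construction. All statistics are computed on the supplied (training)
#' rows only.
#'
#' @param x training feature matrix/data frame.
#' @param labels training class labels.
#' @param icc_report optional `icc_report` from [stability_filter()].
#' @param alpha univariate threshold.
#' @param keep_frac RFE retention fraction.
#' @param folds,seed LASSO CV parameters.
#' @return List of class `selection_trace`: per-stage survivor name
#'   vectors (`stable`, `univariate`, `rfe`, `lasso`), the LASSO detail,
#'   and the univariate P values.
#' @export
selection_cascade <- function(x, labels, icc_report = NULL, alpha = 0.05,
                              keep_frac = 0.30, folds = 10, seed = 1) {
  x <- as.data.frame(x)
  stable <- names(x)
  if (!is.null(icc_report))
    stable <- intersect(stable, icc_report$feature[icc_report$retained])
  if (length(stable) < 2)
    .stop2("rimshrink_data_error", "fewer than 2 features survive stability screening")
  uni <- univariate_filter(x[stable], labels, alpha)
  u_surv <- uni$feature[uni$retained]
  if (length(u_surv) < 2)
    .stop2("rimshrink_data_error", "fewer than 2 features survive univariate screening")
  r_surv <- rfe_select(x[u_surv], labels, keep_frac)
  las <- if (length(r_surv) >= 2)
    lasso_1se(x[r_surv], labels, folds, seed)
  else list(survivors = r_surv, lambda = NA_real_, lambda_min = NA_real_,
            coefficients = setNames(rep(NA_real_, length(r_surv)), r_surv),
            used_min_lambda = FALSE)
  structure(list(stable = stable, univariate = u_surv, rfe = r_surv,
                 lasso = las$survivors, lasso_detail = las,
                 univariate_p = uni),
            class = "selection_trace")
}

#' @exportS3Method base::print
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> stable %d -> univariate %d -> RFE %d -> LASSO %d\n",
              length(x$stable), length(x$univariate), length(x$rfe),
              length(x$lasso)))
  if (length(x$lasso)) cat("  final:", paste(x$lasso, collapse = ", "), "\n")
  invisible(x)
}
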