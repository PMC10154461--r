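#' Fit the logistic radiomics signature
#'
#' Maximum-likelihood logistic regression of the class label (positive
#' class: adenoma) on the selected features, standardized to the
#' training-set mean and standard deviation. The radiomics score of a
#' case is the linear predictor (intercept plus the coefficient-weighted
#' standardized features); the predicted probability is its logistic
#' transform. On (quasi-)separation the fit is stabilized with a small
#' ridge penalty and flagged.
#'
#' @param x training feature matrix/data frame.
#' @param labels training class labels.
#' @param features names of the model features (default: all columns).
#' @return Object of class `radiomics_signature` with elements
#'   `intercept`, `coefficients` (named, standardized scale), `centre`,
#'   `scale`, `features`, `ridged`, `train_scores`.
#' @export
radiomics_signature <- function(x, labels, features = NULL) {
  x <- as.data.frame(x)
  features <- features %||% names(x)
  if (length(features) == 0)
    .stop2("rimshrink_data_error", "no features to fit")
  x <- as.matrix(x[features])
  y <- as.integer(labels == .rimshrink_labels[1])
  st <- standardize_fit(x)
  ridged <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = data.frame(y = y, st$z), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        ridged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (ridged || any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 1e3)) {
    ridged <- TRUE
    .msg("separation detected; refitting with a small ridge penalty")
    if (ncol(st$z) >= 2) {
      rfit <- glmnet::glmnet(st$z, y, family = "binomial", alpha = 0,
                             lambda = 1e-3, standardize = FALSE)
      b <- c(as.numeric(rfit$a0), as.numeric(rfit$beta))
    } else {
      rfit <- glmnet::glmnet(cbind(st$z, 0), y, family = "binomial", alpha = 0,
                             lambda = 1e-3, standardize = FALSE)
      b <- c(as.numeric(rfit$a0), as.numeric(rfit$beta)[1])
    }
  } else {
    b <- as.numeric(coef(fit))
  }
  obj <- structure(list(intercept = b[1],
                        coefficients = setNames(b[-1], features),
                        centre = st$centre, scale = st$scale,
                        features = features, ridged = ridged,
                        n_train = length(y)),
                   class = "radiomics_signature")
  obj$train_scores <- predict(obj, as.data.frame(x), type = "score")
  obj
}

#' @param object,x a `radiomics_signature`.
#' @param newdata data frame containing the model features.
#' @param type `"score"` (linear predictor), `"prob"`, or `"class"`.
#' @param threshold probability cut-off for `type = "class"`.
#' @param ... unused.
#' @rdname radiomics_signature
#' @export
predict.radiomics_signature <- function(object, newdata, type = c("score", "prob", "class"),
                                        threshold = 0.5, ...) {
  type <- match.arg(type)
  z <- sweep(sweep(as.matrix(as.data.frame(newdata)[object$features]),
                   2, object$centre), 2, object$scale, `/`)
  score <- drop(object$intercept + z %*% object$coefficients)
  switch(type,
         score = score,
         prob = plogis(score),
         class = ifelse(plogis(score) >= threshold,
                        .rimshrink_labels[1], .rimshrink_labels[2]))
}

#' @rdname radiomics_signature
#' @export
coef.radiomics_signature <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @rdname radiomics_signature
#' @exportS3Method base::print
print.radiomics_signature <- function(x, ...) {
  cat(sprintf("<radiomics_signature> %d feature(s), trained on %d cases%s\n",
              length(x$features), x$n_train,
              if (x$ridged) " (ridge-stabilized)" else ""))
  print(round(coef(x), 4))
  invisible(x)
}

#' @rdname radiomics_signature
#' @exportS3Method base::summary
summary.radiomics_signature <- function(object, ...) {
  cat("Logistic radiomics signature (positive class: adenoma)\n")
  print(object)
  cat(sprintf("Training radiomics score: median %.3f [IQR %.3f, %.3f]\n",
              median(object$train_scores),
              quantile(object$train_scores, 0.25),
              quantile(object$train_scores, 0.75)))
  invisible(object)
}

# serialize a fitted signature to JSON (names, coefficients,
# standardization constants -- no opaque binary)
#' @rdname radiomics_signature
#' @param path JSON output path.
#' @export
write_signature_json <- function(x, path) {
  jsonlite::write_json(list(intercept = x$intercept,
                            coefficients = as.list(x$coefficients),
                            centre = as.list(x$centre),
                            scale = as.list(x$scale),
                            ridged = x$ridged, n_train = x$n_train),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
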