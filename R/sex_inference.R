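#' Extract the six-marker feature matrix for sex inference
#'
#' Features are logCPM values of the six sex-chromosome marker genes,
#' computed per sample as `log2((count + 0.5) / (library + 1) * 1e6)`
#' (the standard pseudo-count logCPM; see [logcpm()]). The library
#' size is the full column sum of `counts`, so the features reflect
#' each sample's complete sequencing depth.
#'
#' @param counts gene-by-sample count matrix containing all six markers.
#' @param marker_ids marker gene ids, in the fixed order
#'   XIST, EIF1AY, KDM5D, UTY, DDX3Y, RPS4Y1.
#' @return Sample-by-marker numeric matrix (n x 6).
#' @export
extract_sex_features <- function(counts, marker_ids = names(sex_marker_genes())) {
  assert_count_matrix(counts)
  missing <- setdiff(marker_ids, rownames(counts))
  if (length(missing)) {
    stopf("marker gene(s) absent from counts: %s", paste(missing, collapse = ", "))
  }
  lc <- logcpm(counts)
  t(lc[marker_ids, , drop = FALSE])
}

#' Fit the LASSO logistic-regression sex classifier
#'
#' L1-penalized logistic regression of sex on the six marker logCPM
#' features, fitted by coordinate descent over an IRLS quadratic
#' approximation with the intercept unpenalized. The penalty `lambda`
#' is chosen to minimize the mean 10-fold cross-validated binomial
#' deviance over a grid of 100 values log-spaced from `lambda_max`
#' (the smallest penalty with all-zero coefficients) down by a factor
#' of 1e-4; folds are stratified by class and deterministic given
#' `seed`. The final model is refit on all samples at the chosen
#' penalty. Female is the positive class; samples with predicted
#' probability strictly above `threshold` are called female.
#'
#' @param X sample-by-feature matrix from [extract_sex_features()].
#' @param y sex labels (`"female"`/`"male"`), one per row of `X`.
#' @param lambda_grid optional penalty grid; a single value skips
#'   cross-validation and fits at that penalty directly.
#' @param n_folds number of CV folds (must not exceed the smaller
#'   class size).
#' @param seed integer seed controlling fold assignment.
#' @param threshold probability threshold for calling female.
#' @return Object of class `sex_classifier`: intercept, named
#'   coefficient vector, chosen `lambda`, the CV deviance path,
#'   `threshold` and `positive_class = "female"`.
#' @export
fit_lasso_logistic <- function(X, y, lambda_grid = NULL, n_folds = 10L,
                               seed = 1L, threshold = 0.5) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopf("non-finite values in the feature matrix")
  y <- as.character(y)
  if (length(y) != nrow(X)) stopf("length(y) must equal nrow(X)")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stopf("training labels contain a single class ('%s')", classes)
  if (!all(classes %in% c("female", "male"))) {
    stopf("labels must be 'female'/'male', found: %s", paste(classes, collapse = ", "))
  }
  yy <- as.numeric(y == "female")
  n_min <- min(table(y))
  if (n_min < 2L) stopf("need at least 2 samples per class")

  if (is.null(lambda_grid)) {
    lmax <- lasso_lambda_max(X, yy)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100L))
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)

  cv_dev <- NULL
  if (length(lambda_grid) > 1L) {
    if (n_folds > n_min) {
      stopf("n_folds (%d) exceeds the smaller class size (%d)", n_folds, n_min)
    }
    fold <- stratified_folds(yy, n_folds, seed)
    dev <- matrix(NA_real_, nrow = n_folds, ncol = length(lambda_grid))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      path <- lasso_logistic_path(X[tr, , drop = FALSE], yy[tr], lambda_grid)
      eta <- sweep(X[!tr, , drop = FALSE] %*% path$coefficients, 2,
                   path$intercepts, "+")
      dev[f, ] <- apply(stats::plogis(eta), 2, function(p) {
        binomial_deviance(yy[!tr], p)
      })
    }
    cv_dev <- colMeans(dev)
    lambda <- lambda_grid[which.min(cv_dev)]
  } else {
    lambda <- lambda_grid
  }

  path <- lasso_logistic_path(X, yy, lambda)
  model <- list(
    intercept = path$intercepts[1],
    coefficients = setNames(path$coefficients[, 1], colnames(X)),
    lambda = lambda,
    lambda_grid = lambda_grid,
    cv_deviance = cv_dev,
    threshold = threshold,
    positive_class = "female",
    n_folds = if (length(lambda_grid) > 1L) n_folds else NA_integer_,
    seed = seed
  )
  class(model) <- "sex_classifier"
  model
}

#' @export
print.sex_classifier <- function(x, ...) {
  cat("Six-gene LASSO logistic sex classifier\n")
  cat(sprintf("  lambda = %.4g (CV over %s folds), threshold = %g, positive class = %s\n",
              x$lambda, ifelse(is.na(x$n_folds), "no", x$n_folds),
              x$threshold, x$positive_class))
  cat(sprintf("  intercept = %.4f\n", x$intercept))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-8s %+.4f\n", nm, x$coefficients[nm]))
  }
  invisible(x)
}

#' Predict sex from marker features
#'
#' Probability of female is the inverse logit of the linear predictor;
#' a sample is labeled female if and only if the probability is
#' strictly greater than the model's threshold (a probability of
#' exactly 0.5 with the default threshold is therefore called male).
#'
#' @param model a [fit_lasso_logistic()] model.
#' @param X sample-by-feature matrix with columns in the model's
#'   feature order.
#' @return data.frame with `sample_id`, `prob_female` and `sex`.
#' @export
predict_sex <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), names(model$coefficients))) {
    stopf("feature columns (%s) do not match the model's features (%s)",
          paste(colnames(X), collapse = ","),
          paste(names(model$coefficients), collapse = ","))
  }
  prob <- stats::plogis(drop(model$intercept + X %*% model$coefficients))
  data.frame(
    sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    prob_female = prob,
    sex = ifelse(prob > model$threshold, "female", "male"),
    stringsAsFactors = FALSE
  )
}

#' Confusion-matrix performance of a sex classifier
#'
#' Female is the positive class: sensitivity is the recall on female
#' samples and specificity the recall on male samples.
#'
#' @param predicted predicted labels (or a [predict_sex()] data.frame).
#' @param truth true labels, aligned with `predicted`.
#' @return Object of class `classifier_report` with confusion counts
#'   (`tp`, `tn`, `fp`, `fn`) and `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_classifier <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$sex
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stopf("predicted (%d) and truth (%d) lengths differ", length(predicted), length(truth))
  }
  tp <- sum(predicted == "female" & truth == "female")
  tn <- sum(predicted == "male" & truth == "male")
  fp <- sum(predicted == "female" & truth == "male")
  fn <- sum(predicted == "male" & truth == "female")
  out <- list(
    tp = tp, tn = tn, fp = fp, fn = fn, n = length(truth),
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
  class(out) <- "classifier_report"
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("n = %d | TP %d TN %d FP %d FN %d\n", x$n, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("accuracy %.3f, sensitivity %.3f, specificity %.3f (female = positive)\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Fill in unknown sex labels by classifier inference
#'
#' Only samples with `sex == "unknown"` are overwritten; reported
#' labels are never altered. Provenance is recorded in a `sex_source`
#' column (`"reported"` or `"inferred"`), and the derived `group`
#' column is refreshed.
#'
#' @param counts count matrix containing the marker genes.
#' @param meta metadata (may mix reported and unknown sex).
#' @param model trained [fit_lasso_logistic()] classifier.
#' @param marker_ids marker genes, in the model's feature order.
#' @return Metadata with sex filled in and `sex_source` added.
#' @export
infer_missing_sex <- function(counts, meta, model,
                              marker_ids = names(sex_marker_genes())) {
  pair <- validate_pairing(counts, meta)
  meta <- pair$metadata
  meta$sex_source <- ifelse(meta$sex == "unknown", "inferred", "reported")
  unknown <- meta$sex == "unknown"
  if (any(unknown)) {
    X <- extract_sex_features(pair$counts[, meta$sample_id[unknown], drop = FALSE],
                              marker_ids)
    pred <- predict_sex(model, X)
    meta$sex[unknown] <- pred$sex
  }
  meta$group <- derive_group(meta$condition, meta$sex)
  meta
}
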