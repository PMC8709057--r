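# Five-kernel SVM classifier bank for single-trial P300 detection.
# The dual problem is solved by the package's own SMO routine (src/smo.cpp);
# kernels and their scale presets follow the conventions of the point-and-
# click classification tool the models emulate: "medium" and "coarse"
# Gaussian kernel scales are sqrt(P) and 4*sqrt(P) for P features.

#' Kernel specification for the P300 SVM bank
#'
#' The five constructible kernels are linear (`"L"`), quadratic (`"Q"`,
#' polynomial degree 2), cubic (`"C"`, degree 3), medium Gaussian (`"MG"`,
#' kernel scale `sqrt(P)`) and coarse Gaussian (`"CG"`, scale `4 sqrt(P)`),
#' with `P` the feature count. Polynomial kernels are
#' `(1 + <u, v> / P)^degree` (predictors rescaled by `sqrt(P)`, the
#' training tool's automatic kernel scale); Gaussian kernels are
#' `exp(-||u - v||^2 / s^2)`.
#'
#' @param kind one of `"L"`, `"Q"`, `"C"`, `"MG"`, `"CG"`.
#' @param kernel_scale optional override of the Gaussian kernel scale.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("L", "Q", "C", "MG", "CG"),
                        kernel_scale = NULL) {
  kind <- match.arg(kind)
  degree <- switch(kind, L = 1L, Q = 2L, C = 3L, 0L)
  rule <- switch(kind, MG = "sqrt(P)", CG = "4*sqrt(P)", "none")
  structure(list(kind = kind, polynomial_degree = degree,
                 kernel_scale = kernel_scale, kernel_scale_rule = rule),
            class = "kernel_spec")
}

gaussian_scale <- function(spec, p) {
  spec$kernel_scale %||% switch(spec$kind, MG = sqrt(p), CG = 4 * sqrt(p),
                                stop_arg("no scale rule for kernel %s",
                                         spec$kind))
}

# kernel matrix between rows of X and rows of Y (Y = NULL -> Gram of X).
# Polynomial kernels rescale predictors by sqrt(P) (the training tool's
# automatic kernel scale) so inner products are O(1) regardless of the
# feature count; Gaussian kernels use the medium/coarse scale presets.
kernel_matrix <- function(spec, X, Y = NULL) {
  Y <- Y %||% X
  G <- tcrossprod(X, Y)
  p <- ncol(X)
  switch(spec$kind,
    L = G,
    Q = (1 + G / p)^2,
    C = (1 + G / p)^3,
    {
      s <- gaussian_scale(spec, p)
      d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * G
      exp(-pmax(d2, 0) / s^2)
    })
}

labels_to_y <- function(labels) {
  ifelse(labels == "P300", 1, -1)
}

#' Train a P300 SVM classifier
#'
#' Fits a soft-margin SVM (P300 = positive class) with the requested kernel
#' by sequential minimal optimization, and reports the k-fold
#' cross-validated accuracy (stratified folds, deterministic given `seed`).
#'
#' @param x numeric matrix, trials x features.
#' @param labels character vector of `"P300"` / `"nonP300"` labels.
#' @param kernel a [kernel_spec()] or a kernel kind string.
#' @param box_constraint soft-margin box constraint C (default 10; with the
#'   speller's 1:5 class imbalance and single-trial signal levels, a unit
#'   box constraint drives the flatter kernels into degenerate
#'   majority-class solutions).
#' @param k_folds folds for cross-validated accuracy (default 5); 0 skips
#'   cross-validation (`cv_accuracy` is then `NA`).
#' @param seed seed controlling the fold assignment.
#' @param tol SMO KKT-violation stopping tolerance.
#' @param max_iter SMO iteration cap.
#' @return object of class `p300_svm` with the support vectors, dual
#'   coefficients, bias, `cv_accuracy`, and the training descriptor.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 2), 30), matrix(rnorm(60, -2), 30))
#' y <- rep(c("P300", "nonP300"), each = 30)
#' fit <- train_svm(x, y, "L", seed = 1)
#' fit$cv_accuracy
#' @export
train_svm <- function(x, labels, kernel = kernel_spec("L"),
                      box_constraint = 10, k_folds = 5, seed = 1L,
                      tol = 1e-3, max_iter = 200000L) {
  if (is.character(kernel)) kernel <- kernel_spec(kernel)
  stopifnot(inherits(kernel, "kernel_spec"))
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stop_arg("labels must match rows of x")
  if (length(unique(labels)) < 2L)
    stop_arg("training data must contain both classes")
  check_number(box_constraint, "box_constraint", lower = 1e-12)
  check_number(k_folds, "k_folds", lower = 0, integer = TRUE)

  fit_core <- function(xt, yt) {
    K <- kernel_matrix(kernel, xt)
    smo_solve(K, yt, box_constraint, tol, as.integer(max_iter))
  }
  y <- labels_to_y(labels)

  cv_accuracy <- NA_real_
  if (k_folds >= 2L) {
    folds <- stratified_folds(labels, k_folds, seed)
    pred <- character(length(labels))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      sol <- fit_core(x[tr, , drop = FALSE], y[tr])
      sc <- svm_scores(kernel, x[tr, , drop = FALSE], y[tr], sol,
                       x[!tr, , drop = FALSE])
      pred[!tr] <- ifelse(sc >= 0, "P300", "nonP300")
    }
    cv_accuracy <- mean(pred == labels)
  }

  sol <- fit_core(x, y)
  sv <- which(sol$alpha > 1e-8)
  structure(
    list(kernel = kernel, box_constraint = box_constraint,
         sv_x = x[sv, , drop = FALSE], sv_coef = sol$alpha[sv] * y[sv],
         b = sol$b, n_features = ncol(x), n_sv = length(sv),
         cv_folds = k_folds, cv_accuracy = cv_accuracy,
         iterations = sol$iterations,
         train_descriptor = sprintf("%d trials (%d P300), %d features",
                                    nrow(x), sum(y > 0), ncol(x))),
    class = "p300_svm")
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

svm_scores <- function(kernel, sv_x, y_or_coef, sol, newx) {
  K <- kernel_matrix(kernel, newx, sv_x)
  if (is.list(sol)) {
    drop(K %*% (sol$alpha * y_or_coef)) + sol$b
  } else {
    drop(K %*% y_or_coef) + sol
  }
}

#' @export
print.p300_svm <- function(x, ...) {
  cat(sprintf("<p300_svm> kernel=%s  C=%g  SVs=%d/%s  cv(k=%d) acc=%s\n",
              x$kernel$kind, x$box_constraint, x$n_sv, x$train_descriptor,
              x$cv_folds,
              ifelse(is.na(x$cv_accuracy), "NA",
                     sprintf("%.3f", x$cv_accuracy))))
  invisible(x)
}

#' Predict P300 labels or decision scores
#'
#' @param object a trained [train_svm()] model.
#' @param newdata trials x features matrix of the training dimensionality.
#' @param type `"label"` (default) or `"score"` (signed decision values;
#'   positive means P300).
#' @param ... unused.
#' @return character labels or numeric scores.
#' @export
predict.p300_svm <- function(object, newdata, type = c("label", "score"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop_arg("newdata has %d features; model expects %d", ncol(newdata),
             object$n_features)
  sc <- svm_scores(object$kernel, object$sv_x, object$sv_coef, object$b,
                   newdata)
  if (type == "score") sc else ifelse(sc >= 0, "P300", "nonP300")
}

#' Evaluate a model on labelled features
#'
#' Computes the confusion counts and metric suite ([metrics_report()]) of
#' the model's predictions, with P300 as the positive class.
#'
#' @param model a [train_svm()] model.
#' @param features trials x features matrix.
#' @param labels true labels.
#' @return a [metrics_report].
#' @export
evaluate <- function(model, features, labels) {
  if (nrow(as.matrix(features)) != length(labels))
    stop_arg("labels must match rows of features")
  metrics_from_predictions(predict(model, features), labels)
}
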