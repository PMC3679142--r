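# Class-weighted soft-margin SVM on a precomputed Gram matrix.
#
# The per-class-penalty C-SVC dual (penalty C+ on positive slack, C- on
# negative slack) is solved by kernlab's SMO implementation with
# class.weights, which bounds each dual coefficient by the penalty of its
# example's class.  kernlab's internal +/-1 coding of the two factor levels
# is not part of its documented interface, so after fitting we orient the
# decision function against kernlab's own predicted labels and store the
# oriented coefficients: decision(x) = sum_i y_i a_i K(x_i, x) + b, with
# decision > 0 (ties included) predicting the positive class.

#' Training configuration for the class-weighted C-SVC
#'
#' @param c_plus penalty on misclassifying positive (heterodimer) examples
#' @param c_minus penalty on misclassifying negative examples; the usual
#'   C-SVC is recovered at `c_plus == c_minus`.
#' @return list of class `training_config`.
#' @export
training_config <- function(c_plus = 1, c_minus = 1) {
  if (!is.finite(c_plus) || c_plus <= 0 || !is.finite(c_minus) || c_minus <= 0)
    stop("class penalties must be finite and > 0")
  structure(list(c_plus = c_plus, c_minus = c_minus), class = "training_config")
}

#' Fit the class-weighted C-SVC on a precomputed Gram matrix
#'
#' @param gram symmetric positive semidefinite kernel matrix over the
#'   training examples
#' @param labels integer vector in `{+1, -1}`, both classes present
#' @param config a [training_config()]
#' @return object of class `svc_model`: support indices `sv`, oriented dual
#'   coefficients `coef` (`y_i * a_i` for the support examples), bias `b`,
#'   and `n_train`.
#' @export
svc_fit <- function(gram, labels, config = training_config()) {
  gram <- as.matrix(gram)
  if (nrow(gram) != ncol(gram) ||
      max(abs(gram - t(gram))) > 1e-8 * max(1, max(abs(gram))))
    stop("gram must be a symmetric square matrix")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training labels")
  if (length(labels) != nrow(gram)) stop("labels and gram sizes differ")

  y <- factor(labels, levels = c(-1, 1))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(gram), y, type = "C-svc",
                       C = 1,
                       class.weights = c("1" = config$c_plus,
                                         "-1" = config$c_minus),
                       scaled = FALSE)
  sv <- kernlab::SVindex(fit)
  co <- unlist(kernlab::coef(fit))
  bias <- -kernlab::b(fit)   # kernlab decision: K[, sv] %*% co - b(fit)
  raw <- as.vector(gram[, sv, drop = FALSE] %*% co) + bias
  ref <- predict(fit, kernlab::as.kernelMatrix(gram[, sv, drop = FALSE]))
  ref_pm <- ifelse(as.character(ref) == "1", 1, -1)
  nz <- abs(raw) > 1e-10
  flip <- if (any(nz)) mean(sign(raw[nz]) == ref_pm[nz]) < 0.5 else FALSE
  if (flip) { co <- -co; bias <- -bias; raw <- -raw }
  if (any(nz) && mean(sign(raw[nz]) == ref_pm[nz]) < 1)
    warning("decision-value orientation disagrees with the solver on ",
            sum(sign(raw[nz]) != ref_pm[nz]), " example(s)")
  structure(list(sv = sv, coef = as.numeric(co), b = bias,
                 n_train = length(labels), config = config),
            class = "svc_model")
}

#' @export
print.svc_model <- function(x, ...) {
  cat("svc_model:", length(x$sv), "support examples of", x$n_train,
      "| C+ =", x$config$c_plus, "C- =", x$config$c_minus, "\n")
  invisible(x)
}

#' Decision values for new examples
#'
#' @param model an [svc_fit()] model
#' @param gram_rows matrix of kernel values `K(test_r, train_i)`, one row
#'   per test example, columns covering all training examples
#' @return numeric decision values; positive (or zero) means predicted
#'   heterodimer.
#' @export
svc_decision <- function(model, gram_rows) {
  gram_rows <- as_gram_rows(gram_rows, model$n_train)
  as.vector(gram_rows[, model$sv, drop = FALSE] %*% model$coef) + model$b
}

as_gram_rows <- function(gram_rows, n_train) {
  if (is.null(dim(gram_rows))) {
    if (length(gram_rows) %% n_train != 0L)
      stop("gram_rows must have ", n_train, " columns, one per training example")
    gram_rows <- matrix(gram_rows, ncol = n_train, byrow = TRUE)
  }
  if (ncol(gram_rows) != n_train)
    stop("gram_rows must have ", n_train, " columns, one per training example")
  gram_rows
}

#' Predict labels for new examples
#'
#' A decision value of exactly 0 is predicted as +1.
#'
#' @inheritParams svc_decision
#' @return integer vector in `{+1, -1}` (empty for an empty test set).
#' @export
svc_predict <- function(model, gram_rows) {
  gram_rows <- as_gram_rows(gram_rows, model$n_train)
  if (nrow(gram_rows) == 0L) return(integer(0))
  ifelse(svc_decision(model, gram_rows) >= 0, 1L, -1L)
}

#' Precision, recall and F-measure
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F = harmonic mean of the
#' two.  A zero denominator yields 0 (with a message), so a fold with no
#' predicted or no true positives scores 0 rather than NA.
#'
#' @param predicted,truth integer vectors in `{+1, -1}` of equal length
#' @return list of class `prf`: `precision`, `recall`, `fmeasure`, and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
precision_recall_f <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth have different lengths")
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == -1L)
  fn <- sum(predicted == -1L & truth == 1L)
  tn <- sum(predicted == -1L & truth == -1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    message("precision undefined (no predicted positives); reported as 0"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    message("recall undefined (no true positives); reported as 0"); 0 }
  fmeasure <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, fmeasure = fmeasure,
                 tp = tp, fp = fp, fn = fn, tn = tn), class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F %.4f  (TP %d FP %d FN %d)\n",
              x$precision, x$recall, x$fmeasure, x$tp, x$fp, x$fn))
  invisible(x)
}
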