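# Stratified k-fold cross-validation of the pair classifier, the parameter
# grid, and the linear-kernel feature-contribution analysis.
#
# Protocol: folds are stratified on the class label and drawn from a fixed
# seed; within each fold the feature scaler is fit on the training rows
# only, the combined Gram matrix is rebuilt from the scaled features and the
# domain-composition classes, and precision/recall/F are averaged
# arithmetically over folds (mean of per-fold F, not F of pooled counts).

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10)
#' @param seed RNG seed for the fold draw
#' @param stratified keep the class ratio balanced across folds (default
#'   TRUE; with few positives unstratified folds easily lose the positive
#'   class entirely)
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, seed = 1L, stratified = TRUE) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "cv_config")
}

#' Deterministic (optionally stratified) fold assignment
#'
#' @param labels integer labels in `{+1, -1}`
#' @param cv a [cv_config()]
#' @return integer fold id per example, in `1..n_folds`.
#' @export
cv_folds <- function(labels, cv = cv_config()) {
  n <- length(labels)
  if (cv$n_folds > n) stop("more folds than examples")
  with_seed(cv$seed, {
    fold <- integer(n)
    groups <- if (cv$stratified) split(seq_len(n), labels) else list(seq_len(n))
    offset <- 0L
    for (g in groups) {
      sh <- if (length(g) > 1L) sample(g) else g
      fold[sh] <- ((offset + seq_along(sh) - 1L) %% cv$n_folds) + 1L
      offset <- offset + length(sh)   # stagger so small strata spread out
    }
    fold
  })
}

#' Fit the heterodimer classifier on a full labelled feature table
#'
#' @param features labelled feature table from [feature_matrix()] (columns
#'   `protein_a`, `protein_b`, `F1..F7`, `label`)
#' @param domains a [domain_annotation()]; required when `kernel$alpha > 0`
#' @param kernel a [kernel_config()]
#' @param train a [training_config()]
#' @param cv ignored here; present for symmetry with [cross_validate()]
#' @param scale min-max scale features to `[0, 1]` before the linear kernel
#'   (default TRUE)
#' @param feature_set feature subset, e.g. `"F1-7"`, `"F1-5"`, `"F1-5,7"`
#' @return object of class `hd_model` wrapping the fitted [svc_fit()] model
#'   together with the scaler, the scaled training features, the
#'   composition keys and the kernel configuration.
#' @export
hd_fit <- function(features, domains = NULL, kernel = kernel_config(),
                   train = training_config(), scale = TRUE,
                   feature_set = "F1-7") {
  X <- feature_columns(features, feature_set)
  labels <- features$label
  sc <- if (scale) scale_features(X) else
    list(train = as.matrix(X), min = rep(0, ncol(X)), range = rep(1, ncol(X)))
  keys <- composition_keys(features, domains, kernel)
  K <- gram_from_parts(sc$train, keys, kernel)
  m <- svc_fit(K, labels, train)
  structure(list(svc = m, scaler = sc[c("min", "range")], scaled = scale,
                 X = sc$train, keys = keys, labels = labels,
                 kernel = kernel, train = train,
                 feature_set = parse_feature_set(feature_set)),
            class = "hd_model")
}

composition_keys <- function(features, domains, kernel) {
  if (kernel$alpha == 0) return(NULL)
  if (is.null(domains))
    stop("domains annotation is required when alpha > 0")
  vapply(seq_len(nrow(features)), function(i)
    set_composition_key(c(features$protein_a[[i]], features$protein_b[[i]]),
                        domains, kernel$unannotated), "")
}

gram_from_parts <- function(X, keys, kernel, X2 = NULL, keys2 = NULL) {
  lin <- if (is.null(X2)) tcrossprod(X) else tcrossprod(X2, X)
  kd <- if (is.null(keys)) 0 else if (is.null(keys2))
    outer(keys, keys, `==`) + 0 else outer(keys2, keys, `==`) + 0
  combine_grams(lin, kd, kernel)
}

apply_scaler <- function(model, X) {
  if (!model$scaled) return(as.matrix(X))
  m <- sweep(as.matrix(X), 2L, model$scaler$min, "-")
  pos <- model$scaler$range > 0
  m[, pos] <- sweep(m[, pos, drop = FALSE], 2L, model$scaler$range[pos], "/")
  m[, !pos] <- 0
  m
}

#' Predict heterodimer labels or decision values for new pairs
#'
#' @param object an [hd_fit()] model
#' @param features feature table for the new pairs (same columns as used at
#'   fit time)
#' @param domains a [domain_annotation()]; required when the model's
#'   `alpha > 0`
#' @param type `"class"` for +1/-1 labels, `"decision"` for raw values
#' @param ... unused
#' @return integer labels or numeric decision values.
#' @exportS3Method stats::predict
#' @export
predict.hd_model <- function(object, features, domains = NULL,
                             type = c("class", "decision"), ...) {
  type <- match.arg(type)
  Xn <- apply_scaler(object, feature_columns(features, object$feature_set))
  keys2 <- if (is.null(object$keys)) NULL else
    composition_keys(features, domains, object$kernel)
  Kx <- gram_from_parts(object$X, object$keys, object$kernel, Xn, keys2)
  if (type == "decision") svc_decision(object$svc, Kx)
  else svc_predict(object$svc, Kx)
}

#' @export
print.hd_model <- function(x, ...) {
  cat("hd_model:", paste(x$feature_set, collapse = ","),
      "| alpha =", x$kernel$alpha, x$kernel$form,
      "| C+ =", x$train$c_plus, "C- =", x$train$c_minus, "\n")
  print(x$svc)
  invisible(x)
}

#' Cross-validated precision/recall/F of the pair classifier
#'
#' @inheritParams hd_fit
#' @param cv a [cv_config()]
#' @return object of class `cv_result`: `mean` (named vector of averaged
#'   precision, recall, F), `folds` (per-fold data.frame) and the
#'   configurations used.
#' @export
cross_validate <- function(features, domains = NULL, kernel = kernel_config(),
                           train = training_config(), cv = cv_config(),
                           scale = TRUE, feature_set = "F1-7") {
  X <- feature_columns(features, feature_set)
  labels <- features$label
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1")
  keys <- composition_keys(features, domains, kernel)
  fold <- cv_folds(labels, cv)
  per <- vector("list", cv$n_folds)
  for (f in seq_len(cv$n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!any(labels[te] == 1L))
      warning("fold ", f, " contains no positive example; its recall is 0")
    sc <- if (scale) scale_features(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      else list(train = as.matrix(X[tr, , drop = FALSE]),
                apply = as.matrix(X[te, , drop = FALSE]))
    ktr <- keys[tr]; kte <- keys[te]
    K <- gram_from_parts(sc$train, ktr, kernel)
    m <- svc_fit(K, labels[tr], train)
    Kx <- gram_from_parts(sc$train, ktr, kernel, sc$apply, kte)
    p <- precision_recall_f(svc_predict(m, Kx), labels[te])
    per[[f]] <- data.frame(fold = f, precision = p$precision,
                           recall = p$recall, fmeasure = p$fmeasure,
                           tp = p$tp, fp = p$fp, fn = p$fn)
  }
  folds <- do.call(rbind, per)
  structure(list(
    mean = c(precision = mean(folds$precision), recall = mean(folds$recall),
             fmeasure = mean(folds$fmeasure)),
    folds = folds, kernel = kernel, train = train, cv = cv,
    feature_set = parse_feature_set(feature_set)), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (%s, alpha = %g, C+ = %g, C- = %g): P %.3f  R %.3f  F %.3f\n",
    x$cv$n_folds, paste(x$feature_set, collapse = ","), x$kernel$alpha,
    x$train$c_plus, x$train$c_minus,
    x$mean[["precision"]], x$mean[["recall"]], x$mean[["fmeasure"]]))
  invisible(x)
}

#' Grid search over mixing and class-penalty parameters
#'
#' Runs one [cross_validate()] per `(alpha, c_plus, c_minus)` triple (the
#' Gram matrix is rebuilt for every `alpha`).  The best triple by averaged
#' F-measure is reported, ties broken by higher precision, then lower
#' `alpha`.
#'
#' @inheritParams cross_validate
#' @param alpha_grid,cplus_grid,cminus_grid non-empty numeric grids.  The
#'   defaults cover the parameter values printed in the study this package
#'   operationalises: `alpha` from 0 to 1 in steps of 0.1, `C+` in
#'   {0.5, 1, 2, 4}, `C-` in {0.25, 0.5, 1}.
#' @param form combination form passed to [kernel_config()]
#' @return data.frame of class `grid_result` with one row per triple and
#'   columns `feature_set, alpha, c_plus, c_minus, precision, recall,
#'   fmeasure`; attribute `best` holds the selected row.
#' @export
grid_search <- function(features, domains = NULL,
                        alpha_grid = seq(0, 1, by = 0.1),
                        cplus_grid = c(0.5, 1, 2, 4),
                        cminus_grid = c(0.25, 0.5, 1),
                        cv = cv_config(), form = "convex", scale = TRUE,
                        feature_set = "F1-7") {
  stopifnot(length(alpha_grid) > 0, length(cplus_grid) > 0,
            length(cminus_grid) > 0)
  grid <- expand.grid(alpha = alpha_grid, c_plus = cplus_grid,
                      c_minus = cminus_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- cross_validate(features, domains,
                          kernel_config(grid$alpha[[i]], form = form),
                          training_config(grid$c_plus[[i]], grid$c_minus[[i]]),
                          cv, scale, feature_set)
    data.frame(feature_set = paste(res$feature_set, collapse = ","),
               alpha = grid$alpha[[i]], c_plus = grid$c_plus[[i]],
               c_minus = grid$c_minus[[i]],
               precision = res$mean[["precision"]],
               recall = res$mean[["recall"]],
               fmeasure = res$mean[["fmeasure"]])
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$fmeasure, -out$precision, out$alpha)
  attr(out, "best") <- out[ord[[1]], ]
  class(out) <- c("grid_result", class(out))
  out
}

#' Per-feature contribution of the linear decision function
#'
#' For a model trained with `alpha = 0` (pure linear kernel) the primal
#' weights `w = sum_i y_i a_i x_i` exist; the contribution of feature `k`
#' is `w_k * xbar_k`, the weight times the mean (scaled) feature value over
#' the training dataset.  Features are ranked by `|w_k * xbar_k|`
#' descending.
#'
#' @param model an [hd_fit()] model with `kernel$alpha == 0`
#' @param features optional scaled feature matrix over which to average;
#'   defaults to the model's training matrix
#' @return data.frame `feature, weight, mean, product, rank`, ordered by
#'   rank.
#' @export
feature_contributions <- function(model, features = NULL) {
  if (model$kernel$alpha != 0)
    stop("primal feature weights are only defined for alpha = 0 ",
         "(the indicator kernel part has no feature-space coordinates)")
  X <- if (is.null(features)) model$X else as.matrix(features)
  w <- colSums(model$svc$coef * model$X[model$svc$sv, , drop = FALSE])
  xbar <- colMeans(X)
  product <- w * xbar
  out <- data.frame(feature = colnames(model$X), weight = w, mean = xbar,
                    product = product, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$product)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
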