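#' AUC feature filter
#'
#' First stage of the nested waterfall selection: each feature, used raw as
#' a score for the positive (non-DF) class, gets a rank-statistic AUC
#' (midranks for ties); features with AUC below the cutoff are dropped,
#' AUC exactly at the cutoff is kept. By default the orientation is not
#' folded; with `fold_auc = TRUE` the criterion is
#' `max(AUC, 1 - AUC) >= cutoff`.
#'
#' @param values `n x d` training feature matrix.
#' @param labels Training labels (factor DF/non-DF); both classes required.
#' @param auc_cutoff Minimum AUC (default 0.60).
#' @param fold_auc Fold AUC orientation before thresholding.
#' @return Integer vector of kept column indices, with the per-feature AUCs
#'   as attribute `"auc"`. If no feature passes, the 10 features farthest
#'   from AUC 0.5 are returned with a loud warning.
#' @export
select_features_auc <- function(values, labels, auc_cutoff = 0.60,
                                fold_auc = FALSE) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) {
    stop("select_features_auc: both classes required (degenerate labels)")
  }
  np <- sum(pos); nn <- sum(!pos)
  auc <- apply(values, 2, function(x) {
    r <- rank(x)
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  })
  crit <- if (fold_auc) pmax(auc, 1 - auc) else auc
  kept <- which(crit >= auc_cutoff)
  if (!length(kept)) {
    warning("select_features_auc: no feature reached the AUC cutoff; ",
            "falling back to the top 10 by |AUC - 0.5|")
    kept <- order(-abs(auc - 0.5))[seq_len(min(10L, length(auc)))]
    kept <- sort(kept)
  }
  attr(kept, "auc") <- auc
  kept
}

#' Fit the PCA stage of the waterfall selector
#'
#' Standardizes the kept features with training statistics, fits principal
#' axes on training rows only, and keeps the minimal number of components
#' whose cumulative explained variance reaches `variance_threshold`
#' (default 80%). Zero-variance features are dropped with a warning before
#' fitting.
#'
#' @param values `n x d` training feature matrix.
#' @param kept Column indices from [select_features_auc()].
#' @param variance_threshold Explained-variance threshold in `(0, 1]`.
#' @return A fitted `waterfall_selector`: kept indices, training
#'   mean/scale, PCA loadings, `n_components`.
#' @export
reduce_pca <- function(values, kept, variance_threshold = 0.80) {
  stopifnot(nrow(values) >= 2L, length(kept) >= 1L)
  sub <- values[, kept, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  zv <- sds == 0
  if (any(zv)) {
    warning(sprintf("reduce_pca: dropping %d zero-variance feature(s)", sum(zv)))
    kept <- kept[!zv]
    sub <- sub[, !zv, drop = FALSE]
    sds <- sds[!zv]
    if (!length(kept)) stop("reduce_pca: no non-constant feature left")
  }
  mu <- colMeans(sub)
  scaled <- sweep(sweep(sub, 2, mu), 2, sds, "/")
  pc <- stats::prcomp(scaled, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  p <- which(cum >= variance_threshold - 1e-9)[1]
  structure(list(kept = kept, train_mean = mu, train_scale = sds,
                 loadings = pc$rotation[, seq_len(p), drop = FALSE],
                 n_components = p,
                 explained_variance = cum[p],
                 variance_threshold = variance_threshold),
            class = "waterfall_selector")
}

#' Fit the full waterfall selector (AUC filter then PCA)
#'
#' @inheritParams select_features_auc
#' @inheritParams reduce_pca
#' @return A `waterfall_selector` (see [reduce_pca()]), with the AUC stage's
#'   cutoff recorded.
#' @export
fit_waterfall <- function(values, labels, auc_cutoff = 0.60,
                          variance_threshold = 0.80, fold_auc = FALSE) {
  kept <- select_features_auc(values, labels, auc_cutoff, fold_auc)
  sel <- reduce_pca(values, kept, variance_threshold)
  sel$auc_cutoff <- auc_cutoff
  sel
}

#' @export
print.waterfall_selector <- function(x, ...) {
  cat(sprintf("Waterfall selector: %d features kept -> %d components (%.1f%% variance)\n",
              length(x$kept), x$n_components, 100 * x$explained_variance))
  invisible(x)
}

#' Apply a fitted waterfall selector
#'
#' @param object A `waterfall_selector`.
#' @param newdata Feature matrix with the original columns.
#' @param ... Unused.
#' @return `n x p` component matrix.
#' @export
predict.waterfall_selector <- function(object, newdata, ...) {
  sub <- newdata[, object$kept, drop = FALSE]
  scaled <- sweep(sweep(sub, 2, object$train_mean), 2, object$train_scale, "/")
  scaled %*% object$loadings
}

# RBF-SVM with class-balanced weights plus Platt (sigmoid) calibration of
# the decision values, fitted on training rows only.
fit_platt_svm <- function(x, labels, cost = 1, gamma = NULL) {
  y <- droplevels(as_outcome(labels))
  if (nlevels(y) < 2L) stop("fit SVM: both classes required (degenerate labels)")
  tab <- table(y)
  wts <- sum(tab) / (2 * tab)
  gamma <- gamma %||% (1 / (ncol(x) * stats::var(as.vector(x))))
  m <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                  class.weights = stats::setNames(as.numeric(wts), names(tab)),
                  scale = FALSE)
  d <- as.numeric(attr(stats::predict(m, x, decision.values = TRUE),
                       "decision.values"))
  calib <- suppressWarnings(
    stats::glm(as_positive(y) ~ d, family = stats::binomial()))
  structure(list(svm = m, calib = calib, gamma = gamma, cost = cost),
            class = "platt_svm")
}

#' @exportS3Method stats::predict
predict.platt_svm <- function(object, newdata, ...) {
  d <- as.numeric(attr(stats::predict(object$svm, newdata,
                                      decision.values = TRUE),
                       "decision.values"))
  unname(clip(stats::predict(object$calib, data.frame(d = d),
                             type = "response"), 0, 1))
}

#' Train an RBF-SVM on selected components and score test crops
#'
#' Radial-basis SVM (`C = 1`, `gamma = 1 / (p * var)` by default) with
#' class-balanced weights, followed by sigmoid (Platt) calibration fitted
#' on the training decision values; scores are calibrated probabilities of
#' the positive (non-DF) class in `[0, 1]`. The procedure is deterministic.
#'
#' @param train_components,test_components Component matrices from
#'   [predict.waterfall_selector()].
#' @param train_labels Training labels.
#' @param rng_seed Accepted for interface stability; the fit is
#'   deterministic and does not consume randomness.
#' @param cost,gamma SVM hyperparameters.
#' @return Numeric test scores in `[0, 1]`, with the fitted model attached
#'   as attribute `"model"`.
#' @export
fit_score_svm <- function(train_components, train_labels, test_components,
                          rng_seed = 1L, cost = 1, gamma = NULL) {
  model <- fit_platt_svm(train_components, train_labels, cost, gamma)
  scores <- predict(model, test_components)
  attr(scores, "model") <- model
  scores
}

#' Fit the per-backend crop classifier
#'
#' The deep-model head: waterfall selection (AUC filter at 0.60, PCA to 80%
#' explained variance) fitted on training crops only, then the calibrated
#' RBF-SVM of [fit_score_svm()].
#'
#' @inheritParams fit_waterfall
#' @inheritParams fit_score_svm
#' @return An object of class `crop_classifier` with `selector` and `svm`;
#'   use [predict.crop_classifier()] for crop scores.
#' @export
fit_crop_classifier <- function(values, labels, auc_cutoff = 0.60,
                                variance_threshold = 0.80, fold_auc = FALSE,
                                cost = 1, gamma = NULL, rng_seed = 1L) {
  selector <- fit_waterfall(values, labels, auc_cutoff, variance_threshold,
                            fold_auc)
  comps <- predict(selector, values)
  svm <- fit_platt_svm(comps, labels, cost, gamma)
  structure(list(selector = selector, svm = svm, rng_seed = rng_seed),
            class = "crop_classifier")
}

#' @export
print.crop_classifier <- function(x, ...) {
  print(x$selector)
  cat(sprintf("RBF-SVM: cost %g, gamma %.4g, %d support vectors\n",
              x$svm$cost, x$svm$gamma, x$svm$svm$tot.nSV))
  invisible(x)
}

#' Score crops with a fitted crop classifier
#'
#' @param object A `crop_classifier`.
#' @param newdata Raw feature matrix (original columns).
#' @param ... Unused.
#' @return Calibrated scores in `[0, 1]`, higher = more non-DF-like.
#' @export
predict.crop_classifier <- function(object, newdata, ...) {
  predict(object$svm, predict(object$selector, newdata))
}
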