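#' Vote-score aggregation of crop scores to a slide score
#'
#' The slide (and, with one slide per patient, the patient) score is the
#' 75th percentile (linear interpolation) of the slide's crop-score
#' distribution.
#'
#' @param scores Crop scores of one slide (non-empty).
#' @param prob Percentile level (default 75).
#' @return The slide score.
#' @examples
#' aggregate_slide_score(c(0.1, 0.2, 0.3, 0.4))  # 0.325
#' @export
aggregate_slide_score <- function(scores, prob = 75) {
  if (!length(scores)) {
    stop("aggregate_slide_score: missing slide (no retained crop scores)")
  }
  percentile(scores, prob)
}

#' Ensemble threshold from the training class balance
#'
#' The ensemble cut `th` is the training-set fraction of positive-class
#' (non-DF) patients rounded to two decimals; for a 12/43 split this is
#' 0.28.
#'
#' @param labels Training outcome labels.
#' @return `th` in `[0, 1]`.
#' @export
ensemble_threshold <- function(labels) {
  round(mean(as_positive(labels)), 2)
}

#' Three-model ensemble rule
#'
#' If the scores of at least two of the three deep models strictly exceed
#' `th`, the maximum of the three is the final score; otherwise the
#' minimum. Vectorized over patients; permutation-invariant in its three
#' arguments; the output is always one of the inputs.
#'
#' @param s_res,s_dense,s_incep Patient scores in `[0, 1]` from the three
#'   backend models.
#' @param th Ensemble threshold (default 0.28; see [ensemble_threshold()]).
#' @return Combined patient scores.
#' @examples
#' ensemble_combine(0.9, 0.5, 0.1)   # 0.9 (two exceed 0.28 -> max)
#' ensemble_combine(0.1, 0.2, 0.9)   # 0.1 (only one exceeds -> min)
#' @export
ensemble_combine <- function(s_res, s_dense, s_incep, th = 0.28) {
  S <- cbind(s_res, s_dense, s_incep)
  n_over <- rowSums(S > th)
  out <- ifelse(n_over >= 2, apply(S, 1, max), apply(S, 1, min))
  unname(out)
}

#' Soft voting
#'
#' Arithmetic mean of two model scores.
#'
#' @param score_a,score_b Scores in `[0, 1]` (vectorized).
#' @return The averaged score.
#' @export
soft_vote <- function(score_a, score_b) {
  stopifnot(all(score_a >= 0 & score_a <= 1), all(score_b >= 0 & score_b <= 1))
  (score_a + score_b) / 2
}

# One-hot encoder for the clinical covariates, categories fixed from the
# training fold; age standardized by training statistics; unseen test
# categories map to all-zero indicators.
clinical_covariates <- c("gender", "tumor_site", "stage", "T")

fit_clinical_encoder <- function(train) {
  levels_list <- lapply(clinical_covariates, function(v) {
    sort(unique(as.character(train[[v]])))
  })
  names(levels_list) <- clinical_covariates
  mu <- mean(train$age)
  sdv <- stats::sd(train$age)
  if (is.na(sdv) || sdv == 0) sdv <- 1
  list(levels = levels_list, age_mean = mu, age_sd = sdv)
}

apply_clinical_encoder <- function(encoder, records) {
  blocks <- lapply(clinical_covariates, function(v) {
    lv <- encoder$levels[[v]]
    x <- as.character(records[[v]])
    ind <- vapply(lv, function(l) as.numeric(x == l), numeric(nrow(records)))
    if (nrow(records) == 1L) ind <- matrix(ind, nrow = 1L)
    colnames(ind) <- paste(v, lv, sep = "=")
    ind
  })
  age <- (records$age - encoder$age_mean) / encoder$age_sd
  cbind(do.call(cbind, blocks), age = age)
}

#' Fit the clinical SVM and score test patients
#'
#' An RBF-SVM on the clinical covariates (gender, tumor site, stage, T
#' one-hot encoded with training-fold categories; age standardized), with
#' balanced class weights and sigmoid-calibrated scores, mirroring the
#' crop-level classifier.
#'
#' @param train,test Data frames of patient records with the clinical
#'   covariates, `patient_id` and (for `train`) `outcome`.
#' @param rng_seed Accepted for interface stability; the fit is
#'   deterministic.
#' @param cost,gamma SVM hyperparameters.
#' @return Test-patient scores in `[0, 1]`, named by `patient_id`, with the
#'   fitted model as attribute `"model"`.
#' @export
fit_clinical_model <- function(train, test, rng_seed = 1L, cost = 1,
                               gamma = NULL) {
  encoder <- fit_clinical_encoder(train)
  Xtr <- apply_clinical_encoder(encoder, train)
  model <- fit_platt_svm(Xtr, train$outcome, cost, gamma)
  Xte <- apply_clinical_encoder(encoder, test)
  scores <- predict(model, Xte)
  names(scores) <- test$patient_id
  attr(scores, "model") <- list(encoder = encoder, svm = model)
  scores
}
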