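#' Patient-level cross-validation plan
#'
#' Builds a k-fold plan repeated over independent rounds, stratified by
#' outcome (recommended with heavy class imbalance so every test fold has
#' positives). Folds partition the patients within each round; all crops of
#' a patient inherit the patient's fold downstream.
#'
#' @param patient_ids Character vector of patient ids.
#' @param labels Outcome labels aligned with `patient_ids`.
#' @param k Folds per round (default 5).
#' @param rounds Rounds (default 5).
#' @param rng_seed Integer seed; the plan is deterministic given the seed.
#' @param stratify Stratify folds by outcome (default `TRUE`).
#' @return An object of class `cv_plan` with `assignments` (data.frame:
#'   patient_id, round, fold) and the plan parameters.
#' @export
make_cv_splits <- function(patient_ids, labels, k = 5L, rounds = 5L,
                           rng_seed = 1L, stratify = TRUE) {
  n <- length(patient_ids)
  if (k > n) stop("make_cv_splits: k exceeds the number of patients")
  labels <- as_outcome(labels)
  assignments <- do.call(rbind, lapply(seq_len(rounds), function(r) {
    fold <- with_local_seed(derive_seed(rng_seed, "cv", r), {
      f <- integer(n)
      if (stratify) {
        pos_idx <- sample(which(as_positive(labels)))
        neg_idx <- sample(which(!as_positive(labels)))
        ordered <- c(pos_idx, neg_idx)    # deal positives first, then negatives,
        ptr <- 0L                          # continuing round-robin across classes
        for (i in ordered) {
          f[i] <- (ptr %% k) + 1L
          ptr <- ptr + 1L
        }
      } else {
        f <- ((seq_len(n) - 1L) %% k) + 1L
        f <- f[sample.int(n)]
      }
      relabel <- sample.int(k)            # randomize which fold is which
      relabel[f]
    })
    data.frame(patient_id = patient_ids, round = r, fold = fold,
               stringsAsFactors = FALSE)
  }))
  structure(list(assignments = assignments, k = as.integer(k),
                 rounds = as.integer(rounds), rng_seed = rng_seed,
                 stratify = stratify),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("CV plan: %d folds x %d rounds over %d patients (%s)\n",
              x$k, x$rounds, length(unique(x$assignments$patient_id)),
              if (x$stratify) "stratified" else "unstratified"))
  invisible(x)
}

#' Youden-index operating threshold
#'
#' Scans all ROC operating points (midpoints between consecutive distinct
#' scores, plus cuts below and above the score range; prediction rule
#' `score > threshold`) and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`. Ties go to the highest-sensitivity
#' point, then the smaller threshold.
#'
#' @param scores Patient scores.
#' @param labels Outcome labels (both classes required).
#' @return The threshold, with `J`, `sensitivity`, `specificity`
#'   attributes.
#' @export
youden_threshold <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) {
    stop("youden_threshold: both classes required (degenerate labels)")
  }
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  sens <- vapply(cand, function(t) mean(scores[pos] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!pos] <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cand[best])]
  structure(cand[best], J = J[best], sensitivity = sens[best],
            specificity = spec[best])
}

#' Classification metrics at a threshold
#'
#' Confusion counts with `score > threshold` predicting non-DF (the
#' positive class), plus the metric suite for imbalanced binary endpoints:
#' accuracy, sensitivity, specificity, precision, F1 (harmonic mean of
#' sensitivity and precision), G-mean `sqrt(sensitivity * specificity)`,
#' and the threshold-free rank-statistic AUC.
#'
#' @param scores Patient scores.
#' @param labels Outcome labels.
#' @param threshold Operating threshold; [youden_threshold()] when `NULL`.
#' @return An object of class `metrics_report` (a named list of the counts
#'   and metrics).
#' @examples
#' # 3 non-DF all caught, 3 of 8 DF miscalled:
#' m <- compute_metrics(c(.9, .9, .9, .9, .9, .9, rep(.1, 5)),
#'                      c(rep("non-DF", 3), rep("DF", 8)), threshold = 0.5)
#' round(100 * m$accuracy, 1)  # 72.7
#' round(100 * m$g_mean, 1)    # 79.1
#' @export
compute_metrics <- function(scores, labels, threshold = NULL) {
  if (!length(scores)) stop("compute_metrics: empty input")
  stopifnot(length(scores) == length(labels))
  pos <- as_positive(labels)
  if (is.null(threshold)) threshold <- youden_threshold(scores, labels)
  pred <- scores > threshold
  tp <- sum(pred & pos); tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && (sens + prec) > 0) 2 * sens * prec / (sens + prec) else 0
  auc <- if (any(pos) && any(!pos)) rank_auc(scores, pos) else NA_real_
  structure(list(auc = auc, threshold = as.numeric(threshold),
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(scores),
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, g_mean = sqrt(sens * spec)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "AUC %.3f | threshold %.3f | TP %d TN %d FP %d FN %d\n",
    "accuracy %.3f  sensitivity %.3f  specificity %.3f  precision %.3f  ",
    "F1 %.3f  G-mean %.3f\n"),
    x$auc, x$threshold, x$tp, x$tn, x$fp, x$fn, x$accuracy, x$sensitivity,
    x$specificity, x$precision, x$f1, x$g_mean))
  invisible(x)
}

#' Association tests between clinical covariates and outcome
#'
#' Two-sided Wilcoxon-Mann-Whitney for age (continuous); Pearson
#' chi-squared on the contingency table for the categorical/ordinal
#' covariates. Significance is flagged at 0.05. Constant covariates are
#' skipped with a note.
#'
#' @param records Patient records with the clinical covariates.
#' @param outcomes Outcome labels; defaults to `records$outcome`.
#' @return A data.frame: covariate, test, p_value, significant, note.
#' @export
association_tests <- function(records, outcomes = records$outcome) {
  outcomes <- as_outcome(outcomes)
  pos <- as_positive(outcomes)
  rows <- lapply(c("age", clinical_covariates), function(v) {
    x <- records[[v]]
    if (length(unique(x)) < 2L) {
      return(data.frame(covariate = v, test = NA_character_,
                        p_value = NA_real_, significant = NA,
                        note = "constant covariate; test skipped"))
    }
    if (v == "age") {
      p <- stats::wilcox.test(x[pos], x[!pos])$p.value
      test <- "wilcoxon"
    } else {
      tab <- table(as.character(x), ifelse(pos, "non-DF", "DF"))
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi-squared"
    }
    data.frame(covariate = v, test = test, p_value = p,
               significant = p < 0.05, note = "")
  })
  do.call(rbind, rows)
}

backend_model_name <- function(backend_name) {
  switch(backend_name,
         resnet50 = "ResSVM", densenet201 = "DenseSVM",
         inceptionv3 = "InceptionSVM", toy = "ToySVM",
         paste0(backend_name, "SVM"))
}

#' Cross-validate the full prognosis pipeline on extracted features
#'
#' Patient-stratified k-fold cross-validation repeated over independent
#' rounds. Per fold and backend: the waterfall selector and RBF-SVM are
#' fitted on training-fold crops only, test crops are scored, and each test
#' patient receives the 75th percentile of their crop scores. With three or
#' more backends the first three are combined per patient by the ensemble
#' rule into `DeepSVM`; with `clinical` supplied, the clinical SVM is
#' cross-validated on the same folds and soft-voted with `DeepSVM`.
#' Per-round metrics use predictions pooled over the round's test folds,
#' with a Youden-index threshold; summaries are medians and interquartile
#' ranges across rounds.
#'
#' @param features An `mp_features` or a list of them (one per backend).
#' @param clinical Optional data.frame of patient records (enables the
#'   `Clinical` and `DeepSVM+Clinical` models).
#' @param k,rounds,rng_seed,stratify Cross-validation plan; see
#'   [make_cv_splits()].
#' @param auc_cutoff,variance_threshold,fold_auc Waterfall selection
#'   parameters; see [fit_waterfall()].
#' @param cost,gamma SVM hyperparameters.
#' @param percentile Vote-score aggregation percentile (default 75).
#' @param th Fixed ensemble threshold; when `NULL` (default) it is
#'   recomputed per training fold as the rounded non-DF fraction.
#' @return An object of class `dfs_cv`: `patient_scores` and `crop_scores`
#'   data.frames, `metrics` per (model, round), `crop_auc` per (backend
#'   model, round), `summary` of medians/IQRs, and the `plan`.
#' @export
crossval <- function(features, clinical = NULL, k = 5L, rounds = 5L,
                     rng_seed = 1L, stratify = TRUE, auc_cutoff = 0.60,
                     variance_threshold = 0.80, fold_auc = FALSE, cost = 1,
                     gamma = NULL, percentile = 75, th = NULL) {
  if (inherits(features, "mp_features")) features <- list(features)
  stopifnot(length(features) >= 1L,
            all(vapply(features, inherits, logical(1), "mp_features")))
  names(features) <- vapply(features, function(f) f$backend$name, character(1))
  ref <- features[[1]]
  patients <- unique(ref$patient_id)
  plab <- as_outcome(ref$label[match(patients, ref$patient_id)])
  if (!is.null(clinical)) {
    clinical <- clinical[match(patients, clinical$patient_id), , drop = FALSE]
  }
  plan <- make_cv_splits(patients, plab, k, rounds, rng_seed, stratify)

  crop_rows <- list(); patient_rows <- list()
  for (r in seq_len(rounds)) {
    asg <- plan$assignments[plan$assignments$round == r, ]
    for (f in seq_len(k)) {
      test_p <- asg$patient_id[asg$fold == f]
      train_p <- setdiff(patients, test_p)
      if (!length(test_p)) next
      train_lab <- plab[match(train_p, patients)]
      th_fold <- th %||% ensemble_threshold(train_lab)
      fold_scores <- list()
      for (bname in names(features)) {
        fm <- features[[bname]]
        tr <- fm$patient_id %in% train_p
        te <- fm$patient_id %in% test_p
        clf <- fit_crop_classifier(fm$values[tr, , drop = FALSE],
                                   fm$label[tr], auc_cutoff,
                                   variance_threshold, fold_auc, cost, gamma,
                                   rng_seed = derive_seed(rng_seed, r, f, bname))
        sc <- predict(clf, fm$values[te, , drop = FALSE])
        crop_rows[[length(crop_rows) + 1L]] <- data.frame(
          crop_id = fm$crop_id[te], patient_id = fm$patient_id[te],
          fold = f, round = r, backend = bname, score = sc,
          label = as.character(fm$label[te]), stringsAsFactors = FALSE)
        by_pat <- split(sc, fm$patient_id[te])
        slide_scores <- vapply(by_pat, aggregate_slide_score, numeric(1),
                               prob = percentile)
        pres <- intersect(test_p, names(slide_scores))
        if (length(pres) < length(test_p)) {
          warning(sprintf("round %d fold %d: patient(s) %s lost all crops and are excluded",
                          r, f, paste(setdiff(test_p, pres), collapse = ", ")))
        }
        fold_scores[[backend_model_name(bname)]] <- slide_scores[pres]
        patient_rows[[length(patient_rows) + 1L]] <- data.frame(
          patient_id = pres, model = backend_model_name(bname), fold = f,
          round = r, score = unname(slide_scores[pres]),
          label = as.character(plab[match(pres, patients)]),
          stringsAsFactors = FALSE)
      }
      if (length(features) >= 3L) {
        trio <- fold_scores[vapply(names(features)[1:3], backend_model_name,
                                   character(1))]
        common <- Reduce(intersect, lapply(trio, names))
        if (length(common)) {
          ens <- ensemble_combine(trio[[1]][common], trio[[2]][common],
                                  trio[[3]][common], th = th_fold)
          names(ens) <- common
          fold_scores[["DeepSVM"]] <- ens
          patient_rows[[length(patient_rows) + 1L]] <- data.frame(
            patient_id = common, model = "DeepSVM", fold = f, round = r,
            score = unname(ens),
            label = as.character(plab[match(common, patients)]),
            stringsAsFactors = FALSE)
        }
      }
      if (!is.null(clinical)) {
        tr_rec <- clinical[clinical$patient_id %in% train_p, , drop = FALSE]
        te_rec <- clinical[clinical$patient_id %in% test_p, , drop = FALSE]
        cs <- fit_clinical_model(tr_rec, te_rec,
                                 rng_seed = derive_seed(rng_seed, r, f, "clin"))
        patient_rows[[length(patient_rows) + 1L]] <- data.frame(
          patient_id = te_rec$patient_id, model = "Clinical", fold = f,
          round = r, score = unname(cs),
          label = as.character(plab[match(te_rec$patient_id, patients)]),
          stringsAsFactors = FALSE)
        if (!is.null(fold_scores[["DeepSVM"]])) {
          common <- intersect(names(fold_scores[["DeepSVM"]]), names(cs))
          comb <- soft_vote(fold_scores[["DeepSVM"]][common], cs[common])
          patient_rows[[length(patient_rows) + 1L]] <- data.frame(
            patient_id = common, model = "DeepSVM+Clinical", fold = f,
            round = r, score = unname(comb),
            label = as.character(plab[match(common, patients)]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  patient_scores <- do.call(rbind, patient_rows)
  crop_scores <- do.call(rbind, crop_rows)

  metrics <- do.call(rbind, lapply(split(
    patient_scores, patient_scores[c("model", "round")], drop = TRUE),
    function(d) {
      m <- compute_metrics(d$score, d$label)
      data.frame(model = d$model[1], round = d$round[1],
                 as.data.frame(unclass(m)), stringsAsFactors = FALSE)
    }))
  rownames(metrics) <- NULL
  crop_auc <- do.call(rbind, lapply(split(
    crop_scores, crop_scores[c("backend", "round")], drop = TRUE),
    function(d) data.frame(model = backend_model_name(d$backend[1]),
                           round = d$round[1],
                           auc = rank_auc(d$score, d$label),
                           stringsAsFactors = FALSE)))
  rownames(crop_auc) <- NULL

  metric_cols <- c("auc", "accuracy", "sensitivity", "specificity",
                   "precision", "f1", "g_mean")
  summary <- do.call(rbind, lapply(split(metrics, metrics$model), function(d) {
    stats_row <- lapply(metric_cols, function(mc) {
      q <- stats::quantile(d[[mc]], c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
      stats::setNames(c(q[2], q[3] - q[1]), paste0(mc, c("_median", "_iqr")))
    })
    data.frame(model = d$model[1], t(unlist(stats_row)),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  structure(list(patient_scores = patient_scores, crop_scores = crop_scores,
                 metrics = metrics, crop_auc = crop_auc, summary = summary,
                 plan = plan,
                 config = list(k = k, rounds = rounds, rng_seed = rng_seed,
                               auc_cutoff = auc_cutoff,
                               variance_threshold = variance_threshold,
                               cost = cost, gamma = gamma,
                               percentile = percentile, th = th,
                               backends = names(features))),
            class = "dfs_cv")
}

#' @export
print.dfs_cv <- function(x, ...) {
  cat(sprintf("Cross-validated DFS prognosis: %d folds x %d rounds, backends: %s\n",
              x$config$k, x$config$rounds,
              paste(x$config$backends, collapse = ", ")))
  cat("Median AUC across rounds:\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.3f\n", s$model[i], s$auc_median[i]))
  }
  invisible(x)
}

#' @export
summary.dfs_cv <- function(object, ...) {
  object$summary
}

#' Median patient-level AUC of one model
#'
#' @param cv A `dfs_cv`.
#' @param model Model name (default the first backend's model).
#' @return Median across rounds of the per-round pooled AUC.
#' @export
median_auc <- function(cv, model = NULL) {
  model <- model %||% backend_model_name(cv$config$backends[1])
  stats::median(cv$metrics$auc[cv$metrics$model == model])
}

#' Render, preprocess and featurize a whole synthetic cohort
#'
#' Convenience driver over [render_slide()], [preprocess_slide()] and
#' [extract_features()], one patient at a time (slides are discarded after
#' feature extraction so memory stays flat).
#'
#' @param cohort An `mp_cohort`.
#' @param backends List of [feature_backend()] specs.
#' @param opts A [preprocess_options()].
#' @param verbose Print progress.
#' @return Named list of `mp_features`, one per backend.
#' @export
build_cohort_features <- function(cohort, backends = list(feature_backend("toy")),
                                  opts = preprocess_options(), verbose = FALSE) {
  stopifnot(inherits(cohort, "mp_cohort"))
  if (inherits(backends, "feature_backend")) backends <- list(backends)
  parts <- lapply(backends, function(b) list())
  names(parts) <- vapply(backends, function(b) b$name, character(1))
  for (i in seq_len(nrow(cohort$clinical))) {
    p <- cohort$clinical[i, ]
    sl <- render_slide(p, cohort$config)
    crops <- preprocess_slide(sl, opts = opts)
    if (verbose) {
      message(sprintf("%s (%s): %d crops", p$patient_id, p$outcome,
                      length(crops$crops)))
    }
    if (!length(crops$crops)) {
      warning(sprintf("patient %s produced no crops", p$patient_id))
      next
    }
    for (b in seq_along(backends)) {
      parts[[b]][[i]] <- extract_features(crops, backends[[b]])
    }
  }
  lapply(parts, function(pl) rbind_features(pl[!vapply(pl, is.null, logical(1))]))
}

#' Run a full synthetic-cohort experiment
#'
#' Generates the cohort, renders and preprocesses every slide, extracts
#' features for each configured backend, and cross-validates the pipeline.
#'
#' @param config An `experiment_config` (see [experiment_config()]), or a
#'   path to a YAML file for [read_experiment_config()].
#' @param verbose Print progress.
#' @return An object of class `dfs_experiment`: the `dfs_cv` result plus
#'   `cohort` and `features`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort)
  features <- build_cohort_features(cohort, config$backends,
                                    config$preprocess, verbose = verbose)
  cv <- do.call(crossval, c(list(features = features,
                                 clinical = if (config$eval$include_clinical)
                                   cohort$clinical),
                            config$eval[setdiff(names(config$eval),
                                                "include_clinical")]))
  structure(list(cv = cv, cohort = cohort, features = features,
                 config = config),
            class = "dfs_experiment")
}

#' @export
print.dfs_experiment <- function(x, ...) {
  print(x$cohort)
  print(x$cv)
  invisible(x)
}

#' @export
summary.dfs_experiment <- function(object, ...) summary(object$cv)

#' External validation: train on one cohort, test on another
#'
#' Fits every configured model on the full training cohort and evaluates
#' once on the held-out cohort (the design used to validate on an
#' independent institutional cohort).
#'
#' @param train_features,test_features `mp_features` lists (same backends).
#' @param train_clinical,test_clinical Optional clinical records.
#' @param ... Model parameters as in [crossval()].
#' @param th Fixed ensemble threshold; recomputed from the training labels
#'   when `NULL`.
#' @param percentile Vote-score aggregation percentile.
#' @return A list with per-model `metrics` (class `metrics_report`) and
#'   `patient_scores`.
#' @export
external_validate <- function(train_features, test_features,
                              train_clinical = NULL, test_clinical = NULL,
                              th = NULL, percentile = 75, ...) {
  if (inherits(train_features, "mp_features")) train_features <- list(train_features)
  if (inherits(test_features, "mp_features")) test_features <- list(test_features)
  opts <- list(...)
  train_lab_all <- train_features[[1]]$label
  train_patients <- unique(train_features[[1]]$patient_id)
  th <- th %||% ensemble_threshold(
    train_lab_all[match(train_patients, train_features[[1]]$patient_id)])
  scores <- list()
  for (b in seq_along(train_features)) {
    tr <- train_features[[b]]; te <- test_features[[b]]
    clf <- do.call(fit_crop_classifier,
                   c(list(values = tr$values, labels = tr$label), opts))
    sc <- predict(clf, te$values)
    by_pat <- split(sc, te$patient_id)
    scores[[backend_model_name(tr$backend$name)]] <-
      vapply(by_pat, aggregate_slide_score, numeric(1), prob = percentile)
  }
  if (length(scores) >= 3L) {
    common <- Reduce(intersect, lapply(scores[1:3], names))
    ens <- ensemble_combine(scores[[1]][common], scores[[2]][common],
                            scores[[3]][common], th = th)
    names(ens) <- common
    scores[["DeepSVM"]] <- ens
  }
  if (!is.null(train_clinical) && !is.null(test_clinical)) {
    cs <- fit_clinical_model(train_clinical, test_clinical)
    scores[["Clinical"]] <- cs
    if (!is.null(scores[["DeepSVM"]])) {
      common <- intersect(names(scores[["DeepSVM"]]), names(cs))
      scores[["DeepSVM+Clinical"]] <- soft_vote(scores[["DeepSVM"]][common],
                                                cs[common])
    }
  }
  te1 <- test_features[[1]]
  te_lab <- as_outcome(te1$label[match(names(scores[[1]]), te1$patient_id)])
  metrics <- lapply(names(scores), function(m) {
    lab <- as_outcome(te1$label[match(names(scores[[m]]), te1$patient_id)])
    compute_metrics(unname(scores[[m]]), lab)
  })
  names(metrics) <- names(scores)
  ps <- do.call(rbind, lapply(names(scores), function(m) {
    data.frame(patient_id = names(scores[[m]]), model = m,
               score = unname(scores[[m]]),
               label = as.character(as_outcome(
                 te1$label[match(names(scores[[m]]), te1$patient_id)])),
               stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, patient_scores = ps, th = th)
}

#' Experiment configuration
#'
#' Bundles the cohort, preprocessing, backend and evaluation settings with
#' every pipeline constant at its standard value (224-pixel tiles,
#' 90th-percentile density filter, 50 crops, Luma 170 / 25% background
#' rule, AUC cutoff 0.60, 80% PCA variance, 75th-percentile vote score,
#' ensemble threshold from the training class balance, 5 folds x 5
#' rounds).
#'
#' @param cohort A [cohort_config()].
#' @param backends List of [feature_backend()] specs.
#' @param preprocess A [preprocess_options()].
#' @param eval Named list of [crossval()] arguments plus
#'   `include_clinical`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              backends = list(feature_backend("toy")),
                              preprocess = preprocess_options(),
                              eval = list()) {
  if (inherits(backends, "feature_backend")) backends <- list(backends)
  eval_defaults <- list(k = 5L, rounds = 5L, rng_seed = cohort$seed,
                        stratify = TRUE, auc_cutoff = 0.60,
                        variance_threshold = 0.80, fold_auc = FALSE,
                        cost = 1, gamma = NULL, percentile = 75, th = NULL,
                        include_clinical = FALSE)
  eval <- utils::modifyList(eval_defaults, eval, keep.null = TRUE)
  structure(list(cohort = cohort, backends = backends,
                 preprocess = preprocess, eval = eval),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Sections `cohort`, `preprocess`, `features` (list of backend names or
#' `{name, dim}`), and `eval`; every omitted field takes its standard
#' default.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  preprocess <- do.call(preprocess_options, y$preprocess %||% list())
  backends <- lapply(y$features %||% list("toy"), function(b) {
    if (is.character(b)) feature_backend(b)
    else do.call(feature_backend, b)
  })
  experiment_config(cohort, backends, preprocess, y$eval %||% list())
}
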