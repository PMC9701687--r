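test_that("stratified CV folds partition patients with balanced sizes", {
  ids <- sprintf("P%02d", 1:43)
  labels <- c(rep("non-DF", 12), rep("DF", 31))
  plan <- make_cv_splits(ids, labels, k = 5, rounds = 5, rng_seed = 3)
  for (r in 1:5) {
    asg <- plan$assignments[plan$assignments$round == r, ]
    expect_setequal(asg$patient_id, ids)            # every patient tests once
    expect_equal(sort(as.vector(table(asg$fold))), c(8L, 8L, 9L, 9L, 9L))
    pos_per_fold <- table(asg$fold[asg$patient_id %in% ids[1:12]])
    expect_true(all(pos_per_fold >= 2))             # 12 positives over 5 folds
  }
  expect_identical(make_cv_splits(ids, labels, 5, 5, rng_seed = 3)$assignments,
                   plan$assignments)
  expect_false(identical(
    make_cv_splits(ids, labels, 5, 5, rng_seed = 4)$assignments$fold,
    plan$assignments$fold))
  expect_error(make_cv_splits(ids[1:4], labels[1:4], k = 5), "k exceeds")
})

test_that("Youden threshold maximizes J with the stated tie-breaks", {
  # separable case reaches J = 1
  t1 <- youden_threshold(c(0.9, 0.8, 0.1, 0.2),
                         c("non-DF", "non-DF", "DF", "DF"))
  expect_equal(attr(t1, "J"), 1)
  expect_true(t1 > 0.2 && t1 < 0.8)

  # constant scores: J = 0 at every cut
  t2 <- youden_threshold(rep(0.5, 6), rep(c("DF", "non-DF"), 3))
  expect_equal(attr(t2, "J"), 0)

  set.seed(19)
  for (i in 1:15) {
    scores <- round(runif(20), 2)
    pos <- runif(20) < 0.4
    if (!any(pos) || all(pos)) next
    th <- youden_threshold(scores, ifelse(pos, "non-DF", "DF"))
    expect_equal(attr(th, "J"), brute_youden_j(scores, pos))
  }
  expect_error(youden_threshold(runif(5), rep("DF", 5)), "degenerate")
})

test_that("metric suite matches the printed validation worked example", {
  # 3 non-DF (all above threshold), 8 DF of which 3 misclassified:
  scores <- c(0.9, 0.85, 0.8, 0.7, 0.65, 0.6, rep(0.1, 5))
  labels <- c(rep("non-DF", 3), rep("DF", 8))
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(3L, 5L, 3L, 0L))
  expect_equal(round(100 * m$accuracy, 1), 72.7)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.625)
  expect_equal(round(100 * m$g_mean, 1), 79.1)
  expect_equal(round(100 * m$f1, 1), 66.7)
})

test_that("metric identities hold over random confusion configurations", {
  perfect <- compute_metrics(c(0.9, 0.9, 0.1, 0.1),
                             c("non-DF", "non-DF", "DF", "DF"), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$g_mean, 1)

  none <- compute_metrics(c(0.1, 0.2, 0.3), c("non-DF", "DF", "DF"), 0.9)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_equal(none$g_mean, 0)

  set.seed(20)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- runif(n)
    labels <- ifelse(runif(n) < 0.4, "non-DF", "DF")
    if (length(unique(labels)) < 2) next
    m <- compute_metrics(scores, labels, threshold = runif(1))
    expect_equal(m$tp + m$tn + m$fp + m$fn, n)
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    expect_equal(m$specificity, m$tn / (m$tn + m$fp))
    expect_equal(m$g_mean, sqrt(m$sensitivity * m$specificity))
    expect_equal(m$auc, rank_auc(scores, labels == "non-DF"))
  }
  expect_error(compute_metrics(numeric(0), character(0)), "empty")
})

test_that("rank AUC and Youden agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- runif(40)
  labels <- ifelse(runif(40) < 0.35, "non-DF", "DF")
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("DF", "non-DF"), direction = "<", quiet = TRUE)
  expect_equal(rank_auc(scores, labels == "non-DF"), as.numeric(pROC::auc(roc)))
  th <- youden_threshold(scores, labels)
  best <- pROC::coords(roc, "best", best.method = "youden", transpose = FALSE)
  expect_equal(attr(th, "J"),
               max(best$sensitivity + best$specificity - 1))
})

test_that("association tests use the exact Wilcoxon and chi-squared forms", {
  rec <- data.frame(age = c(1, 2, 3, 100, 101, 102),
                    gender = rep(c("Male", "Female"), 3),
                    tumor_site = rep("Trunk", 6),
                    stage = c("I", "I", "I", "III", "III", "III"),
                    T = rep("T2", 6),
                    outcome = c(rep("non-DF", 3), rep("DF", 3)))
  res <- association_tests(rec)
  expect_equal(res$p_value[res$covariate == "age"], 0.1)   # exact permutation
  expect_true(res$p_value[res$covariate == "stage"] < 0.05)  # [[3,0],[0,3]]
  expect_equal(res$note[res$covariate == "tumor_site"],
               "constant covariate; test skipped")

  # diagonal 2x2 table is decisively significant
  rec2 <- data.frame(age = rnorm(20, 50),
                     gender = c(rep("Male", 10), rep("Female", 10)),
                     tumor_site = rep(c("Trunk", "Other"), 10),
                     stage = rep("II", 20),
                     T = rep("T2", 20),
                     outcome = c(rep("non-DF", 10), rep("DF", 10)))
  res2 <- association_tests(rec2)
  expect_lt(res2$p_value[res2$covariate == "gender"], 0.01)
})

test_that("association tests are calibrated under the null", {
  set.seed(42)
  n_sig <- 0L
  for (i in 1:100) {
    rec <- data.frame(age = rnorm(200, 60, 10),
                      gender = sample(c("Male", "Female"), 200, TRUE),
                      tumor_site = rep("Trunk", 200),
                      stage = sample(c("I", "II", "III"), 200, TRUE),
                      T = rep("T2", 200),
                      outcome = sample(c("DF", "non-DF"), 200, TRUE))
    res <- association_tests(rec)
    n_sig <- n_sig + sum(res$significant[res$covariate == "age"])
  }
  expect_lte(n_sig, 10L)
})
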