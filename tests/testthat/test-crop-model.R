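test_that("AUC filter keeps discriminative features and drops the rest", {
  labels <- rep(c("non-DF", "DF"), each = 5)
  perfect <- c(6:10, 1:5)                 # identical ordering to the label
  constant <- rep(1, 10)
  # positives sit at ranks 2,4,6,8,10 -> AUC exactly 0.60
  at_cutoff <- numeric(10)
  at_cutoff[c(1, 3, 5, 7, 9)] <- c(2, 4, 6, 8, 10)   # positives
  at_cutoff[c(2, 4, 6, 8, 10)] <- c(1, 3, 5, 7, 9)   # negatives
  labels_alt <- rep(c("non-DF", "DF"), 5)
  values <- cbind(perfect, constant)
  kept <- select_features_auc(values, labels)
  expect_equal(as.integer(kept), 1L)
  expect_equal(attr(kept, "auc")[[1]], 1.0)
  expect_equal(attr(kept, "auc")[[2]], 0.5)

  kept_at <- select_features_auc(cbind(x = at_cutoff), labels_alt)
  expect_equal(attr(kept_at, "auc")[[1]], 0.6)
  expect_equal(as.integer(kept_at), 1L)   # AUC exactly at the cutoff is kept

  expect_error(select_features_auc(values, rep("DF", 10)), "degenerate")
})

test_that("empty AUC selection falls back to the top-10 with a warning", {
  set.seed(77)
  values <- matrix(rnorm(200 * 20), 200)
  labels <- rep(c("DF", "non-DF"), 100)
  expect_warning(kept <- select_features_auc(values, labels, auc_cutoff = 0.99),
                 "falling back")
  expect_length(kept, 10L)
})

test_that("rank AUC agrees with brute-force pair counting", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(round(runif(n), 2))   # includes ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(rank_auc(scores, pos), brute_auc(scores, pos))
  }
})

test_that("PCA stage keeps the minimal component count at 80% variance", {
  # single direction of variance -> one component suffices
  set.seed(9)
  one_axis <- outer(rnorm(30), c(1, 2, -1))
  sel1 <- reduce_pca(one_axis + 5, 1:3)
  expect_equal(sel1$n_components, 1L)

  # 10 exactly-equal eigenvalues (Helmert frame) -> 8 components reach 80%
  helmert <- stats::contr.helmert(11)
  sel8 <- reduce_pca(helmert, 1:10)
  expect_equal(sel8$n_components, 8L)

  # transform of the training mean row is the zero vector
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  sel <- reduce_pca(X, 1:4, variance_threshold = 0.99)
  centered <- predict(sel, matrix(colMeans(X), 1))
  expect_equal(as.numeric(centered), rep(0, sel$n_components))

  # zero-variance features are dropped with a warning
  Xz <- cbind(X, 7)
  expect_warning(selz <- reduce_pca(Xz, 1:5), "zero-variance")
  expect_false(5L %in% selz$kept)
})

test_that("selector transforms are fitted on and reproducible from training rows", {
  set.seed(11)
  X <- matrix(rnorm(300), 50, 6)
  y <- rep(c("DF", "non-DF"), 25)
  X[, 1] <- X[, 1] + 2 * (y == "non-DF")
  sel <- fit_waterfall(X, y, auc_cutoff = 0.5, variance_threshold = 0.9)
  expect_identical(predict(sel, X), predict(sel, X))
  expect_equal(ncol(predict(sel, X[1:3, , drop = FALSE])), sel$n_components)
})

test_that("the calibrated RBF-SVM separates well-separated blobs", {
  set.seed(12)
  n <- 200
  train <- rbind(matrix(rnorm(n, 0), n / 2, 2),
                 matrix(rnorm(n, 6), n / 2, 2))
  labels <- rep(c("DF", "non-DF"), each = n / 2)
  test <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
  test_lab <- rep(c(FALSE, TRUE), each = 50)
  scores <- fit_score_svm(train, labels, test)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_gte(rank_auc(scores, test_lab), 0.99)

  # identical test rows get identical scores; fit is deterministic
  same <- fit_score_svm(train, labels, test[c(1, 1, 1), , drop = FALSE])
  expect_equal(same[1], same[2])
  expect_equal(same[2], same[3])
  scores2 <- fit_score_svm(train, labels, test)
  expect_identical(as.numeric(scores), as.numeric(scores2))

  expect_error(fit_score_svm(train, rep("DF", n), test), "degenerate")
})

test_that("crop scores stay in the null band under label permutation", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    X <- matrix(rnorm(900 * 12), 900, 12)
    y <- sample(rep(c("DF", "non-DF"), each = 450))
    tr <- 1:500; te <- 501:900
    clf <- suppressWarnings(
      fit_crop_classifier(X[tr, ], y[tr], auc_cutoff = 0.55))
    auc <- rank_auc(predict(clf, X[te, ]), y[te] == "non-DF")
    expect_gte(auc, 0.4)
    expect_lte(auc, 0.6)
  }
})

test_that("test-fold scores do not depend on other test rows", {
  set.seed(13)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- rep(c("DF", "non-DF"), 100)
  X[, 2] <- X[, 2] + (y == "non-DF")
  clf <- suppressWarnings(fit_crop_classifier(X[1:150, ], y[1:150],
                                              auc_cutoff = 0.5))
  te <- X[151:200, ]
  s_all <- predict(clf, te)
  perm <- sample.int(50)
  s_perm <- predict(clf, te[perm, ])
  expect_equal(s_perm, s_all[perm], tolerance = 1e-12)
  s_single <- predict(clf, te[7, , drop = FALSE])
  expect_equal(s_single, s_all[7], tolerance = 1e-12)
})
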