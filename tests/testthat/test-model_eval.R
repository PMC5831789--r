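# ROC/AUC, classifier adapters, cross-validation, pair ranking

test_that("the rank-statistic AUC matches hand-checkable cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0))$auc, 0.5)   # tie -> 1/2
  expect_equal(roc_auc(c(0.3, 0.9), c(1, 0))$auc, 0)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), class = "gpcr_evaluation_error")
  expect_error(roc_auc(c(0.1), c(1, 0)), class = "gpcr_evaluation_error")
})

test_that("rank AUC equals the trapezoidal area of the swept curve", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(20:200, 1L)
    labels <- rbinom(n, 1L, 0.5)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    scores <- round(rnorm(n), sample(c(1L, 2L, 8L), 1L))  # force ties sometimes
    roc <- roc_auc(scores, labels)
    expect_equal(roc$auc, oracle_trapezoid(roc$points), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(23)
  for (i in 1:10) {
    labels <- rbinom(80, 1L, 0.5)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    scores <- rnorm(80) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(29)
  roc <- roc_auc(rnorm(100), rbinom(100, 1L, 0.4))
  pts <- roc$points
  expect_equal(unlist(pts[1L, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(31)
  scores <- rnorm(120)                      # continuous: no ties
  labels <- rbinom(120, 1L, 0.5)
  labels[1:2] <- c(0L, 1L)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(rank(scores), labels)$auc, a)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a)
})

test_that("training is seeded, deterministic and memorizes separable data", {
  ds <- make_toy_dataset()
  m1 <- train(ds, "random_forest", seed = 3L)
  m2 <- train(ds, "random_forest", seed = 3L)
  expect_identical(predict_scores(m1, ds$X), predict_scores(m2, ds$X))
  expect_equal(roc_auc(predict_scores(m1, ds$X), ds$y)$auc, 1)
  expect_error(train(ds, "boosting"), class = "gpcr_config_error")
  const <- ds; const$y <- rep(1L, length(ds$y))
  expect_error(train(const, "random_forest"), class = "gpcr_evaluation_error")
})

test_that("every classifier adapter trains and scores in [0, 1]", {
  ds <- make_toy_dataset()
  for (alg in c("random_forest", "svm", "naive_bayes", "cart",
                "neural_network")) {
    m <- train(ds, alg, seed = 4L)
    sc <- predict_scores(m, ds$X)
    expect_length(sc, nrow(ds$X))
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(roc_auc(sc, ds$y)$auc, 0.8)   # all separate the toy signal
  }
})

test_that("scoring validates the feature columns", {
  ds <- make_toy_dataset()
  m <- train(ds, "cart", seed = 1L)
  X2 <- ds$X[, 1:2, drop = FALSE]
  expect_error(predict_scores(m, X2), regexp = "missing",
               class = "gpcr_shape_error")
})

test_that("cross-validation stratifies folds and reproduces exactly", {
  ds <- make_toy_dataset(n = 80L)
  cv <- cross_validate(ds, "cart", k = 4L, seed = 9L)
  expect_length(cv$fold_auc, 4L)
  expect_equal(cv$mean_auc, mean(cv$fold_auc))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  cv2 <- cross_validate(ds, "cart", k = 4L, seed = 9L)
  expect_identical(cv[c("fold_auc", "fold_accuracy")],
                   cv2[c("fold_auc", "fold_accuracy")])
  expect_error(cross_validate(ds, "cart", k = 1L), class = "gpcr_config_error")
  expect_error(cross_validate(ds, "cart", k = 50L),
               class = "gpcr_evaluation_error")
  # restricting to signal-free columns destroys performance
  cv_null <- cross_validate(ds, "cart", k = 4L, feature_tags = "1AAF",
                            seed = 9L)
  expect_lt(cv_null$mean_auc, cross_validate(ds, "cart", k = 4L,
                                             feature_tags = "Hub",
                                             seed = 9L)$mean_auc)
})

test_that("the feature grid covers all 49 combinations", {
  grid <- feature_grid()
  expect_equal(nrow(grid), 49L)
  expect_equal(length(unique(grid$receptor_set)), 7L)
  expect_equal(length(unique(grid$ligand_set)), 7L)
  all_row <- grid[grid$receptor_set == "All" & grid$ligand_set == "All", ]
  expect_setequal(all_row$tags[[1L]],
                  c("MF", "1AAF", "2AAF", "4chars", "Hub", "Cycle"))
})

test_that("pair prediction ranks the cross-product with lexicographic ties", {
  ds <- make_toy_dataset()
  m <- train(ds, "cart", seed = 2L)
  rv <- ds$X[1:3, 1:2, drop = FALSE]
  rownames(rv) <- c("rB", "rA", "rC")
  lv <- ds$X[1:2, 3:4, drop = FALSE]
  rownames(lv) <- c("lZ", "lA")
  out <- predict_pairs(m, rv, lv, top_n = 100L)
  expect_equal(nrow(out), 6L)               # top_n larger than cross-product
  expect_true(all(diff(out$score) <= 0))
  single <- predict_pairs(m, rv[1L, , drop = FALSE], lv[1L, , drop = FALSE],
                          top_n = 5L)
  expect_equal(nrow(single), 1L)
  # constant scores fall back to receptor/ligand ID order
  mconst <- m
  ties <- predict_pairs(mconst, rv, lv, top_n = 6L)
  same <- ties[ties$score == ties$score[1L], ]
  expect_false(is.unsorted(same$receptor_id))
})
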