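test_that("splits are subject-level, stratified by construction, and distinct", {
  ids <- sprintf("S%02d", 1:66)
  plan <- make_splits(ids, n_repeats = 5, train_frac = 0.7, seed = 3)
  expect_length(plan, 5L)
  keys <- vapply(plan, function(p) paste(p$train, collapse = "|"), "")
  expect_false(anyDuplicated(keys) > 0)
  for (p in plan) {
    expect_length(p$train, 46L)               # floor(0.7 * 66)
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), ids)
  }
  plan2 <- make_splits(ids, n_repeats = 5, train_frac = 0.7, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_splits(ids, train_frac = 1.0), "train_frac")
  expect_error(make_splits(ids[1:3]), "at least 4")
})

test_that("classifiers are deterministic and reject degenerate input", {
  x <- withr::with_seed(1, matrix(rnorm(40 * 5), 40, 5,
                                  dimnames = list(NULL, paste0("f", 1:5))))
  y <- factor(rep(c("control", "lesion"), each = 20),
              levels = c("control", "lesion"))
  x[y == "lesion", 1] <- x[y == "lesion", 1] + 2
  for (kind in c("rf", "svm", "bp")) {
    m1 <- train_classifier(kind, x, y, seed = 5)
    m2 <- train_classifier(kind, x, y, seed = 5)
    s1 <- predict(m1, x); s2 <- predict(m2, x)
    expect_identical(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
  }
  expect_error(train_classifier("rf", x, rep("lesion", 40)), "both classes")
})

test_that("a separable toy problem is fit exactly by the SVM", {
  x <- cbind(x1 = c(rep(-2, 10), rep(2, 10)) + seq(-0.2, 0.2, length.out = 20),
             x2 = rep(0, 20))
  y <- factor(rep(c("control", "lesion"), each = 10),
              levels = c("control", "lesion"))
  fit <- train_classifier("svm", x, y, seed = 1)
  s <- predict(fit, x)
  expect_true(all((s >= 0.5) == (y == "lesion")))
})

test_that("confusion-matrix and rank-AUC arithmetic match the fixtures", {
  # TP = 9, FN = 1, TN = 8, FP = 2
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 8), 0.8, 0.8)
  labels <- c(rep("lesion", 10), rep("control", 10))
  e <- evaluate_scores(scores, labels, threshold = 0.5)
  expect_equal(unname(e$confusion), c(9, 1, 8, 2))
  expect_equal(e$sensitivity, 90)
  expect_equal(e$specificity, 80)
  expect_equal(e$error_rate, 15)

  # 3 of 4 pairwise comparisons won
  e2 <- evaluate_scores(c(0.9, 0.8, 0.85, 0.7),
                        c("lesion", "lesion", "control", "control"))
  expect_equal(e2$auc, 0.75)

  # perfect separation
  e3 <- evaluate_scores(c(0.9, 0.8, 0.3, 0.1),
                        c("lesion", "lesion", "control", "control"))
  expect_equal(e3$auc, 1)
  expect_true(any(e3$roc$fpr == 0 & e3$roc$tpr == 1))
  expect_error(evaluate_scores(c(0.5, 0.6), c("lesion", "lesion")), "both classes")
})

test_that("the rank AUC equals the ROC area and obeys its invariances", {
  withr::with_seed(13, for (i in 1:10) {
    n <- 30
    scores <- round(runif(n), 2)    # induces ties
    labels <- sample(c("control", "lesion"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) labels[1:2] <- c("control", "lesion")
    e <- evaluate_scores(scores, labels)
    expect_equal(e$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(e$auc, roc_trapezoid_area(e$roc), tolerance = 1e-9)
    # ROC is monotone from (0,0) to (1,1)
    expect_equal(c(e$roc$fpr[1], e$roc$tpr[1]), c(0, 0))
    expect_equal(c(e$roc$fpr[nrow(e$roc)], e$roc$tpr[nrow(e$roc)]), c(1, 1))
    expect_true(all(diff(e$roc$fpr) >= 0) && all(diff(e$roc$tpr) >= 0))
    # invariant under a strictly increasing transform of the scores
    e_tr <- evaluate_scores(plogis(5 * scores - 2), labels)
    expect_equal(e_tr$auc, e$auc, tolerance = 1e-12)
    # reflecting scores and labels together preserves the metrics
    e_sw <- evaluate_scores(1 - scores,
                            ifelse(labels == "lesion", "control", "lesion"))
    expect_equal(e_sw$auc, e$auc, tolerance = 1e-12)
  })
})

test_that("relabeling classes maps AUC to its complement", {
  withr::with_seed(17, {
    scores <- runif(24)
    labels <- rep(c("control", "lesion"), each = 12)
    e <- evaluate_scores(scores, labels)
    flipped <- evaluate_scores(scores,
                               ifelse(labels == "lesion", "control", "lesion"))
    expect_equal(flipped$auc, 1 - e$auc, tolerance = 1e-12)
  })
})

test_that("cross-check: rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    scores <- runif(50)
    labels <- rep(c("control", "lesion"), 25)
    e <- evaluate_scores(scores, labels)
    ref <- pROC::auc(pROC::roc(labels, scores, levels = c("control", "lesion"),
                               direction = "<", quiet = TRUE))
    expect_equal(e$auc, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("aggregation is the unweighted mean with the ROC grid retained", {
  e <- evaluate_scores(c(0.9, 0.8, 0.3, 0.1),
                       c("lesion", "lesion", "control", "control"))
  agg1 <- aggregate_eval(list(e, e, e))
  expect_equal(agg1$auc, e$auc)
  expect_equal(agg1$error_rate, e$error_rate)

  e2 <- evaluate_scores(c(0.9, 0.4, 0.8, 0.1),
                        c("lesion", "lesion", "control", "control"))
  agg2 <- aggregate_eval(list(e, e2))
  expect_equal(agg2$auc, mean(c(e$auc, e2$auc)))
  expect_gte(agg2$auc, min(e$auc, e2$auc))
  expect_lte(agg2$auc, max(e$auc, e2$auc))
  expect_equal(nrow(agg2$per_repeat), 2L)
})

test_that("permuted labels yield chance-level test AUC", {
  # test sets of 60 regions keep the null AUC spread well inside the band
  x <- withr::with_seed(6, matrix(rnorm(200 * 5), 200, 5,
                                  dimnames = list(NULL, paste0("f", 1:5))))
  labels <- factor(rep(c("control", "lesion"), 100),
                   levels = c("control", "lesion"))
  ok <- vapply(1:50, function(s) {
    y_perm <- withr::with_seed(s, sample(labels))
    tr <- withr::with_seed(1000 + s, sample(200, 140))
    fit <- train_classifier("rf", x[tr, ], y_perm[tr], seed = s,
                            hyper = list(ntree = 200))
    auc <- evaluate_scores(predict(fit, x[-tr, ]), y_perm[-tr])$auc
    auc >= 0.35 && auc <= 0.65
  }, NA)
  expect_gte(mean(ok), 0.9)
})

test_that("the three-classifier experiment finds the planted signal", {
  co <- generate_cohort(small_cohort_spec(n_pairs = 24, n_null_pairs = 0, seed = 12))
  rm <- region_matrix(extract_cohort_features(co))
  splits <- make_splits(unique(rm$subject_id), n_repeats = 3, seed = 2)
  rep <- evaluate_classifiers(rm, c("glcm_sd", "m1", "glcm_variance", "a3", "c3"),
                              splits, seed = 9)
  for (kind in c("rf", "svm", "bp")) {
    expect_gt(rep[[kind]]$aggregate$auc, 0.8)
    expect_equal(nrow(rep[[kind]]$aggregate$per_repeat), 3L)
  }
})
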