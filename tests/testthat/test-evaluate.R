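test_that("confusion counts partition instances and handle empty ratios", {
  cm <- confusion(c(-1, -1, 1, 1), c(-1, -1, 1, 1))
  expect_equal(cm[c("sensitivity", "specificity", "precision")],
               list(sensitivity = 1, specificity = 1, precision = 1))
  # all predicted positive
  cm <- confusion(rep(1, 6), c(1, 1, -1, -1, -1, -1))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
  # hand-computed 10-instance toy: TP=3 FN=1 TN=4 FP=2
  scores <- c(1, 1, 1, -1, 1, 1, -1, -1, -1, -1)
  labels <- c(1, 1, 1, 1, -1, -1, -1, -1, -1, -1)
  cm <- confusion(scores, labels)
  expect_equal(unlist(cm[c("TP", "FN", "TN", "FP")]),
               c(TP = 3, FN = 1, TN = 4, FP = 2))
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 4 / 6)
  expect_equal(cm$precision, 0.6)
  # undefined ratios are NA, never 0
  expect_true(is.na(confusion(c(-1, -1), c(-1, -1))$sensitivity))
  expect_true(is.na(confusion(c(-1, -1), c(-1, -1))$precision))
})

test_that("AUC ROC equals the brute-force concordant-pair count", {
  expect_equal(auc_roc(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    scores <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # forces ties
    labels <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    expect_equal(auc_roc(scores, labels), auc_bruteforce(scores, labels))
  }
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC ROC is monotone-invariant and sign-reversing", {
  set.seed(6)
  scores <- rnorm(50)
  labels <- c(rep(1, 20), rep(-1, 30))
  a <- auc_roc(scores, labels)
  expect_equal(auc_roc(2 * scores + 1, labels), a)
  expect_equal(auc_roc(tanh(scores), labels), a)
  expect_equal(auc_roc(-scores, labels), 1 - a)
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(80)
  labels <- c(rep(1, 30), rep(-1, 50))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(auc_roc(scores, labels), ref)
})

test_that("AUC PR is average precision over the threshold sweep", {
  expect_equal(auc_pr(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1)
  set.seed(8)
  for (i in 1:5) {
    scores <- rnorm(15)  # distinct almost surely
    labels <- c(1, -1, sample(c(-1, 1), 13, replace = TRUE))
    # with distinct scores, AP = mean over positives of precision at their rank
    ord <- order(scores, decreasing = TRUE)
    y <- labels[ord] > 0
    ap <- mean((cumsum(y) / seq_along(y))[y])
    expect_equal(auc_pr(scores, labels), ap)
  }
})

test_that("matched-specificity thresholds behave at both extremes", {
  scores <- c(5, 4, 3.5, 3, 2, 1.5, 1, 0.5)
  labels <- c(1, 1, 1, -1, -1, -1, -1, -1)
  t1 <- threshold_at_specificity(scores, labels, 1.0)
  expect_gt(t1$threshold, max(scores[labels < 0]))
  expect_equal(t1$specificity, 1)
  t0 <- threshold_at_specificity(scores, labels, 0)
  expect_equal(t0$sensitivity, 1)
  # 5 negatives, target 0.8: exactly one false positive admitted
  t8 <- threshold_at_specificity(scores, labels, 0.8)
  expect_identical(sum(scores[labels < 0] >= t8$threshold), 1L)
  expect_equal(t8$specificity, 0.8)
  expect_error(threshold_at_specificity(scores, labels, 1.5), "\\[0, 1\\]")
  expect_error(threshold_at_specificity(scores, rep(1, 8), 0.5), "negatives")
})

test_that("stratified folds preserve class proportions and reproduce", {
  y <- c(rep(1, 23), rep(-1, 77))
  f <- stratified_folds(y, 5, seed = 3)
  for (k in 1:5) {
    expect_true(abs(sum(y[f == k] > 0) - 23 / 5) <= 1)
    expect_true(abs(sum(y[f == k] < 0) - 77 / 5) <= 1)
  }
  expect_identical(f, stratified_folds(y, 5, seed = 3))
  expect_false(identical(f, stratified_folds(y, 5, seed = 4)))
})

test_that("model selection picks degree 2 when only it can fit the rule", {
  r <- make_rule(seed = 9, type = "xor")
  tr <- encoded_xy(sample_problem(r, 100, 100, 0, seed = 10))
  sel <- select_model(tr$x, tr$y, degrees = 1:2, costs = 1, outer_k = 3,
                      inner_k = 4, repeats = 1, seed = 2)
  expect_identical(sel$config$degree, 2L)
  expect_identical(nrow(sel$winners), 3L)
})

test_that("modal configuration ties break toward simpler models", {
  winners <- data.frame(outer_set = 1:4, degree = c(1L, 2L, 2L, 1L),
                        cost = c(10, 1, 1, 10), inner_auc = 0.9)
  cfg <- sh2pep:::modal_config(winners)
  expect_identical(cfg$degree, 1L)
  winners$cost <- c(10, 1, 10, 1)  # full tie across (d, C) pairs
  cfg <- sh2pep:::modal_config(winners)
  expect_identical(cfg$degree, 1L)
  expect_identical(cfg$cost, 1)
})

test_that("additive rules select the linear kernel in most runs", {
  deg <- vapply(1:8, function(s) {
    r <- make_rule(seed = 400 + s, n_pairwise = 0)
    tr <- encoded_xy(sample_problem(r, 250, 250, 0, seed = 500 + s))
    select_model(tr$x, tr$y, degrees = 1:2, costs = 1, outer_k = 3,
                 inner_k = 4, repeats = 1, seed = s)$config$degree
  }, integer(1))
  expect_gte(mean(deg == 1L), 0.7)
})
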