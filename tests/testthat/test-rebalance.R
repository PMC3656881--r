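test_that("excess negatives trigger positive duplication, no mining", {
  set.seed(2)
  pos <- encode_peptides(sh2pep:::random_windows(10))
  neg <- encode_peptides(sh2pep:::random_windows(100))
  res <- rebalance(list(positives = pos, negatives = neg, unlabeled = NULL))
  expect_identical(nrow(res$balanced_positives), 100L)
  expect_identical(nrow(res$balanced_negatives), 100L)
  expect_identical(res$n_iterations, 0L)
  expect_length(res$mined_idx, 0)
  # every duplicated row is one of the original positives
  expect_true(all(decode_peptides(res$balanced_positives) %in%
                    decode_peptides(pos)))
  expect_false(any(res$flags))
})

test_that("a balanced dataset is a fixed point", {
  set.seed(3)
  pos <- encode_peptides(sh2pep:::random_windows(50))
  neg <- encode_peptides(sh2pep:::random_windows(50))
  res <- rebalance(list(positives = pos, negatives = neg, unlabeled = NULL))
  expect_identical(res$balanced_positives, pos)
  expect_identical(res$balanced_negatives, neg)
  expect_identical(res$n_iterations, 0L)
})

test_that("excess positives are met by mining true negatives from the pool", {
  r <- make_rule(seed = 4, n_pairwise = 1)
  prob <- sample_problem(r, 150, 10, 1000, seed = 7)
  pool <- encode_peptides(prob$unlabeled)
  res <- rebalance(list(positives = encode_peptides(prob$positives),
                        negatives = encode_peptides(prob$negatives),
                        unlabeled = pool),
                   rebalance_config(seed = 1))
  expect_identical(nrow(res$balanced_negatives), 150L)
  expect_identical(nrow(res$balanced_positives), 150L)
  expect_length(res$mined_idx, 140)
  # pool monotonicity: nothing mined twice
  expect_identical(anyDuplicated(res$mined_idx), 0L)
  expect_identical(sum(res$trace$batch), 140L)
  expect_lte(res$n_iterations, rebalance_config()$max_iterations)
  # mined peptides overwhelmingly carry the hidden non-binding label
  purity <- mean(prob$hidden_labels[res$mined_idx] < 0)
  expect_gte(purity, 0.9)
  expect_false(any(res$flags))
  # the returned model is trained on the balanced data and usable
  te <- sample_problem(r, 50, 50, 0, seed = 8)
  dv <- decision_value(res$model,
                       encode_peptides(c(te$positives, te$negatives)))
  expect_gt(auc_roc(dv, c(rep(1, 50), rep(-1, 50))), 0.7)
})

test_that("pool exhaustion yields a flagged best-effort balance", {
  r <- make_rule(seed = 4, n_pairwise = 1)
  prob <- sample_problem(r, 60, 10, 20, seed = 9)
  expect_warning(
    res <- rebalance(list(positives = encode_peptides(prob$positives),
                          negatives = encode_peptides(prob$negatives),
                          unlabeled = encode_peptides(prob$unlabeled)),
                    rebalance_config(seed = 1)),
    NA)  # no warning, flag instead
  expect_true(res$flags["pool_exhausted"])
  expect_length(res$mined_idx, 20)
  expect_identical(nrow(res$balanced_negatives), 60L)  # topped up by copies
})

test_that("the loop always halts at max_iterations", {
  r <- make_rule(seed = 4, n_pairwise = 1)
  prob <- sample_problem(r, 60, 10, 500, seed = 9)
  res <- rebalance(list(positives = encode_peptides(prob$positives),
                        negatives = encode_peptides(prob$negatives),
                        unlabeled = encode_peptides(prob$unlabeled)),
                   rebalance_config(batch_fraction = 0.01,
                                    max_iterations = 3, seed = 1))
  expect_true(res$flags["max_iterations"])
  expect_identical(res$n_iterations, 3L)
  expect_length(res$mined_idx, 3)  # one per iteration at this fraction
})

test_that("degenerate inputs are rejected", {
  set.seed(5)
  pos <- encode_peptides(sh2pep:::random_windows(5))
  expect_error(rebalance(list(positives = pos, negatives = NULL,
                              unlabeled = NULL)), "at least one")
  neg <- encode_peptides(sh2pep:::random_windows(2))
  expect_error(rebalance(list(positives = pos, negatives = neg,
                              unlabeled = NULL)), "pool is empty")
  expect_error(rebalance_config(batch_fraction = 0))
})

test_that("self-training beats untreated specificity and random-resample
           sensitivity on imbalanced problems", {
  ok <- logical(6)
  for (s in seq_along(ok)) {
    r <- make_rule(seed = 1000 + s, n_pairwise = 1)
    prob <- sample_problem(r, 150, 10, 1000, seed = 2000 + s)
    te <- encoded_xy(sample_problem(r, 100, 100, 0, seed = 3000 + s))
    pos <- encode_peptides(prob$positives)
    neg <- encode_peptides(prob$negatives)
    pool <- encode_peptides(prob$unlabeled)
    ev <- function(m) confusion(decision_value(m, te$x), te$y)
    orig <- ev(svm_train(rbind(pos, neg), c(rep(1, 150), rep(-1, 10))))
    set.seed(s)
    rnd <- ev(svm_train(rbind(pos, neg, pool[sample(1000, 140), ]),
                        c(rep(1, 150), rep(-1, 150))))
    reb <- rebalance(list(positives = pos, negatives = neg, unlabeled = pool),
                     rebalance_config(seed = s))
    semi <- ev(reb$model)
    ok[s] <- semi$specificity > orig$specificity &&
      semi$sensitivity > rnd$sensitivity
  }
  expect_gte(mean(ok), 0.8)
})
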