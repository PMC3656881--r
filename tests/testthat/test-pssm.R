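test_that("weight matrix entries are positional frequency differences", {
  # positives all carry Pro at offset +3; background covers all 20 residues
  positives <- rep("AAYAAPA", 5)
  background <- paste0("AAYAA", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A")
  wm <- build_pssm(positives, background)
  expect_identical(dim(wm$W), c(19L, 6L))
  expect_equal(wm$W["P", "3"], 1 - 1 / 20)
  expect_true(all(wm$W[, "3"][rownames(wm$W) != "P"] <= 0))
  # identical populations give the null matrix
  wm0 <- build_pssm(background, background)
  expect_equal(max(abs(wm0$W)), 0)
  expect_error(build_pssm(character(0), background), "non-empty")
})

test_that("toy matrix equals hand-counted frequency differences", {
  positives <- c("KAYDAAA", "KAYDAAA", "KCYDAAA", "AAYDAAA")
  background <- c("KAYDAAA", "AAYAAAA", "DDYDDDD", "AAYAAAA",
                  "KKYKKKK", "AAYDAAA", "GGYGGGG", "AAYAAAA")
  wm <- build_pssm(positives, background)
  # offset -2: K in 3/4 positives vs 2/8 background
  expect_equal(wm$W["K", "-2"], 3 / 4 - 2 / 8)
  # offset +1: D in 4/4 positives vs 3/8 background
  expect_equal(wm$W["D", "1"], 1 - 3 / 8)
  # Cys never represented: 'C' at -1 in positives contributes nothing
  expect_false("C" %in% rownames(wm$W))
  # offset -1: A in 3/4 positives (the C drops out) vs 5/8 background
  expect_equal(wm$W["A", "-1"], 3 / 4 - 5 / 8)
})

test_that("raw scores are position-wise lookup sums", {
  positives <- c("KAYDAAA", "AAYDAAA")
  background <- c("GGYGGGG", "KKYKKKK", "AAYAAAA", "DDYDDDD")
  wm <- build_pssm(positives, background)
  set.seed(4)
  peps <- sh2pep:::random_windows(20)
  offsets <- c("-2", "-1", "1", "2", "3", "4")
  manual <- vapply(peps, function(p) {
    ch <- strsplit(p, "")[[1]][c(1, 2, 4, 5, 6, 7)]
    s <- 0
    for (j in 1:6)
      if (ch[j] %in% rownames(wm$W)) s <- s + wm$W[ch[j], offsets[j]]
    s
  }, numeric(1))
  expect_equal(pssm_raw_score(wm, peps), unname(manual))
  # zero matrix scores zero; pads contribute nothing
  wm0 <- wm; wm0$W[] <- 0
  expect_equal(pssm_raw_score(wm0, peps), rep(0, 20))
  expect_equal(pssm_raw_score(wm, "--YDAAA"),
               sum(wm$W[cbind(c("D", "A", "A", "A"), c("1", "2", "3", "4"))]))
})

test_that("reference calibration picks the top-percentile raw score", {
  # a frequency-difference matrix from large seeded populations gives an
  # effectively tie-free raw-score distribution
  set.seed(6)
  wm <- build_pssm(sh2pep:::random_windows(300), sh2pep:::random_windows(500))
  wins <- sh2pep:::random_windows(1000)
  cal <- calibrate_reference(wm, wins, percentile = 10)
  scores <- sort(pssm_raw_score(wm, wins), decreasing = TRUE)
  expect_equal(cal$s_ref, scores[100])  # the 100th-highest of 1000
  # at the default percentile, ceiling(0.045 N) windows reach the reference
  cal45 <- calibrate_reference(wm, wins, percentile = 4.5)
  expect_identical(sum(pssm_raw_score(wm, wins) >= cal45$s_ref),
                   as.integer(ceiling(0.045 * 1000)))
  expect_error(calibrate_reference(wm, wins[1:50]), "at least 100")
})

test_that("relative scores threshold at one, boundary inclusive", {
  wm <- build_pssm(c("KAYDAAA", "KAYDAAD"), c("GGYGGGG", "AAYAAAA"))
  expect_error(relative_score(wm, "KAYDAAA"), "not calibrated")
  set.seed(6)
  cal <- calibrate_reference(wm, sh2pep:::random_windows(1000))
  # a window scoring exactly at the reference is called binding
  at_ref <- cal$s_ref / cal$s_ref
  expect_equal(at_ref, 1)
  expect_identical(pssm_predict(cal, "KAYDAAA"),
                   ifelse(relative_score(cal, "KAYDAAA") >= 1, 1L, -1L))
  # zero raw score is non-binding
  expect_identical(pssm_predict(cal, "GGYGGGG"),
                   ifelse(relative_score(cal, "GGYGGGG") >= 1, 1L, -1L))
  expect_lt(relative_score(cal, "--Y----"), 1)
})

test_that("raw score is additive over disjoint position blocks", {
  wm <- build_pssm(c("KAYDAAA", "AAYDAAD"), c("GGYGGGG", "KKYKKKK"))
  set.seed(8)
  for (i in 1:10) {
    w <- sh2pep:::random_windows(1)
    left <- paste0(substr(w, 1, 2), "Y----")
    right <- paste0("--Y", substr(w, 4, 7))
    expect_equal(pssm_raw_score(wm, w),
                 pssm_raw_score(wm, left) + pssm_raw_score(wm, right))
  }
})

test_that("weight matrices round-trip through TSV with their sidecar", {
  wm <- build_pssm(c("KAYDAAA", "KAYDAAD"), c("GGYGGGG", "AAYAAAA"))
  set.seed(6)
  wm <- calibrate_reference(wm, sh2pep:::random_windows(500))
  path <- withr::local_tempfile(fileext = ".tsv")
  save_pssm(wm, path)
  wm2 <- load_pssm(path)
  expect_equal(wm2$W, wm$W)
  expect_equal(wm2$s_ref, wm$s_ref)
  expect_equal(wm2$percentile, 4.5)
})

test_that("the linear baseline cannot resolve mutual-exclusion binding", {
  r <- make_rule(seed = 3, type = "xor")
  tr <- sample_problem(r, 500, 500, 0, seed = 11)
  te <- sample_problem(r, 300, 300, 0, seed = 12)
  yt <- c(rep(1, 300), rep(-1, 300))
  wm <- build_pssm(tr$positives, c(tr$positives, tr$negatives))
  a <- auc_roc(pssm_raw_score(wm, c(te$positives, te$negatives)), yt)
  expect_gt(a, 0.4)
  expect_lt(a, 0.6)
})
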