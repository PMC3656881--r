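# shared fixtures: encoded train/test splits of synthetic problems

encoded_xy <- function(problem) {
  list(x = encode_peptides(c(problem$positives, problem$negatives)),
       y = c(rep(1L, length(problem$positives)),
             rep(-1L, length(problem$negatives))))
}

# a small separable additive problem reused by several model tests
small_additive <- function(seed = 5, n = 100) {
  r <- make_rule(seed = seed, n_pairwise = 0)
  list(rule = r,
       train = encoded_xy(sample_problem(r, n, n, 0, seed = seed + 100)),
       test = encoded_xy(sample_problem(r, n, n, 0, seed = seed + 200)))
}

# explicit quadratic feature map for the inhomogeneous kernel:
# phi(x) = (1, sqrt(2) x_i, x_i^2, sqrt(2) x_i x_j (i<j)) so that
# phi(x).phi(z) = (x.z + 1)^2
phi_quad <- function(x) {
  n <- length(x)
  cross <- if (n > 1) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    sqrt(2) * x[idx[, 1]] * x[idx[, 2]]
  } else numeric(0)
  c(1, sqrt(2) * x, x^2, cross)
}

# high-affinity binders under a rule: top-scoring sampled positives
strong_binders <- function(rule, k, seed) {
  p <- suppressWarnings(sample_problem(rule, 60, 0, 0, seed = seed))
  p$positives[order(-score_rule(rule, p$positives))][seq_len(k)]
}

# brute-force AUC ROC: concordant pairs over all pos x neg pairs, ties half
auc_bruteforce <- function(scores, labels) {
  p <- scores[labels > 0]; n <- scores[labels < 0]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}
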