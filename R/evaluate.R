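# Performance measures and the model-selection protocol.
#
# Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision = TP/(TP+FP);
# AUC ROC via the rank (Mann-Whitney) statistic with ties counted half; AUC
# PR as average precision over the threshold sweep. Model selection follows a
# nested protocol: an outer stratified 5-fold cross-validation repeated 5
# times (or repeated 75/25 random splits), an inner 10-fold cross-validation
# choosing (degree, cost) by AUC ROC on each outer training set, and the
# modal configuration across outer folds used for the final assessment.

#' Confusion counts and derived measures
#'
#' Predictions are positive when `score >= threshold`. Ratios with an empty
#' denominator are reported as `NA`, never as 0.
#'
#' @param scores numeric classifier scores.
#' @param labels +1/-1 (or logical) true labels.
#' @param threshold decision threshold (default 0).
#' @return list with `TP`, `TN`, `FP`, `FN`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
confusion <- function(scores, labels, threshold = 0) {
  if (is.logical(labels)) labels <- ifelse(labels, 1L, -1L)
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  pred <- scores >= threshold
  TP <- sum(pred & labels > 0); FN <- sum(!pred & labels > 0)
  TN <- sum(!pred & labels < 0); FP <- sum(pred & labels < 0)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       sensitivity = ratio(TP, TP + FN),
       specificity = ratio(TN, TN + FP),
       precision = ratio(TP, TP + FP))
}

check_two_class <- function(labels) {
  if (!any(labels > 0) || !any(labels < 0))
    stop("both classes must be present to compute a curve area")
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic: the probability that a
#' random positive outscores a random negative, with ties counted half.
#' Invariant under strictly monotone score transforms.
#'
#' @param scores numeric classifier scores.
#' @param labels +1/-1 (or logical) true labels.
#' @return AUC ROC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1L, -1L)
  stopifnot(length(scores) == length(labels))
  check_two_class(labels)
  n_pos <- sum(labels > 0); n_neg <- sum(labels < 0)
  r <- rank(scores)  # average ranks handle ties as half-concordant
  (sum(r[labels > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average precision over the full threshold sweep: precision at each distinct
#' score threshold weighted by the recall increment (step-wise interpolation,
#' unbiased under tied scores).
#'
#' @inheritParams auc_roc
#' @return AUC PR in \[0, 1\].
#' @export
auc_pr <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1L, -1L)
  stopifnot(length(scores) == length(labels))
  check_two_class(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord] > 0
  # group tied scores: curve points only at distinct thresholds
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  n_at <- seq_along(s)[last_of_group]
  recall <- tp / sum(y)
  precision <- tp / n_at
  sum(diff(c(0, recall)) * precision)
}

#' Threshold achieving a target specificity
#'
#' Returns the smallest threshold whose specificity (fraction of negatives
#' scored below it) reaches the target, plus the sensitivity at that
#' threshold -- the protocol used to compare sensitivities of different
#' scorers at a comparator's fixed specificity.
#'
#' @param scores numeric scores.
#' @param labels +1/-1 (or logical) true labels; negatives must be present.
#' @param target_specificity required specificity in \[0, 1\].
#' @return list with `threshold`, `sensitivity`, `specificity` (achieved).
#' @export
threshold_at_specificity <- function(scores, labels, target_specificity) {
  if (is.logical(labels)) labels <- ifelse(labels, 1L, -1L)
  stopifnot(length(scores) == length(labels))
  if (!any(labels < 0)) stop("negatives are required to set a specificity")
  if (target_specificity > 1 || target_specificity < 0)
    stop("target specificity must be in [0, 1]")
  neg <- scores[labels < 0]
  candidates <- sort(unique(scores))
  candidates <- c(candidates[1] - 1, candidates, max(scores) + 1)
  spec <- vapply(candidates, function(t) mean(neg < t), numeric(1))
  t_star <- candidates[which(spec >= target_specificity)[1]]
  pos <- scores[labels > 0]
  list(threshold = t_star,
       sensitivity = if (length(pos)) mean(pos >= t_star) else NA_real_,
       specificity = mean(neg < t_star))
}

#' Stratified fold assignment
#'
#' Assigns instances to `k` folds preserving the class proportions within
#' one instance per fold, reproducibly for a fixed seed.
#'
#' @param labels +1/-1 (or logical) labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  if (is.logical(labels)) labels <- ifelse(labels, 1L, -1L)
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    folds[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

# mean inner-CV AUC ROC of one (degree, cost) configuration
cv_auc <- function(x, y, degree, cost, coef0 = 1, k = 10L, seed = 1L) {
  k <- min(k, sum(y > 0), sum(y < 0))
  if (k < 2L) stop("too few instances per class for cross-validation")
  folds <- stratified_folds(y, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- svm_train(x[tr, , drop = FALSE], y[tr], degree = degree,
                   cost = cost, coef0 = coef0)
    auc_roc(decision_value(m, x[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs)
}

# modal (degree, cost) with ties broken toward smaller degree, then smaller
# cost (Occam preference)
modal_config <- function(winners) {
  tab <- stats::aggregate(n ~ degree + cost,
                          data = transform(winners, n = 1L), FUN = sum)
  tab <- tab[order(-tab$n, tab$degree, tab$cost), ]
  list(degree = tab$degree[1], cost = tab$cost[1])
}

#' Nested model selection
#'
#' Runs the full selection protocol on one domain dataset: for every outer
#' training set (stratified k-fold, repeated, or repeated 75/25 random
#' splits), an inner cross-validation picks the (degree, cost) pair
#' maximizing AUC ROC over the supplied grids; the most frequent winning pair
#' across all outer training sets becomes the selected configuration, whose
#' outer-fold performance is then reported with standard deviations.
#'
#' @param x encoded instance matrix.
#' @param y +1/-1 labels.
#' @param degrees,costs hyper-parameter grids (defaults `1:3` and
#'   `c(0.01, 0.1, 1, 10, 100)`).
#' @param outer `"cv"` (stratified k-fold) or `"split"` (random 75/25).
#' @param outer_k outer fold count (default 5).
#' @param repeats protocol repetitions (default 5 for `"cv"`, 10 splits for
#'   `"split"`).
#' @param inner_k inner fold count (default 10).
#' @param coef0 kernel offset.
#' @param seed integer seed for all fold assignments.
#' @param train_fraction training share for `outer = "split"`.
#' @return list with `config` (selected degree/cost), `winners` (per outer
#'   training set), and `report` (mean/sd of sensitivity, specificity,
#'   precision, AUC ROC, AUC PR over outer folds).
#' @export
select_model <- function(x, y, degrees = c(1L, 2L, 3L),
                         costs = c(0.01, 0.1, 1, 10, 100),
                         outer = c("cv", "split"), outer_k = 5L,
                         repeats = NULL, inner_k = 10L, coef0 = 1,
                         seed = 1L, train_fraction = 0.75) {
  outer <- match.arg(outer)
  if (is.logical(y)) y <- ifelse(y, 1L, -1L)
  if (is.null(repeats)) repeats <- if (outer == "cv") 5L else 10L
  grid <- expand.grid(degree = degrees, cost = costs)
  outer_sets <- list()
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, repeats)
  for (r in seq_len(repeats)) {
    if (outer == "cv") {
      k <- min(outer_k, sum(y > 0), sum(y < 0))
      if (k < outer_k)
        warning("fold count reduced to ", k, " (too few instances per class)")
      folds <- stratified_folds(y, k, rep_seeds[r])
      for (f in seq_len(k))
        outer_sets[[length(outer_sets) + 1L]] <- which(folds == f)
    } else {
      set.seed(rep_seeds[r])
      test <- unlist(lapply(c(1, -1), function(cls) {
        idx <- which(y == cls)
        sample(idx, max(1L, round((1 - train_fraction) * length(idx))))
      }))
      outer_sets[[length(outer_sets) + 1L]] <- test
    }
  }
  winners <- list(); perf <- list()
  for (i in seq_along(outer_sets)) {
    test <- outer_sets[[i]]
    tr_x <- x[-test, , drop = FALSE]; tr_y <- y[-test]
    inner_auc <- vapply(seq_len(nrow(grid)), function(g)
      cv_auc(tr_x, tr_y, grid$degree[g], grid$cost[g], coef0,
             k = inner_k, seed = rep_seeds[(i - 1L) %% repeats + 1L]),
      numeric(1))
    ord <- order(-inner_auc, grid$degree, grid$cost)
    winners[[i]] <- data.frame(outer_set = i, degree = grid$degree[ord[1]],
                               cost = grid$cost[ord[1]],
                               inner_auc = inner_auc[ord[1]])
  }
  winners <- do.call(rbind, winners)
  config <- modal_config(winners)
  for (i in seq_along(outer_sets)) {
    test <- outer_sets[[i]]
    m <- svm_train(x[-test, , drop = FALSE], y[-test],
                   degree = config$degree, cost = config$cost, coef0 = coef0)
    dv <- decision_value(m, x[test, , drop = FALSE])
    cm <- confusion(dv, y[test])
    perf[[i]] <- data.frame(outer_set = i, sensitivity = cm$sensitivity,
                            specificity = cm$specificity,
                            precision = cm$precision,
                            auc_roc = auc_roc(dv, y[test]),
                            auc_pr = auc_pr(dv, y[test]))
  }
  perf <- do.call(rbind, perf)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  report <- sapply(perf[, -1], agg)
  list(config = config, winners = winners, folds = perf, report = report)
}
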