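# Iterative self-training rebalancing of imbalanced per-domain datasets.
#
# If negatives are in excess, positives are simply duplicated to parity
# (over-sampling; no synthetic instances are invented). If positives are in
# excess, an initial model is trained with over-sampled negatives, all
# unlabeled pool peptides are scored, and those most confidently predicted
# negative (smallest decision value) are moved into the negative set in
# batches, refitting the model each iteration, until the dataset is balanced.

#' Rebalancing configuration
#'
#' @param batch_fraction fraction of the remaining positive/negative deficit
#'   mined per iteration (at least one instance per batch).
#' @param max_iterations hard cap on mining iterations.
#' @param degree,cost,coef0 kernel configuration of the scoring model used
#'   during mining (unless a custom `train_fun` is given to [rebalance()]).
#' @param seed seed for the duplication draws.
#' @return a `rebalance_config` list.
#' @export
rebalance_config <- function(batch_fraction = 0.25, max_iterations = 20L,
                             degree = 2L, cost = 1, coef0 = 1, seed = 1L) {
  stopifnot(batch_fraction > 0, batch_fraction <= 1, max_iterations >= 1L)
  structure(list(batch_fraction = batch_fraction,
                 max_iterations = as.integer(max_iterations),
                 degree = as.integer(degree), cost = cost, coef0 = coef0,
                 seed = as.integer(seed)),
            class = "rebalance_config")
}

# duplicate rows (seeded, with replacement) until n_total rows
oversample_to <- function(x, n_total) {
  n <- nrow(x)
  if (n >= n_total) return(x)
  extra <- sample.int(n, n_total - n, replace = TRUE)
  x[c(seq_len(n), extra), , drop = FALSE]
}

#' Rebalance an imbalanced domain dataset by self-training
#'
#' Balances the labeled classes of a per-domain dataset. Excess negatives are
#' met by duplicating positives; excess positives trigger iterative negative
#' mining: a model trained on the current (negative-over-sampled) data scores
#' the unlabeled pool, and the peptides most confidently predicted
#' non-binding -- smallest signed decision value, ties broken by pool
#' order -- are added to the negatives in batches until parity. Mined
#' peptides leave the pool permanently. If the pool runs out, the remaining
#' deficit is covered by duplicating negatives and the result is flagged.
#'
#' @param dataset an `sh2_dataset` (from [compile_datasets()]) or any list
#'   with encoded matrices `positives`, `negatives` and (left branch)
#'   `unlabeled`.
#' @param config a [rebalance_config()].
#' @param train_fun optional `function(x, y)` returning a model understood by
#'   `score_fun`; defaults to [svm_train()] with the config's kernel.
#' @param score_fun optional `function(model, x)` returning decision values;
#'   defaults to [decision_value()].
#' @return object of class `rebalance_result`: `balanced_positives`,
#'   `balanced_negatives` (encoded matrices), `mined_idx` (pool row indices,
#'   in mining order), `mined_decision_values`, `n_iterations`, `trace`
#'   (per-iteration counts), `flags` (`pool_exhausted`, `max_iterations`),
#'   and `model` (final model trained on the balanced data).
#' @export
rebalance <- function(dataset, config = rebalance_config(),
                      train_fun = NULL, score_fun = decision_value) {
  pos <- dataset$positives; neg <- dataset$negatives
  if (NROW(pos) < 1L || NROW(neg) < 1L)
    stop("rebalancing requires at least one positive and one negative")
  if (is.null(train_fun))
    train_fun <- function(x, y)
      svm_train(x, y, degree = config$degree, cost = config$cost,
                coef0 = config$coef0)
  set.seed(config$seed)
  np <- nrow(pos); nn <- nrow(neg)
  flags <- c(pool_exhausted = FALSE, max_iterations = FALSE)
  trace <- list()
  mined_idx <- integer(0); mined_dv <- numeric(0)

  if (np <= nn) {
    # negatives in excess (or parity): duplicate positives
    bal_pos <- oversample_to(pos, nn)
    bal_neg <- neg
    n_iter <- 0L
  } else {
    pool <- dataset$unlabeled
    if (NROW(pool) < 1L)
      stop("positives are in excess but the unlabeled pool is empty")
    avail <- seq_len(nrow(pool))
    n_iter <- 0L
    repeat {
      deficit <- np - (nn + length(mined_idx))
      if (deficit <= 0L) break
      if (length(avail) == 0L) { flags["pool_exhausted"] <- TRUE; break }
      if (n_iter >= config$max_iterations) {
        flags["max_iterations"] <- TRUE; break
      }
      n_iter <- n_iter + 1L
      cur_neg <- rbind(neg, pool[mined_idx, , drop = FALSE])
      train_x <- rbind(pos, oversample_to(cur_neg, np))
      train_y <- c(rep(1L, np), rep(-1L, max(np, nrow(cur_neg))))
      model <- train_fun(train_x, train_y)
      dv <- score_fun(model, pool[avail, , drop = FALSE])
      batch <- as.integer(min(max(1L, ceiling(config$batch_fraction * deficit)),
                              deficit, length(avail)))
      take <- order(dv, seq_along(avail))[seq_len(batch)]  # ties: pool order
      mined_idx <- c(mined_idx, avail[take])
      mined_dv <- c(mined_dv, dv[take])
      avail <- avail[-take]
      trace[[n_iter]] <- data.frame(
        iteration = n_iter, n_pos = np, n_neg_real = nn,
        n_mined_total = length(mined_idx), batch = batch,
        pool_left = length(avail))
    }
    bal_pos <- pos
    bal_neg <- rbind(neg, pool[mined_idx, , drop = FALSE])
    if (nrow(bal_neg) < np) bal_neg <- oversample_to(bal_neg, np)
  }
  final_x <- rbind(bal_pos, bal_neg)
  final_y <- c(rep(1L, nrow(bal_pos)), rep(-1L, nrow(bal_neg)))
  structure(list(
    balanced_positives = bal_pos, balanced_negatives = bal_neg,
    mined_idx = mined_idx, mined_decision_values = mined_dv,
    n_iterations = n_iter,
    trace = if (length(trace)) do.call(rbind, trace) else NULL,
    flags = flags, model = train_fun(final_x, final_y)),
    class = "rebalance_result")
}

#' @export
print.rebalance_result <- function(x, ...) {
  cat("<rebalance_result> ", nrow(x$balanced_positives), " pos / ",
      nrow(x$balanced_negatives), " neg after ", x$n_iterations,
      " mining iteration(s), ", length(x$mined_idx), " peptides mined",
      if (any(x$flags)) paste0(" [", paste(names(x$flags)[x$flags],
                                           collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}
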