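# Synthetic per-domain binding problems.
#
# A binding rule scores a peptide window from additive position-specific
# weights plus optional non-additive pairwise terms (joint-requirement "and"
# terms, or a balanced mutual-exclusion "xor" rule) and labels it positive
# when the score reaches a threshold calibrated to a requested background
# prevalence. Rules are the ground truth against which every downstream stage
# (rebalancing, model selection, the PSSM baseline, the proteome scan) is
# exercised.

#' Create a synthetic binding rule
#'
#' Builds a deterministic, seeded ground-truth rule for a synthetic SH2-like
#' domain. With `n_pairwise = 0` the rule is purely additive over the six
#' flanking positions, so a linear discriminant is Bayes-optimal. With
#' `n_pairwise > 0` and `type = "and"`, binding additionally requires the
#' joint presence of amino acids from two position-specific sets (the
#' classical non-additive dependency: neither set member suffices alone).
#' `type = "xor"` produces a balanced mutual-exclusion rule -- binding iff
#' exactly one of two position-specific amino-acid sets (each covering half
#' the alphabet) is matched -- under which every single-position feature is
#' marginally uninformative and only an interaction-aware model can
#' discriminate.
#'
#' @param seed integer seed; the rule is a deterministic function of it.
#' @param n_pairwise number of pairwise terms (>= 1 implied for `type="xor"`).
#' @param noise_rate probability in \[0, 0.5) of flipping an observed label.
#' @param type `"and"` or `"xor"` pairwise structure.
#' @param prevalence target background positive rate (ignored for `"xor"`,
#'   which is balanced by construction).
#' @param effect size of each pairwise "and" effect relative to the additive
#'   part (additive weights have sd `additive_sd`).
#' @param additive_sd standard deviation of the additive weights.
#' @param set_size number of amino acids in each pairwise-term set
#'   (default 6 for `"and"`, 3 for `"xor"`).
#' @return object of class `binding_rule`.
#' @details `"xor"` rules come with a position-biased background
#'   distribution (stored in the rule and used by [sample_problem()]): each
#'   interacting position gives total probability 0.5 to its amino-acid set,
#'   emulating the compositional bias of a binding motif's key positions.
#'   This keeps the exclusion balanced -- every single position-specific
#'   residue is marginally uninformative about binding -- so only a model of
#'   the joint occurrence can discriminate.
#' @examples
#' r <- make_rule(seed = 1, n_pairwise = 1)
#' score_rule(r, c("AAYAAAA", "KKYNNNN"))
#' @export
make_rule <- function(seed, n_pairwise = 0L, noise_rate = 0,
                      type = c("and", "xor"), prevalence = 0.25,
                      effect = 3, additive_sd = 0.5, set_size = NULL) {
  type <- match.arg(type)
  stopifnot(noise_rate >= 0, noise_rate < 0.5, n_pairwise >= 0L)
  set.seed(as.integer(seed))
  if (type == "xor") {
    if (n_pairwise < 1L) n_pairwise <- 1L
    k <- as.integer(set_size %||% 3L)
    pos <- sample(WINDOW_OFFSETS, 2L)
    pairwise <- list(list(pos1 = pos[1], set1 = sample(AA20, k),
                          pos2 = pos[2], set2 = sample(AA20, k),
                          effect = 1))
    additive <- matrix(0, nrow = 20L, ncol = 6L,
                       dimnames = list(AA20, WINDOW_OFFSETS))
    background <- matrix(1 / 20, nrow = 20L, ncol = 6L,
                         dimnames = list(AA20, WINDOW_OFFSETS))
    for (t in pairwise) {
      j1 <- match(t$pos1, WINDOW_OFFSETS); j2 <- match(t$pos2, WINDOW_OFFSETS)
      background[, j1] <- ifelse(AA20 %in% t$set1, 0.5 / k, 0.5 / (20 - k))
      background[, j2] <- ifelse(AA20 %in% t$set2, 0.5 / k, 0.5 / (20 - k))
    }
    rule <- structure(list(type = "xor", additive = additive,
                           pairwise = pairwise, threshold = 0.5,
                           noise_rate = noise_rate, prevalence = 0.5,
                           background = background,
                           seed = as.integer(seed)),
                      class = "binding_rule")
    return(rule)
  }
  set_size <- as.integer(set_size %||% 6L)
  additive <- matrix(stats::rnorm(120L, sd = if (n_pairwise == 0L) 1 else additive_sd),
                     nrow = 20L, ncol = 6L, dimnames = list(AA20, WINDOW_OFFSETS))
  pairwise <- list()
  if (n_pairwise > 0L) {
    for (k in seq_len(n_pairwise)) {
      pos <- sample(WINDOW_OFFSETS, 2L)
      pairwise[[k]] <- list(pos1 = pos[1], set1 = sample(AA20, set_size),
                            pos2 = pos[2], set2 = sample(AA20, set_size),
                            effect = effect)
    }
  }
  rule <- structure(list(type = "and", additive = additive, pairwise = pairwise,
                         threshold = NA_real_, noise_rate = noise_rate,
                         prevalence = prevalence, background = NULL,
                         seed = as.integer(seed)),
                    class = "binding_rule")
  # calibrate the threshold so the background positive rate matches the
  # requested prevalence (estimated on a large seeded background sample)
  bg <- random_windows(20000L)
  rule$threshold <- unname(stats::quantile(score_rule(rule, bg),
                                           probs = 1 - prevalence, type = 1))
  rule
}

#' @export
print.binding_rule <- function(x, ...) {
  cat("<binding_rule> type=", x$type, ", ", length(x$pairwise),
      " pairwise term(s), threshold=", signif(x$threshold, 4),
      ", noise_rate=", x$noise_rate, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Score peptides under a binding rule
#'
#' Additive position weights summed over the six flanks, plus each pairwise
#' term's effect when both of its position-specific sets are matched. For
#' `"xor"` rules the score is the 0/1 indicator of exactly one set matching.
#'
#' @param rule a `binding_rule`.
#' @param peptides character vector of 7-mer windows.
#' @return numeric scores.
#' @export
score_rule <- function(rule, peptides) {
  stopifnot(inherits(rule, "binding_rule"))
  peptides <- validate_peptides(peptides)
  chars <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                  nrow = length(peptides), byrow = TRUE)
  flanks <- chars[, FLANK_IDX, drop = FALSE]
  if (rule$type == "xor") {
    t1 <- rule$pairwise[[1]]
    a <- flanks[, match(t1$pos1, WINDOW_OFFSETS)] %in% t1$set1
    b <- flanks[, match(t1$pos2, WINDOW_OFFSETS)] %in% t1$set2
    return(as.numeric(xor(a, b)))
  }
  s <- numeric(length(peptides))
  for (j in seq_len(6L)) {
    slot <- match(flanks[, j], AA20)
    hit <- !is.na(slot)
    s[hit] <- s[hit] + rule$additive[cbind(slot[hit], j)]
  }
  for (t in rule$pairwise) {
    a <- flanks[, match(t$pos1, WINDOW_OFFSETS)] %in% t$set1
    b <- flanks[, match(t$pos2, WINDOW_OFFSETS)] %in% t$set2
    s <- s + t$effect * (a & b)
  }
  s
}

#' True labels under a binding rule
#'
#' @param rule a `binding_rule`.
#' @param peptides 7-mer windows.
#' @return +1/-1 noise-free labels (score >= threshold).
#' @export
rule_labels <- function(rule, peptides) {
  ifelse(score_rule(rule, peptides) >= rule$threshold, 1L, -1L)
}

# i.i.d. background windows; freq is NULL (uniform), a named amino-acid
# frequency vector (same at every position), or a 20 x 6 position-specific
# frequency matrix. Draws from the current RNG stream.
random_windows <- function(n, freq = NULL) {
  if (n == 0L) return(character(0))
  if (is.matrix(freq)) {
    flanks <- vapply(seq_len(6L), function(j)
      sample(AA20, n, replace = TRUE, prob = freq[AA20, j]),
      character(n))
    flanks <- matrix(flanks, nrow = n)
  } else {
    probs <- if (is.null(freq)) NULL else freq[AA20] / sum(freq[AA20])
    flanks <- matrix(sample(AA20, 6L * n, replace = TRUE, prob = probs),
                     nrow = n)
  }
  paste0(flanks[, 1], flanks[, 2], "Y", flanks[, 3], flanks[, 4],
         flanks[, 5], flanks[, 6])
}

#' Sample a synthetic domain problem
#'
#' Draws labeled positives/negatives and an unlabeled pool from the uniform
#' background peptide distribution under a binding rule, by rejection
#' sampling. Observed labels incorporate the rule's symmetric flip noise;
#' requested class counts are exact in the observed labels. The unlabeled
#' pool keeps its hidden noise-free rule labels for downstream evaluation.
#'
#' @param rule a `binding_rule`.
#' @param n_pos,n_neg requested observed-label class sizes (>= 0).
#' @param n_unlabeled size of the unlabeled pool.
#' @param seed integer seed.
#' @param background background distribution: a named amino-acid frequency
#'   vector or a 20 x 6 position-specific frequency matrix; defaults to the
#'   rule's own background (uniform unless the rule defines one).
#' @param max_draws rejection-sampling budget (default 1e6 windows).
#' @return object of class `sh2_problem` with fields `positives`, `negatives`,
#'   `unlabeled`, `hidden_labels` (of the pool), `rule`, `seed`, `degenerate`.
#' @export
sample_problem <- function(rule, n_pos, n_neg, n_unlabeled = 0L, seed = 1L,
                           background = NULL, max_draws = 1e6) {
  stopifnot(inherits(rule, "binding_rule"), n_pos >= 0L, n_neg >= 0L)
  if (is.null(background)) background <- rule$background
  set.seed(as.integer(seed))
  pos <- character(0); neg <- character(0)
  drawn <- 0L
  while ((length(pos) < n_pos || length(neg) < n_neg) && drawn < max_draws) {
    batch <- min(5000L, as.integer(max_draws) - drawn)
    w <- random_windows(batch, background)
    drawn <- drawn + batch
    lab <- rule_labels(rule, w)
    if (rule$noise_rate > 0) {
      flip <- stats::runif(batch) < rule$noise_rate
      lab[flip] <- -lab[flip]
    }
    pos <- utils::head(c(pos, w[lab > 0]), n_pos)
    neg <- utils::head(c(neg, w[lab < 0]), n_neg)
  }
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop("sampling budget of ", max_draws, " windows exhausted with ",
         length(pos), "/", n_pos, " positives and ",
         length(neg), "/", n_neg, " negatives drawn")
  pool <- random_windows(as.integer(n_unlabeled), background)
  degenerate <- n_pos == 0L || n_neg == 0L
  if (degenerate)
    warning("degenerate problem: one class is empty")
  structure(list(rule = rule, positives = pos, negatives = neg,
                 unlabeled = pool,
                 hidden_labels = if (n_unlabeled > 0L) rule_labels(rule, pool)
                                 else integer(0),
                 seed = as.integer(seed), degenerate = degenerate),
            class = "sh2_problem")
}

#' @export
print.sh2_problem <- function(x, ...) {
  cat("<sh2_problem> ", length(x$positives), " pos / ", length(x$negatives),
      " neg, pool ", length(x$unlabeled), ", rule type ", x$rule$type,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic problem as an interaction table
#'
#' Emits the labeled part of a synthetic problem in the tab-separated
#' interaction format consumed by [read_interactions()].
#'
#' @param problem an `sh2_problem`.
#' @param domain_id domain identifier for the records.
#' @param path output TSV path.
#' @param source source tag written to the records.
#' @return the records data frame, invisibly.
#' @export
problem_to_interactions <- function(problem, domain_id, path = NULL,
                                    source = "synthetic") {
  stopifnot(inherits(problem, "sh2_problem"))
  recs <- data.frame(
    domain_id = domain_id,
    peptide = c(problem$positives, problem$negatives),
    kd_nM = NA_real_,
    label = c(rep(1L, length(problem$positives)),
              rep(-1L, length(problem$negatives))),
    source = source, stringsAsFactors = FALSE)
  if (!is.null(path)) write_interactions(recs, path)
  invisible(recs)
}

#' Build a synthetic proteome with planted phosphosites
#'
#' Embeds given peptide windows at known tyrosine sites inside random protein
#' sequences and adds background proteins carrying random windows at
#' experimentally "verified" sites, producing the three inputs of the scan
#' stage: a proteome, a phosphosite table and a localization table. All
#' proteins (and the scanning domains) share the localization term
#' `"cytoplasm"` unless `terms` is supplied per protein.
#'
#' @param windows 7-mer windows to plant (pad-free).
#' @param n_background number of additional background proteins.
#' @param seed integer seed.
#' @param flank_len residues on each side of the embedded window.
#' @param terms optional character vector of localization terms to sample from.
#' @return list with `proteome` (named character), `sites` (data frame
#'   `protein_id`, `site`), `localization` (data frame `protein_id`, `term`),
#'   and `planted` (data frame `protein_id`, `site`, `window`).
#' @export
make_scan_fixture <- function(windows, n_background = 20L, seed = 1L,
                              flank_len = 10L, terms = "cytoplasm") {
  set.seed(as.integer(seed))
  stopifnot(all(nchar(windows) == 7L))
  rand_seq <- function(n) paste(sample(setdiff(AA20, "Y"), n, replace = TRUE),
                                collapse = "")
  proteome <- character(0); sites <- list(); planted <- list()
  for (i in seq_along(windows)) {
    id <- sprintf("PLANT%03d", i)
    proteome[id] <- paste0(rand_seq(flank_len), windows[i], rand_seq(flank_len))
    site <- flank_len + 3L
    sites[[length(sites) + 1L]] <- data.frame(protein_id = id, site = site)
    planted[[length(planted) + 1L]] <-
      data.frame(protein_id = id, site = site, window = windows[i])
  }
  for (i in seq_len(n_background)) {
    id <- sprintf("BG%03d", i)
    w <- random_windows(1L)
    proteome[id] <- paste0(rand_seq(flank_len), w, rand_seq(flank_len))
    sites[[length(sites) + 1L]] <-
      data.frame(protein_id = id, site = flank_len + 3L)
  }
  sites <- do.call(rbind, sites)
  loc <- data.frame(protein_id = rep(names(proteome), each = length(terms)),
                    term = rep(terms, length(proteome)))
  list(proteome = proteome, sites = sites, localization = loc,
       planted = do.call(rbind, planted))
}
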