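# Dataset compilation: turn heterogeneous interaction measurements into clean
# per-domain training sets.
#
# Rules: dissociation constants below 2000 nM define binding; (domain,
# peptide) pairs labeled positive by one source and negative by another are
# discarded entirely; positives already present in the primary source are
# removed from secondary sources; domains with fewer than 40 positives are
# dropped (too few instances to fit a complex model reliably).

#' Class label from a dissociation constant
#'
#' Apparent dissociation constants (K_d) below 2000 nM are considered binding
#' (+1); all other pairs non-binding (-1). The boundary is strict: exactly
#' 2000 nM is non-binding.
#'
#' @param kd_nM positive dissociation constants in nM.
#' @param threshold_nM binding threshold (default 2000).
#' @return integer vector of +1/-1 labels.
#' @examples
#' label_from_kd(c(160, 2000, 3500))  # +1 -1 -1
#' @export
label_from_kd <- function(kd_nM, threshold_nM = 2000) {
  if (length(kd_nM) == 0) return(integer(0))
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("kd_nM must be finite and positive")
  ifelse(kd_nM < threshold_nM, 1L, -1L)
}

# attach labels: explicit label wins over kd when both present (with a
# warning on disagreement); rows with neither are an error
label_records <- function(records) {
  records <- check_interactions(records)
  kd_lab <- rep(NA_integer_, nrow(records))
  has_kd <- !is.na(records$kd_nM)
  kd_lab[has_kd] <- label_from_kd(records$kd_nM[has_kd])
  lab <- ifelse(!is.na(records$label), records$label, kd_lab)
  disagree <- !is.na(records$label) & !is.na(kd_lab) & records$label != kd_lab
  if (any(disagree))
    warning(sum(disagree), " record(s) have an explicit label disagreeing ",
            "with the K_d-derived label; the explicit label was kept")
  records$label <- as.integer(lab)
  records
}

record_key <- function(records)
  paste(records$domain_id, toupper(records$peptide), sep = "\t")

#' Remove cross-source label conflicts
#'
#' Collapses exact duplicate (domain, peptide, label) records, then removes
#' entirely every (domain, peptide) pair that carries both a positive and a
#' negative label across sources -- such measurements are considered
#' unreliable and are discarded from both sides.
#'
#' @param records labeled interaction records (see [read_interactions()];
#'   the `label` column must be filled, e.g. via K_d thresholding).
#' @return list with `records` (cleaned), `n_conflicts` (number of discarded
#'   (domain, peptide) pairs), `n_conflict_rows` (rows they occupied),
#'   `n_duplicates` (duplicate rows collapsed).
#' @export
resolve_conflicts <- function(records) {
  records <- label_records(records)
  n_in <- nrow(records)
  dup <- duplicated(paste(record_key(records), records$label, sep = "\t"))
  records <- records[!dup, , drop = FALSE]
  key <- record_key(records)
  both <- tapply(records$label, key, function(l) any(l > 0) && any(l < 0))
  conflict_keys <- names(both)[both]
  keep <- !(key %in% conflict_keys)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       n_conflicts = length(conflict_keys),
       n_conflict_rows = sum(!keep),
       n_duplicates = sum(dup))
  # conservation: n_in == nrow(out) + n_conflict_rows + n_duplicates
}

#' Deduplicate positives across sources
#'
#' Positive interactions already present in the primary source are removed
#' from the other sources; per-source unique counts are reported.
#'
#' @param primary_positives,other_positives labeled record data frames
#'   holding only positive records.
#' @return list with `other_unique` (records of `other_positives` not in the
#'   primary source) and `counts` (per-source data frame with `n_input`,
#'   `n_shared`, `n_unique`).
#' @export
deduplicate_positives <- function(primary_positives, other_positives) {
  stopifnot(all(primary_positives$label > 0), all(other_positives$label > 0))
  shared <- record_key(other_positives) %in% record_key(primary_positives)
  per_source <- function(src) {
    sel <- other_positives$source == src
    data.frame(source = src, n_input = sum(sel),
               n_shared = sum(sel & shared), n_unique = sum(sel & !shared))
  }
  counts <- do.call(rbind, lapply(unique(other_positives$source), per_source))
  out <- other_positives[!shared, , drop = FALSE]
  rownames(out) <- NULL
  list(other_unique = out, counts = counts)
}

#' Compile per-domain datasets
#'
#' Splits conflict-free labeled records by domain, removes duplicate
#' (peptide, label) pairs within a domain, and encodes positives and
#' negatives with the positional one-hot scheme.
#'
#' @param records labeled, conflict-free interaction records.
#' @param unlabeled optional character vector of unlabeled peptide windows
#'   attached to every domain as its mining pool.
#' @param scheme encoding scheme (default `"full20"`).
#' @return named list of `sh2_dataset` objects (fields `domain_id`,
#'   `positives`, `negatives`, `unlabeled` as encoded matrices).
#' @export
compile_datasets <- function(records, unlabeled = NULL, scheme = "full20") {
  records <- label_records(records)
  key <- paste(record_key(records), records$label, sep = "\t")
  records <- records[!duplicated(key), , drop = FALSE]
  pool <- if (length(unlabeled)) encode_peptides(unlabeled, scheme) else NULL
  out <- lapply(split(records, records$domain_id), function(r) {
    pos <- unique(toupper(r$peptide[r$label > 0]))
    neg <- unique(toupper(r$peptide[r$label < 0]))
    structure(list(
      domain_id = r$domain_id[1],
      positives = if (length(pos)) encode_peptides(pos, scheme) else NULL,
      negatives = if (length(neg)) encode_peptides(neg, scheme) else NULL,
      unlabeled = pool, scheme = scheme), class = "sh2_dataset")
  })
  out[order(names(out))]
}

#' @export
print.sh2_dataset <- function(x, ...) {
  cat("<sh2_dataset> ", x$domain_id, ": ", NROW(x$positives), " pos / ",
      NROW(x$negatives), " neg, pool ", NROW(x$unlabeled), "\n", sep = "")
  invisible(x)
}

#' Drop domains with too few positives
#'
#' Domains with fewer than `min_positives` positive interactions are removed:
#' no complex model can be fit reliably on them. The boundary keeps a domain
#' with exactly `min_positives` positives.
#'
#' @param datasets named list of `sh2_dataset` objects.
#' @param min_positives retention threshold (default 40).
#' @return list with `datasets` (retained) and `report` (data frame with
#'   per-domain `n_pos`, `n_neg`, `retained`).
#' @export
filter_domains <- function(datasets, min_positives = 40L) {
  n_pos <- vapply(datasets, function(d) NROW(d$positives), integer(1))
  n_neg <- vapply(datasets, function(d) NROW(d$negatives), integer(1))
  keep <- n_pos >= min_positives
  report <- data.frame(domain_id = names(datasets), n_pos = n_pos,
                       n_neg = n_neg, retained = keep, row.names = NULL)
  list(datasets = datasets[keep], report = report)
}

#' Simulate a literature-style interaction survey
#'
#' Constructs three synthetic interaction tables whose marginal counts match
#' a typical compilation of one high-density peptide-array survey (positives
#' only, no negative evidence) and two affinity microarray surveys (K_d
#' measurements for a full domain x peptide grid). The defaults mirror the
#' published survey sizes this package's compilation rules were designed for:
#' a 61-domain x 920-peptide array with 7544 positive pairs, a 105 x 20 and
#' an 85 x 41 microarray grid with 160 and 314 sub-2000 nM interactions of
#' which 112 and 135 also appear in the peptide array, 149 array-positive
#' pairs measured as non-binding on the microarrays, and 10 array domains
#' with fewer than 40 positives.
#'
#' @param seed integer seed.
#' @param n_domains,n_peptides,n_pos peptide-array grid and positive count.
#' @param grid2,grid3 microarray grids as
#'   `c(domains, peptides, positives, shared_with_array)`.
#' @param n_conflicts number of array-positive / microarray-negative pairs.
#' @param n_small_domains,small_domain_pos number of low-coverage array
#'   domains and their positive count (below the retention threshold).
#' @return list of record data frames `peptide_array`, `microarray2`,
#'   `microarray3` in the [read_interactions()] layout.
#' @export
simulate_survey_tables <- function(seed = 1L,
                                   n_domains = 61L, n_peptides = 920L,
                                   n_pos = 7544L,
                                   grid2 = c(105L, 20L, 160L, 112L),
                                   grid3 = c(85L, 41L, 314L, 135L),
                                   n_conflicts = 149L,
                                   n_small_domains = 10L,
                                   small_domain_pos = 30L) {
  set.seed(as.integer(seed))
  stopifnot(grid2[2] + grid3[2] <= n_peptides)
  peptides <- unique(random_windows(as.integer(n_peptides * 1.2)))
  while (length(peptides) < n_peptides)
    peptides <- unique(c(peptides, random_windows(1000L)))
  peptides <- peptides[seq_len(n_peptides)]
  pep2 <- peptides[seq_len(grid2[2])]
  pep3 <- peptides[grid2[2] + seq_len(grid3[2])]
  pep_fill <- peptides[-seq_len(grid2[2] + grid3[2])]
  dom_pa <- sprintf("SH2-%03d", seq_len(n_domains))
  small <- utils::tail(dom_pa, n_small_domains)
  big <- setdiff(dom_pa, small)
  dom2 <- c(dom_pa, sprintf("MA2-%03d", seq_len(grid2[1] - n_domains)))
  dom3 <- c(big[seq_len(min(length(big), grid3[1]))],
            sprintf("MA3-%03d", seq_len(max(0L, grid3[1] - length(big)))))

  pick_cells <- function(doms, peps, n, exclude = character(0)) {
    # sample n distinct (domain, peptide) cells avoiding `exclude` keys
    cells <- expand.grid(domain_id = doms, peptide = peps,
                         stringsAsFactors = FALSE)
    key <- paste(cells$domain_id, cells$peptide, sep = "\t")
    cells <- cells[!(key %in% exclude), , drop = FALSE]
    stopifnot(nrow(cells) >= n)
    cells[sample(nrow(cells), n), , drop = FALSE]
  }

  # microarray positives: `shared` cells reappear in the array's positive
  # set, the rest are unique to each microarray but kept in big array domains
  ma2_pos <- pick_cells(big, pep2, grid2[3])
  ma3_pos <- pick_cells(intersect(dom3, big), pep3, grid3[3])
  shared2 <- ma2_pos[seq_len(grid2[4]), ]
  shared3 <- ma3_pos[seq_len(grid3[4]), ]

  # conflicts: array-positive pairs that the microarrays measured as
  # non-binding (placed on microarray cells outside the positive sets)
  n_c2 <- floor(n_conflicts / 2); n_c3 <- n_conflicts - n_c2
  confl2 <- pick_cells(big, pep2, n_c2,
                       exclude = paste(ma2_pos$domain_id, ma2_pos$peptide,
                                       sep = "\t"))
  confl3 <- pick_cells(intersect(dom3, big), pep3, n_c3,
                       exclude = paste(ma3_pos$domain_id, ma3_pos$peptide,
                                       sep = "\t"))

  # peptide-array positives: shared + conflict pairs plus random filler over
  # peptides unseen by the microarrays; low-coverage domains get few pairs
  pa <- rbind(shared2, shared3, confl2, confl3)
  n_small_tot <- n_small_domains * small_domain_pos
  fill_small <- data.frame(
    domain_id = rep(small, each = small_domain_pos),
    peptide = unlist(lapply(seq_len(n_small_domains), function(i)
      sample(pep_fill, small_domain_pos))),
    stringsAsFactors = FALSE)
  n_fill <- n_pos - nrow(pa) - n_small_tot
  stopifnot(n_fill >= 0)
  fill_big <- pick_cells(big, pep_fill, n_fill,
                         exclude = paste(fill_small$domain_id,
                                         fill_small$peptide, sep = "\t"))
  pa <- rbind(pa, fill_small, fill_big)
  stopifnot(nrow(pa) == n_pos, !anyDuplicated(paste(pa$domain_id, pa$peptide)))

  make_records <- function(cells, kd, label, source)
    data.frame(domain_id = cells$domain_id, peptide = cells$peptide,
               kd_nM = kd, label = label, source = source,
               stringsAsFactors = FALSE)

  pa_recs <- make_records(pa, NA_real_, 1L, "peptide_array")
  grid_records <- function(doms, peps, pos_cells, source) {
    cells <- expand.grid(domain_id = doms, peptide = peps,
                         stringsAsFactors = FALSE)
    key <- paste(cells$domain_id, cells$peptide, sep = "\t")
    is_pos <- key %in% paste(pos_cells$domain_id, pos_cells$peptide, sep = "\t")
    kd <- ifelse(is_pos, stats::runif(nrow(cells), 1, 1999),
                 stats::runif(nrow(cells), 2000, 10000))
    make_records(cells, kd, NA_integer_, source)
  }
  list(peptide_array = pa_recs,
       microarray2 = grid_records(dom2, pep2, ma2_pos, "microarray2"),
       microarray3 = grid_records(dom3, pep3, ma3_pos, "microarray3"))
}
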