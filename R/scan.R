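# Proteome-wide scanning with eligibility filters.
#
# A (domain, site) pair is eligible when (1) the site residue is a tyrosine,
# (2) the site is an experimentally verified phosphosite, and (3) the mature
# protein and the domain-bearing protein share at least one subcellular
# localization term. Proteins without any localization annotation are skipped
# entirely. Eligible windows are scored by the trained per-domain models and
# ranked by decision value.

loc_map_from_df <- function(localization) {
  stopifnot(all(c("protein_id", "term") %in% names(localization)))
  lapply(split(localization$term, localization$protein_id), unique)
}

#' Eligibility of a (protein site, domain) pair
#'
#' Applies the three eligibility filters. The filters commute; a pair is
#' eligible iff all three hold.
#'
#' @param protein_id protein carrying the candidate peptide.
#' @param site 1-based position of the candidate tyrosine.
#' @param domain_protein_id protein expressing the SH2 domain.
#' @param proteome named character vector of protein sequences.
#' @param phosphosites data frame with columns `protein_id`, `site` of
#'   verified phosphotyrosines.
#' @param localization data frame with columns `protein_id`, `term`.
#' @return logical.
#' @export
site_eligible <- function(protein_id, site, domain_protein_id, proteome,
                          phosphosites, localization) {
  loc <- loc_map_from_df(localization)
  if (!protein_id %in% names(proteome)) {
    warning("unknown protein '", protein_id, "' skipped")
    return(FALSE)
  }
  seq <- proteome[[protein_id]]
  if (site < 1L || site > nchar(seq) ||
      substr(toupper(seq), site, site) != "Y") return(FALSE)
  if (!any(phosphosites$protein_id == protein_id &
           phosphosites$site == site)) return(FALSE)
  pt <- loc[[protein_id]]; dt <- loc[[domain_protein_id]]
  if (is.null(pt) || is.null(dt)) return(FALSE)
  length(intersect(pt, dt)) > 0L
}

#' Proteome scan with trained domain models
#'
#' Scores every eligible (domain, phosphosite) pair with the trained
#' per-domain SVM models, reports the top-ranked predictions per domain, and
#' flags promiscuous peptides predicted to bind more than
#' `promiscuity_threshold` distinct domains.
#'
#' @param models named list of `sh2_svm` models (names = domain ids).
#' @param proteome named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param phosphosites data frame with columns `protein_id`, `site`
#'   (1-based) of experimentally verified phosphotyrosines.
#' @param localization data frame with columns `protein_id`, `term`.
#' @param domain_proteins named character map domain id -> protein id
#'   expressing the domain (default: the domain id itself).
#' @param top_k predictions reported per domain (default 50).
#' @param promiscuity_threshold a peptide predicted positive by more than
#'   this many domains is reported as promiscuous (default 40).
#' @return object of class `scan_result`: `predictions` (data frame
#'   `domain_id`, `protein_id`, `site`, `window`, `score`, `rank`, ranked by
#'   non-increasing score within each domain, ties broken by protein id and
#'   site), `promiscuous` (data frame `protein_id`, `site`, `window`,
#'   `n_domains`), `n_sites_scored`, `n_sites_skipped`.
#' @export
scan_proteome <- function(models, proteome, phosphosites, localization,
                          domain_proteins = NULL, top_k = 50L,
                          promiscuity_threshold = 40L) {
  stopifnot(length(models) >= 1L, top_k >= 1L)
  if (inherits(proteome, "XStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  if (is.null(domain_proteins))
    domain_proteins <- stats::setNames(names(models), names(models))
  loc <- loc_map_from_df(localization)

  empty <- data.frame(domain_id = character(0), protein_id = character(0),
                      site = integer(0), window = character(0),
                      score = numeric(0), rank = integer(0))
  sites <- unique(phosphosites[, c("protein_id", "site")])
  known <- sites$protein_id %in% names(proteome)
  if (any(!known))
    warning("skipping ", sum(!known), " phosphosite(s) on unknown protein(s): ",
            paste(utils::head(unique(sites$protein_id[!known]), 5),
                  collapse = ", "))
  sites <- sites[known, , drop = FALSE]
  n_skipped <- sum(!known)
  if (nrow(sites)) {
    annotated <- sites$protein_id %in% names(loc)
    n_skipped <- n_skipped + sum(!annotated)
    sites <- sites[annotated, , drop = FALSE]  # unannotated proteins skipped
  }
  if (nrow(sites)) {
    is_tyr <- mapply(function(p, s) {
      s >= 1L && s <= nchar(proteome[[p]]) &&
        substr(toupper(proteome[[p]]), s, s) == "Y"
    }, sites$protein_id, sites$site)
    n_skipped <- n_skipped + sum(!is_tyr)
    sites <- sites[is_tyr, , drop = FALSE]
  }
  if (nrow(sites) == 0L)
    return(structure(list(predictions = empty, promiscuous = NULL,
                          n_sites_scored = 0L, n_sites_skipped = n_skipped),
                     class = "scan_result"))

  windows <- mapply(function(p, s) extract_window(proteome[[p]], s),
                    sites$protein_id, sites$site)
  enc <- encode_peptides(windows, "full20")

  preds <- list(); pos_calls <- list()
  for (dom in names(models)) {
    dp <- domain_proteins[[dom]]
    dt <- loc[[dp]]
    if (is.null(dt)) {
      warning("domain '", dom, "' protein '", dp,
              "' has no localization annotation; domain skipped")
      next
    }
    share <- vapply(sites$protein_id, function(p)
      length(intersect(loc[[p]], dt)) > 0L, logical(1))
    if (!any(share)) next
    dv <- decision_value(models[[dom]], enc[share, , drop = FALSE])
    d <- data.frame(domain_id = dom, protein_id = sites$protein_id[share],
                    site = sites$site[share], window = windows[share],
                    score = dv, row.names = NULL)
    d <- d[order(-d$score, d$protein_id, d$site), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    pos_calls[[dom]] <- d[d$score >= 0, c("protein_id", "site", "window")]
    preds[[dom]] <- utils::head(d, top_k)
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else empty
  rownames(predictions) <- NULL

  promiscuous <- NULL
  if (length(pos_calls)) {
    allpos <- do.call(rbind, pos_calls)
    if (nrow(allpos)) {
      key <- paste(allpos$protein_id, allpos$site, sep = "\t")
      n_dom <- table(key)
      hot <- names(n_dom)[n_dom > promiscuity_threshold]
      if (length(hot)) {
        first <- allpos[match(hot, key), , drop = FALSE]
        promiscuous <- data.frame(first,
                                  n_domains = as.integer(n_dom[hot]),
                                  row.names = NULL)
        promiscuous <- promiscuous[order(-promiscuous$n_domains), ,
                                   drop = FALSE]
      }
    }
  }
  structure(list(predictions = predictions, promiscuous = promiscuous,
                 n_sites_scored = nrow(sites), n_sites_skipped = n_skipped),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> ", nrow(x$predictions), " prediction rows over ",
      length(unique(x$predictions$domain_id)), " domain(s); ",
      x$n_sites_scored, " sites scored, ", x$n_sites_skipped, " skipped; ",
      NROW(x$promiscuous), " promiscuous peptide(s)\n", sep = "")
  invisible(x)
}
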