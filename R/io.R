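# Tabular and sequence I/O.
#
# All tables are tab-separated with a header, UTF-8, '.' decimal, missing
# values as empty fields; CRLF input is accepted. Protein sequences are read
# from standard FASTA via Biostrings.

INTERACTION_COLS <- c("domain_id", "peptide", "kd_nM", "label", "source")

check_interactions <- function(records) {
  missing <- setdiff(INTERACTION_COLS, names(records))
  if (length(missing))
    stop("interaction table lacks column(s): ", paste(missing, collapse = ", "))
  records$kd_nM <- as.numeric(records$kd_nM)
  records$label <- suppressWarnings(as.integer(records$label))
  records
}

#' Read an interaction table
#'
#' Reads tab-separated interaction records with header columns `domain_id`,
#' `peptide`, `kd_nM`, `label`, `source`. Each row must carry a valid 7-mer
#' window and at least one of `kd_nM` (positive) or `label` (+1/-1).
#' Malformed rows are reported with their line numbers; up to `error_budget`
#' such rows are dropped with a warning, any more is an error.
#'
#' @param path TSV file path.
#' @param error_budget number of malformed rows tolerated (default 0).
#' @return data frame of interaction records.
#' @export
read_interactions <- function(path, error_budget = 0L) {
  records <- utils::read.delim(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE,
                               na.strings = c("", "NA"))
  records <- check_interactions(records)
  line_no <- seq_len(nrow(records)) + 1L  # header is line 1
  problems <- character(0)
  bad <- logical(nrow(records))
  pep <- toupper(ifelse(is.na(records$peptide), "", records$peptide))
  ok_pep <- nchar(pep) == 7L & substr(pep, 3, 3) == "Y"
  for (i in which(!ok_pep)) {
    bad[i] <- TRUE
    problems <- c(problems, paste0("line ", line_no[i],
                                   ": invalid peptide window '",
                                   records$peptide[i], "'"))
  }
  no_evidence <- is.na(records$kd_nM) & is.na(records$label)
  for (i in which(no_evidence)) {
    bad[i] <- TRUE
    problems <- c(problems,
                  paste0("line ", line_no[i], ": neither kd_nM nor label"))
  }
  bad_kd <- !is.na(records$kd_nM) & records$kd_nM <= 0
  for (i in which(bad_kd)) {
    bad[i] <- TRUE
    problems <- c(problems, paste0("line ", line_no[i],
                                   ": non-positive kd_nM"))
  }
  bad_label <- !is.na(records$label) & !(records$label %in% c(-1L, 1L))
  for (i in which(bad_label)) {
    bad[i] <- TRUE
    problems <- c(problems, paste0("line ", line_no[i],
                                   ": label must be +1 or -1"))
  }
  if (sum(bad) > error_budget)
    stop("malformed interaction rows (", sum(bad), " > budget ",
         error_budget, "):\n  ", paste(problems, collapse = "\n  "))
  if (any(bad))
    warning("dropped ", sum(bad), " malformed row(s):\n  ",
            paste(problems, collapse = "\n  "))
  records$peptide <- pep
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction table
#'
#' @param records interaction record data frame.
#' @param path output TSV path.
#' @export
write_interactions <- function(records, path) {
  records <- check_interactions(records)
  utils::write.table(records[, INTERACTION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write FASTA protein sequences
#'
#' Thin wrappers around Biostrings. Sequence names are truncated at the
#' first whitespace.
#'
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA files")
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to write FASTA files")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read phosphosite and localization tables
#'
#' `read_phosphosites` expects columns `protein_id`, `site` (1-based);
#' `read_localization` expects `protein_id`, `term`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_phosphosites <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "site") %in% names(d)))
  d$site <- as.integer(d$site)
  d
}

#' @rdname read_phosphosites
#' @export
read_localization <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "term") %in% names(d)))
  d
}
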