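# Position-specific scoring-matrix baseline with relative-score
# thresholding.
#
# The weight matrix holds, for each of 6 positions and 19 amino acids (Cys is
# not represented), the difference between the position-specific amino-acid
# frequency in the positive peptides and in a background set. A peptide's raw
# score is the dot product of the vectorized matrix with the 114-dimensional
# Cys-free one-hot encoding. The raw score is normalized by a reference
# score -- the raw score at a fixed top percentile of a large proteome-wide
# window population -- so that relative scores >= 1 predict binding.

#' Build a PSSM weight matrix
#'
#' `W[a, j] = freq(a at position j | positives) - freq(a at position j |
#' background)` over the 19-letter Cys-free alphabet. An optional log-odds
#' transform (with pseudocounts) is provided as an alternative weighting.
#'
#' @param positives character vector of binding 7-mer windows.
#' @param background character vector of background 7-mer windows.
#' @param transform `"difference"` (default) or `"logodds"`.
#' @param pseudocount added count for the log-odds transform.
#' @return object of class `weight_matrix` (uncalibrated: no reference score
#'   yet).
#' @export
build_pssm <- function(positives, background,
                       transform = c("difference", "logodds"),
                       pseudocount = 1) {
  transform <- match.arg(transform)
  if (length(positives) == 0L || length(background) == 0L)
    stop("positives and background must be non-empty")
  pos_freq <- colMeans(encode_peptides(positives, "noCys19"))
  bg_freq <- colMeans(encode_peptides(background, "noCys19"))
  if (transform == "difference") {
    w <- pos_freq - bg_freq
  } else {
    npos <- length(positives); nbg <- length(background)
    w <- log((pos_freq * npos + pseudocount) / (npos + 19 * pseudocount)) -
         log((bg_freq * nbg + pseudocount) / (nbg + 19 * pseudocount))
  }
  W <- matrix(w, nrow = 19L, ncol = 6L,
              dimnames = list(AA19, WINDOW_OFFSETS))
  structure(list(W = W, transform = transform, s_ref = NULL,
                 percentile = NULL, n_positives = length(positives),
                 n_background = length(background)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("<weight_matrix> 19 x 6 (", x$transform, "), built from ",
      x$n_positives, " positives vs ", x$n_background, " background; ",
      if (is.null(x$s_ref)) "uncalibrated"
      else paste0("S_ref=", signif(x$s_ref, 4), " (top ", x$percentile, "%)"),
      "\n", sep = "")
  invisible(x)
}

#' Raw PSSM score
#'
#' Dot product of the vectorized weight matrix (columns = positions) with the
#' Cys-free 114-dimensional encoding; Cys and pad positions contribute zero.
#'
#' @param wm a `weight_matrix`.
#' @param peptides 7-mer windows.
#' @return numeric raw scores.
#' @export
pssm_raw_score <- function(wm, peptides) {
  stopifnot(inherits(wm, "weight_matrix"))
  as.vector(encode_peptides(peptides, "noCys19") %*% as.vector(wm$W))
}

#' Calibrate the reference score
#'
#' Sets the domain's reference score to the raw score at the top
#' `percentile`% of a large window population (proteome-wide tyrosine
#' windows): with N windows, the ceiling(percentile/100 * N)-th highest raw
#' score. The default percentile 4.5 is the mean of the two values (3.5 and
#' 5.5) obtained by F-measure optimization on two representative domains in
#' the original baseline's calibration; it is configurable.
#'
#' @param wm a `weight_matrix`.
#' @param proteome_windows character vector of at least 100 windows.
#' @param percentile top percentile defining the reference (default 4.5).
#' @return the calibrated `weight_matrix` (with `s_ref` set).
#' @export
calibrate_reference <- function(wm, proteome_windows, percentile = 4.5) {
  stopifnot(inherits(wm, "weight_matrix"))
  n <- length(proteome_windows)
  if (n < 100L)
    stop("reference calibration needs at least 100 windows (got ", n, ")")
  scores <- sort(pssm_raw_score(wm, proteome_windows), decreasing = TRUE)
  k <- ceiling(percentile / 100 * n)
  s_ref <- scores[k]
  if (!is.finite(s_ref) || s_ref <= 0)
    stop("reference score is not positive (", signif(s_ref, 4),
         "); the matrix does not separate the top of this population")
  wm$s_ref <- s_ref
  wm$percentile <- percentile
  wm
}

#' Relative PSSM score and binding call
#'
#' `relative_score = raw_score / S_ref`; a relative score >= 1 predicts
#' binding (boundary inclusive).
#'
#' @param wm a calibrated `weight_matrix`.
#' @param peptides 7-mer windows.
#' @return `relative_score` returns numeric scores; `pssm_predict` returns
#'   +1/-1 binding calls.
#' @export
relative_score <- function(wm, peptides) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (is.null(wm$s_ref))
    stop("weight matrix is not calibrated; run calibrate_reference() first")
  pssm_raw_score(wm, peptides) / wm$s_ref
}

#' @rdname relative_score
#' @export
pssm_predict <- function(wm, peptides) {
  ifelse(relative_score(wm, peptides) >= 1, 1L, -1L)
}

#' Serialize / restore a weight matrix
#'
#' The matrix is written as a TSV (rows = amino acids, columns = offsets)
#' with a JSON sidecar (`<path>.json`) holding the reference score,
#' percentile and provenance counts.
#'
#' @param wm a `weight_matrix`.
#' @param path TSV path.
#' @return `load_pssm` returns the restored `weight_matrix`.
#' @export
save_pssm <- function(wm, path) {
  stopifnot(inherits(wm, "weight_matrix"))
  utils::write.table(wm$W, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  meta <- list(schema = "sh2pep-pssm/1.0", transform = wm$transform,
               s_ref = wm$s_ref, percentile = wm$percentile,
               n_positives = wm$n_positives, n_background = wm$n_background)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_pssm
#' @export
load_pssm <- function(path) {
  W <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  stopifnot(identical(rownames(W), AA19), ncol(W) == 6L)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(W = W, transform = meta$transform,
                 s_ref = meta$s_ref, percentile = meta$percentile,
                 n_positives = meta$n_positives,
                 n_background = meta$n_background),
            class = "weight_matrix")
}
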