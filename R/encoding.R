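# Peptide windows and positional one-hot encodings.
#
# A peptide window is a 7-residue string covering offsets -2..+4 around a
# phosphotyrosine fixed at offset 0 (string index 3). The central Tyr carries
# no information and is never encoded; the six flanking positions are one-hot
# encoded position-major, 20 (or 19, Cys excluded) amino-acid slots per
# position in fixed alphabetical one-letter-code order.

#' @name encoding-constants
#' @title Encoding constants
#' @description Fixed alphabets, window offsets and encoding dimensions used
#'   throughout the package. `AA20` is the 20 amino-acid one-letter alphabet in
#'   alphabetical order; `AA19` drops Cys (the ordering used by the PSSM
#'   baseline). The window spans offsets -2..+4 with the phosphotyrosine at
#'   offset 0, giving 6 encoded positions and dimensions 20*6 = 120 and
#'   19*6 = 114.
#' @keywords internal
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA19 <- setdiff(AA20, "C")
PAD <- "-"
# encoded flank offsets relative to the central pTyr
WINDOW_OFFSETS <- c(-2L, -1L, 1L, 2L, 3L, 4L)
# string indices of the flanks inside the 7-mer (centre 'Y' is index 3)
FLANK_IDX <- c(1L, 2L, 4L, 5L, 6L, 7L)
DIM_FULL20 <- 120L
DIM_NOCYS19 <- 114L

# residues accepted but not encodable: ambiguity/rare codes map to an all-zero
# block, like the pad symbol
UNENCODABLE <- c("B", "J", "O", "U", "X", "Z")

encoding_alphabet <- function(scheme = c("full20", "noCys19")) {
  scheme <- match.arg(scheme)
  if (scheme == "full20") AA20 else AA19
}

#' Validate peptide windows
#'
#' Checks that each string is a valid 7-residue phosphotyrosine window:
#' length 7, `Y` at the central position, and flanking characters drawn from
#' the amino-acid alphabet, the pad symbol `-`, or an ambiguity code.
#'
#' @param peptides character vector of 7-mer windows.
#' @return invisibly, the upper-cased peptides; errors on the first invalid
#'   window with its index.
#' @export
validate_peptides <- function(peptides) {
  if (!is.character(peptides) || length(peptides) == 0)
    stop("peptides must be a non-empty character vector")
  peptides <- toupper(peptides)
  bad_len <- which(nchar(peptides) != 7L)
  if (length(bad_len))
    stop("peptide ", bad_len[1], " ('", peptides[bad_len[1]],
         "') does not have length 7")
  bad_y <- which(substr(peptides, 3L, 3L) != "Y")
  if (length(bad_y))
    stop("peptide ", bad_y[1], " ('", peptides[bad_y[1]],
         "') lacks the central Tyr at offset 0")
  allowed <- c(AA20, PAD, UNENCODABLE)
  chars <- strsplit(peptides, "")
  for (i in seq_along(chars)) {
    extra <- setdiff(chars[[i]][FLANK_IDX], allowed)
    if (length(extra))
      stop("peptide ", i, " ('", peptides[i],
           "') contains invalid residue '", extra[1], "'")
  }
  invisible(peptides)
}

#' Extract a phosphotyrosine-centered peptide window
#'
#' Cuts the 7-residue window spanning offsets -2..+4 around a tyrosine at a
#' given 1-based site of a protein sequence. Positions falling outside the
#' sequence are filled with the pad symbol `-`.
#'
#' @param protein_sequence amino-acid string.
#' @param site 1-based position of the tyrosine anchoring the window.
#' @return a 7-character window with `Y` at index 3.
#' @examples
#' extract_window("MKNGYENPTAK", 5)  # "NGYENPT"
#' extract_window("YAAAA", 1)        # "--YAAAA"
#' @export
extract_window <- function(protein_sequence, site) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  protein_sequence <- toupper(protein_sequence)
  n <- nchar(protein_sequence)
  site <- as.integer(site)
  if (is.na(site) || site < 1L || site > n)
    stop("site ", site, " is out of range for a sequence of length ", n)
  if (substr(protein_sequence, site, site) != "Y")
    stop("residue at site ", site, " is '",
         substr(protein_sequence, site, site), "', not 'Y'")
  res <- strsplit(protein_sequence, "")[[1]]
  idx <- (site - 2L):(site + 4L)
  win <- ifelse(idx >= 1L & idx <= n, res[pmax(pmin(idx, n), 1L)], PAD)
  paste(win, collapse = "")
}

#' One-hot encode peptide windows
#'
#' Maps 7-mer phosphotyrosine windows to binary row vectors. Under scheme
#' `full20` each of the 6 flanking positions gets a 20-slot block
#' (dimension 120); under `noCys19` Cys is excluded (19 slots, dimension 114,
#' the layout used by the PSSM baseline). The central pTyr is never encoded;
#' pad and ambiguity characters contribute an all-zero block (ambiguity codes
#' raise a warning).
#'
#' @param peptides character vector of valid 7-mer windows.
#' @param scheme `"full20"` or `"noCys19"`.
#' @return binary matrix, one row per peptide, with column names
#'   `"<offset>:<aa>"` in position-major order.
#' @examples
#' rowSums(encode_peptides("AAYAAAA"))            # 6
#' ncol(encode_peptides("AAYAAAA", "noCys19"))    # 114
#' @export
encode_peptides <- function(peptides, scheme = c("full20", "noCys19")) {
  scheme <- match.arg(scheme)
  peptides <- validate_peptides(peptides)
  alpha <- encoding_alphabet(scheme)
  p <- length(alpha)
  n <- length(peptides)
  mat <- matrix(0L, nrow = n, ncol = 6L * p,
                dimnames = list(peptides,
                                paste0(rep(WINDOW_OFFSETS, each = p), ":",
                                       rep(alpha, 6L))))
  chars <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  flanks <- chars[, FLANK_IDX, drop = FALSE]
  if (any(flanks %in% UNENCODABLE))
    warning("ambiguous/unencodable residues (",
            paste(sort(unique(flanks[flanks %in% UNENCODABLE])), collapse = ", "),
            ") encoded as all-zero blocks")
  for (j in seq_len(6L)) {
    slot <- match(flanks[, j], alpha)  # NA for pad/Cys-excluded/ambiguity
    hit <- which(!is.na(slot))
    mat[cbind(hit, (j - 1L) * p + slot[hit])] <- 1L
  }
  mat
}

#' Decode a full20 encoding back to peptide windows
#'
#' Inverse of [encode_peptides()] under scheme `full20`: all-zero blocks decode
#' to the pad symbol, so windows over the plain 20-letter alphabet round-trip
#' exactly.
#'
#' @param x binary matrix with 120 columns.
#' @return character vector of 7-mer windows.
#' @export
decode_peptides <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != DIM_FULL20)
    stop("decode expects a ", DIM_FULL20, "-column full20 encoding")
  out <- apply(x, 1L, function(v) {
    flanks <- vapply(seq_len(6L), function(j) {
      block <- v[((j - 1L) * 20L + 1L):(j * 20L)]
      k <- which(block != 0)
      if (length(k) == 0L) PAD else if (length(k) == 1L) AA20[k]
      else stop("block ", j, " has ", length(k), " bits set")
    }, character(1L))
    paste0(flanks[1], flanks[2], "Y", flanks[3], flanks[4], flanks[5], flanks[6])
  })
  unname(out)
}
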