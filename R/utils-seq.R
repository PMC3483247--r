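#' IUPAC nucleotide ambiguity sets
#'
#' Mapping from IUPAC nucleotide codes to the set of bases each code matches.
#' Used for degenerate-primer matching.
#' @keywords internal
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement for plain character DNA, including IUPAC
#' ambiguity codes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTM")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Match a window against an IUPAC degenerate pattern
#'
#' Exact matching: every window base must lie in the IUPAC set of the pattern
#' at that position; no mismatches are tolerated. Unequal lengths never match.
#'
#' @param pattern IUPAC degenerate string (e.g. a degenerate primer).
#' @param window Character vector of plain DNA windows to test.
#' @return Logical vector, one element per window.
#' @examples
#' match_degenerate("TTMY", c("TTAT", "TTGT"))
#' @export
match_degenerate <- function(pattern, window) {
  stopifnot(length(pattern) == 1L)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(pat %in% names(iupac_sets))) {
    stop("pattern contains non-IUPAC characters")
  }
  np <- length(pat)
  ok_len <- nchar(window) == np
  out <- logical(length(window))
  if (!any(ok_len)) return(out)
  win <- window[ok_len]
  hit <- rep(TRUE, length(win))
  for (i in seq_len(np)) {
    hit <- hit & substr(win, i, i) %in% iupac_sets[[pat[i]]]
  }
  out[ok_len] <- hit
  out
}

#' Expand a degenerate IUPAC string into concrete realisations
#'
#' Draws one random concrete sequence per requested realisation; degenerate
#' synthesis produces an oligo mixture, so each simulated read carries one
#' realisation of the primer.
#'
#' @param pattern IUPAC degenerate string.
#' @param n Number of realisations to draw.
#' @return Character vector of length `n`.
#' @keywords internal
expand_degenerate <- function(pattern, n = 1L) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  cols <- lapply(pat, function(cc) {
    opts <- iupac_sets[[cc]]
    if (length(opts) == 1L) rep(opts, n) else sample(opts, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

# Longest common prefix length of two strings (integer-coded comparison).
lcp_len <- function(a, b) {
  na <- length(a); nb <- length(b)
  k <- min(na, nb)
  if (k == 0L) return(0L)
  mism <- which(a[seq_len(k)] != b[seq_len(k)])
  if (length(mism) == 0L) k else mism[1L] - 1L
}

# Longest common suffix length of two strings (integer-coded comparison).
lcs_len <- function(a, b) {
  na <- length(a); nb <- length(b)
  k <- min(na, nb)
  if (k == 0L) return(0L)
  mism <- which(a[na - seq_len(k) + 1L] != b[nb - seq_len(k) + 1L])
  if (length(mism) == 0L) k else mism[1L] - 1L
}

# Integer-encode a DNA string for fast per-base comparisons.
seq_ints <- function(x) utf8ToInt(x)

#' Write sequences to FASTA
#'
#' Plain-text FASTA writer with stable record order, used for simulator and
#' allele output.
#'
#' @param sequences Named character vector (names become record ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  lines <- character(2L * length(sequences))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- unname(sequences)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
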