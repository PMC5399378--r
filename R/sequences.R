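#' Normalize a nucleotide sequence to RNA spelling
#'
#' Uppercases and converts T to U.  The genome itself is kept in its input
#' alphabet elsewhere; RNA spelling is used for folding and all mature-level
#' operations, where U and T are treated as equivalent on input.
#'
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,U,N}`.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Normalize a nucleotide sequence to DNA spelling
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,T,N}`.
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement
#'
#' Works for both DNA and RNA spelling; the output uses the spelling of the
#' input (U stays U, T stays T).  `N` is self-complementary.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- if (grepl("[Uu]", s)) chartr("ACGUNacgun", "UGCANugcan", s)
            else chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Fraction of G+C bases
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param sequence character scalar or vector.
#' @return numeric in `[0, 1]`.
#' @export
gc_fraction <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  vapply(toupper(sequence), function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    v <- v[v != "N"]
    if (!length(v)) return(NA_real_)
    sum(v %in% c("G", "C")) / length(v)
  }, numeric(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length sequences (spelling-insensitive)
hamming <- function(a, b) {
  a <- as_rna(a); b <- as_rna(b)
  if (nchar(a) != nchar(b)) stop("hamming() needs equal-length sequences")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# substring with 0-based half-open coordinates (internal convention)
subseq0 <- function(s, start, end) substr(s, start + 1L, end)
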