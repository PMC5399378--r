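#' Genomic intervals and the printed locus-string convention
#'
#' Internally every interval is 0-based, half-open, on the plus strand,
#' with an explicit strand flag.  The locus-string rendering used in
#' published precursor catalogs is 1-based inclusive, with minus-strand
#' loci printed high-to-low (e.g. `"S648_2373-2295:-"`), and is treated
#' purely as a serialization format: `parse_locus()` and `format_locus()`
#' are mutual inverses on all valid strings.
#'
#' @param scaffold_id scaffold name (no underscores-with-digit-dash
#'   ambiguity is assumed beyond the final `_<a>-<b>:<strand>` suffix).
#' @param start,end 0-based half-open plus-strand span, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return `genome_interval()` returns a one-row `data.frame` with columns
#'   `scaffold`, `start`, `end`, `strand`.
#' @examples
#' iv <- parse_locus("S648_2373-2295:-")
#' interval_length(iv)  # 79
#' format_locus(iv)     # back to the input string
#' @export
genome_interval <- function(scaffold_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) ||
      any(start >= end))
    stop("invalid interval: need 0 <= start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(scaffold = scaffold_id, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' @rdname genome_interval
#' @param locus_string locus string `"<scaffold>_<a>-<b>:<strand>"` with
#'   positive 1-based inclusive coordinates; `a > b` implies minus strand.
#' @export
parse_locus <- function(locus_string) {
  m <- regmatches(locus_string,
                  regexec("^(.+)_([0-9]+)-([0-9]+):([+-])$", locus_string))
  rows <- lapply(seq_along(locus_string), function(k) {
    g <- m[[k]]
    if (length(g) != 5L)
      stop("malformed locus string: '", locus_string[k],
           "' (expected <scaffold>_<a>-<b>:<strand>)")
    a <- as.integer(g[3]); b <- as.integer(g[4])
    if (is.na(a) || is.na(b) || a < 1L || b < 1L)
      stop("malformed locus string: bad coordinate in '", locus_string[k], "'")
    strand <- g[5]
    if (a > b && strand != "-")
      stop("malformed locus string: '", locus_string[k],
           "' prints a > b but is not on the minus strand")
    genome_interval(g[2], min(a, b) - 1L, max(a, b), strand)
  })
  do.call(rbind, rows)
}

#' @rdname genome_interval
#' @param interval a `genome_interval()` data frame (possibly many rows).
#' @export
format_locus <- function(interval) {
  a <- ifelse(interval$strand == "-", interval$end, interval$start + 1L)
  b <- ifelse(interval$strand == "-", interval$start + 1L, interval$end)
  sprintf("%s_%d-%d:%s", interval$scaffold, a, b, interval$strand)
}

#' @rdname genome_interval
#' @export
interval_length <- function(interval) interval$end - interval$start

# overlap length of [s1,e1) and [s2,e2) (0 if disjoint), vectorized
overlap_length <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# reciprocal overlap fraction: overlap / length of each, both must reach frac
reciprocal_overlap <- function(s1, e1, s2, e2, frac = 0.5) {
  ov <- overlap_length(s1, e1, s2, e2)
  ov >= frac * (e1 - s1) & ov >= frac * (e2 - s2)
}
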