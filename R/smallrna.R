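#' Map small RNA reads onto a genome (ungapped, best hits only)
#'
#' Full-length ungapped placement of each read on both strands with at
#' most `max_mm` substitutions.  Per read, only the best-scoring hits
#' (score = aligned length minus mismatches) are kept; ties are all
#' retained and flagged multi-mapping.  Identity and length thresholds
#' mirror a cross-species short-read screen: identity >= `min_identity`,
#' aligned length >= `min_len`, mismatches <= `max_mm`.  Reads shorter
#' than `min_len` are dropped (their count is reported as an attribute).
#'
#' @param reads read set: data frame with `id`, `sequence`
#'   ([read_fastq()]) or named character vector, ~18-30 nt.
#' @param genome named character vector of scaffold sequences.
#' @param min_identity minimum fraction of matching positions.
#' @param min_len minimum aligned length, nt.
#' @param max_mm maximum substitutions.
#' @return data frame with `read_id`, `scaffold`, `start`, `end`,
#'   `strand`, `mismatches`, `aligned_length`, `identity`, `multi`;
#'   attribute `n_dropped_short` counts discarded short reads.
#' @export
map_reads <- function(reads, genome, min_identity = 0.90, min_len = 20L,
                      max_mm = 2L) {
  if (is.data.frame(reads))
    reads <- stats::setNames(reads$sequence, reads$id)
  short <- nchar(reads) < min_len
  n_dropped <- sum(short)
  reads <- reads[!short]
  hits <- scan_for_matures(genome, reads, max_mm)  # same Hamming engine
  names(hits)[names(hits) == "query_id"] <- "read_id"
  if (nrow(hits)) {
    hits$aligned_length <- hits$end - hits$start
    hits$identity <- (hits$aligned_length - hits$mismatches) /
      hits$aligned_length
    hits <- hits[hits$identity >= min_identity &
                 hits$aligned_length >= min_len, , drop = FALSE]
    # best hits per read: maximal score, all ties kept
    score <- hits$aligned_length - hits$mismatches
    best <- stats::ave(score, hits$read_id, FUN = max)
    hits <- hits[score == best, , drop = FALSE]
    nhit <- stats::ave(seq_len(nrow(hits)), hits$read_id,
                       FUN = length)
    hits$multi <- nhit > 1L
    rownames(hits) <- NULL
  } else {
    hits$aligned_length <- integer(0)
    hits$identity <- numeric(0)
    hits$multi <- logical(0)
  }
  attr(hits, "n_dropped_short") <- n_dropped
  hits
}

# overlap-cluster read hits on one scaffold+strand into loci; returns a
# data frame with the modal (most read-supported) hit span per locus
.hit_loci <- function(hits) {
  out <- list()
  for (key in unique(paste(hits$scaffold, hits$strand))) {
    h <- hits[paste(hits$scaffold, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, h$start[-1] >= cummax(h$end)[-nrow(h)]))
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      span <- paste(hh$start, hh$end)
      modal <- names(sort(table(span), decreasing = TRUE))[1]
      ms <- as.integer(strsplit(modal, " ")[[1]])
      out[[length(out) + 1L]] <- data.frame(
        scaffold = hh$scaffold[1], strand = hh$strand[1],
        start = ms[1], end = ms[2], n_reads = nrow(hh),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_reads = integer()))
  do.call(rbind, out)
}

#' Build precursor candidates around read-mapping loci
#'
#' Read hits are clustered into loci; each locus span plus `flank` bp on
#' both sides is scanned for the shortest window containing the hit that
#' passes the full filter battery, with the mature set to the
#' read-matched segment.  Loci clipped at scaffold edges are still
#' evaluated and flagged.
#'
#' @param hits hit table from [map_reads()].
#' @param genome named character vector of scaffold sequences.
#' @param flank flanking sequence on each side, bp.
#' @param criteria a [filter_criteria()] object.
#' @param params a [hairpin_scan_params()] object (sweep lengths/stride).
#' @param temperature folding temperature.
#' @return candidate data frame with `n_reads` support column.
#' @export
loci_from_hits <- function(hits, genome, flank = 100L,
                           criteria = filter_criteria(),
                           params = hairpin_scan_params(),
                           temperature = 37) {
  loci <- .hit_loci(hits)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    sc <- loci$scaffold[i]
    slen <- nchar(genome[[sc]])
    rs <- max(0L, loci$start[i] - flank)
    re <- min(slen, loci$end[i] + flank)
    edge <- rs == 0L && loci$start[i] - flank < 0L ||
      re == slen && loci$end[i] + flank > slen
    best <- sweep_candidate(genome[[sc]], loci$start[i], loci$end[i],
                            rs, re, loci$strand[i], criteria, params,
                            temperature)
    if (!is.null(best)) {
      row <- candidate_df(
        id = format_locus(genome_interval(sc, best$ws, best$we,
                                          loci$strand[i])),
        scaffold = sc, start = best$ws, end = best$we,
        strand = loci$strand[i], seq = best$seq,
        structure = best$structure, mfe = best$mfe, track = "smallrna",
        mat_start = best$mat_start, mat_end = best$mat_end, edge = edge)
      row$n_reads <- loci$n_reads[i]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- candidate_df()
    out$n_reads <- integer(0)
    return(out)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Exclude candidates overlapping expressed (mRNA) regions
#'
#' Candidates whose locus accumulates strictly more than `max_reads`
#' mRNA reads are removed; a locus with exactly `max_reads` is kept.
#' Coverage is matched by any overlap on the same scaffold (strand
#' blind); loci absent from the coverage table count as zero.
#'
#' @param candidates candidate data frame.
#' @param mrna_coverage data frame with `scaffold`, `start`, `end` and a
#'   `count` (or BED `score`) column of mRNA read counts.
#' @param max_reads exclusion threshold (strict `>`).
#' @return filtered candidate data frame.
#' @export
exclude_expressed <- function(candidates, mrna_coverage, max_reads = 10L) {
  if (!nrow(candidates) || is.null(mrna_coverage) || !nrow(mrna_coverage))
    return(candidates)
  cnt <- mrna_coverage$count
  if (is.null(cnt)) cnt <- suppressWarnings(as.numeric(mrna_coverage$score))
  if (is.null(cnt) || all(is.na(cnt)))
    stop("mrna_coverage needs a numeric 'count' (or 'score') column")
  total <- vapply(seq_len(nrow(candidates)), function(i) {
    m <- mrna_coverage$scaffold == candidates$scaffold[i] &
      overlap_length(mrna_coverage$start, mrna_coverage$end,
                     candidates$start[i], candidates$end[i]) > 0L
    sum(cnt[m], na.rm = TRUE)
  }, numeric(1))
  res <- candidates[total <= max_reads, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count reads supporting a mature sequence
#'
#' Number of reads within Hamming distance `max_mm` of the mature or its
#' reverse complement; when read and mature lengths differ, the shorter
#' sequence is slid ungapped along the longer one and the best placement
#' is used.
#'
#' @param mature mature miRNA sequence.
#' @param reads read set (data frame with `sequence` or character
#'   vector).
#' @param max_mm maximum substitutions.
#' @return integer count.
#' @export
count_read_support <- function(mature, reads, max_mm = 2L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (!length(reads)) return(0L)
  mat <- as_dna(mature)
  targets <- c(mat, revcomp(mat))
  sum(vapply(as_dna(reads), function(r) {
    any(vapply(targets, function(t) {
      a <- if (nchar(r) >= nchar(t)) r else t
      b <- if (nchar(r) >= nchar(t)) t else r
      nrow(.mismatch_scan_cpp(a, b, max_mm)) > 0L
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE))
}

#' Run the full small-RNA discovery track
#'
#' @inheritParams map_reads
#' @inheritParams loci_from_hits
#' @param mrna_coverage optional coverage table for
#'   [exclude_expressed()].
#' @param max_mrna_reads exclusion threshold.
#' @return list with `candidates`, `hits`.
#' @export
smallrna_track <- function(reads, genome, mrna_coverage = NULL,
                           criteria = filter_criteria(),
                           params = hairpin_scan_params(),
                           flank = 100L, max_mrna_reads = 10L,
                           min_identity = 0.90, min_len = 20L,
                           max_mm = 2L, temperature = 37) {
  hits <- map_reads(reads, genome, min_identity, min_len, max_mm)
  cand <- loci_from_hits(hits, genome, flank, criteria, params,
                         temperature)
  cand <- exclude_expressed(cand, mrna_coverage, max_mrna_reads)
  list(candidates = cand, hits = hits)
}
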