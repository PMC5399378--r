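#' Scan a genome for mismatch-limited matches to known mature miRNAs
#'
#' One exact Hamming scan over both strands replaces the classical
#' two-stage word-seeded screen plus pattern match: every genomic window
#' within `max_mismatches` substitutions of a query is reported exactly
#' once (no indels).  Coordinates are 0-based half-open on the plus
#' strand; minus-strand hits are windows whose reverse complement matches
#' the query.
#'
#' @param genome named character vector of scaffold sequences
#'   ([read_genome()]).
#' @param queries mature query set: data frame with `id` and `sequence`
#'   ([read_fasta()]) or a named character vector.
#' @param max_mismatches maximum Hamming distance.
#' @return data frame with columns `query_id`, `scaffold`, `start`,
#'   `end`, `strand`, `mismatches`.
#' @export
scan_for_matures <- function(genome, queries, max_mismatches = 2L) {
  if (is.data.frame(queries))
    queries <- stats::setNames(queries$sequence, queries$id)
  if (any(nchar(queries) < 15L))
    stop("query shorter than 15 nt is uninformative; drop it first")
  qdna <- as_dna(queries)
  out <- list()
  for (sc in names(genome)) {
    subject <- as_dna(genome[[sc]])
    for (ori in c("+", "-")) {
      qs <- if (ori == "+") qdna else revcomp(qdna)
      h <- .mismatch_scan_batch_cpp(subject, unname(qs), max_mismatches)
      if (!nrow(h)) next
      qlen <- nchar(qs)[h$query]
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(queries)[h$query], scaffold = sc,
        start = h$pos - 1L, end = h$pos - 1L + qlen, strand = ori,
        mismatches = h$mismatches, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(query_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start, res$strand, res$query_id), ]
  rownames(res) <- NULL
  res
}

#' Build precursor candidates around mature hits
#'
#' For each hit, discovery windows of `window + 2 * pad` bp are placed
#' with the mature on either arm -- the window opening `pad` bp before
#' the hit (mature on the hit-proximal arm) through the window closing
#' `pad` bp after it.  Window placement around a hit is
#' under-determined, so the whole placement range is swept: the shortest
#' window containing the hit that passes the filter battery (with the
#' mature attached) is kept, lowest MFE among equals, and then trimmed
#' of terminal unpaired runs.  Hits whose placement range is clipped at
#' a scaffold edge are still evaluated and flagged.
#'
#' @param hits hit table from [scan_for_matures()].
#' @param genome named character vector of scaffold sequences.
#' @param window core window size in bp.
#' @param pad extension on both ends in bp.
#' @param criteria a [filter_criteria()] object.
#' @param params a [hairpin_scan_params()] object (sweep lengths and
#'   stride).
#' @param temperature folding temperature.
#' @return candidate data frame (see [apply_filters()]) with mature
#'   offsets attached; sequences are in transcript orientation.
#' @export
build_precursor_candidates <- function(hits, genome, window = 110L,
                                       pad = 20L,
                                       criteria = filter_criteria(),
                                       params = hairpin_scan_params(),
                                       temperature = 37) {
  rows <- list()
  span <- window + 2L * pad
  for (i in seq_len(nrow(hits))) {
    sc <- hits$scaffold[i]
    slen <- nchar(genome[[sc]])
    hs <- hits$start[i]; he <- hits$end[i]
    # union of the two arm placements: [he + pad - span, hs - pad + span)
    rs <- he + pad - span
    re <- hs - pad + span
    edge <- rs < 0L || re > slen
    rs <- max(0L, rs); re <- min(slen, re)
    best <- sweep_candidate(genome[[sc]], hs, he, rs, re,
                            hits$strand[i], criteria, params, temperature)
    if (is.null(best)) next
    row <- candidate_df(
      id = sprintf("%s|%s", hits$query_id[i],
                   format_locus(genome_interval(sc, best$ws, best$we,
                                                hits$strand[i]))),
      scaffold = sc, start = best$ws, end = best$we,
      strand = hits$strand[i], seq = best$seq,
      structure = best$structure, mfe = best$mfe, track = "homology",
      mat_start = as.integer(best$mat_start),
      mat_end = as.integer(best$mat_end), edge = edge)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(candidate_df())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Resolve overlapping candidates by minimum folding energy
#'
#' Among candidates whose genomic spans overlap on the same strand, only
#' the best one survives.  With `prefer = "mfe"` (the classical rule)
#' that is the lowest MFE, ties toward the longer precursor, then the
#' lexicographically smallest locus string.  With `prefer = "short"`
#' (used by the structure-only scan, whose sweep is shortest-first) it
#' is the shortest candidate, ties toward lower MFE.  Applied greedily,
#' so the output is overlap-free within every connected overlap
#' component.
#'
#' @param candidates candidate data frame.
#' @param prefer representative choice, `"mfe"` or `"short"`.
#' @return filtered candidate data frame.
#' @export
resolve_overlaps <- function(candidates, prefer = c("mfe", "short")) {
  prefer <- match.arg(prefer)
  if (nrow(candidates) < 2L) return(candidates)
  locus <- format_locus(candidates)
  len <- candidates$end - candidates$start
  ord <- if (prefer == "mfe") order(candidates$mfe, -len, locus)
         else order(len, candidates$mfe, locus)
  keep <- logical(nrow(candidates))
  for (i in ord) {
    kept <- which(keep)
    clash <- kept[candidates$scaffold[kept] == candidates$scaffold[i] &
                  candidates$strand[kept] == candidates$strand[i] &
                  overlap_length(candidates$start[kept], candidates$end[kept],
                                 candidates$start[i], candidates$end[i]) > 0L]
    if (!length(clash)) keep[i] <- TRUE
  }
  res <- candidates[sort(which(keep)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full homology discovery track
#'
#' [scan_for_matures()] then [build_precursor_candidates()], the filter
#' battery, and [resolve_overlaps()].
#'
#' @inheritParams scan_for_matures
#' @inheritParams build_precursor_candidates
#' @param criteria a [filter_criteria()] object.
#' @return list with `candidates` (passing, overlap-resolved), `hits`,
#'   and `rejected`.
#' @export
homology_track <- function(genome, queries, max_mismatches = 2L,
                           criteria = filter_criteria(),
                           temperature = 37) {
  hits <- scan_for_matures(genome, queries, max_mismatches)
  cand <- build_precursor_candidates(hits, genome,
                                     temperature = temperature)
  flt <- apply_filters(cand, criteria)
  list(candidates = resolve_overlaps(flt$pass), hits = hits,
       rejected = flt$rejected)
}
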