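#' Parameters for the structure-only hairpin scan
#'
#' The scan folds genomic windows over an ascending length sweep and, per
#' position, keeps the shortest window that passes the energy and
#' single-loop checks.  An alignment-score style gate is expressed
#' structurally as `min_stem_pairs`, the minimum number of base pairs in
#' the MFE structure.  `screen_min` controls a complementarity pre-screen
#' (best local anti-diagonal score, +1 per canonical/GU pair, -1.5 per
#' mismatch) used purely for speed; set it to 0 to fold every window.
#'
#' @param window_lengths ascending sweep of window lengths, nt.
#' @param min_loop minimum hairpin loop size, nt.
#' @param stride scan stride along the genome, nt.
#' @param min_stem_pairs minimum base pairs in the MFE structure.
#' @param screen_min pre-screen score threshold (0 disables).
#' @return list of class `hairpin_scan_params`.
#' @export
hairpin_scan_params <- function(window_lengths = seq(60L, 130L, by = 10L),
                                min_loop = 5L, stride = 5L,
                                min_stem_pairs = 16L, screen_min = 15) {
  stopifnot(!is.unsorted(window_lengths), min_loop >= 3L, stride >= 1L)
  structure(list(window_lengths = as.integer(window_lengths),
                 min_loop = as.integer(min_loop),
                 stride = as.integer(stride),
                 min_stem_pairs = as.integer(min_stem_pairs),
                 screen_min = screen_min),
            class = "hairpin_scan_params")
}

# does [s,e) overlap any masked interval on this scaffold?
.masked <- function(mask, sc, s, e) {
  if (is.null(mask)) return(FALSE)
  m <- mask[mask$scaffold == sc, , drop = FALSE]
  any(overlap_length(m$start, m$end, s, e) > 0L)
}

#' De novo hairpin discovery across a genome
#'
#' Structure-only scan: genomic windows are folded in ascending length
#' order and the shortest window passing the full filter battery (plus
#' the `min_stem_pairs` gate) is emitted for each position; overlapping
#' emissions are reduced to one candidate per overlap component (lowest
#' MFE).  Windows overlapping `mask` intervals or containing `N` are
#' skipped.  Deterministic given genome and parameters.
#'
#' @param genome named character vector of scaffold sequences.
#' @param params a [hairpin_scan_params()] object.
#' @param criteria a [filter_criteria()] object.
#' @param mask optional BED-like data frame (`scaffold`, `start`, `end`)
#'   of regions to exclude (repeats, coding sequence).
#' @param temperature folding temperature.
#' @return candidate data frame, all rows passing the filter battery;
#'   each emitted window is trimmed to its stem-loop unit, with the
#'   pre-trim window recorded in `win_start`/`win_len`.
#' @export
scan_hairpins <- function(genome, params = hairpin_scan_params(),
                          criteria = filter_criteria(), mask = NULL,
                          temperature = 37) {
  rows <- list()
  wmax <- max(params$window_lengths)
  for (sc in names(genome)) {
    gseq <- as_dna(genome[[sc]])
    slen <- nchar(gseq)
    if (slen < min(params$window_lengths)) next
    wscreen <- min(wmax, slen)
    pre <- .screen_scan_cpp(gseq, wscreen, params$stride, params$min_loop)
    starts <- pre$pos[pre$score >= params$screen_min] - 1L
    # windows anchored near the scaffold end are screened by the last
    # full-size window; add its tail positions explicitly
    tail_start <- slen - wscreen
    if (tail_start >= 0L && length(pre$pos) &&
        pre$score[length(pre$score)] >= params$screen_min) {
      extra <- seq.int(max(0L, tail_start), slen - min(params$window_lengths),
                       by = params$stride)
      starts <- sort(unique(c(starts, extra)))
    }
    for (ws in starts) {
      hit <- NULL
      for (len in params$window_lengths) {
        we <- ws + len
        if (we > slen) break
        if (.masked(mask, sc, ws, we)) break
        wseq <- subseq0(gseq, ws, we)
        if (grepl("N", wseq, fixed = TRUE)) break
        if (params$screen_min > 0 &&
            .screen_hairpin_cpp(wseq, params$min_loop) < params$screen_min)
          next
        f <- fold(wseq, temperature)
        npairs <- nchar(gsub("[^(]", "", f$structure))
        if (npairs < params$min_stem_pairs) next
        frep <- evaluate_candidate(wseq, f$structure, f$mfe, criteria)
        if (frep$pass_all) {
          hit <- list(start = ws, end = we, seq = as_rna(wseq),
                      structure = f$structure, mfe = f$mfe)
          break  # shortest passing window for this position
        }
      }
      if (!is.null(hit)) {
        # trim the window to its stem-loop unit so that candidates are
        # tight hairpins (comparable across loci, e.g. for clustering);
        # fall back to the window if the trimmed unit no longer passes
        tr <- trim_to_stemloop(hit$seq, temperature)
        use_tr <- tr$end - tr$start < nchar(hit$seq) &&
          evaluate_candidate(tr$seq, tr$structure, tr$mfe,
                             criteria)$pass_all
        cs <- if (use_tr) hit$start + tr$start else hit$start
        ce <- if (use_tr) hit$start + tr$end else hit$end
        row <- candidate_df(
          id = format_locus(genome_interval(sc, cs, ce, "+")),
          scaffold = sc, start = cs, end = ce, strand = "+",
          seq = if (use_tr) tr$seq else hit$seq,
          structure = if (use_tr) tr$structure else hit$structure,
          mfe = if (use_tr) tr$mfe else hit$mfe, track = "denovo")
        row$win_start <- hit$start
        row$win_len <- nchar(hit$seq)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) return(candidate_df())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  # one candidate per overlap component; the sweep is shortest-first, so
  # the shortest emission represents the locus
  resolve_overlaps(res, prefer = "short")
}

#' Cluster candidates by identity and flag repeat families
#'
#' Greedy longest-first clustering: each unassigned sequence in length
#' order seeds a cluster and absorbs every remaining sequence whose best
#' ungapped identity over the shorter sequence (either orientation) is at
#' least `identity_threshold`.  Clusters with `repeat_min_members` or
#' more members at distinct genomic loci look like repeat families (e.g.
#' palindromic repeats that fold into hairpins) and are excluded; one
#' representative (lowest MFE) is kept for every surviving cluster.
#'
#' @param candidates candidate data frame.
#' @param identity_threshold minimum ungapped identity.
#' @param repeat_min_members cluster size at which a cluster is treated
#'   as a repeat family.
#' @return list with `candidates` (representatives of surviving
#'   clusters), `excluded` (members of repeat clusters) and `clusters`
#'   (per-candidate cluster assignment).
#' @export
cluster_and_flag_repeats <- function(candidates, identity_threshold = 0.9,
                                     repeat_min_members = 3L) {
  n <- nrow(candidates)
  if (!n)
    return(list(candidates = candidates, excluded = candidates,
                clusters = integer(0)))
  ord <- order(-nchar(candidates$seq))
  cluster <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in ord) {
    if (!is.na(cluster[i])) next
    next_id <- next_id + 1L
    cluster[i] <- next_id
    for (j in ord) {
      if (!is.na(cluster[j])) next
      idf <- max(.ungapped_identity_cpp(candidates$seq[i], candidates$seq[j]),
                 .ungapped_identity_cpp(candidates$seq[i],
                                        revcomp(candidates$seq[j])))
      if (idf >= identity_threshold) cluster[j] <- next_id
    }
  }
  # repeat call requires members at distinct genomic loci
  loci <- paste(candidates$scaffold, candidates$start, candidates$strand)
  n_loci <- tapply(loci, cluster, function(x) length(unique(x)))
  is_repeat_cluster <- as.integer(names(n_loci)[n_loci >= repeat_min_members])
  excluded <- candidates[cluster %in% is_repeat_cluster, , drop = FALSE]
  keep_idx <- integer(0)
  for (cl in setdiff(unique(cluster), is_repeat_cluster)) {
    members <- which(cluster == cl)
    keep_idx <- c(keep_idx, members[which.min(candidates$mfe[members])])
  }
  res <- candidates[sort(keep_idx), , drop = FALSE]
  rownames(res) <- NULL
  list(candidates = res, excluded = excluded, clusters = cluster)
}
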