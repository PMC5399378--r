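# Isolating the stem-loop unit of a folded window.
#
# Discovery windows carry flanking background around the true precursor.
# "Trimming" reduces a window to the maximal stem-loop unit around an
# anchor: starting from the hairpin loop nearest the anchor, the closing
# pair is extended outward through stacks, bulges and interior loops, and
# stops at any multibranch junction or the exterior loop.  The trimmed
# sequence is refolded and the procedure iterated until the span is
# stable, so the first and last positions of the final structure are
# paired.

# 1-based [start, end] span of the stem-loop unit containing/nearest the
# anchor midpoint; NULL when the structure has no hairpin loop
stemloop_unit <- function(dotbracket, anchor_mid = NULL) {
  p <- pair_table(dotbracket)
  loops <- hairpin_loop_runs(dotbracket)
  if (!nrow(loops)) return(NULL)
  if (is.null(anchor_mid)) {
    # no anchor: pick the loop of the best-supported (deepest) stem
    depth <- vapply(seq_len(nrow(loops)), function(k) {
      i <- loops$start[k] - 1L
      sum(p[seq_len(i)] > loops$end[k])
    }, numeric(1))
    k <- which.max(depth)
  } else {
    mid <- (loops$start + loops$end) / 2
    k <- which.min(abs(mid - anchor_mid))
  }
  i <- loops$start[k] - 1L
  j <- loops$end[k] + 1L
  repeat {
    a <- i - 1L
    while (a >= 1L && p[a] == 0L) a <- a - 1L
    if (a < 1L || p[a] < j) break            # exterior or sibling helix
    b <- p[a]
    between <- seq.int(j + 1L, length.out = max(0L, b - j - 1L))
    if (length(between) && any(p[between] > 0L)) break  # multibranch
    i <- a; j <- b
  }
  c(i, j)
}

# Trim a candidate window to its stem-loop unit.  `anchor` is an optional
# 0-based half-open interval (e.g. a mature hit) inside `sequence`; the
# returned offsets map the trimmed span back into the window.
trim_to_stemloop <- function(sequence, temperature = 37, anchor = NULL,
                             max_iter = 5L) {
  off <- 0L
  seq_cur <- sequence
  f <- fold(seq_cur, temperature)
  for (iter in seq_len(max_iter)) {
    mid <- if (!is.null(anchor)) (anchor[1] + anchor[2]) / 2 - off else NULL
    span <- stemloop_unit(f$structure, mid)
    if (is.null(span)) break
    if (span[1] == 1L && span[2] == nchar(seq_cur)) break
    seq_new <- substr(seq_cur, span[1], span[2])
    if (nchar(seq_new) < 10L) break
    off <- off + span[1] - 1L
    seq_cur <- seq_new
    f <- fold(seq_cur, temperature)
  }
  list(start = off, end = off + nchar(seq_cur), seq = seq_cur,
       structure = f$structure, mfe = f$mfe)
}

# Trim terminal unpaired runs (never cutting into [keep_s, keep_e),
# 0-based) and refold until stable.
trim_unpaired_ends <- function(sequence, keep_s = NA, keep_e = NA,
                               temperature = 37, max_iter = 5L) {
  off <- 0L
  f <- fold(sequence, temperature)
  for (it in seq_len(max_iter)) {
    p <- pair_table(f$structure)
    paired <- which(p > 0L)
    if (!length(paired)) break
    s <- paired[1] - 1L; e <- paired[length(paired)]  # 0-based half-open
    if (!is.na(keep_s)) s <- min(s, keep_s - off)
    if (!is.na(keep_e)) e <- max(e, keep_e - off)
    s <- max(s, 0L); e <- min(e, nchar(sequence))
    if (s == 0L && e == nchar(sequence)) break
    sequence <- substr(sequence, s + 1L, e)
    off <- off + s
    if (nchar(sequence) < 10L) break
    f <- fold(sequence, temperature)
  }
  list(start = off, end = off + nchar(sequence), seq = sequence,
       structure = f$structure, mfe = f$mfe)
}

# Shortest window inside [region_s, region_e) that contains the anchor
# [mat_s, mat_e) and passes the full filter battery with the mature
# attached; among passing windows of that length the lowest MFE wins.
# The chosen window is then trimmed of terminal unpaired runs.  Windows
# and coordinates are genomic plus-strand; evaluation happens in
# transcript orientation.  Returns NULL if nothing passes.
sweep_candidate <- function(gseq, mat_s, mat_e, region_s, region_e,
                            strand, criteria, params, temperature = 37) {
  best <- NULL
  for (len in params$window_lengths) {
    if (len > region_e - region_s) break
    ws_min <- max(region_s, mat_e - len)
    ws_max <- min(region_e - len, mat_s)
    if (ws_max < ws_min) next
    for (ws in seq.int(ws_min, ws_max, by = params$stride)) {
      we <- ws + len
      wseq <- subseq0(gseq, ws, we)
      if (grepl("N", wseq, fixed = TRUE)) next
      if (params$screen_min > 0 &&
          .screen_hairpin_cpp(wseq, params$min_loop) < params$screen_min)
        next
      if (strand == "+") {
        m0 <- mat_s - ws; m1 <- mat_e - ws
        cseq <- as_rna(wseq)
      } else {
        m0 <- we - mat_e; m1 <- we - mat_s
        cseq <- as_rna(revcomp(wseq))
      }
      f <- fold(cseq, temperature)
      frep <- evaluate_candidate(cseq, f$structure, f$mfe, criteria,
                                 mat_start = m0, mat_end = m1)
      if (!frep$pass_all) next
      # among passing windows of this length prefer the placement that
      # pairs the mature best (a cut partner arm unpairs the mature
      # edge), then the lower energy
      pt <- pair_table(f$structure)
      mp <- mean(pt[seq.int(m0 + 1L, m1)] > 0L)
      if (is.null(best) || mp > best$mature_paired + 1e-9 ||
          (abs(mp - best$mature_paired) <= 1e-9 && f$mfe < best$mfe))
        best <- list(ws = ws, we = we, seq = cseq,
                     structure = f$structure, mfe = f$mfe,
                     mat_start = m0, mat_end = m1, mature_paired = mp)
    }
    if (!is.null(best)) break  # shortest passing window length
  }
  if (is.null(best)) return(NULL)
  # polish: drop terminal unpaired runs (keeping the mature intact);
  # if the refolded trim no longer passes, fall back to a plain strip
  # of the chosen window's terminal dots (same fold, no refold)
  tr <- trim_unpaired_ends(best$seq, best$mat_start, best$mat_end,
                           temperature)
  tr_ok <- tr$end - tr$start < nchar(best$seq) &&
    evaluate_candidate(tr$seq, tr$structure, tr$mfe, criteria,
                       mat_start = best$mat_start - tr$start,
                       mat_end = best$mat_end - tr$start)$pass_all
  if (!tr_ok) {
    p <- pair_table(best$structure)
    paired <- which(p > 0L)
    if (length(paired)) {
      s <- min(paired[1] - 1L, best$mat_start)
      e <- max(paired[length(paired)], best$mat_end)
      tr <- list(start = s, end = e,
                 seq = substr(best$seq, s + 1L, e),
                 structure = substr(best$structure, s + 1L, e),
                 mfe = best$mfe)
      tr_ok <- (e - s) < nchar(best$seq) &&
        evaluate_candidate(tr$seq, tr$structure, tr$mfe, criteria,
                           mat_start = best$mat_start - s,
                           mat_end = best$mat_end - s)$pass_all
    }
  }
  if (tr$end - tr$start < nchar(best$seq)) {
    if (tr_ok) {
      if (strand == "+") {
        best$ws <- best$ws + tr$start
        best$we <- best$ws + (tr$end - tr$start)
      } else {
        best$we <- best$we - tr$start
        best$ws <- best$we - (tr$end - tr$start)
      }
      best$mat_start <- best$mat_start - tr$start
      best$mat_end <- best$mat_end - tr$start
      best$seq <- tr$seq; best$structure <- tr$structure
      best$mfe <- tr$mfe
    }
  }
  best
}
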