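#' Infer 5p/3p mature arms of a single-loop precursor
#'
#' Searches for a paired-segment pattern: a 5' segment of `min_len` to
#' `max_len` nt whose reverse complement matches a 3' segment with at
#' most `max_mm` mismatches, the two segments separated by `gap_min` to
#' `gap_max` nt.  Both arms must lie entirely outside the hairpin loop
#' run, on their own side.  Among valid pairs, the one whose arms abut
#' the loop most closely (minimal summed distance to the loop run) wins;
#' ties break toward fewer mismatches, then longer arms, then the
#' leftmost 5' start.  If no pair matches, the 24-nt windows immediately
#' flanking the loop on each arm are returned (`method = "fallback24"`,
#' clipped at the precursor ends).
#'
#' @param sequence precursor sequence.
#' @param fold_result its [fold()] result (must have exactly one hairpin
#'   loop).
#' @param min_len,max_len arm length bounds, nt.
#' @param gap_min,gap_max separation bounds between the arms, nt.
#' @param max_mm maximum mismatches between the 5' arm and the reverse
#'   complement of the 3' arm.
#' @return list of class `mature_call`: `p5` and `p3` (0-based half-open
#'   intervals within the precursor), `method` (`"pair_pattern"` or
#'   `"fallback24"`), `pair_mismatches` (NA for fallback).
#' @export
infer_mature <- function(sequence, fold_result, min_len = 22L,
                         max_len = 27L, gap_min = 5L, gap_max = 50L,
                         max_mm = 6L) {
  db <- fold_result$structure
  if (count_hairpin_loops(db) != 1L)
    stop("mature inference needs a single-loop fold (got ",
         count_hairpin_loops(db), " loops)")
  loop <- hairpin_loop_runs(db)  # 1-based inclusive
  rna <- as_rna(sequence)
  hits <- .pair_pattern_scan_cpp(rna, min_len, max_len, gap_min, gap_max,
                                 max_mm)
  if (nrow(hits)) {
    # arms must sit on their own side of the loop, outside the loop run
    e5 <- hits$start5 + hits$len - 1L       # 1-based inclusive ends
    s3 <- hits$start3
    ok <- e5 < loop$start & s3 > loop$end
    hits <- hits[ok, , drop = FALSE]
    e5 <- e5[ok]; s3 <- s3[ok]
  }
  if (nrow(hits)) {
    dist <- (loop$start - 1L - e5) + (s3 - loop$end - 1L)
    ord <- order(dist, hits$mismatches, -hits$len, hits$start5)
    b <- hits[ord[1], ]
    call <- list(p5 = c(b$start5 - 1L, b$start5 - 1L + b$len),
                 p3 = c(b$start3 - 1L, b$start3 - 1L + b$len),
                 method = "pair_pattern", pair_mismatches = b$mismatches)
  } else {
    L <- nchar(rna)
    call <- list(p5 = c(max(0L, loop$start - 1L - 24L), loop$start - 1L),
                 p3 = c(loop$end, min(L, loop$end + 24L)),
                 method = "fallback24", pair_mismatches = NA_integer_)
  }
  class(call) <- "mature_call"
  call
}

#' Extract the mature sequences named by a mature call
#' @param sequence precursor sequence.
#' @param call a `mature_call` from [infer_mature()].
#' @return named character vector with elements `5p` and `3p`.
#' @export
mature_sequences <- function(sequence, call) {
  rna <- as_rna(sequence)
  c(`5p` = subseq0(rna, call$p5[1], call$p5[2]),
    `3p` = subseq0(rna, call$p3[1], call$p3[2]))
}

#' Resolve the originating strand of a precursor from layered evidence
#'
#' Evidence classes are consulted in a fixed priority order --
#' `reference_mature_hit`, then `est_hit`, then `smallrna_hit` -- and the
#' first non-empty class decides, taking its best-scoring item.  A score
#' tie between strands within the winning class falls back to the plus
#' strand and is flagged.  With no evidence at all the precursor is
#' tentatively represented on the plus strand.
#'
#' @param evidence data frame with columns `source` (one of the three
#'   classes), `strand` (`"+"`/`"-"`), `score` (numeric, higher wins).
#' @return list with `strand`, `provenance` (winning class or
#'   `"default_plus"`), `tied` flag.
#' @export
infer_strand <- function(evidence = NULL) {
  classes <- c("reference_mature_hit", "est_hit", "smallrna_hit")
  if (!is.null(evidence) && nrow(evidence)) {
    bad <- setdiff(unique(evidence$source), classes)
    if (length(bad)) stop("unknown evidence class: ", bad[1])
    for (cl in classes) {
      e <- evidence[evidence$source == cl, , drop = FALSE]
      if (!nrow(e)) next
      top <- e[e$score == max(e$score), , drop = FALSE]
      strands <- unique(top$strand)
      if (length(strands) == 1L)
        return(list(strand = strands, provenance = cl, tied = FALSE))
      return(list(strand = "+", provenance = cl, tied = TRUE))
    }
  }
  list(strand = "+", provenance = "default_plus", tied = FALSE)
}

#' Assign the seed family of a mature miRNA
#'
#' The family seed is mature nucleotides 2-7 (1-based); matures sharing
#' the seed belong to the same family.
#'
#' @param mature mature sequence(s), at least 7 nt.
#' @return character vector of 6-mer seeds (RNA spelling).
#' @export
assign_family <- function(mature) {
  if (any(nchar(mature) < 7L))
    stop("mature shorter than 7 nt has no seed")
  substr(as_rna(mature), 2L, 7L)
}

#' Merge the three discovery tracks into one catalog with Venn counts
#'
#' Candidates whose precursor spans overlap reciprocally by at least
#' `min_reciprocal` on the same scaffold and strand are unified into one
#' locus (representative = lowest MFE); each merged locus records the
#' set of tracks that found it.  The Venn decomposition over the three
#' tracks is returned alongside.
#'
#' @param homology,denovo,smallrna candidate data frames (any may be
#'   empty or NULL); their `track` columns are set accordingly.
#' @param min_reciprocal reciprocal-overlap fraction defining "same
#'   locus".
#' @return list with `catalog` (merged candidate table, `tracks` column
#'   comma-separated) and `venn` (named integer vector over the 7
#'   regions plus `union`).
#' @export
merge_tracks <- function(homology = NULL, denovo = NULL, smallrna = NULL,
                         min_reciprocal = 0.5) {
  sets <- list(homology = homology, denovo = denovo, smallrna = smallrna)
  all <- list()
  for (tr in names(sets)) {
    d <- sets[[tr]]
    if (is.null(d) || !nrow(d)) next
    d <- d[, intersect(names(d), names(candidate_df())), drop = FALSE]
    d$track <- tr
    all[[tr]] <- d
  }
  empty_venn <- stats::setNames(
    integer(8), c("homology", "denovo", "smallrna", "homology+denovo",
                  "homology+smallrna", "denovo+smallrna",
                  "homology+denovo+smallrna", "union"))
  if (!length(all)) return(list(catalog = candidate_df(), venn = empty_venn))
  x <- do.call(rbind, all)
  rownames(x) <- NULL
  n <- nrow(x)
  # union-find over reciprocal-overlap edges (same scaffold + strand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (x$scaffold[i] != x$scaffold[j] || x$strand[i] != x$strand[j]) next
    if (reciprocal_overlap(x$start[i], x$end[i], x$start[j], x$end[j],
                           min_reciprocal)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  rows <- list(); venn <- empty_venn
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    tracks <- sort(unique(x$track[members]))
    rep_i <- members[which.min(x$mfe[members])]
    row <- x[rep_i, , drop = FALSE]
    row$tracks <- paste(tracks, collapse = ",")
    rows[[length(rows) + 1L]] <- row
    key <- paste(intersect(c("homology", "denovo", "smallrna"), tracks),
                 collapse = "+")
    venn[key] <- venn[key] + 1L
  }
  venn["union"] <- sum(venn[names(venn) != "union"])
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  list(catalog = catalog, venn = venn)
}

#' Classify conservation of miRNA families from a presence matrix
#'
#' A family present in at least one non-tunicate species is widely
#' conserved; a family present only in tunicates, in at least two of
#' them (the focal species included), is tunicate specific; a family
#' seen only in the focal species -- or absent from the matrix, which is
#' flagged -- is species specific.
#'
#' @param families character vector of family names to classify.
#' @param matrix presence data frame: column `family` plus one
#'   logical/0-1 column per species.
#' @param clades named character vector mapping species column names to
#'   `"tunicate"` or `"other_metazoan"`.
#' @param focal name of the focal species column (must be present).
#' @return data frame with `family`, `class`, `flag`.
#' @export
classify_conservation <- function(families, matrix, clades, focal) {
  if (!focal %in% names(matrix))
    stop("focal species column '", focal, "' absent from matrix")
  species <- setdiff(names(matrix), "family")
  if (!all(species %in% names(clades)))
    stop("every species column needs a clade annotation")
  res <- lapply(families, function(fam) {
    row <- matrix[matrix$family == fam, , drop = FALSE]
    if (!nrow(row))
      return(data.frame(family = fam, class = "species_specific",
                        flag = "unmatched"))
    present <- species[as.logical(row[1, species])]
    non_tunicate <- present[clades[present] == "other_metazoan"]
    tunicate <- present[clades[present] == "tunicate"]
    cl <- if (length(non_tunicate)) "widely_conserved"
          else if (length(tunicate) >= 2L) "tunicate_specific"
          else "species_specific"
    data.frame(family = fam, class = cl, flag = "")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Re-scan mature miRNAs against a second genome
#'
#' Per mature: best ungapped genomic match with at most `max_mm`
#' mismatches over at least `min_len` aligned nt (full length first,
#' then `min_len`-nt windows of the mature).  Each matched locus plus or
#' minus `flank` bp is then searched for the shortest window passing the
#' full filter battery at `refold_temp` (canonical stem-loop check).
#'
#' @param matures data frame (`id`, `sequence`) or named character
#'   vector of mature sequences.
#' @param other_genome named character vector of scaffold sequences.
#' @param max_mm maximum mismatches (2 or 4 in practice).
#' @param min_len minimum aligned length for partial matches.
#' @param refold_temp folding temperature for the stem-loop check.
#' @param criteria a [filter_criteria()] object.
#' @param flank flank size around the match.
#' @param params a [hairpin_scan_params()] object.
#' @return list with `per_mature` (data frame `id`, `hit`,
#'   `canonical_stemloop`, `mismatches`) and `summary` (`n`, `n_hit`,
#'   `frac_hit`, `n_canonical`, `frac_canonical_of_hit`).
#' @export
rescan_homologs <- function(matures, other_genome, max_mm = 4L,
                            min_len = 20L, refold_temp = 18,
                            criteria = filter_criteria(), flank = 100L,
                            params = hairpin_scan_params()) {
  if (is.data.frame(matures))
    matures <- stats::setNames(matures$sequence, matures$id)
  per <- lapply(names(matures), function(id) {
    q <- matures[[id]]
    hits <- scan_for_matures(other_genome, stats::setNames(q, id), max_mm)
    if (!nrow(hits) && nchar(q) > min_len) {
      # tolerate end trimming: try min_len-nt windows of the mature
      wins <- vapply(seq_len(nchar(q) - min_len + 1L), function(o)
        substr(q, o, o + min_len - 1L), character(1))
      names(wins) <- paste0(id, "#", seq_along(wins))
      hits <- scan_for_matures(other_genome, wins, max_mm)
    }
    if (!nrow(hits))
      return(data.frame(id = id, hit = FALSE, canonical_stemloop = FALSE,
                        mismatches = NA_integer_))
    best <- hits[which.min(hits$mismatches), ]
    pseudo <- data.frame(read_id = id, scaffold = best$scaffold,
                         start = best$start, end = best$end,
                         strand = best$strand,
                         mismatches = best$mismatches)
    cand <- loci_from_hits(pseudo, other_genome, flank, criteria, params,
                           temperature = refold_temp)
    data.frame(id = id, hit = TRUE, canonical_stemloop = nrow(cand) > 0L,
               mismatches = best$mismatches)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  n <- nrow(per); n_hit <- sum(per$hit); n_can <- sum(per$canonical_stemloop)
  list(per_mature = per,
       summary = list(n = n, n_hit = n_hit,
                      frac_hit = if (n) n_hit / n else NA_real_,
                      n_canonical = n_can,
                      frac_canonical_of_hit =
                        if (n_hit) n_can / n_hit else NA_real_))
}

#' Resolve candidate strands from mapped evidence tables
#'
#' Assembles per-candidate [infer_strand()] evidence from hit tables:
#' reference-mature hits, EST hits and small-RNA read hits overlapping
#' the candidate span (same scaffold).  Scores are `-mismatches` when a
#' `mismatches` column is present, otherwise 0.  Candidates without any
#' overlapping evidence stay on the plus strand (`default_plus`).
#'
#' @param candidates candidate data frame.
#' @param ref_hits,est_hits,read_hits optional hit tables with
#'   `scaffold`, `start`, `end`, `strand` (and `mismatches`) columns.
#' @return the candidate data frame with `strand` replaced and a
#'   `strand_provenance` column appended.
#' @export
resolve_catalog_strands <- function(candidates, ref_hits = NULL,
                                    est_hits = NULL, read_hits = NULL) {
  if (!nrow(candidates)) return(candidates)
  pick <- function(hits, sc, s, e, source) {
    if (is.null(hits) || !nrow(hits)) return(NULL)
    m <- hits$scaffold == sc &
      overlap_length(hits$start, hits$end, s, e) > 0L
    if (!any(m)) return(NULL)
    score <- if (!is.null(hits$mismatches)) -hits$mismatches[m] else 0
    data.frame(source = source, strand = hits$strand[m], score = score)
  }
  prov <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ev <- rbind(
      pick(ref_hits, candidates$scaffold[i], candidates$start[i],
           candidates$end[i], "reference_mature_hit"),
      pick(est_hits, candidates$scaffold[i], candidates$start[i],
           candidates$end[i], "est_hit"),
      pick(read_hits, candidates$scaffold[i], candidates$start[i],
           candidates$end[i], "smallrna_hit"))
    call <- infer_strand(ev)
    if (call$strand != candidates$strand[i]) {
      # re-orient the stored sequence and mature offsets
      L <- nchar(candidates$seq[i])
      candidates$seq[i] <- revcomp(candidates$seq[i])
      candidates$structure[i] <- NA_character_
      if (!is.na(candidates$mat_start[i])) {
        ms <- candidates$mat_start[i]; me <- candidates$mat_end[i]
        candidates$mat_start[i] <- L - me
        candidates$mat_end[i] <- L - ms
      }
      candidates$strand[i] <- call$strand
    }
    prov[i] <- call$provenance
  }
  # refold re-oriented candidates so structures stay consistent
  redo <- which(is.na(candidates$structure))
  for (i in redo) {
    f <- fold(candidates$seq[i])
    candidates$structure[i] <- f$structure
    candidates$mfe[i] <- f$mfe
  }
  candidates$strand_provenance <- prov
  candidates
}
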