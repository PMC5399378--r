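#' Configuration of the synthetic genome generator
#'
#' The generator states a world matching what the pipeline is built for:
#' an AT-rich genome (default background GC 0.35, as in ascidian
#' genomes), canonical single-loop precursors of 60-130 nt planted on
#' random strands, ~26-nt reads sampled from the dominant mature arm at
#' a given depth with substitution errors, and reference matures
#' diverged from the planted truth by an exact number of substitutions.
#'
#' @param genome_length scaffold length, nt.
#' @param background_gc background GC fraction.
#' @param n_precursors number of planted precursors.
#' @param stem_len_range inclusive range of stem lengths (base pairs).
#' @param loop_len_range inclusive range of hairpin loop sizes (>= 5).
#' @param stem_mismatch_range inclusive range of planted stem
#'   mismatches.
#' @param gu_fraction fraction of stem pairs converted to G-U wobbles.
#' @param mature_len planted mature length, nt (matches the read
#'   length).
#' @param n_repeat_copies copies of one planted palindromic repeat
#'   (0 disables).
#' @param read_depth mean reads per expressed mature (Poisson).
#' @param read_error_rate per-base substitution error rate of reads.
#' @param divergence_to_reference substitutions between planted matures
#'   and the emitted reference query set.
#' @param seed integer seed; every generator output is a pure function
#'   of the configuration including the seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 200000L,
                             background_gc = 0.35,
                             n_precursors = 50L,
                             stem_len_range = c(28L, 45L),
                             loop_len_range = c(5L, 15L),
                             stem_mismatch_range = c(0L, 3L),
                             gu_fraction = 0.10,
                             mature_len = 26L,
                             n_repeat_copies = 0L,
                             read_depth = 30,
                             read_error_rate = 0.01,
                             divergence_to_reference = 0L,
                             seed = 1L) {
  stopifnot(loop_len_range[1] >= 5L, stem_len_range[1] >= 16L,
            background_gc >= 0, background_gc <= 1,
            read_error_rate >= 0, read_error_rate <= 1,
            stem_len_range[1] <= stem_len_range[2],
            loop_len_range[1] <= loop_len_range[2],
            mature_len <= stem_len_range[1])
  structure(as.list(environment()), class = "synthetic_config")
}

.DNA <- c("A", "C", "G", "T")

.random_dna <- function(n, gc) {
  paste(sample(.DNA, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate one canonical precursor with planted matures
#'
#' Arm A is random, arm B its reverse complement with `n_mismatch`
#' substitutions and a `gu_frac` share of pairs converted to G-U
#' wobbles; the hairpin is `armA + loop + armB`.  The planted 5p mature
#' is the `mature_len`-nt stretch of arm A abutting the loop and the 3p
#' mature its counterpart on arm B.  The construct is folded and must
#' pass the full filter battery (with the 5p mature attached); failing
#' draws are regenerated up to `max_tries` times.  Uses the R RNG: seed
#' outside for determinism.
#'
#' @param stem_len stem length (pairs), >= 16.
#' @param loop_len hairpin loop size, >= 5.
#' @param n_mismatch substitutions planted into arm B.
#' @param gu_frac fraction of stem positions converted to G-U.
#' @param mature_len planted mature length.
#' @param criteria a [filter_criteria()] object used for verification.
#' @param temperature verification folding temperature.
#' @param max_tries regeneration budget.
#' @param min_duplex_defects minimum number of non-Watson-Crick stem
#'   positions (wobbles plus mismatches) placed inside the mature
#'   window.  Real mature/star duplexes are never perfectly
#'   complementary; this floor keeps the two arms distinguishable by a
#'   mismatch-limited scan.
#' @return list with `seq` (DNA), `structure`, `mfe`, `p5`, `p3`
#'   (0-based half-open intervals within the precursor).
#' @export
make_precursor <- function(stem_len, loop_len, n_mismatch = 0L,
                           gu_frac = 0, mature_len = 26L,
                           criteria = filter_criteria(),
                           temperature = 37, max_tries = 50L,
                           min_duplex_defects = 3L) {
  if (loop_len < 5L) stop("loop_len must be >= 5")
  if (stem_len < 16L) stop("stem_len must be >= 16")
  if (mature_len > stem_len) stop("mature_len cannot exceed stem_len")
  for (try in seq_len(max_tries)) {
    armA <- strsplit(.random_dna(stem_len, gc = 0.5), "")[[1]]
    armB <- strsplit(revcomp(paste(armA, collapse = "")), "")[[1]]
    # armB[k] pairs armA[stem_len + 1 - k]; the planted matures cover
    # armB positions 1..mature_len (and the paired armA positions)
    n_gu <- max(round(gu_frac * stem_len),
                min_duplex_defects - n_mismatch)
    n_mut <- min(stem_len, n_gu + n_mismatch)
    n_in_mat <- min(mature_len, max(min_duplex_defects, 0L), n_mut)
    outside <- setdiff(seq_len(stem_len), seq_len(mature_len))
    n_out <- min(length(outside), n_mut - n_in_mat)
    mut <- c(sample(mature_len, n_mut - n_out),
             if (n_out) sample(outside, n_out))
    mut <- sample(mut)  # shuffle so head/tail split is unbiased
    gu_pos <- utils::head(mut, n_gu)
    mm_pos <- utils::tail(mut, length(mut) - n_gu)
    for (k in gu_pos) {
      a <- armA[stem_len + 1L - k]
      if (a == "G") armB[k] <- "T"
      else if (a == "T") armB[k] <- "G"
      else mm_pos <- c(mm_pos, k)  # A/C cannot wobble: plant a mismatch
    }
    for (k in mm_pos) {
      a <- armA[stem_len + 1L - k]
      non_pairing <- switch(a, A = c("A", "C", "G"), C = c("A", "C", "T"),
                            G = c("A", "G"), T = c("C", "T"))
      armB[k] <- sample(non_pairing, 1L)
    }
    loop <- .random_dna(loop_len, gc = 0.35)
    seq <- paste0(paste(armA, collapse = ""), loop,
                  paste(armB, collapse = ""))
    L <- nchar(seq)
    p5 <- c(stem_len - mature_len, stem_len)
    p3 <- c(stem_len + loop_len, stem_len + loop_len + mature_len)
    f <- fold(seq, temperature)
    frep <- evaluate_candidate(seq, f$structure, f$mfe, criteria,
                               mat_start = p5[1], mat_end = p5[2])
    if (frep$pass_all)
      return(list(seq = seq, structure = f$structure, mfe = f$mfe,
                  p5 = p5, p3 = p3))
  }
  stop("could not generate a passing precursor in ", max_tries,
       " tries (parameters may be unreachable)")
}

#' Plant a synthetic genome with ground truth
#'
#' I.i.d. background at the configured GC with `n_precursors` canonical
#' precursors planted non-overlapping on random strands (minus-strand
#' plantings insert the reverse complement), plus an optional
#' palindromic repeat family planted `n_repeat_copies` times.
#' Deterministic given the configuration (which includes the seed).
#'
#' @param config a [synthetic_config()] object.
#' @return list with `genome` (named character vector, one scaffold
#'   `"S1"`) and `truth` (data frame: one row per planting with
#'   precursor/mature genomic intervals, strand, mature sequences in
#'   transcript orientation, `dominant_arm`, `family_seed`,
#'   `is_repeat`).
#' @export
plant_genome <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n_total <- config$n_precursors + config$n_repeat_copies
  slot <- config$genome_length %/% max(1L, n_total)
  min_needed <- n_total * (2L * config$stem_len_range[2] +
                             config$loop_len_range[2] + 400L)
  if (config$genome_length < min_needed)
    stop("genome too small for the requested plantings; need >= ",
         min_needed, " nt")
  genome <- .random_dna(config$genome_length, config$background_gc)
  repeat_unit <- NULL
  if (config$n_repeat_copies > 0L)
    repeat_unit <- make_precursor(
      sample(seq(config$stem_len_range[1], config$stem_len_range[2]), 1L),
      sample(seq(config$loop_len_range[1], config$loop_len_range[2]), 1L),
      0L, 0, config$mature_len)
  rows <- list()
  for (i in seq_len(n_total)) {
    is_rep <- i > config$n_precursors
    pre <- if (is_rep) repeat_unit else make_precursor(
      sample(seq(config$stem_len_range[1], config$stem_len_range[2]), 1L),
      sample(seq(config$loop_len_range[1], config$loop_len_range[2]), 1L),
      sample(seq(config$stem_mismatch_range[1],
                 config$stem_mismatch_range[2]), 1L),
      config$gu_fraction, config$mature_len)
    L <- nchar(pre$seq)
    # one planting per slot, margin 200 nt from slot edges
    lo <- (i - 1L) * slot + 200L
    hi <- i * slot - 200L - L
    if (hi <= lo) stop("slots too small; enlarge the genome")
    start <- sample(seq(lo, hi), 1L)
    strand <- sample(c("+", "-"), 1L)
    inserted <- if (strand == "+") pre$seq else revcomp(pre$seq)
    substr(genome, start + 1L, start + L) <- inserted
    # genomic mature intervals (plus-strand coordinates)
    tx_to_genomic <- function(iv) {
      if (strand == "+") c(start + iv[1], start + iv[2])
      else c(start + L - iv[2], start + L - iv[1])
    }
    g5 <- tx_to_genomic(pre$p5); g3 <- tx_to_genomic(pre$p3)
    mat5 <- as_rna(subseq0(pre$seq, pre$p5[1], pre$p5[2]))
    mat3 <- as_rna(subseq0(pre$seq, pre$p3[1], pre$p3[2]))
    rows[[i]] <- data.frame(
      id = sprintf("pre%03d", i), scaffold = "S1",
      start = start, end = start + L, strand = strand,
      p5_start = g5[1], p5_end = g5[2], p3_start = g3[1], p3_end = g3[2],
      mature_5p = mat5, mature_3p = mat3,
      dominant_arm = if (is_rep) "5p" else sample(c("5p", "3p"), 1L),
      family_seed = assign_family(mat5),
      mfe = pre$mfe, is_repeat = is_rep, stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character(),
               p5_start = integer(), p5_end = integer(),
               p3_start = integer(), p3_end = integer(),
               mature_5p = character(), mature_3p = character(),
               dominant_arm = character(), family_seed = character(),
               mfe = numeric(), is_repeat = logical())
  rownames(truth) <- NULL
  list(genome = c(S1 = genome), truth = truth)
}

#' Sample sequencing reads from planted matures
#'
#' Poisson(`depth`) 26-nt-style reads per non-repeat planting, drawn
#' from the dominant mature arm in transcript orientation, with i.i.d.
#' substitution errors at `error_rate`.  Read names encode the planting
#' of origin for truth evaluation.
#'
#' @param truth truth table from [plant_genome()].
#' @param depth mean reads per mature.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return data frame with `id`, `sequence` (DNA spelling).
#' @export
make_reads <- function(truth, depth = 30, error_rate = 0.01, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(truth))) {
    if (truth$is_repeat[i]) next
    mat <- as_dna(if (truth$dominant_arm[i] == "5p")
      truth$mature_5p[i] else truth$mature_3p[i])
    n <- stats::rpois(1L, depth)
    if (n == 0L) next
    reads <- vapply(seq_len(n), function(k) {
      v <- strsplit(mat, "")[[1]]
      err <- which(stats::runif(length(v)) < error_rate)
      for (p in err) v[p] <- sample(setdiff(.DNA, v[p]), 1L)
      paste(v, collapse = "")
    }, character(1))
    out[[length(out) + 1L]] <- data.frame(
      id = sprintf("read_%s_%d", truth$id[i], seq_len(n)),
      sequence = reads, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(), sequence = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emit a reference mature set diverged from the planted truth
#'
#' One query per planted mature arm (5p and 3p of every non-repeat
#' planting) with exactly `divergence` substitutions.  Substituted
#' positions avoid the seed (nucleotides 2-7) so that family assignment
#' stays stable at the divergences the homology cutoff is exercised at,
#' and substituted bases are chosen so they never restore
#' complementarity with the opposite arm (the query's Hamming distance
#' to every planted genomic window is then exactly `divergence` at its
#' own arm and at least the planted duplex-defect count elsewhere).
#'
#' @param truth truth table from [plant_genome()].
#' @param divergence number of substitutions per query.
#' @param seed integer seed.
#' @return data frame with `id`, `sequence` (RNA spelling).
#' @export
make_reference_matures <- function(truth, divergence = 0L, seed = 1L) {
  set.seed(seed)
  truth <- truth[!truth$is_repeat, , drop = FALSE]
  rows <- list()
  RNA <- c("A", "C", "G", "U")
  for (i in seq_len(nrow(truth))) {
    for (arm in c("5p", "3p")) {
      mat <- if (arm == "5p") truth$mature_5p[i] else truth$mature_3p[i]
      other <- if (arm == "5p") truth$mature_3p[i] else truth$mature_5p[i]
      v <- strsplit(as_rna(mat), "")[[1]]
      cp <- strsplit(revcomp(as_rna(other)), "")[[1]]  # aligned counterpart
      if (divergence > length(v)) stop("divergence exceeds mature length")
      allowed <- setdiff(seq_along(v), 2:7)
      if (divergence > length(allowed))
        stop("divergence too large to keep the seed intact")
      for (p in sample(allowed, divergence)) {
        choices <- setdiff(RNA, c(v[p], cp[p]))
        v[p] <- sample(choices, 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("ref_%s_%s", truth$id[i], arm),
        sequence = paste(v, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Synthetic 3' UTR set with planted target sites
#'
#' Random-background UTRs; in `n_planted` of them a perfect
#' reverse-complement site of one miRNA is planted at a random offset.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param n_utr number of UTRs.
#' @param utr_len UTR length.
#' @param n_planted number of UTRs carrying a planted site.
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @return list with `utrs` (data frame `gene_id`, `sequence`) and
#'   `truth` (data frame `gene_id`, `mirna_id`, `position`).
#' @export
make_target_utrs <- function(mirnas, n_utr = 50L, utr_len = 400L,
                             n_planted = 10L, gc = 0.35, seed = 1L) {
  set.seed(seed)
  stopifnot(n_planted <= n_utr)
  utrs <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_utr)),
                     sequence = vapply(seq_len(n_utr), function(i)
                       .random_dna(utr_len, gc), character(1)),
                     stringsAsFactors = FALSE)
  planted <- sample(n_utr, n_planted)
  truth <- list()
  for (g in planted) {
    mid <- sample(names(mirnas), 1L)
    site <- as_dna(revcomp(mirnas[[mid]]))
    pos <- sample(utr_len - nchar(site), 1L)
    s <- utrs$sequence[g]
    substr(s, pos + 1L, pos + nchar(site)) <- site
    utrs$sequence[g] <- s
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = utrs$gene_id[g], mirna_id = mid, position = pos,
      stringsAsFactors = FALSE)
  }
  list(utrs = utrs, truth = do.call(rbind, truth))
}
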