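#' Filtration criteria for precursor candidates
#'
#' The shared filter battery every candidate must pass: precursor length
#' within `[len_min, len_max]` (inclusive), at most `max_loops` hairpin
#' loops, GC content within `[gc_min, gc_max]` (inclusive), strictly more
#' than `paired_min` of positions paired, and MFE at or below
#' `mfe_slope * L + mfe_intercept`.  Two checks that were historically
#' manual are automated and applied only when a mature call is attached:
#' no single bulge/interior-loop side in the stem longer than `max_bulge`
#' nt, and at least `1 - mature_in_loop_max_frac` of mature positions
#' outside the hairpin loop run.
#'
#' @param len_min,len_max precursor length bounds, nt.
#' @param max_loops maximum number of hairpin loops.
#' @param gc_min,gc_max inclusive GC-content bounds.
#' @param paired_min strict lower bound on the paired fraction.
#' @param mfe_slope,mfe_intercept threshold line, kcal/mol (per nt for the
#'   slope).
#' @param max_bulge largest tolerated single unpaired run in the stem, nt.
#' @param require_mature_in_stem apply the two mature-aware checks when a
#'   mature is attached.
#' @param mature_in_loop_max_frac maximum fraction of mature positions
#'   allowed inside the hairpin loop.
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(len_min = 50L, len_max = 130L, max_loops = 1L,
                            gc_min = 0.30, gc_max = 0.70,
                            paired_min = 0.55,
                            mfe_slope = -0.31, mfe_intercept = 6.00,
                            max_bulge = 10L,
                            require_mature_in_stem = TRUE,
                            mature_in_loop_max_frac = 0.10) {
  stopifnot(len_min < len_max, 0 <= gc_min, gc_min < gc_max, gc_max <= 1)
  structure(list(len_min = len_min, len_max = len_max,
                 max_loops = max_loops, gc_min = gc_min, gc_max = gc_max,
                 paired_min = paired_min, mfe_slope = mfe_slope,
                 mfe_intercept = mfe_intercept, max_bulge = max_bulge,
                 require_mature_in_stem = require_mature_in_stem,
                 mature_in_loop_max_frac = mature_in_loop_max_frac),
            class = "filter_criteria")
}

# canonical candidate table; sequences are stored in transcript orientation
# (already reverse-complemented for minus-strand loci), RNA spelling.
# mat_start/mat_end are 0-based half-open offsets within `seq`.
candidate_df <- function(id = character(), scaffold = character(),
                         start = integer(), end = integer(),
                         strand = character(), seq = character(),
                         structure = character(), mfe = numeric(),
                         track = character(),
                         mat_start = integer(), mat_end = integer(),
                         edge = logical()) {
  n <- length(id)
  data.frame(id = id, scaffold = scaffold, start = start, end = end,
             strand = strand, seq = seq, structure = structure, mfe = mfe,
             track = track,
             mat_start = if (length(mat_start)) mat_start else
               rep(NA_integer_, n),
             mat_end = if (length(mat_end)) mat_end else
               rep(NA_integer_, n),
             edge = if (length(edge)) edge else rep(FALSE, n),
             stringsAsFactors = FALSE)
}

#' Evaluate one candidate against the filter battery
#'
#' Each criterion is evaluated independently and reported with its
#' measured value; `pass_all` is their conjunction.  The bulge and
#' mature-in-loop checks pass vacuously when no mature is attached (they
#' belong to the curation stage, which needs an arm call).
#'
#' @param sequence precursor sequence.
#' @param structure its MFE dot-bracket (fold first; this function does
#'   not fold).
#' @param mfe the MFE in kcal/mol.
#' @param criteria a [filter_criteria()] object.
#' @param mat_start,mat_end optional 0-based half-open mature offsets
#'   within `sequence`.
#' @return list of class `filter_report`: per-criterion `pass`/`value`
#'   entries plus `pass_all`.
#' @export
evaluate_candidate <- function(sequence, structure, mfe,
                               criteria = filter_criteria(),
                               mat_start = NA, mat_end = NA) {
  if (is.null(structure) || is.na(structure) || !nzchar(structure))
    stop("candidate has no fold: fold the sequence first")
  L <- nchar(sequence)
  met <- structure_metrics(sequence, structure)
  thr <- criteria$mfe_slope * L + criteria$mfe_intercept
  out <- list(
    length = list(value = L,
                  pass = L >= criteria$len_min & L <= criteria$len_max),
    loops = list(value = met$loop_count,
                 pass = met$loop_count >= 1 &
                   met$loop_count <= criteria$max_loops),
    gc = list(value = met$gc_fraction,
              pass = met$gc_fraction >= criteria$gc_min &
                met$gc_fraction <= criteria$gc_max),
    paired = list(value = met$paired_fraction,
                  pass = met$paired_fraction > criteria$paired_min),
    mfe = list(value = mfe, threshold = thr, pass = mfe <= thr))
  has_mature <- length(mat_start) == 1L && length(mat_end) == 1L &&
    !is.na(mat_start) && !is.na(mat_end)
  if (criteria$require_mature_in_stem && has_mature) {
    out$bulge <- list(value = met$max_unpaired_run_in_stem,
                      pass = met$max_unpaired_run_in_stem <=
                        criteria$max_bulge)
    loops <- hairpin_loop_runs(structure)
    mat_pos <- seq.int(mat_start + 1L, mat_end)  # 1-based positions
    in_loop <- 0L
    if (nrow(loops))
      in_loop <- sum(vapply(mat_pos, function(p)
        any(p >= loops$start & p <= loops$end), logical(1)))
    frac <- in_loop / length(mat_pos)
    out$mature_in_loop <- list(value = frac,
                               pass = frac <= criteria$mature_in_loop_max_frac)
  } else {
    out$bulge <- list(value = met$max_unpaired_run_in_stem, pass = TRUE)
    out$mature_in_loop <- list(value = NA_real_, pass = TRUE)
  }
  out$pass_all <- all(vapply(out, function(x) isTRUE(x$pass), logical(1)))
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  for (nm in setdiff(names(x), "pass_all"))
    cat(sprintf("%-15s %-5s value=%s\n", nm,
                ifelse(x[[nm]]$pass, "PASS", "fail"),
                format(x[[nm]]$value, digits = 4)))
  cat("pass_all:", x$pass_all, "\n")
  invisible(x)
}

#' Apply the filter battery to a candidate table
#'
#' @param candidates candidate data frame with at least `seq`,
#'   `structure`, `mfe` (and optionally `mat_start`, `mat_end`) columns.
#' @param criteria a [filter_criteria()] object.
#' @return list with `pass` (rows whose report passes every criterion)
#'   and `rejected` (remaining rows with a `reason` column naming the
#'   first failing criterion).
#' @export
apply_filters <- function(candidates, criteria = filter_criteria()) {
  if (!nrow(candidates))
    return(list(pass = candidates,
                rejected = cbind(candidates, reason = character(0))))
  ms <- if (!is.null(candidates$mat_start)) candidates$mat_start else
    rep(NA_integer_, nrow(candidates))
  me <- if (!is.null(candidates$mat_end)) candidates$mat_end else
    rep(NA_integer_, nrow(candidates))
  reports <- lapply(seq_len(nrow(candidates)), function(i) {
    evaluate_candidate(candidates$seq[i], candidates$structure[i],
                       candidates$mfe[i], criteria,
                       mat_start = ms[i], mat_end = me[i])
  })
  ok <- vapply(reports, `[[`, logical(1), "pass_all")
  reason <- vapply(reports, function(r) {
    nm <- setdiff(names(r), "pass_all")
    fail <- nm[!vapply(r[nm], function(x) isTRUE(x$pass), logical(1))]
    if (length(fail)) fail[1] else NA_character_
  }, character(1))
  rejected <- candidates[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  list(pass = candidates[ok, , drop = FALSE], rejected = rejected)
}

#' Benchmark the filter battery on a precursor compendium
#'
#' Folds each precursor, computes every structural metric, and reports
#' the per-criterion pass percentages, the all-pass percentage, and
#' histogram tables (length, loop count, GC, paired fraction, MFE vs
#' length) for the whole compendium.  Mature-aware checks are not part of
#' the benchmark: no arm calls exist for compendium entries.
#'
#' @param precursors record data frame ([read_fasta()]) or named
#'   character vector of precursor sequences.
#' @param criteria a [filter_criteria()] object.
#' @param temperature folding temperature, degrees Celsius.
#' @param progress print a dot every 500 precursors.
#' @return list of class `criteria_report`: `n_precursors`, `n_skipped`,
#'   `percent` (named vector: `length`, `loops`, `mfe`, `gc`, `paired`,
#'   `all`), `histograms`, and the per-precursor `metrics` table.
#' @export
benchmark_compendium <- function(precursors, criteria = filter_criteria(),
                                 temperature = 37, progress = FALSE) {
  if (is.data.frame(precursors))
    precursors <- stats::setNames(precursors$sequence, precursors$id)
  seqs <- as_rna(precursors)
  usable <- !grepl("N", seqs, fixed = TRUE) & nchar(seqs) >= 10
  n_skipped <- sum(!usable)
  seqs <- seqs[usable]
  if (!length(seqs)) stop("no usable precursor records")
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    f <- fold(seqs[i], temperature)
    met <- structure_metrics(seqs[i], f$structure)
    rows[[i]] <- data.frame(id = names(seqs)[i], length = met$length,
                            loop_count = met$loop_count,
                            paired_fraction = met$paired_fraction,
                            gc_fraction = met$gc_fraction, mfe = f$mfe)
    if (progress && i %% 500 == 0) cat(".")
  }
  metrics <- do.call(rbind, rows)
  pass <- data.frame(
    length = metrics$length >= criteria$len_min &
      metrics$length <= criteria$len_max,
    loops = metrics$loop_count == 1,
    mfe = metrics$mfe <= criteria$mfe_slope * metrics$length +
      criteria$mfe_intercept,
    gc = metrics$gc_fraction >= criteria$gc_min &
      metrics$gc_fraction <= criteria$gc_max,
    paired = metrics$paired_fraction > criteria$paired_min)
  pass$all <- pass$length & pass$loops & pass$mfe & pass$gc & pass$paired
  pct <- 100 * colMeans(pass)
  hist_breaks <- seq(0, max(200, max(metrics$length) + 10), by = 10)
  out <- list(
    n_precursors = nrow(metrics), n_skipped = n_skipped,
    percent = pct,
    histograms = list(
      length = table(cut(metrics$length, hist_breaks)),
      loop_count = table(metrics$loop_count),
      gc = table(cut(metrics$gc_fraction, seq(0, 1, 0.05))),
      paired = table(cut(metrics$paired_fraction, seq(0, 1, 0.05)))),
    metrics = metrics)
  structure(out, class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf("criteria benchmark on %d precursors (%d skipped)\n",
              x$n_precursors, x$n_skipped))
  for (nm in names(x$percent))
    cat(sprintf("  %-8s %6.1f %%\n", nm, x$percent[[nm]]))
  invisible(x)
}

#' Fit the MFE-versus-length line on a compendium
#'
#' Utility regression of MFE on precursor length; the shipped default
#' threshold constants are fixed, this only reports what a given
#' compendium would suggest.
#'
#' @param lengths,mfes numeric vectors (e.g. from the `metrics` table of
#'   [benchmark_compendium()]).
#' @return list with `slope`, `intercept` and the fitted `lm` object.
#' @export
fit_mfe_line <- function(lengths, mfes) {
  fit <- stats::lm(mfes ~ lengths)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}
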