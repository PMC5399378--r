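#' Predict the minimum-free-energy secondary structure of an RNA
#'
#' Self-contained Zuker-style dynamic program over a simplified
#' nearest-neighbor thermodynamic model (Turner-like stacking energies,
#' size-dependent loop initiation penalties, affine multibranch term).
#' Deterministic for a fixed sequence and temperature, and invariant to
#' T/U spelling of the input.  Loop penalties are treated as entropic and
#' stacks carry a fixed extra enthalpy, so the MFE at a lower temperature
#' is never above the MFE at a higher one.
#'
#' This engine honors the folding *contract* the pipeline needs (MFE in
#' kcal/mol under a standard-shaped nearest-neighbor model, dot-bracket
#' MFE structure, temperature as a parameter); it is not numerically
#' interchangeable with a full Turner-2004 implementation.
#'
#' @param sequence RNA (or DNA; T is read as U) string, length >= 10,
#'   alphabet `{A,C,G,U/T}`.
#' @param temperature folding temperature in degrees Celsius.
#' @return an object of class `fold_result`: list with `structure`
#'   (dot-bracket), `mfe` (kcal/mol, 0 for an open chain), `temperature`.
#' @examples
#' fold("GGGAGGAAAACCUCCC")$structure
#' @export
fold <- function(sequence, temperature = 37) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- .fold_cpp(as_rna(sequence), temperature)
  structure(res, class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", sprintf("MFE = %.2f kcal/mol at %g C\n",
                                 x$mfe, x$temperature), sep = "")
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param dotbracket balanced dot-bracket string over `(`, `.`, `)`.
#' @return integer vector `p` with `p[i]` = 1-based partner of position
#'   `i`, or 0 if unpaired.
#' @export
pair_table <- function(dotbracket) {
  v <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (any(!v %in% c("(", ".", ")"))) stop("invalid dot-bracket character")
  p <- integer(length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  p
}

#' Count hairpin loops in a dot-bracket structure
#'
#' A hairpin loop is a maximal unpaired run closed directly by a base
#' pair that encloses no other pair.  Multibranch and interior loops do
#' not count: canonical precursors have exactly one hairpin loop.
#'
#' @inheritParams pair_table
#' @return integer loop count.
#' @export
count_hairpin_loops <- function(dotbracket) {
  pair_table(dotbracket)  # validates balance
  length(gregexpr("\\(\\.+\\)", dotbracket)[[1]][
    gregexpr("\\(\\.+\\)", dotbracket)[[1]] > 0])
}

#' Fraction of paired positions in a dot-bracket structure
#'
#' The denominator is the full structure length, loop positions included.
#'
#' @inheritParams pair_table
#' @return numeric in `[0, 1]`.
#' @export
paired_fraction <- function(dotbracket) {
  pair_table(dotbracket)  # validates balance
  v <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  sum(v != ".") / length(v)
}

#' Length-dependent MFE acceptance threshold
#'
#' A precursor of length `L` passes the energy criterion when its MFE is
#' at or below `-0.31 * L + 6.00` kcal/mol.
#'
#' @param L precursor length in nt, `L > 0`.
#' @return threshold in kcal/mol.
#' @export
mfe_threshold <- function(L) {
  if (any(L <= 0)) stop("L must be positive")
  -0.31 * L + 6.00
}

# hairpin-loop runs: list of (start, end) 1-based inclusive unpaired runs
# closed by a pair enclosing no other pair
hairpin_loop_runs <- function(dotbracket) {
  m <- gregexpr("\\(\\.+\\)", dotbracket)[[1]]
  if (m[1] < 0) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) + 1L,
             end = as.integer(m) + attr(m, "match.length") - 2L)
}

# largest single unpaired run that is inside the structure but not a
# hairpin loop (i.e. one side of a bulge or interior loop)
max_unpaired_run_in_stem <- function(dotbracket) {
  p <- pair_table(dotbracket)
  loops <- hairpin_loop_runs(dotbracket)
  v <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  paired_pos <- which(p > 0)
  if (!length(paired_pos)) return(0L)
  runs <- rle(v == ".")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- 0L
  for (k in which(runs$values)) {
    s <- starts[k]; e <- ends[k]
    # skip terminal overhangs and hairpin loops
    if (s == 1L || e == length(v)) next
    if (any(loops$start == s & loops$end == e)) next
    best <- max(best, e - s + 1L)
  }
  best
}

#' Structural metrics of a folded candidate
#'
#' @param sequence the folded sequence.
#' @param dotbracket its MFE structure.
#' @return list with `length`, `loop_count`, `paired_fraction`,
#'   `gc_fraction`, `max_unpaired_run_in_stem`.
#' @export
structure_metrics <- function(sequence, dotbracket) {
  if (nchar(sequence) != nchar(dotbracket))
    stop("sequence and structure lengths differ")
  list(length = nchar(sequence),
       loop_count = count_hairpin_loops(dotbracket),
       paired_fraction = paired_fraction(dotbracket),
       gc_fraction = gc_fraction(sequence),
       max_unpaired_run_in_stem = max_unpaired_run_in_stem(dotbracket))
}
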