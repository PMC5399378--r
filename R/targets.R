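#' Extract 3' UTRs from gene models
#'
#' The 3' UTR is operationally the `length` bases immediately following
#' the translation stop on the coding strand: downstream of the model
#' end for plus-strand genes, upstream of the model start (reverse
#' complemented) for minus-strand genes.  UTRs truncated by a scaffold
#' edge are clipped and flagged; models with an unknown strand are
#' skipped (their count is reported as an attribute).
#'
#' @param gene_models data frame with `scaffold`, `start`, `end`,
#'   `strand`, `id` (internal 0-based coordinates; see [read_gff3()]).
#' @param genome named character vector of scaffold sequences.
#' @param length UTR length in bp.
#' @return data frame `gene_id`, `scaffold`, `start`, `end`, `strand`,
#'   `sequence`, `clipped`.
#' @export
extract_utr3 <- function(gene_models, genome, length = 400L) {
  keep <- gene_models$strand %in% c("+", "-") &
    gene_models$scaffold %in% names(genome)
  skipped <- sum(!keep)
  gm <- gene_models[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(gm)), function(i) {
    sc <- gm$scaffold[i]; slen <- nchar(genome[[sc]])
    if (gm$strand[i] == "+") {
      s <- gm$end[i]; e <- min(slen, s + length)
    } else {
      e <- gm$start[i]; s <- max(0L, e - length)
    }
    if (e - s < 1L) return(NULL)
    sq <- subseq0(genome[[sc]], s, e)
    if (gm$strand[i] == "-") sq <- revcomp(sq)
    data.frame(gene_id = gm$id[i], scaffold = sc, start = s, end = e,
               strand = gm$strand[i], sequence = sq,
               clipped = (e - s) < length, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character(),
               sequence = character(), clipped = logical())
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Minimum miRNA:target duplex hybridization energy
#'
#' Intermolecular-only duplex energy under the same simplified
#' nearest-neighbor model as [fold()]: the best antiparallel alignment of
#' the miRNA against the target window, with bounded bulges/interior
#' loops and no intramolecular pairs, subject to the helix constraint
#' that miRNA positions `helix_frame[1]..helix_frame[2]` (1-based) form a
#' contiguous helix with consecutive target positions.
#'
#' @param mirna miRNA sequence, 18-27 nt (shorter toy inputs allowed).
#' @param utr_window target sequence.
#' @param helix_frame integer pair `(a, b)`; positions `a..b` must all be
#'   paired.
#' @param temperature duplex temperature.
#' @return list with `energy` (kcal/mol; `Inf` when the constraint is
#'   unsatisfiable) and `target_pos` (1-based 3'-most target position of
#'   the anchor helix).
#' @export
duplex_energy <- function(mirna, utr_window, helix_frame = c(1L, 6L),
                          temperature = 37) {
  .duplex_energy_cpp(as_rna(mirna), as_rna(utr_window),
                     as.integer(helix_frame[1]),
                     as.integer(helix_frame[2]), temperature)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson doublet shuffle: returns a random sequence with
#' exactly the same dinucleotide (and hence mononucleotide) composition,
#' the energy-relevant composition for duplex scanning nulls.
#'
#' @param sequence input sequence.
#' @return shuffled sequence (same alphabet and spelling).
#' @export
dinucleotide_shuffle <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < 3L) return(sequence)
  letters_ <- unique(v)
  last <- v[n]
  # successor edge lists
  succ <- split(v[-1], factor(v[-n], levels = letters_))
  for (tries in 1:100) {
    # pick a random last edge per vertex (except the terminal vertex)
    last_edge <- vapply(letters_, function(a) {
      if (a == last || !length(succ[[a]])) NA_character_
      else sample(succ[[a]], 1L)
    }, character(1))
    # the last-edge graph must lead every vertex to the terminal vertex
    ok <- TRUE
    for (a in letters_) {
      if (a == last || !length(succ[[a]])) next
      cur <- a; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) return(sequence)  # degenerate composition; give up gracefully
  out <- character(n); out[1] <- v[1]
  remaining <- lapply(stats::setNames(letters_, letters_), function(a) {
    e <- succ[[a]]
    if (!is.na(last_edge[[a]]) && a != last) {
      drop <- match(last_edge[[a]], e)
      e <- e[-drop]
    }
    if (length(e)) e <- sample(e)
    # non-terminal vertices traverse their chosen last edge last
    if (!is.na(last_edge[[a]]) && a != last) e <- c(e, last_edge[[a]])
    e
  })
  ptr <- stats::setNames(rep(1L, length(letters_)), letters_)
  for (k in 2:n) {
    a <- out[k - 1L]
    out[k] <- remaining[[a]][ptr[[a]]]
    ptr[[a]] <- ptr[[a]] + 1L
  }
  paste(out, collapse = "")
}

# Extreme-value (GEV) fit by L-moments (Hosking's estimators).  Duplex
# best-site scores are maxima of many dependent, *bounded* local scores,
# so their null typically has a Weibull-type (bounded) upper tail: the
# shape must be fitted, a two-parameter Gumbel badly overestimates the
# tail.  Parameterization: F(x) = exp(-(1 - k (x - xi)/a)^(1/k)), Gumbel
# as k -> 0.
fit_evd <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 30L) stop("too few finite scores to fit the null (need >= 30)")
  j <- 0:(n - 1)
  b0 <- mean(x)
  b1 <- sum(j / (n - 1) * x) / n
  b2 <- sum(j * (j - 1) / ((n - 1) * (n - 2)) * x) / n
  l1 <- b0; l2 <- 2 * b1 - b0; l3 <- 6 * b2 - 6 * b1 + b0
  t3 <- l3 / l2
  cc <- 2 / (3 + t3) - log(2) / log(3)
  k <- 7.8590 * cc + 2.9554 * cc^2
  if (abs(k) < 1e-6) {
    beta <- l2 / log(2)
    return(list(xi = l1 - 0.5772157 * beta, a = beta, k = 0))
  }
  a <- l2 * k / ((1 - 2^(-k)) * gamma(1 + k))
  xi <- l1 - a * (1 - gamma(1 + k)) / k
  list(xi = xi, a = a, k = k)
}

# upper-tail p-value under the fitted extreme-value null for score x
evd_pvalue <- function(x, fit) {
  if (fit$k == 0) {
    p <- 1 - exp(-exp(-(x - fit$xi) / fit$a))
  } else {
    z <- pmax(1 - fit$k * (x - fit$xi) / fit$a, 0)
    p <- 1 - exp(-z^(1 / fit$k))
  }
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Scan miRNAs against 3' UTRs with an empirical significance model
#'
#' For each miRNA x UTR pair the best duplex over the helix-constraint
#' sweep (`-f 1,6` through `-f 6,11` style frames) is computed; the
#' score (negative energy) is referred to a per-miRNA extreme-value
#' null (GEV with fitted shape, L-moment estimators) built on
#' dinucleotide-shuffled UTRs, and sites with `p <= p_max` are
#' reported.
#'
#' @param mirnas data frame (`id`, `sequence`) or named character
#'   vector of mature miRNA sequences.
#' @param utrs UTR table from [extract_utr3()] (or data frame with
#'   `gene_id`, `sequence`).
#' @param p_max p-value cutoff.
#' @param frames list of helix-constraint frames.
#' @param n_shuffle shuffled UTRs per miRNA for the null fit (>= 200;
#'   the default is larger because the fit must extrapolate the 99th
#'   percentile).
#' @param temperature duplex temperature.
#' @param bh apply a Benjamini-Hochberg correction per miRNA (off by
#'   default; the raw cutoff is the classical protocol).
#' @return data frame of class `target_sites`: `gene_id`, `mirna_id`,
#'   `position`, `duplex_energy`, `p_value`, `frame`.
#' @export
scan_targets <- function(mirnas, utrs, p_max = 0.01,
                         frames = lapply(1:6, function(a) c(a, a + 5L)),
                         n_shuffle = 500L, temperature = 37, bh = FALSE) {
  if (is.data.frame(mirnas))
    mirnas <- stats::setNames(mirnas$sequence, mirnas$id)
  if (n_shuffle < 200L)
    stop("need n_shuffle >= 200 to fit the null (got ", n_shuffle, ")")
  if (!nrow(utrs))
    return(data.frame(gene_id = character(), mirna_id = character(),
                      position = integer(), duplex_energy = numeric(),
                      p_value = numeric(), frame = character()))
  fa <- vapply(frames, `[`, integer(1), 1L)
  fb <- vapply(frames, `[`, integer(1), 2L)
  best_site <- function(mi, utr_seq) {
    d <- .duplex_energy_frames_cpp(mi, as_rna(utr_seq), fa, fb,
                                   temperature)
    k <- which.min(d$energy)
    if (!length(k) || !is.finite(d$energy[k]))
      return(list(energy = Inf, target_pos = NA_integer_, frame = NA))
    list(energy = d$energy[k], target_pos = d$target_pos[k],
         frame = sprintf("%d,%d", fa[k], fb[k]))
  }
  out <- list()
  for (mid in names(mirnas)) {
    mi <- as_rna(mirnas[[mid]])
    # per-miRNA null on dinucleotide-shuffled UTRs
    null_scores <- vapply(seq_len(n_shuffle), function(k) {
      u <- utrs$sequence[((k - 1L) %% nrow(utrs)) + 1L]
      -best_site(mi, dinucleotide_shuffle(u))$energy
    }, numeric(1))
    fit <- fit_evd(null_scores)
    obs <- lapply(seq_len(nrow(utrs)), function(i) {
      b <- best_site(mi, utrs$sequence[i])
      p <- if (is.finite(b$energy)) evd_pvalue(-b$energy, fit) else 1
      data.frame(gene_id = utrs$gene_id[i], mirna_id = mid,
                 position = b$target_pos, duplex_energy = b$energy,
                 p_value = p, frame = as.character(b$frame),
                 stringsAsFactors = FALSE)
    })
    obs <- do.call(rbind, obs)
    if (bh) obs$p_value <- stats::p.adjust(obs$p_value, "BH")
    out[[mid]] <- obs[obs$p_value <= p_max, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("target_sites", class(res))
  res
}
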