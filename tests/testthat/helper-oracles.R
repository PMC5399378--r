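# Independent oracles used across the suite.  These deliberately avoid
# the package's own scanning/structure code paths: string-level brute
# force and a from-scratch pair-table parser.

# brute-force Hamming scan of `query` over every window of `subject`
# (plus strand only); returns 0-based starts and mismatch counts
brute_hamming_scan <- function(subject, query, max_mm) {
  sv <- strsplit(toupper(chartr("U", "T", subject)), "")[[1]]
  qv <- strsplit(toupper(chartr("U", "T", query)), "")[[1]]
  m <- length(qv); n <- length(sv)
  out_pos <- integer(0); out_mm <- integer(0)
  if (m > n) return(data.frame(start = out_pos, mismatches = out_mm))
  for (s in 0:(n - m)) {
    mm <- sum(sv[(s + 1):(s + m)] != qv)
    if (mm <= max_mm) { out_pos <- c(out_pos, s); out_mm <- c(out_mm, mm) }
  }
  data.frame(start = out_pos, mismatches = out_mm)
}

# brute-force both-strand scan mirroring scan_for_matures output columns
brute_scan_both <- function(genome, queries, max_mm) {
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(x)), "")[[1]]),
          collapse = "")
  }
  rows <- list()
  for (sc in names(genome)) for (qi in seq_along(queries)) {
    for (ori in c("+", "-")) {
      q <- if (ori == "+") queries[[qi]] else rc(queries[[qi]])
      h <- brute_hamming_scan(genome[[sc]], q, max_mm)
      if (!nrow(h)) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(queries)[qi], scaffold = sc, start = h$start,
        end = h$start + nchar(q), strand = ori, mismatches = h$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(query_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  out <- do.call(rbind, rows)
  out[order(out$scaffold, out$start, out$strand, out$query_id), ]
}

# independent pair-table parser: explicit index stack, no regex
oracle_pair_table <- function(db) {
  v <- strsplit(db, "")[[1]]
  p <- integer(length(v)); open <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") open <- c(open, i)
    if (v[i] == ")") {
      j <- open[length(open)]; open <- open[-length(open)]
      p[i] <- j; p[j] <- i
    }
  }
  p
}

# hairpin loops from the pair table: pairs (i, j = p[i] > i) whose
# enclosed region contains no paired position
oracle_loop_count <- function(db) {
  p <- oracle_pair_table(db)
  n_loops <- 0L
  for (i in seq_along(p)) {
    j <- p[i]
    if (j <= i) next
    inner <- seq.int(i + 1L, j - 1L)
    if (length(inner) && all(p[inner] == 0L)) n_loops <- n_loops + 1L
  }
  n_loops
}

oracle_paired_fraction <- function(db) {
  p <- oracle_pair_table(db)
  sum(p > 0L) / length(p)
}

# enumerate every valid dot-bracket structure of length n (balanced,
# innermost pairs enclose >= 3 unpaired positions), via the grammar
# S -> "." S | "(" C ")" S | "";  C valid with >= 1 pair or >= 3 dots
enumerate_structures <- local({
  memo <- list()
  gen <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (n == 0L) "" else character(0)
    if (n >= 1L) res <- c(res, paste0(".", gen(n - 1L)))
    if (n >= 5L) {
      for (inner_len in 3L:(n - 2L)) {
        rest_len <- n - inner_len - 2L
        for (inner in gen(inner_len)) {
          if (!grepl("(", inner, fixed = TRUE) &&
              nchar(gsub("[^.]", "", inner)) < 3L) next
          if (!grepl("(", inner, fixed = TRUE) && inner_len < 3L) next
          for (rest in gen(rest_len))
            res <- c(res, paste0("(", inner, ")", rest))
        }
      }
    }
    memo[[key]] <<- res
    res
  }
  gen
})

# random valid structures: MFE structures of random sequences (the
# comparison under test is loop counting / paired fraction versus the
# oracle parser, not the fold itself)
random_structures <- function(n_struct, len_range = c(20L, 80L)) {
  vapply(seq_len(n_struct), function(k) {
    L <- sample(seq(len_range[1], len_range[2]), 1L)
    s <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    fold(s)$structure
  }, character(1))
}

# simplified-model duplex energy by exhaustive alignment enumeration
# (independent of the C++ DP): all monotone pair chains with bounded
# gaps, energy recomputed in R from the same published constants
oracle_duplex <- function(mirna, target, f_a, f_b, max_gap = 10L) {
  enc <- function(s) {
    v <- strsplit(chartr("Tt", "Uu", toupper(s)), "")[[1]]
    match(v, c("A", "C", "G", "U"))
  }
  PT <- function(a, b) {
    key <- paste0(c("A", "C", "G", "U")[a], c("A", "C", "G", "U")[b])
    switch(key, CG = 1L, GC = 2L, GU = 3L, UG = 4L, AU = 5L, UA = 6L, 0L)
  }
  raw <- rbind(
    c(-2.40, -3.30, -2.10, -1.40, -2.10, -2.10),
    c(-3.30, -3.40, -2.50, -1.50, -2.20, -2.40),
    c(-2.10, -2.50,  1.30, -0.50, -1.40, -1.30),
    c(-1.40, -1.50, -0.50,  0.30, -0.60, -1.00),
    c(-2.10, -2.20, -1.40, -0.60, -1.10, -0.90),
    c(-2.10, -2.40, -1.30, -1.00, -0.90, -1.30))
  flip <- c(2L, 1L, 4L, 3L, 6L, 5L)
  stack <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6)
    stack[a, b] <- (raw[a, b] + raw[flip[b], flip[a]]) / 2
  au_pen <- function(pt) if (pt >= 3L) 0.5 else 0
  bulge <- function(nn) {
    b <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
    if (nn <= 6L) b[nn] else 4.4 + 1.07 * log(nn / 6)
  }
  interior <- function(nn, n1, n2) {
    g <- if (nn == 2L) 1.5 else if (nn == 3L) 1.8 else
      1.1 + if (nn > 4L) 1.07 * log(nn / 4) else 0
    g + min(3, 0.6 * abs(n1 - n2))
  }
  loopE <- function(pt_out, pt_in, n1, n2) {
    if (n1 == 0L && n2 == 0L) return(stack[pt_out, pt_in])
    nn <- n1 + n2
    if (n1 == 0L || n2 == 0L) {
      if (nn == 1L) return(bulge(1L) + stack[pt_out, pt_in])
      return(bulge(nn) + au_pen(pt_out) + au_pen(pt_in))
    }
    interior(nn, n1, n2) + au_pen(pt_out) + au_pen(pt_in)
  }
  q <- enc(mirna); t <- enc(target)
  m <- length(q); n <- length(t)
  best <- Inf
  # extend right of pair (i, j), returning min additional energy
  ext_right <- function(i, j) {
    e <- au_pen(PT(q[i], t[j]))
    for (gi in 0:max_gap) for (gj in 0:max_gap) {
      ni <- i + 1L + gi; nj <- j - 1L - gj
      if (ni > m || nj < 1L) next
      pt2 <- PT(q[ni], t[nj])
      if (!pt2) next
      e <- min(e, loopE(PT(q[i], t[j]), pt2, gi, gj) + ext_right(ni, nj))
    }
    e
  }
  ext_left <- function(i, j) {
    e <- 4.1 + au_pen(PT(q[i], t[j]))  # duplex initiation
    for (gi in 0:max_gap) for (gj in 0:max_gap) {
      pi <- i - 1L - gi; pj <- j + 1L + gj
      if (pi < 1L || pj > n) next
      pt2 <- PT(q[pi], t[pj])
      if (!pt2) next
      e <- min(e, ext_left(pi, pj) + loopE(pt2, PT(q[i], t[j]), gi, gj))
    }
    e
  }
  hl <- f_b - f_a
  for (tj in seq.int(hl + 1L, n)) {
    ok <- TRUE
    for (k in 0:hl) if (!PT(q[f_a + k], t[tj - k])) { ok <- FALSE; break }
    if (!ok) next
    helix <- 0
    for (k in seq_len(hl))
      helix <- helix + stack[PT(q[f_a + k - 1L], t[tj - k + 1L]),
                             PT(q[f_a + k], t[tj - k])]
    e <- ext_left(f_a, tj) + helix + ext_right(f_b, tj - hl)
    best <- min(best, e)
  }
  best
}

# genomic span of a candidate's mature segment
mature_genomic <- function(cand, i) {
  if (cand$strand[i] == "+")
    c(cand$start[i] + cand$mat_start[i], cand$start[i] + cand$mat_end[i])
  else
    c(cand$end[i] - cand$mat_end[i], cand$end[i] - cand$mat_start[i])
}

# fraction of planted loci overlapped by a candidate on the right strand
planted_recall <- function(cands, truth, check_strand = TRUE) {
  if (!nrow(truth)) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    m <- cands$scaffold == truth$scaffold[i] &
      pmin(cands$end, truth$end[i]) - pmax(cands$start, truth$start[i]) > 0
    if (check_strand) m <- m & cands$strand == truth$strand[i]
    any(m)
  }, logical(1))
  mean(hit)
}
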