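test_that("map_reads keeps only best hits at the stated thresholds", {
  set.seed(31)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  read <- substr(g, 1001, 1026)  # 26-nt planted verbatim
  h <- map_reads(c(r1 = read), c(S1 = g))
  expect_equal(nrow(h[h$strand == "+" & h$start == 1000L, ]), 1L)
  expect_equal(h$mismatches[h$start == 1000L], 0L)
  expect_equal(h$aligned_length[h$start == 1000L], 26L)

  # three substitutions: rejected by the mismatch cutoff
  v <- strsplit(read, "")[[1]]
  v[c(2, 10, 20)] <- vapply(v[c(2, 10, 20)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  h3 <- map_reads(c(r3 = paste(v, collapse = "")), c(S1 = g))
  expect_false(any(h3$start == 1000L & h3$strand == "+"))

  # two loci at 0 and 1 mismatches: only the best is kept
  site <- substr(g, 2001, 2026)
  v <- strsplit(site, "")[[1]]
  v[13] <- setdiff(c("A", "C", "G", "T"), v[13])[1]
  g2 <- paste0(g, paste(v, collapse = ""), substr(g, 101, 300))
  hb <- map_reads(c(rb = site), c(S1 = g2))
  expect_true(any(hb$start == 2000L & hb$mismatches == 0L))
  expect_false(any(hb$start == 4000L))  # the 1-mm copy loses

  # ties are all kept and flagged multi-mapping
  g3 <- paste0(g, substr(g, 2001, 2026))
  ht <- map_reads(c(rt = site), c(S1 = g3))
  expect_equal(sum(ht$mismatches == 0L), 2L)
  expect_true(all(ht$multi[ht$mismatches == 0L]))

  # short reads are dropped with a count
  hs <- map_reads(c(short = "ACGTACGTACGTACGTAC", ok = read), c(S1 = g))
  expect_equal(attr(hs, "n_dropped_short"), 1L)
})

test_that("map_reads equals the brute-force oracle on small genomes", {
  set.seed(32)
  g <- c(S1 = paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = ""))
  reads <- c(vapply(1:5, function(k)
    paste(sample(c("A", "C", "G", "T"), 26, TRUE), collapse = ""),
    character(1)),
    substr(g[["S1"]], 3001, 3026), revcomp(substr(g[["S1"]], 4001, 4026)))
  names(reads) <- sprintf("r%d", seq_along(reads))
  got <- map_reads(reads, g)
  want <- brute_scan_both(g, as.list(reads), 2)
  # oracle has no best-hit logic; apply it the same way independently
  want$score <- (want$end - want$start) - want$mismatches
  best <- tapply(want$score, want$query_id, max)
  want <- want[want$score == best[want$query_id], ]
  got_key <- sort(paste(got$read_id, got$start, got$strand, got$mismatches))
  want_key <- sort(paste(want$query_id, want$start, want$strand,
                         want$mismatches))
  expect_equal(got_key, want_key)
})

test_that("read-guided loci recover planted precursors and matures", {
  sim <- shared_sim()
  res <- smallrna_track(sim$reads, sim$genome)
  truth <- sim$truth
  expect_gte(planted_recall(res$candidates, truth), 7 / 8)
  # recovered matures overlap the planted dominant-arm mature >= 90%
  for (i in seq_len(nrow(truth))) {
    ci <- which(res$candidates$scaffold == truth$scaffold[i] &
                res$candidates$strand == truth$strand[i] &
                pmin(res$candidates$end, truth$end[i]) -
                  pmax(res$candidates$start, truth$start[i]) > 0)
    if (!length(ci)) next
    mg <- mature_genomic(res$candidates, ci[1])
    ts <- if (truth$dominant_arm[i] == "5p")
      c(truth$p5_start[i], truth$p5_end[i])
    else c(truth$p3_start[i], truth$p3_end[i])
    ov <- min(mg[2], ts[2]) - max(mg[1], ts[1])
    expect_gte(ov / (ts[2] - ts[1]), 0.9)
  }
  # a hit in unstructured background yields no passing candidate
  set.seed(33)
  bg <- c(S1 = paste(sample(c("A", "C", "G", "T"), 1200, TRUE,
                            prob = c(.4, .1, .1, .4)), collapse = ""))
  fake <- data.frame(read_id = "x", scaffold = "S1", start = 600L,
                     end = 626L, strand = "+", mismatches = 0L)
  expect_equal(nrow(loci_from_hits(fake, bg)), 0L)
  # a hit near the scaffold start is clipped but still evaluated
  near <- data.frame(read_id = "y", scaffold = "S1", start = 30L,
                     end = 56L, strand = "+", mismatches = 0L)
  expect_silent(loci_from_hits(near, bg))
})

test_that("expression exclusion uses a strict > threshold", {
  cand <- candidate_df(id = c("a", "b", "c"), scaffold = "S1",
                       start = c(0L, 500L, 900L),
                       end = c(80L, 580L, 980L), strand = "+",
                       seq = strrep("A", 80), structure = strrep(".", 80),
                       mfe = -20, track = "smallrna")
  cov <- data.frame(scaffold = "S1", start = c(10L, 510L),
                    end = c(70L, 570L), count = c(11L, 10L))
  kept <- exclude_expressed(cand, cov)
  expect_equal(kept$id, c("b", "c"))  # 11 reads out, exactly 10 kept
  # empty coverage excludes nothing
  expect_equal(nrow(exclude_expressed(cand, cov[0, ])), 3L)
  # idempotent, and monotone in the threshold
  expect_equal(exclude_expressed(kept, cov), kept)
  expect_lte(nrow(exclude_expressed(cand, cov, max_reads = 5L)),
             nrow(exclude_expressed(cand, cov, max_reads = 20L)))
})

test_that("count_read_support counts Hamming neighbours both ways", {
  set.seed(34)
  mat <- paste(sample(c("A", "C", "G", "U"), 26, TRUE), collapse = "")
  reads <- rep(as_dna(mat), 15)
  expect_equal(count_read_support(mat, reads), 15L)
  expect_equal(count_read_support(mat, character(0)), 0L)
  expect_equal(count_read_support(mat, c("ACGTACGTACGTACGTACGTACGTAC")), 0L)
  # reads with 1-3 errors: equals the brute-force Hamming count
  noisy <- vapply(1:30, function(k) {
    v <- strsplit(as_dna(mat), "")[[1]]
    for (p in sample(26, sample(1:3, 1)))
      v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }, character(1))
  brute <- sum(vapply(noisy, function(r)
    sum(strsplit(r, "")[[1]] != strsplit(as_dna(mat), "")[[1]]) <= 2,
    logical(1)))
  expect_equal(count_read_support(mat, noisy), brute)
  # reverse-complement reads support the same mature
  expect_equal(count_read_support(mat, revcomp(as_dna(mat))), 1L)
})
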