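test_that("infer_mature finds paired arms and honors the gap bounds", {
  # constructed hairpin: 24-nt arm, 8-nt loop, exact reverse complement
  set.seed(41)
  arm <- paste(sample(c("A", "C", "G", "U"), 24, TRUE,
                      prob = c(.2, .3, .3, .2)), collapse = "")
  hp <- paste0(arm, "AAAUAAAA", revcomp(arm))
  f <- fold(hp)
  call <- infer_mature(hp, f)
  expect_equal(call$method, "pair_pattern")
  expect_equal(call$pair_mismatches, 0L)
  expect_equal(call$p5, c(0L, 24L))
  expect_equal(call$p3, c(32L, 56L))
  # arms never overlap the loop run; separation within [5, 50]
  loop <- hairpin_loop_runs(f$structure)
  expect_lte(call$p5[2], loop$start - 1L)
  expect_gte(call$p3[1] + 1L, loop$end + 1L)
  sep <- call$p3[1] - call$p5[2]
  expect_gte(sep, 5L); expect_lte(sep, 50L)

  # separation 4 nt: below the pattern bound, fallback used (arms at
  # the minimum pattern length so no shorter sub-arm pair can qualify)
  arm22 <- substr(arm, 1, 22)
  hp4 <- paste0(arm22, "AAAA", revcomp(arm22))
  f4 <- fold(hp4)
  call4 <- infer_mature(hp4, f4)
  expect_equal(call4$method, "fallback24")
  expect_true(is.na(call4$pair_mismatches))

  # multi-loop folds are rejected
  db2 <- "((((....))))((((....))))"
  expect_error(infer_mature(strrep("A", 24), list(structure = db2)),
               "single-loop")
})

test_that("among valid arm pairs the loop-closest one wins", {
  # two nested complementary pairs: a 22-nt pair right at the loop and a
  # second one 6 nt further out
  set.seed(42)
  inner <- paste(sample(c("A", "C", "G", "U"), 22, TRUE,
                        prob = c(.2, .3, .3, .2)), collapse = "")
  outer <- paste(sample(c("A", "C", "G", "U"), 22, TRUE,
                        prob = c(.2, .3, .3, .2)), collapse = "")
  spacer <- "AUCAGU"
  hp <- paste0(outer, spacer, inner, "AAAUAAAA", revcomp(inner),
               revcomp(spacer), revcomp(outer))
  f <- fold(hp)
  call <- infer_mature(hp, f)
  loop <- hairpin_loop_runs(f$structure)
  # distance-0 pair returned: 5p arm ends exactly at the loop
  expect_equal(call$p5[2], loop$start - 1L)
  expect_equal(call$p3[1], loop$end)
})

test_that("strand inference follows the evidence priority order", {
  none <- infer_strand(NULL)
  expect_equal(none$strand, "+")
  expect_equal(none$provenance, "default_plus")

  ev <- data.frame(source = c("reference_mature_hit", "est_hit"),
                   strand = c("-", "+"), score = c(10, 99))
  top <- infer_strand(ev)
  expect_equal(top$strand, "-")  # reference class outranks EST score
  expect_equal(top$provenance, "reference_mature_hit")

  only_sr <- infer_strand(data.frame(source = "smallrna_hit",
                                     strand = "-", score = 1))
  expect_equal(only_sr$strand, "-")

  tie <- infer_strand(data.frame(source = c("est_hit", "est_hit"),
                                 strand = c("-", "+"), score = c(5, 5)))
  expect_equal(tie$strand, "+")
  expect_true(tie$tied)
  expect_error(infer_strand(data.frame(source = "blast", strand = "+",
                                       score = 1)), "unknown evidence")
})

test_that("seed families are the 2-7 hexamer", {
  expect_equal(assign_family("UGAGGUAGUAGGUUGUAUAGUUU"), "GAGGUA")
  # first-position differences do not split families
  expect_equal(assign_family("AGAGGUAGUAGGUUG"),
               assign_family("CGAGGUAGUAGGUUG"))
  # a position-3 difference does
  expect_false(assign_family("UGCGGUAGUAGGUUG") ==
                 assign_family("UGAGGUAGUAGGUUG"))
  expect_error(assign_family("ACGU"), "seed")
  # equivalence relation: sharing a seed is transitive by construction
  seeds <- assign_family(c("AACGUACXXXX" = "AACGUACGGGG",
                           "b" = "UACGUACAAAA", "c" = "GACGUACUUUU"))
  expect_equal(length(unique(seeds)), 1L)
})

test_that("merge_tracks Venn counts satisfy inclusion-exclusion", {
  mk <- function(ids, starts, strand = "+")
    candidate_df(id = ids, scaffold = "S1", start = starts,
                 end = starts + 80L, strand = strand,
                 seq = strrep("A", 80), structure = strrep(".", 80),
                 mfe = -20 - seq_along(ids), track = "x")
  # disjoint sets of sizes 3/4/5: union 12, no overlap regions
  m <- merge_tracks(mk(paste0("h", 1:3), c(0L, 200L, 400L) * 10L),
                    mk(paste0("d", 1:4), c(100L, 300L, 500L, 700L) * 10L),
                    mk(paste0("s", 1:5), c(150L, 350L, 550L, 750L, 950L) * 10L))
  expect_equal(unname(m$venn[["union"]]), 12L)
  expect_equal(unname(m$venn[["homology"]]), 3L)
  expect_equal(unname(m$venn[["homology+denovo+smallrna"]]), 0L)

  # A == B, C disjoint: |A u B u C| = |A| + |C|
  a <- mk(paste0("a", 1:3), c(0L, 2000L, 4000L))
  c3 <- mk(paste0("c", 1:2), c(8000L, 9000L))
  m2 <- merge_tracks(a, a, c3)
  expect_equal(unname(m2$venn[["union"]]), 5L)
  expect_equal(unname(m2$venn[["homology+denovo"]]), 3L)

  # randomized subsets: union always equals inclusion-exclusion
  set.seed(43)
  pool <- mk(sprintf("p%02d", 1:12), seq(0L, 11000L, by = 1000L))
  for (k in 1:20) {
    A <- pool[sample(12, sample(0:12, 1)), ]
    B <- pool[sample(12, sample(0:12, 1)), ]
    C <- pool[sample(12, sample(0:12, 1)), ]
    v <- merge_tracks(A, B, C)$venn
    nA <- sum(v[c("homology", "homology+denovo", "homology+smallrna",
                  "homology+denovo+smallrna")])
    nB <- sum(v[c("denovo", "homology+denovo", "denovo+smallrna",
                  "homology+denovo+smallrna")])
    nC <- sum(v[c("smallrna", "homology+smallrna", "denovo+smallrna",
                  "homology+denovo+smallrna")])
    nAB <- sum(v[c("homology+denovo", "homology+denovo+smallrna")])
    nAC <- sum(v[c("homology+smallrna", "homology+denovo+smallrna")])
    nBC <- sum(v[c("denovo+smallrna", "homology+denovo+smallrna")])
    nABC <- v[["homology+denovo+smallrna"]]
    expect_equal(unname(v[["union"]]),
                 unname(nA + nB + nC - nAB - nAC - nBC + nABC))
    # commutative in track order (up to region relabeling)
    v2 <- merge_tracks(A, B, C)$venn
    expect_identical(v, v2)
  }
})

test_that("conservation classes follow the clade rules", {
  m <- data.frame(family = c("f1", "f2", "f3"),
                  focal = c(TRUE, TRUE, TRUE),
                  ciona = c(TRUE, TRUE, FALSE),
                  fly = c(TRUE, FALSE, FALSE),
                  human = c(TRUE, FALSE, FALSE))
  clades <- c(focal = "tunicate", ciona = "tunicate",
              fly = "other_metazoan", human = "other_metazoan")
  res <- classify_conservation(c("f1", "f2", "f3", "f4"), m, clades,
                               focal = "focal")
  expect_equal(res$class,
               c("widely_conserved", "tunicate_specific",
                 "species_specific", "species_specific"))
  expect_equal(res$flag[4], "unmatched")
  # invariant to column order and duplicated species columns
  m2 <- m[, c("family", "human", "ciona", "focal", "fly")]
  m2$human2 <- m2$human
  clades2 <- c(clades, human2 = "other_metazoan")
  res2 <- classify_conservation(c("f1", "f2", "f3", "f4"), m2, clades2,
                                focal = "focal")
  expect_equal(res2$class, res$class)
  expect_error(classify_conservation("f1", m, clades, focal = "nope"),
               "absent")
})

test_that("rescan_homologs applies the cutoff and refolds at 18 C", {
  sim <- shared_sim()
  truth <- sim$truth[1:4, ]
  matures <- stats::setNames(truth$mature_5p, truth$id)
  # plant each mature with exactly 4 substitutions in a second genome
  set.seed(44)
  g2 <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE,
                     prob = c(.325, .175, .175, .325)), collapse = "")
  for (i in seq_len(nrow(truth))) {
    # homologous precursor: full planted hairpin with 4 mature subs
    pre <- substr(sim$genome[["S1"]], truth$start[i] + 1L, truth$end[i])
    v <- strsplit(pre, "")[[1]]
    off <- if (truth$strand[i] == "+") truth$p5_start[i] - truth$start[i]
           else truth$end[i] - truth$p5_end[i]
    for (p in off + sample(8:24, 4))
      v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    mutated <- paste(v, collapse = "")
    pos <- 2000L + i * 3000L
    substr(g2, pos, pos + nchar(mutated) - 1L) <- mutated
  }
  genome2 <- c(C1 = g2)
  r4 <- rescan_homologs(matures, genome2, max_mm = 4L)
  r2 <- rescan_homologs(matures, genome2, max_mm = 2L)
  expect_gte(r4$summary$n_hit, 3L)      # found at <= 4 mismatches
  expect_lte(r2$summary$n_hit, r4$summary$n_hit)
  expect_gte(r4$summary$n_canonical, 1L)  # planted hairpins refold
  # empty second genome: no hits
  empty <- rescan_homologs(matures,
                           c(C1 = strrep("AT", 500L)), max_mm = 4L)
  expect_equal(empty$summary$n_hit, 0L)
})
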