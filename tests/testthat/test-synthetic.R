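test_that("make_precursor builds verified canonical hairpins", {
  set.seed(61)
  p <- make_precursor(30, 8, 0, 0)
  f <- fold(p$seq)
  expect_equal(count_hairpin_loops(f$structure), 1L)
  expect_gt(paired_fraction(f$structure), 0.55)
  expect_lte(f$mfe, mfe_threshold(nchar(p$seq)))
  # matures sit inside the precursor on opposite arms
  expect_lte(p$p5[2], 30L)
  expect_gte(p$p3[1], 38L)

  expect_error(make_precursor(30, 4), "loop_len")
  expect_error(make_precursor(10, 8), "stem_len")
  # unreachable parameters exhaust the retry budget
  expect_error(make_precursor(16, 8, n_mismatch = 14L, mature_len = 16,
                              max_tries = 3L), "tries")

  # determinism under a fixed RNG state
  set.seed(62); a <- make_precursor(28, 7, 2, 0.1)
  set.seed(62); b <- make_precursor(28, 7, 2, 0.1)
  expect_identical(a, b)
})

test_that("plant_genome is deterministic with verified truth", {
  cfg <- synthetic_config(genome_length = 30000L, n_precursors = 5L,
                          seed = 63L)
  sim1 <- plant_genome(cfg)
  sim2 <- plant_genome(cfg)
  expect_identical(sim1, sim2)
  expect_equal(nrow(sim1$truth), 5L)
  # planted loci are non-overlapping and inside the genome
  tr <- sim1$truth[order(sim1$truth$start), ]
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
  expect_true(all(tr$end <= nchar(sim1$genome[["S1"]])))
  # every planted precursor passes the battery when refolded in place
  for (i in seq_len(nrow(tr))) {
    s <- substr(sim1$genome[["S1"]], tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-") s <- revcomp(s)
    f <- fold(s)
    expect_true(evaluate_candidate(s, f$structure, f$mfe)$pass_all)
  }
  # background GC near the configured value (measured off plantings)
  bg <- substr(sim1$genome[["S1"]], 1, tr$start[1])
  expect_equal(gc_fraction(bg), 0.35, tolerance = 0.02)
  # no precursors: pure background, empty truth
  cfg0 <- synthetic_config(genome_length = 5000L, n_precursors = 0L,
                           seed = 64L)
  sim0 <- plant_genome(cfg0)
  expect_equal(nrow(sim0$truth), 0L)
  # a genome too small for the plantings is refused
  expect_error(plant_genome(synthetic_config(genome_length = 5000L,
                                             n_precursors = 40L)),
               "too small")
  expect_error(synthetic_config(loop_len_range = c(4L, 10L)))
})

test_that("reads sample planted matures with the stated error model", {
  sim <- shared_sim()
  reads <- sim$reads
  # ~depth reads per planting
  expect_equal(nrow(reads), 30 * nrow(sim$truth), tolerance = 0.3)
  expect_true(all(nchar(reads$sequence) == 26L))
  # error_rate 0: every read is an exact substring of the genome
  clean <- make_reads(sim$truth, depth = 5, error_rate = 0, seed = 65L)
  gplus <- sim$genome[["S1"]]
  gminus <- revcomp(gplus)
  for (r in clean$sequence)
    expect_true(grepl(r, gplus, fixed = TRUE) ||
                  grepl(r, gminus, fixed = TRUE))
  # depth 0: no reads
  expect_equal(nrow(make_reads(sim$truth, depth = 0, seed = 66L)), 0L)
  # deterministic per seed
  expect_identical(make_reads(sim$truth, 10, 0.01, seed = 67L),
                   make_reads(sim$truth, 10, 0.01, seed = 67L))
})

test_that("reference matures carry exactly the requested divergence", {
  sim <- shared_sim()
  refs0 <- make_reference_matures(sim$truth, divergence = 0L, seed = 68L)
  expect_equal(refs0$sequence[seq(1, nrow(refs0), by = 2)],
               sim$truth$mature_5p)
  for (dv in c(1L, 2L, 3L)) {
    refs <- make_reference_matures(sim$truth, divergence = dv, seed = 68L)
    for (i in seq_len(nrow(sim$truth))) {
      q5 <- refs$sequence[2L * i - 1L]
      mm <- sum(strsplit(q5, "")[[1]] !=
                  strsplit(sim$truth$mature_5p[i], "")[[1]])
      expect_equal(mm, dv)
      # the seed hexamer is untouched: family assignment is stable
      expect_equal(assign_family(q5), sim$truth$family_seed[i])
    }
  }
  expect_error(make_reference_matures(sim$truth, divergence = 25L),
               "seed intact|exceeds")
})

test_that("truth tables round-trip through the i/o layer", {
  sim <- shared_sim()
  bed <- tempfile(fileext = ".bed")
  write_bed(data.frame(scaffold = sim$truth$scaffold,
                       start = sim$truth$start, end = sim$truth$end,
                       name = sim$truth$id, score = 0,
                       strand = sim$truth$strand), bed)
  back <- read_bed(bed)
  expect_equal(back$start, sim$truth$start)
  expect_equal(back$end, sim$truth$end)
  expect_equal(back$strand, sim$truth$strand)
  fa <- tempfile(fileext = ".fa")
  write_fasta(stats::setNames(sim$truth$mature_5p, sim$truth$id), fa)
  expect_equal(read_fasta(fa)$sequence, sim$truth$mature_5p)
})
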