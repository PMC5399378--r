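test_that("evaluate_candidate applies each criterion independently", {
  # 64-nt single-hairpin candidate in the spirit of the printed miR-9
  # row: threshold at L=64 is -13.84, an MFE of -20.3 passes
  set.seed(1)
  p <- make_precursor(25, 8, 1, 0.1, mature_len = 22)
  rep64 <- evaluate_candidate(p$seq, p$structure, -20.3)
  expect_equal(rep64$mfe$threshold,
               -0.31 * nchar(p$seq) + 6.00)
  expect_true(rep64$mfe$pass)

  # length 45 fails the length criterion regardless of other values
  short <- evaluate_candidate(strrep("A", 45), strrep(".", 45), -50)
  expect_false(short$length$pass)
  expect_false(short$pass_all)

  # a two-hairpin fold fails the loop criterion
  db2 <- "((((....))))..((((....))))"
  rep2 <- evaluate_candidate(strrep("A", nchar(db2)), db2, -20)
  expect_equal(rep2$loops$value, 2L)
  expect_false(rep2$loops$pass)

  expect_error(evaluate_candidate("ACGU", NA, -1), "fold")
})

test_that("evaluate_candidate is pure and mature checks gate correctly", {
  set.seed(2)
  p <- make_precursor(30, 8, 2, 0.1)
  a <- evaluate_candidate(p$seq, p$structure, p$mfe,
                          mat_start = p$p5[1], mat_end = p$p5[2])
  b <- evaluate_candidate(p$seq, p$structure, p$mfe,
                          mat_start = p$p5[1], mat_end = p$p5[2])
  expect_identical(a, b)
  # without a mature, the two curation checks pass vacuously
  no_mat <- evaluate_candidate(p$seq, p$structure, p$mfe)
  expect_true(no_mat$bulge$pass)
  expect_true(no_mat$mature_in_loop$pass)
  expect_true(is.na(no_mat$mature_in_loop$value))
  # a mature centered on the loop fails the mature-in-loop check
  loop <- hairpin_loop_runs(p$structure)
  bad <- evaluate_candidate(p$seq, p$structure, p$mfe,
                            mat_start = loop$start - 3L,
                            mat_end = loop$end + 3L)
  expect_false(bad$mature_in_loop$pass)
})

test_that("apply_filters partitions candidates with reasons", {
  empty <- apply_filters(candidate_df())
  expect_equal(nrow(empty$pass), 0L)
  expect_equal(nrow(empty$rejected), 0L)

  set.seed(3)
  p <- make_precursor(30, 8, 1, 0.1)
  good <- candidate_df(id = "g", scaffold = "S1", start = 0L,
                       end = nchar(p$seq), strand = "+", seq = p$seq,
                       structure = p$structure, mfe = p$mfe, track = "t")
  bad <- good; bad$id <- "b"; bad$mfe <- 0  # fails the energy criterion
  res <- apply_filters(rbind(good, bad))
  expect_equal(res$pass$id, "g")
  expect_equal(res$rejected$reason, "mfe")
})

test_that("the printed-catalog MFE audit finds exactly one violation", {
  tab <- conserved_mirna_table()
  pass <- tab$mfe_kcal <= mfe_threshold(tab$length_nt)
  expect_equal(sum(pass), 36L)
  expect_equal(tab$family[!pass], "miR-7")
  expect_equal(tab$length_nt[!pass], 86L)
})

test_that("benchmark_compendium reports consistent percentages", {
  set.seed(4)
  pres <- vapply(1:20, function(k)
    make_precursor(sample(25:40, 1), sample(6:12, 1), sample(0:2, 1),
                   0.1)$seq, character(1))
  names(pres) <- sprintf("p%02d", 1:20)
  rep <- benchmark_compendium(pres)
  expect_equal(rep$n_precursors, 20L)
  # generated canonical precursors pass every criterion by construction
  expect_equal(unname(rep$percent), rep(100, 6), tolerance = 1e-9)

  # conjunction bound: all-pass <= each per-criterion percentage
  set.seed(5)
  mixed <- c(pres, junk = paste(sample(c("A", "U"), 80, TRUE,
                                       prob = c(.7, .3)), collapse = ""))
  repm <- benchmark_compendium(mixed)
  expect_true(all(repm$percent["all"] <=
                    repm$percent[setdiff(names(repm$percent), "all")]))

  # a single precursor failing only GC zeroes GC and all-pass
  gc_bad <- paste(rep(c("G", "C"), 20), collapse = "")
  stem <- paste0(gc_bad, "AUAAUA", revcomp(gc_bad))
  one <- benchmark_compendium(c(x = stem))
  expect_equal(unname(one$percent["gc"]), 0)
  expect_equal(unname(one$percent["all"]), 0)
})

test_that("widening any single criterion never shrinks pass rates", {
  set.seed(6)
  pres <- c(
    vapply(1:6, function(k)
      make_precursor(sample(20:40, 1), sample(6:14, 1), sample(0:3, 1),
                     0.15, mature_len = 20)$seq, character(1)),
    vapply(1:6, function(k)
      paste(sample(c("A", "C", "G", "U"), 90, TRUE), collapse = ""),
      character(1)))
  names(pres) <- sprintf("s%02d", seq_along(pres))
  base <- filter_criteria()
  wider <- list(
    filter_criteria(len_min = 30L, len_max = 150L),
    filter_criteria(gc_min = 0.2, gc_max = 0.8),
    filter_criteria(max_loops = 3L),
    filter_criteria(paired_min = 0.40),
    filter_criteria(mfe_intercept = 12))
  b0 <- benchmark_compendium(pres, base)
  for (w in wider) {
    bw <- benchmark_compendium(pres, w)
    expect_true(all(bw$percent >= b0$percent - 1e-9))
  }
})

test_that("fit_mfe_line recovers a linear MFE-length trend", {
  set.seed(7)
  L <- sample(50:130, 200, TRUE)
  mfe <- -0.31 * L + 6 + rnorm(200, 0, 1)
  fit <- fit_mfe_line(L, mfe)
  expect_equal(fit$slope, -0.31, tolerance = 0.02)
  expect_equal(fit$intercept, 6, tolerance = 1.5)
})
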