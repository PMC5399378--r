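test_that("extract_utr3 takes 400 bp after the stop on the coding strand", {
  set.seed(51)
  g <- c(S1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  models <- data.frame(
    scaffold = "S1", start = c(100L, 1200L, 1700L),
    end = c(1000L, 1500L, 1950L), strand = c("+", "-", "+"),
    type = "gene", id = c("plus", "minus", "edge"))
  u <- extract_utr3(models, g, length = 400L)
  # plus-strand gene ending at 1000: UTR = [1000, 1400)
  expect_equal(u$start[u$gene_id == "plus"], 1000L)
  expect_equal(u$end[u$gene_id == "plus"], 1400L)
  expect_equal(u$sequence[u$gene_id == "plus"],
               substr(g[["S1"]], 1001, 1400))
  # minus-strand gene: reverse complement of the 400 bp upstream span
  expect_equal(u$start[u$gene_id == "minus"], 800L)
  expect_equal(u$sequence[u$gene_id == "minus"],
               revcomp(substr(g[["S1"]], 801, 1200)))
  # gene 50 bp from the scaffold end: clipped and flagged
  expect_equal(nchar(u$sequence[u$gene_id == "edge"]), 50L)
  expect_true(u$clipped[u$gene_id == "edge"])
  # unknown strand is skipped with a count
  bad <- rbind(models, data.frame(scaffold = "S1", start = 1L, end = 2L,
                                  strand = ".", type = "gene", id = "x"))
  expect_equal(attr(extract_utr3(bad, g), "n_skipped"), 1L)
})

test_that("duplex energy is optimal for the perfect complement", {
  set.seed(52)
  mi <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  site <- revcomp(mi)
  perfect <- duplex_energy(mi, site, c(1L, 6L))
  expect_lt(perfect$energy, -15)
  # embedding the perfect site in a longer window gives the same optimum
  set.seed(53)
  pad <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                           collapse = "")
  win <- paste0(pad(15), site, pad(15))
  embedded <- duplex_energy(mi, win, c(1L, 6L))
  expect_equal(embedded$energy, perfect$energy, tolerance = 1e-9)
  # windows with no pairing possible under the constraint: no site
  poly <- duplex_energy("CCCCCCCCCCCCCCCCCCCCC", strrep("U", 30), c(1L, 6L))
  expect_equal(poly$energy, Inf)
  expect_error(duplex_energy(mi, site, c(20L, 25L)), "constraint")
})

test_that("duplex energy equals exhaustive enumeration on toy instances", {
  set.seed(54)
  for (k in 1:6) {
    mi <- paste(sample(c("A", "C", "G", "U"), 12, TRUE,
                       prob = c(.2, .3, .3, .2)), collapse = "")
    win <- paste0(paste(sample(c("A", "C", "G", "U"), 4, TRUE), collapse = ""),
                  revcomp(substr(mi, 3, 10)),
                  paste(sample(c("A", "C", "G", "U"), 4, TRUE), collapse = ""))
    for (fr in list(c(3L, 8L), c(4L, 9L))) {
      got <- duplex_energy(mi, win, fr)$energy
      want <- oracle_duplex(mi, win, fr[1], fr[2])
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("forcing a mismatch into the constrained helix never helps", {
  set.seed(55)
  for (k in 1:10) {
    mi <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
    site <- revcomp(mi)
    base <- duplex_energy(mi, site, c(2L, 7L))$energy
    v <- strsplit(site, "")[[1]]
    # break a pair inside the constrained helix (site is reverse-aligned)
    pos <- length(v) - 3L
    v[pos] <- setdiff(c("A", "C", "G", "U"), v[pos])[1]
    worse <- duplex_energy(mi, paste(v, collapse = ""), c(2L, 7L))$energy
    expect_gte(worse, base - 1e-9)
  }
})

test_that("dinucleotide_shuffle preserves doublet composition", {
  set.seed(56)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                    prob = c(.35, .15, .15, .35)), collapse = "")
  doublets <- function(x) {
    v <- strsplit(x, "")[[1]]
    sort(table(paste0(v[-length(v)], v[-1])))
  }
  changed <- FALSE
  for (k in 1:10) {
    sh <- dinucleotide_shuffle(s)
    expect_equal(doublets(sh), doublets(s))
    if (sh != s) changed <- TRUE
  }
  expect_true(changed)  # it actually shuffles
})

test_that("scan_targets recovers planted perfect-complement sites", {
  set.seed(57)
  mirnas <- c(m1 = paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                         collapse = ""))
  tu <- make_target_utrs(mirnas, n_utr = 25L, n_planted = 6L, seed = 58L)
  sites <- scan_targets(mirnas, tu$utrs, p_max = 0.01, n_shuffle = 200L)
  expect_true(all(tu$truth$gene_id %in% sites$gene_id))
  # p-values decrease with stronger duplexes
  ord <- order(sites$duplex_energy)
  expect_true(all(diff(sites$p_value[ord]) >= -1e-12))
  # empty UTR set gives an empty result
  empty <- scan_targets(mirnas, tu$utrs[0, ], n_shuffle = 200L)
  expect_equal(nrow(empty), 0L)
  expect_error(scan_targets(mirnas, tu$utrs, n_shuffle = 50L), ">= 200")
})
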