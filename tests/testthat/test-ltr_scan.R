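# Identical-LTR scanning: exact recovery of implanted elements, rejection of
# divergent pairs, TSD detection, and the LTR identity measure.

test_that("implanted identical-LTR elements are recovered at exact truth coordinates", {
  w <- cached_world(1)
  g <- c(chr1 = w$genome)
  cand <- find_identical_ltr_pairs(g)
  truth <- w$truth[w$truth$expected != "not_detected", ]
  expect_equal(nrow(cand), nrow(truth))
  expect_equal(cand$start, truth$start)
  expect_equal(cand$end, truth$end)
  expect_equal(cand$ltr5_end, truth$ltr5_end)
  expect_equal(cand$ltr3_start, truth$ltr3_start)
  expect_true(all(cand$ltr_identity == 100))
  # maximality: extending any reported pair by one base breaks identity
  for (i in seq_len(nrow(cand))) {
    l5 <- substr(w$genome, cand$ltr5_start[i] - 1L, cand$ltr5_end[i])
    l3 <- substr(w$genome, cand$ltr3_start[i] - 1L, cand$ltr3_end[i])
    expect_false(identical(l5, l3))
    r5 <- substr(w$genome, cand$ltr5_start[i], cand$ltr5_end[i] + 1L)
    r3 <- substr(w$genome, cand$ltr3_start[i], cand$ltr3_end[i] + 1L)
    expect_false(identical(r5, r3))
  }
})

test_that("a single LTR substitution removes the pair at similarity 100", {
  w <- cached_world(1)
  expect_false(any(find_identical_ltr_pairs(c(chr1 = w$genome))$start ==
                     w$truth$start[w$truth$element_id == "decoy_ltr"]))
})

test_that("repeat-free sequence yields no candidates and short contigs are skipped", {
  bg <- make_background(50000, seed = 11)
  expect_equal(nrow(find_identical_ltr_pairs(c(c1 = bg))), 0L)
  expect_message(
    res <- find_identical_ltr_pairs(c(tiny = substr(bg, 1, 500))),
    "shorter than min_element_span")
  expect_equal(nrow(res), 0L)
  expect_equal(nrow(find_identical_ltr_pairs(character())), 0L)
})

test_that("reverse-complementing the genome mirrors candidate coordinates", {
  w <- cached_world(1, decoys = FALSE)
  g <- w$genome
  L <- nchar(g)
  fwd <- find_identical_ltr_pairs(c(chr1 = g))
  rev <- find_identical_ltr_pairs(
    c(chr1 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(g)))))
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(rev$start, L - fwd$end + 1L)
  expect_equal(rev$end, L - fwd$start + 1L)
})

test_that("overlapping nested repeats resolve to the longest element", {
  # two pairs sharing an interval: an inner 150-bp pair nested inside the
  # element of an outer 150-bp pair; only the longer element survives
  set.seed(5)
  ltr_o <- rand_dna_str(150)
  ltr_i <- rand_dna_str(150)
  mid <- rand_dna_str(800)
  g <- paste0(rand_dna_str(1200), ltr_o,
              rand_dna_str(400), ltr_i, mid, ltr_i, rand_dna_str(400),
              ltr_o, rand_dna_str(1200))
  cand <- find_identical_ltr_pairs(
    c(c1 = g), scan_params(min_element_span = 1000, max_element_span = 5000))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$ltr_len, 150L)
  expect_equal(cand$end - cand$start + 1L,
               150L + 400L + 150L + 800L + 150L + 400L + 150L)
})

test_that("TSD detection matches brute-force enumeration and flags edges", {
  p <- scan_params(tsd_min = 4, tsd_max = 5)
  set.seed(21)
  # exact 4-bp duplication by construction
  core <- rand_dna_str(1500)
  g <- paste0(rand_dna_str(300), "ACGT", core, "ACGT", rand_dna_str(300))
  cand <- data.frame(contig = "c1", start = 305L, end = 304L + 1500L,
                     ltr5_start = 305L, ltr5_end = 404L,
                     ltr3_start = 1705L, ltr3_end = 1804L, ltr_len = 100L,
                     ltr_identity = 100, tsd_seq = NA_character_,
                     strand = "+", stringsAsFactors = FALSE)
  out <- detect_tsd(c(c1 = g), cand, p)
  expect_equal(out$tsd_seq, "ACGT")
  expect_equal(out$tsd_flag, "ok")

  # flanks sharing 6 identical bases but tsd_max 5: the 5-base window wins,
  # matching brute force over all window lengths (a sub-window of a longer
  # duplication is itself adjacent only for a periodic repeat, hence AAAAAA)
  g6 <- paste0(rand_dna_str(300), "AAAAAA", core, "AAAAAA", rand_dna_str(300))
  cand6 <- cand
  cand6$start <- 307L; cand6$end <- 306L + 1500L
  out6 <- detect_tsd(c(c1 = g6), cand6, p)
  expect_equal(nchar(out6$tsd_seq), 5L)
  expect_equal(out6$tsd_seq,
               oracle_tsd(substr(g6, 1, 306), substr(g6, 1807, nchar(g6)),
                          4L, 5L))

  # no shared duplication
  gno <- paste0(strrep("A", 300), "CCCC", core, "GGGG", strrep("A", 300))
  candno <- cand
  out_no <- detect_tsd(c(c1 = gno), candno, p)
  expect_true(is.na(out_no$tsd_seq))

  # contig edge
  cedge <- cand
  cedge$start <- 3L
  out_e <- detect_tsd(c(c1 = g), cedge, p)
  expect_true(is.na(out_e$tsd_seq))
  expect_equal(out_e$tsd_flag, "contig_edge")
})

test_that("ltr_identity counts mismatches and handles alignment and errors", {
  set.seed(31)
  a <- rand_dna_str(968)
  b <- mutate_at(a, c(100, 500, 900))
  expect_equal(round(ltr_identity(a, b), 2), 99.69)
  expect_equal(ltr_identity(a, a), 100)
  c500 <- rand_dna_str(500)
  expect_equal(ltr_identity(c500, mutate_at(c500, seq(10, 460, by = 50))), 98)
  # symmetry, and 100 iff identical for equal lengths
  d <- mutate_at(a, 42)
  expect_equal(ltr_identity(a, d), ltr_identity(d, a))
  expect_lt(ltr_identity(a, d), 100)
  # unequal lengths go through global alignment: one deleted base costs one
  # alignment column
  trunc <- paste0(substr(a, 1, 99), substr(a, 101, 968))
  expect_gt(ltr_identity(a, trunc), 99.5)
  expect_lt(ltr_identity(a, trunc), 100)
  expect_error(ltr_identity("", a), "empty")
  # N never matches, even against N
  expect_equal(ltr_identity("ACGTN", "ACGTN"), 80)
})

test_that("scan_params rejects invalid bounds", {
  expect_error(scan_params(min_ltr_len = 10, seed_kmer = 20))
  expect_error(scan_params(min_element_span = 150, min_ltr_len = 100))
  expect_error(scan_params(ltr_similarity_pct = 95), "100")
  expect_error(scan_params(tsd_min = 10, tsd_max = 5))
})

test_that("candidate tables round-trip through GFF3 and TSV writers", {
  w <- cached_world(1)
  g <- c(chr1 = w$genome)
  cand <- detect_tsd(g, find_identical_ltr_pairs(g))
  tmp <- file.path(tempdir(), "scan_out")
  paths <- write_candidates(cand, tmp)
  gff <- readLines(paths[["gff3"]])
  expect_equal(gff[1], "##gff-version 3")
  expect_equal(sum(grepl("\tLTR_retrotransposon\t", gff)), nrow(cand))
  expect_equal(sum(grepl("\tlong_terminal_repeat\t", gff)), 2L * nrow(cand))
  back <- utils::read.delim(paths[["tsv"]])
  expect_equal(back$start, cand$start)
  expect_equal(back$tsd_seq, cand$tsd_seq)
})
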