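# Junction-query construction, read mapping, meaningful-read rules,
# presence calls, genotypes and population frequencies.

make_pw <- function(seed, ...) {
  key <- paste0("popworld_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_population_world(seed, ...)
  }
  .fixtures[[key]]
}

test_that("junction queries have the stated lengths, window and round-trip", {
  pw <- make_pw(1)
  g <- c(locus_region = pw$genome_with)
  q <- build_junction_queries(g, pw$candidate)  # tsd_len 5 by construction
  expect_s3_class(q, "junction_queries")
  expect_equal(nchar(q$ins5), 400L)
  expect_equal(nchar(q$ins3), 400L)
  expect_equal(nchar(q$initial), 400L - q$tsd_len)
  expect_equal(q$window, c(190L, 210L))

  # tsd_len 4 gives the 396-base initial-state query
  c4 <- pw$candidate
  c4$tsd_seq <- substr(c4$tsd_seq, 1, 4)
  expect_equal(nchar(build_junction_queries(g, c4)$initial), 396L)

  # an absent TSD means nothing is trimmed from the 3' flank
  c0 <- pw$candidate
  c0$tsd_seq <- NA_character_
  q0 <- build_junction_queries(g, c0)
  expect_equal(nchar(q0$initial), 400L)
  expect_equal(q0$tsd_len, 0L)

  # errors: flank or element too short
  tiny <- pw$candidate
  tiny$start <- 50L
  expect_error(build_junction_queries(g, tiny), "insufficient flank")
  short_el <- pw$candidate
  short_el$end <- short_el$start + 100L
  expect_error(build_junction_queries(g, short_el), "shorter than flank")
})

test_that("the initial-state query reconstructs the pre-insertion locus", {
  pw <- make_pw(1)
  q <- build_junction_queries(c(locus_region = pw$genome_with), pw$candidate)
  tl <- q$tsd_len
  site <- pw$candidate$start - tl  # implant site in background coordinates
  truth_window <- substr(pw$genome_without, site - 200L + tl,
                         site - 200L + tl + nchar(q$initial) - 1L)
  expect_equal(q$initial, truth_window)
})

test_that("read mapping honours the identity cutoff and full-length flag", {
  pw <- make_pw(1)
  q <- build_junction_queries(c(locus_region = pw$genome_with), pw$candidate)
  r <- substr(q$ins5, 150, 299)
  m <- map_read(r, q)
  m5 <- m[m$query_id == "ins5", ]
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$identity, 100)
  expect_true(m5$full_length)
  expect_equal(c(m5$q_start, m5$q_end), c(150L, 299L))

  # the reverse complement maps identically
  mrc <- map_read(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r))), q)
  mrc5 <- mrc[mrc$query_id == "ins5", ]
  expect_equal(c(mrc5$q_start, mrc5$q_end), c(150L, 299L))
  expect_equal(mrc5$orientation, "-")

  # two mismatches: 148/150 = 98.7% < 99%, mapping rejected
  r2 <- mutate_at(r, c(40, 90))
  m2 <- map_read(r2, q)
  expect_false("ins5" %in% m2$query_id[m2$identity >= 99])

  # read matching only its first 100 bases is not full length
  r3 <- paste0(substr(q$ins5, 150, 249), rand_dna_str(50))
  m3 <- map_read(r3, q, min_identity = 50)
  m35 <- m3[m3$query_id == "ins5", ]
  expect_true(nrow(m35) == 0L || !any(m35$full_length))
})

test_that("meaningfulness requires full length and full junction coverage", {
  pw <- make_pw(1)
  q <- build_junction_queries(c(locus_region = pw$genome_with), pw$candidate)
  mk <- function(s, e, full) data.frame(
    read_id = "r", query_id = "ins5", q_start = s, q_end = e,
    identity = 100, e_value = 0, full_length = full, orientation = "+")
  expect_true(is_meaningful(mk(185L, 334L, TRUE), q))
  expect_false(is_meaningful(mk(195L, 344L, TRUE), q))
  expect_false(is_meaningful(mk(150L, 350L, FALSE), q))
})

test_that("presence counts respect genotype truth and read order", {
  pw <- make_pw(2, allele_freq = 0.5, n_individuals = 4)
  g <- c(locus_region = pw$genome_with)
  q <- build_junction_queries(g, pw$candidate)
  expect_equal(call_presence(character(), q), c(n_ins = 0L, n_empty = 0L))
  for (i in seq_len(4)) {
    cnt <- call_presence(pw$sample_reads[[i]], q)
    truth <- pw$population$genotype[i]
    if (truth == "ii") {
      expect_gt(cnt[["n_ins"]], 0); expect_equal(cnt[["n_empty"]], 0L)
    } else if (truth == "--") {
      expect_equal(cnt[["n_ins"]], 0L); expect_gt(cnt[["n_empty"]], 0)
    } else {
      expect_gt(cnt[["n_ins"]], 0); expect_gt(cnt[["n_empty"]], 0)
    }
    # order invariance
    shuffled <- pw$sample_reads[[i]][sample(length(pw$sample_reads[[i]]))]
    expect_equal(call_presence(shuffled, q), cnt)
  }
})

test_that("genotype calls follow the diploid and pool rules", {
  expect_equal(genotype_sample(c(5, 0))$genotype, "ii")
  expect_equal(genotype_sample(c(3, 4))$genotype, "i-")
  expect_equal(genotype_sample(c(0, 7))$genotype, "--")
  expect_equal(genotype_sample(c(0, 0))$genotype, "nocall")
  expect_error(genotype_sample(c(1, 0), sample_kind = "pool_with_size"),
               "pool_size")
  pool <- genotype_sample(c(9, 0), sample_kind = "pool_with_size",
                          pool_size = 5)
  expect_equal(pool$genotype, "ii")
  expect_equal(pool$pool_size, 5L)
  mixed <- genotype_sample(c(4, 6), sample_kind = "pool_with_size",
                           pool_size = 5)
  expect_equal(mixed$genotype, "i-")
})

test_that("population frequencies follow the stated arithmetic and IN > 4 rule", {
  calls <- do.call(rbind, c(
    lapply(1:4, function(i) genotype_sample(c(5, 0), paste0("a", i), "L")),
    lapply(1:2, function(i) genotype_sample(c(3, 3), paste0("b", i), "L")),
    lapply(1:4, function(i) genotype_sample(c(0, 5), paste0("c", i), "L"))
  ))
  groups <- stats::setNames(rep("g1", 10), calls$sample_id)
  f <- population_frequencies(calls, groups)
  expect_equal(f$n_individuals, 10L)
  expect_equal(f$freq_i, 0.5)
  expect_equal(f$freq_empty, 0.5)
  expect_equal(c(f$freq_ii, f$freq_het, f$freq_mm), c(0.4, 0.2, 0.4))
  expect_true(f$reported)

  # 3 individuals: frequencies withheld
  small <- calls[1:3, ]
  fs <- population_frequencies(small, stats::setNames(rep("g", 3),
                                                      small$sample_id))
  expect_false(fs$reported)
  expect_true(is.na(fs$freq_i))

  # a homozygous pool of known size contributes pool_size individuals
  pcalls <- rbind(
    genotype_sample(c(9, 0), "pool1", "L", "pool_with_size", pool_size = 5),
    genotype_sample(c(4, 0), "ind1", "L")
  )
  fp <- population_frequencies(pcalls, stats::setNames(rep("g", 2),
                                                       pcalls$sample_id))
  expect_equal(fp$n_individuals, 6L)
  expect_equal(fp$freq_i, 1)
  expect_true(fp$reported)

  # a mixed-evidence pool is excluded from individual-based frequencies but
  # still counted in the total-data tally
  mcalls <- rbind(pcalls,
                  genotype_sample(c(3, 3), "pool2", "L", "pool_with_size",
                                  pool_size = 4))
  fm <- population_frequencies(mcalls, stats::setNames(rep("g", 3),
                                                       mcalls$sample_id))
  expect_equal(fm$n_individuals, 6L)
  expect_equal(fm$n_samples_total, 3L)
})

test_that("fixed and absent loci never yield contradictory evidence", {
  pw1 <- make_pw(5, allele_freq = 1, n_individuals = 3)
  res1 <- genotype_locus(c(locus_region = pw1$genome_with), pw1$candidate,
                         pw1$sample_reads)
  expect_true(all(res1$calls$genotype == "ii"))
  expect_true(all(res1$calls$n_empty_reads == 0L))
  pw0 <- make_pw(6, allele_freq = 0, n_individuals = 3)
  res0 <- genotype_locus(c(locus_region = pw0$genome_with), pw0$candidate,
                         pw0$sample_reads)
  expect_true(all(res0$calls$genotype == "--"))
  expect_true(all(res0$calls$n_ins_reads == 0L))
})

test_that("genotypes are recovered with substitution sequencing errors", {
  pw <- make_pw(7, allele_freq = 0.5, n_individuals = 5, error_rate = 0.002,
                coverage = 15)
  res <- genotype_locus(c(locus_region = pw$genome_with), pw$candidate, pw$sample_reads)
  expect_equal(res$calls$genotype, pw$population$genotype)
})
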