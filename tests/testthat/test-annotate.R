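# Retroviral annotation: translation, RT homology, classification, ORF
# labeling, domain architecture and the intactness filter cascade.

test_that("six-frame translation follows the codon table and covers both strands", {
  out <- six_frame_translate("ATGAAATAA")
  expect_equal(out$peptide[out$strand == "+" & out$frame == 0], "MK*")
  expect_error(six_frame_translate("ATGXX"), "A,C,G,T,N")
  expect_error(six_frame_translate("AT"), "codon")

  # reverse-complementing the input swaps the strand labels
  set.seed(1)
  s <- rand_dna_str(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- six_frame_translate(s)
  b <- six_frame_translate(rc)
  expect_setequal(a$peptide[a$strand == "+"], b$peptide[b$strand == "-"])
  expect_setequal(a$peptide[a$strand == "-"], b$peptide[b$strand == "+"])

  # length accounting: per strand the three frames cover all but at most
  # two bases
  per_strand <- tapply(nchar(a$peptide) * 3L, a$strand, sum)
  expect_true(all(per_strand >= 3L * 300L - 2L * 3L))
  expect_true(all(per_strand <= 3L * 300L))
})

test_that("the toy panel is internally consistent", {
  p <- cached_panel()
  gene_aa <- attr(p, "gene_aa")
  expect_equal(unname(p$orf_min_len),
               unname(floor(0.8 * apply(gene_aa, 2, min))))
  expect_equal(length(p$rt_queries), 6L)
  expect_equal(length(p$decoy_rts), 2L)
  # panel genomes have identical terminal LTRs by construction
  lay <- attr(p, "layout")
  for (nm in names(p$genomes)) {
    g <- p$genomes[[nm]]
    ll <- lay[[nm]]$ltr_len
    expect_identical(substr(g, 1, ll), substr(g, nchar(g) - ll + 1, nchar(g)))
  }
})

test_that("RT homology search finds panel self-hits and rejects noise and stops", {
  p <- cached_panel()
  w <- cached_world(1, decoys = FALSE)
  g <- c(chr1 = w$genome)
  cand <- find_identical_ltr_pairs(g)
  el <- element_seq(g, cand[1, ])
  interior <- substr(el, cand$ltr_len + 1, nchar(el) - cand$ltr_len)
  hit <- rt_homology_search(interior, p)
  expect_false(is.null(hit))
  expect_gt(hit$aa_len, 100)
  expect_gt(hit$identity, 99)
  expect_lte(hit$e_value, 1e-5)
  expect_equal(hit$query_id, "panelvirus02_RT")

  # random sequence: no homology
  expect_null(rt_homology_search(rand_dna_str(3000), p))

  # in-frame stops across the RT region: no stop-free fragment above 100 aa
  # remains, so the hit disappears
  lay <- attr(p, "layout")[["panelvirus02"]]
  pol <- lay$genes$pol
  ll <- lay$ltr_len
  broken <- interior
  for (codon in c(180, 270, 360)) {
    at <- pol[["start"]] - ll + 3 * (codon - 1)  # interior coordinates
    broken <- paste0(substr(broken, 1, at - 1), "TAA",
                     substr(broken, at + 3, nchar(broken)))
  }
  expect_null(rt_homology_search(broken, p))

  p_empty <- p
  p_empty$rt_queries <- character(0)
  expect_error(rt_homology_search(interior, p_empty), "empty")
})

test_that("RT classification separates retroviral and decoy references", {
  p <- cached_panel()
  expect_equal(classify_rt(p$rt_queries[[3]], p), "retrovirus")
  expect_equal(classify_rt(p$decoy_rts[[1]], p), "retrotransposon")
  # half/half chimera of the two top references falls inside the margin
  chim <- paste0(substr(p$rt_queries[[1]], 1, 150),
                 substr(p$decoy_rts[[1]], 151, nchar(p$decoy_rts[[1]])))
  expect_equal(classify_rt(chim, p), "unclassified")
  p0 <- p
  p0$decoy_rts <- character()
  expect_warning(cl <- classify_rt(p$rt_queries[[1]], p0), "decoy")
  expect_equal(cl, "retrovirus")
})

test_that("ORF annotation labels the four core genes in order", {
  p <- cached_panel()
  orfs <- annotate_orfs(p$genomes[["panelvirus03"]], p)
  core <- orfs[orfs$gene != "other", ]
  expect_equal(core$gene, c("gag", "pro", "pol", "env"))
  expect_equal(core$aa_len, unname(attr(p, "gene_aa")["panelvirus03", ]))
  # labeled spans never overlap
  expect_true(all(core$start[-1] > core$end[-nrow(core)]))
  # all-N interior yields nothing
  expect_equal(nrow(annotate_orfs(strrep("N", 3000), p)), 0L)
})

test_that("domain architecture requires ordered motifs and a hydrophobic TM", {
  p <- cached_panel()
  pol <- p$gene_refs$pol[["panelvirus01"]]
  env <- p$gene_refs$env[["panelvirus01"]]
  d <- check_domain_architecture(pol, env, p)
  expect_true(all(d$flags))
  expect_true(d$pol_order_ok)
  expect_true(all(diff(unlist(d$positions[c("RT", "RH", "IN")])) > 0))

  # a poly-Ile 19-mer is a maximal-hydropathy TM
  d2 <- check_domain_architecture("MAAA", paste0("MRRR", strrep("I", 19), "RRR"), p)
  expect_true(d2$flags[["TM"]])

  # IN motif placed before the RT motifs: order fails, architecture absent
  prof <- p$motif_profiles
  pats <- function(dom) prof$pattern[prof$domain == dom & prof$pattern != ""]
  bad_pol <- paste0("M", strrep("A", 10), pats("IN"), strrep("A", 10),
                    pats("RT")[1], strrep("A", 5), pats("RT")[2],
                    strrep("A", 10), strrep("G", 30))
  d3 <- check_domain_architecture(bad_pol, env, p)
  expect_false(d3$flags[["IN"]])
  expect_false(d3$pol_order_ok)
})

test_that("the intactness cascade passes intact elements and codes each decoy failure", {
  w <- cached_world(1)
  g <- c(chr1 = w$genome)
  cand <- detect_tsd(g, find_identical_ltr_pairs(g))
  for (i in seq_len(nrow(cand))) {
    rec <- annotate_element(g, cand[i, ], w$panel)
    truth <- w$truth[match(cand$start[i], w$truth$start), ]
    if (truth$expected == "pass") {
      expect_equal(rec$verdict, "pass")
      expect_length(rec$fail_reasons, 0)
    } else {
      expect_equal(rec$verdict, "fail")
      expect_true(truth$expected %in% rec$fail_reasons,
                  label = paste(truth$element_id, "->",
                                paste(rec$fail_reasons, collapse = ",")))
    }
    # verdict is a pure function of its inputs: rerunning reproduces it
    rec2 <- check_intactness(rec, w$panel)
    expect_equal(rec2$verdict, rec$verdict)
    expect_equal(rec2$fail_reasons, rec$fail_reasons)
  }
})

test_that("a gag ORF just under the cutoff fails as short_orf", {
  p <- cached_panel()
  # shrink gag of panelvirus02 by an in-frame internal deletion to ~75% of
  # its own length, below the 80%-of-shortest cutoff
  lay <- attr(p, "layout")[["panelvirus02"]]
  g2 <- p$genomes[["panelvirus02"]]
  gag <- lay$genes$gag
  cut_codons <- ceiling((attr(p, "gene_aa")["panelvirus02", "gag"] -
                           p$orf_min_len[["gag"]]) / 3) * 3 + 24
  del_start <- gag[["start"]] + 150
  el <- paste0(substr(g2, 1, del_start - 1),
               substr(g2, del_start + 3 * cut_codons, nchar(g2)))
  bg <- make_background(4000, seed = 9)
  ins <- paste0(substr(bg, 1, 2000), el, substr(bg, 2001, 4000))
  cand <- find_identical_ltr_pairs(c(c1 = ins))
  expect_equal(nrow(cand), 1L)
  rec <- annotate_element(c(c1 = ins), detect_tsd(c(c1 = ins), cand)[1, ], p)
  expect_equal(rec$verdict, "fail")
  expect_true("short_orf:gag" %in% rec$fail_reasons)
  expect_false("premature_stop:gag" %in% rec$fail_reasons)
})

test_that("gene order violations are reported", {
  p <- cached_panel()
  # rebuild a genome with pol and pro swapped
  lay <- attr(p, "layout")[["panelvirus04"]]
  g <- p$genomes[["panelvirus04"]]
  pro <- lay$genes$pro; pol <- lay$genes$pol
  seg <- function(sp) substr(g, sp[["start"]], sp[["end"]])
  between <- substr(g, pro[["end"]] + 1, pol[["start"]] - 1)
  swapped <- paste0(substr(g, 1, pro[["start"]] - 1), seg(pol), between,
                    seg(pro), substr(g, pol[["end"]] + 1, nchar(g)))
  bg <- make_background(4000, seed = 10)
  ins <- paste0(substr(bg, 1, 2000), swapped, substr(bg, 2001, 4000))
  cand <- find_identical_ltr_pairs(c(c1 = ins))
  rec <- annotate_element(c(c1 = ins), detect_tsd(c(c1 = ins), cand)[1, ], p)
  expect_equal(rec$verdict, "fail")
  expect_true("order_violation" %in% rec$fail_reasons)
})

test_that("motif profiles round-trip through the TSV fixture", {
  path <- system.file("extdata", "motif_profiles.tsv", package = "ervi")
  expect_true(nzchar(path))
  expect_equal(read_motif_profiles(path), default_motif_profiles())
})
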