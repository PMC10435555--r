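# Synthetic test worlds: toy reference panels of replication-competent
# retrovirus genomes, repeat-free backgrounds, provirus implants (intact or
# deliberately broken decoys), Hardy-Weinberg populations and sequencing
# reads -- all pure functions of (parameters, seed) with machine-readable
# truth, so every pipeline stage can be validated without external data.

.BASES <- c("A", "C", "G", "T")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.rand_peptide <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                   collapse = "")

# codons per amino acid, standard genetic code
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# encode a peptide as DNA with random synonymous codons (no stop codons)
.encode_peptide <- function(pep) {
  ct <- .codon_table()
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cods <- ct[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# spacer with stop codons in all three forward frames, so no ORF can run
# across gene boundaries
.SPACER <- "TTAGTTAGTTAGTTAG"

# substitute at given positions with a different base
.mutate_dna <- function(seq, positions) {
  sv <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    sv[p] <- sample(setdiff(.BASES, sv[p]), 1L)
  }
  paste(sv, collapse = "")
}

.mutate_peptide <- function(pep, rate) {
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (p in hit) aa[p] <- sample(setdiff(.AA20, aa[p]), 1L)
  paste(aa, collapse = "")
}

#' Generate a repeat-free random background sequence
#'
#' Uniform-random DNA in which no `seed_kmer`-mer occurs twice, so decoy LTR
#' pairs cannot arise by chance: any duplicate k-mer is rejection-sampled
#' away.
#'
#' @param length background length in bases.
#' @param seed integer seed.
#' @param seed_kmer k-mer size that must be unique (default 20, matching the
#'   scanner's seed).
#' @return a DNA string.
#' @export
make_background <- function(length, seed, seed_kmer = 20L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  s <- .rand_dna(length)
  k <- seed_kmer
  repeat {
    kmers <- substring(s, 1:(length - k + 1L), k:length)
    dup <- which(duplicated(kmers))
    if (!length(dup)) break
    s <- .mutate_dna(s, dup + (k %/% 2L))  # hit the duplicate's middle base
  }
  s
}

# gene layout of a panel genome, amino-acid lengths -> nucleotide spans
.panel_layout <- function(ltr_len, aa_lens, utr5 = 40L, utr3 = 40L) {
  sp <- nchar(.SPACER)
  pos <- ltr_len + sp + utr5 + sp
  layout <- list()
  for (gene in c("gag", "pro", "pol", "env")) {
    nt_len <- 3L * (aa_lens[[gene]] + 1L)  # ATG..stop inclusive
    layout[[gene]] <- c(start = pos + 1L, end = pos + nt_len)
    pos <- pos + nt_len + sp
  }
  attr(layout, "interior_end") <- pos + utr3 + sp
  layout
}

#' Build a toy reference panel of replication-competent retrovirus genomes
#'
#' Generates `n_genomes` synthetic proviral genomes, each with identical
#' 5'/3' LTRs and intact `gag`-`pro`-`pol`-`env` ORFs; every Pol embeds the
#' bundled RT/RH/IN motifs in order and every Env a 19-residue hydrophobic
#' transmembrane stretch, so each panel member passes the intactness filter
#' by construction. The per-gene intact-ORF cutoffs are set to 80\% of the
#' shortest panel ORF (applied at toy scale). RT protein queries are the
#' motif-bearing Pol segment of each genome; `n_decoys` retrotransposon-like
#' decoy RTs are heavily mutated copies of the first query (still alignable,
#' but nearer to themselves than to any retroviral query). Genomes are
#' mutually unrelated random sequences, so pairwise identities stay far
#' below 95\% and the panel clusters into singleton vOTUs.
#'
#' This panel is synthetic: a stand-in with the same structure as a curated
#' reference set, not derived from any real retrovirus sequence.
#'
#' @param seed integer seed.
#' @param n_genomes number of panel genomes (default 6, minimum 2).
#' @param n_decoys number of decoy RTs (default 2).
#' @param fasta optional path; when given, panel genomes are written there
#'   as FASTA.
#' @return an `ervi_panel` whose `genomes` field holds the panel sequences;
#'   attribute `"layout"` records per-genome LTR length and gene spans,
#'   attribute `"gene_aa"` the per-gene amino-acid lengths.
#' @export
make_reference_panel <- function(seed = 1L, n_genomes = 6L, n_decoys = 2L,
                                 fasta = NULL) {
  stopifnot(n_genomes >= 2L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  prof <- default_motif_profiles()
  pat <- function(dom, i) prof$pattern[prof$domain == dom & prof$idx == i]
  tm19 <- "IILLVVFAVLGLLIIAGLV"  # mean Kyte-Doolittle hydropathy ~3.5

  ltr_lens <- rep_len(c(160L, 220L, 280L, 320L, 360L, 400L), n_genomes)
  genomes <- character(n_genomes)
  names(genomes) <- sprintf("panelvirus%02d", seq_len(n_genomes))
  gene_aa <- matrix(0L, n_genomes, 4L,
                    dimnames = list(names(genomes),
                                    c("gag", "pro", "pol", "env")))
  gene_refs <- list(gag = character(), pro = character(), pol = character(),
                    env = character())
  rt_queries <- character(n_genomes)
  layouts <- vector("list", n_genomes)

  embed <- function(pep, motif, at) {
    # overwrite residues at..at+len-1 with the motif
    paste0(substr(pep, 1L, at - 1L), motif,
           substr(pep, at + nchar(motif), nchar(pep)))
  }

  for (i in seq_len(n_genomes)) {
    aa <- c(gag = 280L + 7L * i, pro = 140L + 4L * i,
            pol = 640L + 9L * i, env = 350L + 5L * i)
    gene_aa[i, ] <- aa
    peps <- list(
      gag = paste0("M", .rand_peptide(aa[["gag"]] - 1L)),
      pro = paste0("M", .rand_peptide(aa[["pro"]] - 1L)),
      pol = paste0("M", .rand_peptide(aa[["pol"]] - 1L)),
      env = paste0("M", .rand_peptide(aa[["env"]] - 1L))
    )
    peps$pol <- embed(peps$pol, pat("RT", 1L), 120L)
    peps$pol <- embed(peps$pol, pat("RT", 2L), 170L)
    peps$pol <- embed(peps$pol, pat("RH", 1L), round(0.55 * aa[["pol"]]))
    peps$pol <- embed(peps$pol, pat("IN", 1L), round(0.78 * aa[["pol"]]))
    peps$env <- embed(peps$env, tm19, round(0.6 * aa[["env"]]))
    rt_queries[i] <- substr(peps$pol, 100L, 400L)

    ltr <- .rand_dna(ltr_lens[i])
    utr5 <- .rand_dna(40L); utr3 <- .rand_dna(40L)
    genomes[i] <- paste0(
      ltr, .SPACER, utr5, .SPACER,
      .encode_peptide(peps$gag), "TAA", .SPACER,
      .encode_peptide(peps$pro), "TAA", .SPACER,
      .encode_peptide(peps$pol), "TAA", .SPACER,
      .encode_peptide(peps$env), "TAA", .SPACER,
      utr3, .SPACER, ltr
    )
    layouts[[i]] <- list(ltr_len = ltr_lens[i],
                         genes = .panel_layout(ltr_lens[i], as.list(aa)))
    for (gene in names(peps)) {
      gene_refs[[gene]] <- c(gene_refs[[gene]],
                             stats::setNames(peps[[gene]],
                                             names(genomes)[i]))
    }
  }
  names(rt_queries) <- paste0(names(genomes), "_RT")
  decoys <- character(n_decoys)
  if (n_decoys > 0L) {
    for (j in seq_len(n_decoys)) {
      decoys[j] <- .mutate_peptide(rt_queries[[1L]], rate = 0.45)
    }
    names(decoys) <- sprintf("retrotransposon_RT%02d", seq_len(n_decoys))
  }
  orf_min <- floor(0.8 * apply(gene_aa, 2L, min))
  panel <- reference_panel(
    rt_queries = rt_queries, decoy_rts = decoys,
    orf_min_len = orf_min, gene_refs = gene_refs,
    motif_profiles = prof, genomes = genomes
  )
  names(layouts) <- names(genomes)
  attr(panel, "layout") <- layouts
  attr(panel, "gene_aa") <- gene_aa
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes), fasta)
  }
  panel
}

# nt span of a gene within a (possibly re-laid-out) element
.gene_span <- function(panel, source, gene) {
  attr(panel, "layout")[[source]]$genes[[gene]]
}

#' Specification of one provirus implant
#'
#' @param element_id identifier for the implant.
#' @param source name of the panel genome supplying the element.
#' @param site 1-based background position: the target-site duplication is
#'   the `tsd_len` bases starting there, and the element is inserted between
#'   the two TSD copies.
#' @param ltr_divergence number of substitutions applied to the 3' LTR
#'   (0 = identical LTRs); substitutions are spaced evenly across the LTR.
#' @param tsd_len target-site duplication length (default 5).
#' @param disruptions character vector of decoy mutations, each one of
#'   `"premature_stop:<gene>"`, `"frameshift:<gene>"`, `"delete:<gene>"`,
#'   `"retrotransposon_rt"`.
#' @return a list of class `implant_spec`.
#' @export
implant_spec <- function(element_id, source, site, ltr_divergence = 0L,
                         tsd_len = 5L, disruptions = character()) {
  structure(list(element_id = element_id, source = source,
                 site = as.integer(site),
                 ltr_divergence = as.integer(ltr_divergence),
                 tsd_len = as.integer(tsd_len),
                 disruptions = disruptions),
            class = "implant_spec")
}

# build the (possibly disrupted) element sequence for a spec; returns the
# sequence plus its LTR length
.build_element <- function(panel, spec) {
  el <- panel$genomes[[spec$source]]
  lay <- attr(panel, "layout")[[spec$source]]
  ltr_len <- lay$ltr_len
  # apply disruptions right-to-left so earlier coordinates stay valid
  dis <- spec$disruptions
  ord <- order(-vapply(dis, function(d) {
    if (d == "retrotransposon_rt") lay$genes$pol[["start"]]
    else lay$genes[[sub("^[a-z_]+:", "", d)]][["start"]]
  }, numeric(1)))
  for (d in dis[ord]) {
    if (d == "retrotransposon_rt") {
      # swap the RT segment of pol (aa 100-400) for a decoy RT of equal length
      gs <- lay$genes$pol[["start"]]
      nt_from <- gs + 3L * 99L
      nt_to <- gs + 3L * 400L - 1L
      decoy_nt <- .encode_peptide(panel$decoy_rts[[1L]])
      stopifnot(nchar(decoy_nt) == nt_to - nt_from + 1L)
      el <- paste0(substr(el, 1L, nt_from - 1L), decoy_nt,
                   substr(el, nt_to + 1L, nchar(el)))
    } else {
      gene <- sub("^[a-z_]+:", "", d)
      kind <- sub(":.*$", "", d)
      span <- lay$genes[[gene]]
      aa_len <- (span[["end"]] - span[["start"]] + 1L) %/% 3L - 1L
      if (kind == "premature_stop") {
        # placed at 70% of the gene: late enough to leave the RT homology
        # segment intact, early enough to truncate well below the cutoff
        k <- floor(0.7 * aa_len)  # codon index replaced by TAA
        p <- span[["start"]] + 3L * k
        el <- paste0(substr(el, 1L, p - 1L), "TAA",
                     substr(el, p + 3L, nchar(el)))
      } else if (kind == "frameshift") {
        p <- span[["start"]] + 3L * floor(0.3 * aa_len)
        el <- paste0(substr(el, 1L, p), "A", substr(el, p + 1L, nchar(el)))
      } else if (kind == "delete") {
        el <- paste0(substr(el, 1L, span[["start"]] - 1L), .SPACER,
                     substr(el, span[["end"]] + 1L, nchar(el)))
      } else {
        stop("unknown disruption: ", d)
      }
    }
  }
  if (spec$ltr_divergence > 0L) {
    # evenly spaced substitutions across the 3' LTR
    L <- ltr_len
    k <- spec$ltr_divergence
    pos <- round(seq_len(k) * L / (k + 1L))
    el_len <- nchar(el)
    el <- .mutate_dna(el, el_len - L + pos)
  }
  list(seq = el, ltr_len = ltr_len)
}

#' Implant proviruses into a background sequence
#'
#' Each element (a panel genome, optionally carrying decoy disruptions and
#' LTR divergence) is inserted at its background site with the target-site
#' duplication copied to both flanks. The element bases adjacent to each
#' junction are forced to differ from the corresponding TSD base, so that
#' maximal exact extension of an identical LTR pair recovers the true spans
#' exactly. The truth table records realized coordinates on the final
#' genome.
#'
#' @param background background DNA string (see [make_background()]).
#' @param specs a single [implant_spec()] or a list of them (sites must not
#'   overlap).
#' @param panel the `ervi_panel` supplying elements.
#' @param seed integer seed (codon and mutation choices).
#' @return list with `genome` (the post-insertion sequence), `background`,
#'   and `truth`: a data.frame with `element_id`, `source`, `start`, `end`,
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`, `ltr_len`,
#'   `tsd_seq`, `ltr_divergence`, `disruptions`.
#' @export
implant_provirus <- function(background, specs, panel, seed = 1L) {
  if (inherits(specs, "implant_spec")) specs <- list(specs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sites <- vapply(specs, `[[`, integer(1), "site")
  if (anyDuplicated(sites)) stop("overlapping implants: duplicate sites")
  ord <- order(sites)
  specs <- specs[ord]
  genome <- background
  offset <- 0L
  rows <- list()
  for (spec in specs) {
    built <- .build_element(panel, spec)
    el <- built$seq
    ltr_len <- built$ltr_len
    site <- spec$site + offset
    tl <- spec$tsd_len
    if (site < 2L || site + tl - 1L > nchar(genome)) {
      stop("implant site out of range for ", spec$element_id)
    }
    tsd <- substr(genome, site, site + tl - 1L)
    # junction guarantee: base before the 3' LTR must differ from the last
    # TSD base; base after the 5' LTR must differ from the first TSD base
    el_len <- nchar(el)
    fix <- function(s, pos, avoid) {
      if (substr(s, pos, pos) == avoid) {
        sv <- strsplit(s, "", fixed = TRUE)[[1L]]
        sv[pos] <- setdiff(.BASES, avoid)[1L]
        s <- paste(sv, collapse = "")
      }
      s
    }
    el <- fix(el, el_len - ltr_len, substr(tsd, tl, tl))
    el <- fix(el, ltr_len + 1L, substr(tsd, 1L, 1L))
    genome <- paste0(substr(genome, 1L, site + tl - 1L), el,
                     substr(genome, site, nchar(genome)))
    start <- site + tl
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = spec$element_id, source = spec$source,
      start = start, end = start + el_len - 1L,
      ltr5_start = start, ltr5_end = start + ltr_len - 1L,
      ltr3_start = start + el_len - ltr_len, ltr3_end = start + el_len - 1L,
      ltr_len = ltr_len, tsd_seq = tsd,
      ltr_divergence = spec$ltr_divergence,
      disruptions = paste(spec$disruptions, collapse = ","),
      stringsAsFactors = FALSE
    )
    offset <- offset + tl + el_len
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(genome = genome, background = background, truth = truth)
}

#' Simulate a diploid population segregating one insertion
#'
#' Genotypes are drawn under Hardy-Weinberg proportions at the given
#' insertion allele frequency; each individual carries two haplotypes, the
#' genome with or without the implant.
#'
#' @param genome_with,genome_without the two locus haplotype sequences
#'   (identical except for the implant).
#' @param allele_freq insertion allele frequency in \[0, 1\].
#' @param n_individuals population size (>= 1).
#' @param seed integer seed.
#' @return list with `truth` (data.frame `individual`, `genotype` in
#'   `ii`/`i-`/`--`) and `haplotypes` (list of two-sequence character
#'   vectors per individual).
#' @export
simulate_population <- function(genome_with, genome_without, allele_freq,
                                n_individuals, seed = 1L) {
  stopifnot(allele_freq >= 0, allele_freq <= 1)
  if (n_individuals < 1L) stop("n_individuals must be at least 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  alleles <- matrix(stats::runif(2L * n_individuals) < allele_freq,
                    nrow = n_individuals)
  genotype <- ifelse(rowSums(alleles) == 2L, "ii",
                     ifelse(rowSums(alleles) == 1L, "i-", "--"))
  haplotypes <- lapply(seq_len(n_individuals), function(i) {
    ifelse(alleles[i, ], genome_with, genome_without)
  })
  names(haplotypes) <- sprintf("ind%03d", seq_len(n_individuals))
  list(truth = data.frame(individual = names(haplotypes),
                          genotype = genotype, stringsAsFactors = FALSE),
       haplotypes = haplotypes)
}

#' Simulate uniform-coverage sequencing reads from haplotypes
#'
#' Each haplotype is sampled at `coverage` fold with uniform start
#' positions and random orientation; substitution errors are applied per
#' base at `error_rate`. Read names encode haplotype, start and strand for
#' debugging. The read count per haplotype is
#' `ceiling(coverage * length / read_len)`.
#'
#' @param haplotypes character vector of haplotype sequences (named).
#' @param read_len read length (>= 30).
#' @param coverage per-haplotype fold coverage (> 0).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(haplotypes, read_len = 150L, coverage = 10,
                           error_rate = 0, seed = 1L) {
  stopifnot(read_len >= 30L, coverage > 0, error_rate >= 0, error_rate < 1)
  if (any(nchar(haplotypes) < read_len)) {
    stop("read_len exceeds a haplotype length")
  }
  if (is.null(names(haplotypes))) {
    names(haplotypes) <- paste0("hap", seq_along(haplotypes))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- list()
  for (h in names(haplotypes)) {
    s <- haplotypes[[h]]
    L <- nchar(s)
    n <- ceiling(coverage * L / read_len)
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
    reads <- substring(s, starts, starts + read_len - 1L)
    if (error_rate > 0) {
      nerr <- stats::rbinom(n, read_len, error_rate)
      for (i in which(nerr > 0L)) {
        reads[i] <- .mutate_dna(reads[i],
                                sample.int(read_len, nerr[i]))
      }
    }
    flip <- stats::runif(n) < 0.5
    reads[flip] <- .revcomp(reads[flip])
    names(reads) <- sprintf("%s_%d_%s_%d", h, starts,
                            ifelse(flip, "r", "f"), seq_len(n))
    out[[h]] <- reads
  }
  unlist(unname(out))
}

#' Write reads to a FASTQ file
#'
#' Constant quality (Q40, `"I"`); a debugging convenience, not an error
#' model.
#'
#' @param reads named character vector of reads.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), path)
  invisible(path)
}

#' Build a complete scan/annotate test world
#'
#' Assembles a repeat-free background and implants one intact element plus
#' (optionally) the standard decoy set: divergent 1-mismatch LTRs, a
#' premature stop in pol, a 1-bp frameshift in pol, a retrotransposon RT
#' swap, and a deleted env. The truth table carries the expected filter
#' outcome per element (`pass`, `not_detected`, or the expected failure
#' reason code).
#'
#' The divergent-LTR decoy uses the panel genome with the shortest LTR
#' (160 bp) and places its single substitution at the LTR midpoint: exact
#' sub-repeats on either side (~80 bp) then fall below the scanner's
#' 100 bp minimum LTR length, which is what makes a 1-mismatch pair
#' undetectable to an exact-repeat scanner.
#'
#' @param seed integer seed.
#' @param background_len background length (default 60000).
#' @param decoys include the decoy set (default TRUE).
#' @return list with `panel`, `background`, `genome`, `truth` (the implant
#'   truth table plus an `expected` column).
#' @export
make_world <- function(seed = 1L, background_len = 60000L, decoys = TRUE) {
  panel <- make_reference_panel(seed)
  bg <- make_background(background_len, seed + 1000L)
  specs <- list(implant_spec("intact", "panelvirus02", site = 4000L))
  expected <- c(intact = "pass")
  if (decoys) {
    specs <- c(specs, list(
      implant_spec("decoy_ltr", "panelvirus01", site = 12000L,
                   ltr_divergence = 1L),
      implant_spec("decoy_stop", "panelvirus03", site = 20000L,
                   disruptions = "premature_stop:pol"),
      implant_spec("decoy_frameshift", "panelvirus04", site = 28000L,
                   disruptions = "frameshift:pol"),
      implant_spec("decoy_rt", "panelvirus05", site = 36000L,
                   disruptions = "retrotransposon_rt"),
      implant_spec("decoy_noenv", "panelvirus06", site = 44000L,
                   disruptions = "delete:env")
    ))
    expected <- c(expected,
                  decoy_ltr = "not_detected",
                  decoy_stop = "premature_stop:pol",
                  decoy_frameshift = "short_orf:pol",
                  decoy_rt = "not_retroviral",
                  decoy_noenv = "missing_gene:env")
  }
  world <- implant_provirus(bg, specs, panel, seed = seed + 2000L)
  world$truth$expected <- unname(expected[world$truth$element_id])
  world$panel <- panel
  world
}

#' Build a population genotyping test world for one locus
#'
#' A small repeat-free locus region with one intact implant, a diploid
#' population at the requested allele frequency, and error-configurable
#' reads per individual covering both haplotypes.
#'
#' @param seed integer seed.
#' @param allele_freq insertion allele frequency.
#' @param n_individuals population size.
#' @param region_len length of the locus region (default 3000).
#' @param coverage per-haplotype fold coverage.
#' @param read_len read length.
#' @param error_rate per-base substitution error rate.
#' @return list with `panel`, `genome_with`, `genome_without`, `truth`
#'   (implant truth), `population` (genotype truth), `sample_reads` (named
#'   list of read vectors per individual), and `candidate` (the true locus
#'   as a one-row candidate table usable by [build_junction_queries()]).
#' @export
make_population_world <- function(seed = 1L, allele_freq = 0.5,
                                  n_individuals = 6L, region_len = 3000L,
                                  coverage = 10, read_len = 150L,
                                  error_rate = 0) {
  panel <- make_reference_panel(seed)
  bg <- make_background(region_len, seed + 3000L)
  world <- implant_provirus(
    bg, implant_spec("locus1", "panelvirus02", site = region_len %/% 2L),
    panel, seed = seed + 4000L)
  pop <- simulate_population(world$genome, world$background, allele_freq,
                             n_individuals, seed = seed + 5000L)
  sample_reads <- lapply(seq_len(n_individuals), function(i) {
    simulate_reads(pop$haplotypes[[i]], read_len = read_len,
                   coverage = coverage, error_rate = error_rate,
                   seed = seed + 6000L + i)
  })
  names(sample_reads) <- names(pop$haplotypes)
  tr <- world$truth
  candidate <- data.frame(
    contig = "locus_region", start = tr$start, end = tr$end,
    ltr5_start = tr$ltr5_start, ltr5_end = tr$ltr5_end,
    ltr3_start = tr$ltr3_start, ltr3_end = tr$ltr3_end,
    ltr_len = tr$ltr_len, ltr_identity = 100,
    tsd_seq = tr$tsd_seq, strand = "+", stringsAsFactors = FALSE
  )
  list(panel = panel, genome_with = world$genome,
       genome_without = world$background, truth = tr,
       population = pop$truth, sample_reads = sample_reads,
       candidate = candidate)
}
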