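# Retroviral annotation and intactness filtering of identical-LTR candidates:
# six-frame translation, RT homology search, retrovirus-vs-retrotransposon
# classification, ORF annotation, the 80%-of-shortest ORF length rule and
# RT-RH-IN / transmembrane domain-architecture checks.

# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Default ordered motif profiles for domain-architecture checks
#'
#' A small editable table of ordered amino-acid motif patterns per domain
#' (`X` matches any residue). The TM row is empty: transmembrane presence is
#' decided by the hydrophobic-stretch rule, not a motif. The same table ships
#' as a TSV under `inst/extdata/motif_profiles.tsv`, and the synthetic
#' reference panel embeds exactly these motifs.
#'
#' @return data.frame with columns `domain`, `idx`, `pattern`.
#' @export
default_motif_profiles <- function() {
  data.frame(
    domain = c("RT", "RT", "RH", "IN", "TM"),
    idx = c(1L, 2L, 1L, 1L, 1L),
    pattern = c("KLLPQGMKG", "VQYMDDILL", "IHTDGSSFV", "HSDNGPAFV", ""),
    stringsAsFactors = FALSE
  )
}

#' Read motif profiles from a TSV file
#'
#' @param path TSV with columns `domain`, `idx`, `pattern`.
#' @return data.frame as in [default_motif_profiles()].
#' @export
read_motif_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"),
                          na.strings = character())
  stopifnot(all(c("domain", "idx", "pattern") %in% names(df)))
  df
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames 0/1/2 on the forward strand and on the reverse complement, using
#' the standard genetic code. Stop codons are rendered as `*` (never
#' dropped); codons containing N translate to `X`.
#'
#' @param seq DNA string over A/C/G/T/N, length at least 3.
#' @return data.frame with columns `strand` (`+`/`-`), `frame` (0/1/2) and
#'   `peptide`.
#' @export
six_frame_translate <- function(seq) {
  .validate_dna(seq, "seq")
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  pep <- function(s, f) {
    n <- length(s) - f
    n <- n - (n %% 3L)
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = f + 1L, width = n),
      if.fuzzy.codon = "X"
    ))
  }
  data.frame(
    strand = rep(c("+", "-"), each = 3L),
    frame = rep(0:2, 2L),
    peptide = c(pep(fwd, 0L), pep(fwd, 1L), pep(fwd, 2L),
                pep(rev, 0L), pep(rev, 1L), pep(rev, 2L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a reference panel object
#'
#' @param rt_queries named character vector of retroviral RT protein queries.
#' @param decoy_rts named character vector of retrotransposon RT proteins
#'   (may be empty, with degraded classification).
#' @param orf_min_len named integer vector with entries `gag`, `pro`, `pol`,
#'   `env`: minimum intact amino-acid length per core gene (80\% of the
#'   shortest panel ORF).
#' @param gene_refs list with elements `gag`, `pro`, `pol`, `env`, each a
#'   named character vector of reference protein sequences used for ORF
#'   labeling.
#' @param motif_profiles motif table, see [default_motif_profiles()].
#' @param genomes optional named character vector of panel provirus genomes.
#' @return object of class `ervi_panel`.
#' @export
reference_panel <- function(rt_queries, decoy_rts = character(),
                            orf_min_len, gene_refs,
                            motif_profiles = default_motif_profiles(),
                            genomes = NULL) {
  stopifnot(length(rt_queries) > 0,
            all(c("gag", "pro", "pol", "env") %in% names(orf_min_len)),
            all(c("gag", "pro", "pol", "env") %in% names(gene_refs)))
  structure(list(
    rt_queries = rt_queries, decoy_rts = decoy_rts,
    orf_min_len = orf_min_len, gene_refs = gene_refs,
    motif_profiles = motif_profiles, genomes = genomes
  ), class = "ervi_panel")
}

#' @export
print.ervi_panel <- function(x, ...) {
  cat("Reference panel:", length(x$rt_queries), "retroviral RT queries,",
      length(x$decoy_rts), "decoy RTs\n")
  cat("ORF minimum lengths (aa):",
      paste(names(x$orf_min_len), x$orf_min_len, sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$genomes)) cat(length(x$genomes), "panel genomes\n")
  invisible(x)
}

#' Search a candidate interior for retroviral reverse-transcriptase homology
#'
#' Each panel RT query is aligned locally (BLOSUM62, affine gaps 11/1)
#' against all six translated frames of the candidate interior; e-values
#' follow the Karlin-Altschul formulation over the combined six-frame search
#' space. A hit is reported only if its e-value is at most `e_max`, its
#' aligned length exceeds 100 aa and the aligned region contains no stop
#' codon.
#'
#' @param candidate_seq interior sequence of a candidate (between the LTRs).
#' @param panel an `ervi_panel`.
#' @param e_max e-value cutoff (default 1e-5).
#' @return list with `query_id`, `aa_len`, `score`, `e_value`, `identity`,
#'   `peptide` (aligned candidate peptide, gaps removed), `strand`, `frame`;
#'   or `NULL` when no qualifying hit exists.
#' @export
rt_homology_search <- function(candidate_seq, panel, e_max = 1e-5) {
  stopifnot(inherits(panel, "ervi_panel"))
  if (length(panel$rt_queries) == 0L) stop("empty RT query panel")
  frames <- six_frame_translate(candidate_seq)
  n_space <- sum(nchar(frames$peptide))
  best <- NULL
  for (fi in seq_len(nrow(frames))) {
    pept <- frames$peptide[fi]
    if (nchar(pept) < 30L) next
    seeded <- vapply(panel$rt_queries, .shared_kmer_count, integer(1),
                     b = pept) >= 3L
    if (!any(seeded)) next
    al <- .align_protein_batch(panel$rt_queries[seeded], pept)
    ev <- .ka_evalue(al$score, nchar(panel$rt_queries[seeded]), n_space,
                     .KA_PROT$lambda, .KA_PROT$K)
    qnames <- names(panel$rt_queries)[seeded]
    ok <- ev <= e_max & al$columns > 100L &
      !grepl("*", al$subject_block, fixed = TRUE)
    if (!any(ok)) next
    qi <- which(ok)[which.max(al$score[ok])]
    if (is.null(best) || al$score[qi] > best$score) {
      best <- list(
        query_id = qnames[qi],
        aa_len = al$columns[qi],
        score = al$score[qi],
        e_value = ev[qi],
        identity = 100 * al$matches[qi] / al$columns[qi],
        peptide = gsub("-", "", al$subject_block[qi], fixed = TRUE),
        strand = frames$strand[fi],
        frame = frames$frame[fi]
      )
    }
  }
  best
}

#' Classify an RT peptide as retroviral or retrotransposon-derived
#'
#' Nearest-reference classification: the peptide is aligned against the
#' union of retroviral RT queries and retrotransposon decoys and labeled by
#' the class of the best-scoring reference. When the top scores of the two
#' classes differ by less than `margin` of the higher one the call is
#' `unclassified`.
#'
#' @param hit_peptide protein string (expected > 100 aa).
#' @param panel an `ervi_panel`.
#' @param margin ambiguity margin as a fraction of the top score.
#' @return one of `"retrovirus"`, `"retrotransposon"`, `"unclassified"`.
#' @export
classify_rt <- function(hit_peptide, panel, margin = 0.1) {
  stopifnot(inherits(panel, "ervi_panel"), nchar(hit_peptide) > 0)
  if (length(panel$decoy_rts) == 0L) {
    warning("no decoy RTs in panel: classification degenerates to retrovirus")
    return("retrovirus")
  }
  sc <- function(refs) {
    if (length(refs) == 0L) return(-Inf)
    max(.align_protein_batch(refs, hit_peptide)$score)
  }
  s_rv <- sc(panel$rt_queries)
  s_tn <- sc(panel$decoy_rts)
  top <- max(s_rv, s_tn)
  if (abs(s_rv - s_tn) < margin * top) return("unclassified")
  if (s_rv > s_tn) "retrovirus" else "retrotransposon"
}

#' Annotate open reading frames on an element
#'
#' Finds all ORFs of at least 25 codons (first ATG after a stop, to the next
#' stop) in the six frames of the element's sense strand, and labels them
#' `gag`/`pro`/`pol`/`env` by best protein-level local alignment against the
#' panel gene references (others carry `gene = "other"`). When two labeled
#' gene ORFs overlap, the lower-scoring one is demoted to `other`, so
#' reported gene assignments never overlap.
#'
#' @param candidate_seq element sequence (sense strand).
#' @param panel an `ervi_panel`.
#' @param label_e_max e-value cutoff for accepting a gene label.
#' @param label_min_aa ORFs shorter than this are reported unlabeled
#'   (`other`) without alignment; far below any core-gene minimum, this only
#'   skips spurious micro-ORFs.
#' @return data.frame with columns `gene`, `start`, `end` (1-based element
#'   coordinates, ATG through stop codon), `strand`, `frame`, `aa_len`,
#'   `peptide`, `label_score`, `has_premature_stop` (filled by
#'   [check_intactness()]), ordered 5' to 3'.
#' @export
annotate_orfs <- function(candidate_seq, panel, label_e_max = 1e-5,
                          label_min_aa = 60L) {
  stopifnot(inherits(panel, "ervi_panel"))
  L <- nchar(candidate_seq)
  frames <- six_frame_translate(candidate_seq)
  orfs <- list()
  for (fi in seq_len(nrow(frames))) {
    pept <- frames$peptide[fi]
    if (nchar(pept) == 0L) next
    f <- frames$frame[fi]; str <- frames$strand[fi]
    # stop-delimited segments; ORF = first M of a segment through its stop
    segs <- strsplit(pept, "*", fixed = TRUE)[[1L]]
    offset <- 0L
    n_seg <- length(segs)
    ended_by_stop <- c(rep(TRUE, n_seg - 1L),
                       substr(pept, nchar(pept), nchar(pept)) == "*")
    for (si in seq_along(segs)) {
      seg <- segs[si]
      m <- regexpr("M", seg, fixed = TRUE)
      if (m > 0 && ended_by_stop[si]) {
        a <- offset + as.integer(m)      # aa position of ATG in frame
        b <- offset + nchar(seg)         # last aa before stop
        aa_len <- b - a + 1L
        if (aa_len >= 25L) {
          nt_start_f <- f + 3L * (a - 1L) + 1L
          nt_end_f <- f + 3L * (b + 1L)   # include stop codon
          if (str == "+") {
            st <- nt_start_f; en <- nt_end_f
          } else {
            st <- L - nt_end_f + 1L; en <- L - nt_start_f + 1L
          }
          orfs[[length(orfs) + 1L]] <- data.frame(
            gene = "other", start = st, end = en, strand = str, frame = f,
            aa_len = aa_len, peptide = substr(seg, as.integer(m), nchar(seg)),
            label_score = NA_real_, has_premature_stop = FALSE,
            stringsAsFactors = FALSE
          )
        }
      }
      offset <- offset + nchar(seg) + 1L
    }
  }
  if (length(orfs) == 0L) return(.empty_orfs())
  df <- do.call(rbind, orfs)

  # label by best alignment against the panel gene references; one batched
  # alignment call per reference (all ORF peptides at once)
  ref_space <- sum(vapply(panel$gene_refs, function(g) sum(nchar(g)),
                          numeric(1)))
  best_gene <- rep("other", nrow(df))
  best_score <- rep(-Inf, nrow(df))
  big <- which(df$aa_len >= label_min_aa)
  if (length(big)) {
    for (gene in c("gag", "pro", "pol", "env")) {
      for (ref in panel$gene_refs[[gene]]) {
        seeded <- big[vapply(df$peptide[big], .shared_kmer_count,
                             integer(1), b = ref) >= 3L]
        if (!length(seeded)) next
        al <- .align_protein_batch(df$peptide[seeded], ref)
        ev <- .ka_evalue(al$score, nchar(ref), ref_space,
                         .KA_PROT$lambda, .KA_PROT$K)
        better <- al$score > best_score[seeded]
        bi <- seeded[better]
        best_score[bi] <- al$score[better]
        best_gene[bi] <- ifelse(ev[better] <= label_e_max, gene, "other")
      }
    }
  }
  df$gene <- best_gene
  df$label_score <- best_score

  # demote overlapping labeled ORFs: keep best score per gene, then resolve
  # cross-gene overlap by score
  for (gene in c("gag", "pro", "pol", "env")) {
    gi <- which(df$gene == gene)
    if (length(gi) > 1L) {
      keep <- gi[which.max(df$label_score[gi])]
      df$gene[setdiff(gi, keep)] <- "other"
    }
  }
  lab <- which(df$gene != "other")
  if (length(lab) > 1L) {
    lab <- lab[order(-df$label_score[lab])]
    kept <- integer(0)
    for (i in lab) {
      if (any(df$start[i] <= df$end[kept] & df$end[i] >= df$start[kept])) {
        df$gene[i] <- "other"
      } else {
        kept <- c(kept, i)
      }
    }
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_orfs <- function() {
  data.frame(gene = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), aa_len = integer(),
             peptide = character(), label_score = numeric(),
             has_premature_stop = logical(), stringsAsFactors = FALSE)
}

#' Check RT-RH-IN and transmembrane domain architecture
#'
#' RT, RH and IN presence is decided by ordered motif-profile matches in the
#' Pol peptide (`X` in a pattern matches any residue); the architecture is
#' valid only when all matched positions increase strictly in the order
#' RT < RH < IN (the sequential search makes an out-of-order domain count as
#' absent). TM presence in Env uses a hydrophobic-stretch rule: any window of
#' `tm_window` residues with mean Kyte-Doolittle hydropathy at least
#' `tm_hydropathy`.
#'
#' @param pol_peptide,env_peptide non-empty protein strings.
#' @param panel an `ervi_panel` (supplies motif profiles).
#' @param tm_window,tm_hydropathy TM rule parameters (defaults 19 and 1.6).
#' @return list with `flags` (named logical RT/RH/IN/TM), `positions`
#'   (named list of matched motif positions) and `pol_order_ok`.
#' @export
check_domain_architecture <- function(pol_peptide, env_peptide, panel,
                                      tm_window = 19L, tm_hydropathy = 1.6) {
  stopifnot(nchar(pol_peptide) > 0, nchar(env_peptide) > 0)
  prof <- panel$motif_profiles
  flags <- c(RT = FALSE, RH = FALSE, IN = FALSE, TM = FALSE)
  positions <- list()

  # sequential search: each successive motif must start after the previous
  # match, enforcing RT < RH < IN
  cursor <- 0L
  order_ok <- TRUE
  for (dom in c("RT", "RH", "IN")) {
    pats <- prof$pattern[prof$domain == dom & prof$pattern != ""]
    pats <- pats[order(prof$idx[prof$domain == dom & prof$pattern != ""])]
    if (length(pats) == 0L) next
    dom_pos <- integer(0)
    ok <- TRUE
    for (p in pats) {
      rx <- gsub("X", ".", p, fixed = TRUE)
      m <- regexpr(rx, substring(pol_peptide, cursor + 1L))
      if (m < 0) { ok <- FALSE; break }
      pos <- cursor + as.integer(m)
      dom_pos <- c(dom_pos, pos)
      cursor <- pos
    }
    # independent (order-free) presence, for reporting
    present_anywhere <- all(vapply(pats, function(p) {
      regexpr(gsub("X", ".", p, fixed = TRUE), pol_peptide) > 0
    }, logical(1)))
    flags[dom] <- ok
    if (!ok && present_anywhere) order_ok <- FALSE
    positions[[dom]] <- if (ok) dom_pos else integer(0)
  }

  # TM: hydrophobic window in Env
  aa <- strsplit(env_peptide, "", fixed = TRUE)[[1L]]
  h <- unname(.KD[aa])
  h[is.na(h)] <- 0
  if (length(h) >= tm_window) {
    cs <- cumsum(c(0, h))
    win <- (cs[(tm_window + 1L):length(cs)] -
              cs[1:(length(cs) - tm_window)]) / tm_window
    if (any(win >= tm_hydropathy)) {
      flags["TM"] <- TRUE
      positions$TM <- which.max(win >= tm_hydropathy)
    }
  }
  list(flags = flags, positions = positions, pol_order_ok = order_ok)
}

#' Annotate a scan candidate into a full element record
#'
#' Runs the RT homology search on the candidate interior, classifies the hit
#' (retrovirus vs retrotransposon), orients the element by the RT reading
#' frame, annotates ORFs and domain architecture, and leaves the verdict to
#' [check_intactness()].
#'
#' @param genome as in [find_identical_ltr_pairs()].
#' @param candidate one-row candidate data.frame.
#' @param panel an `ervi_panel`.
#' @param e_max e-value cutoff for the RT search.
#' @return object of class `ervi_record`.
#' @export
annotate_element <- function(genome, candidate, panel, e_max = 1e-5) {
  el <- element_seq(genome, candidate)
  interior <- substr(el, candidate$ltr_len + 1L, nchar(el) - candidate$ltr_len)
  rt_hit <- rt_homology_search(interior, panel, e_max)
  classification <- "unclassified"
  strand <- "+"
  if (!is.null(rt_hit)) {
    classification <- classify_rt(rt_hit$peptide, panel)
    strand <- rt_hit$strand
  }
  sense <- if (strand == "-") .revcomp(el) else el
  orfs <- annotate_orfs(sense, panel)
  pol <- orfs$peptide[orfs$gene == "pol"]
  env <- orfs$peptide[orfs$gene == "env"]
  # a missing peptide leaves its own domains absent without hiding the other
  domains <- check_domain_architecture(
    if (length(pol) == 1L) pol else "G",
    if (length(env) == 1L) env else "G",
    panel)
  rec <- structure(list(
    candidate = candidate, seq = el, sense_seq = sense, strand = strand,
    rt_hit = rt_hit, classification = classification,
    orfs = orfs, domain_flags = domains$flags,
    pol_order_ok = domains$pol_order_ok,
    verdict = NA_character_, fail_reasons = character()
  ), class = "ervi_record")
  check_intactness(rec, panel)
}

#' Apply the replication-intactness filter cascade to an element record
#'
#' The verdict is `pass` only when the element is classified retroviral, all
#' four core genes (`gag`, `pro`, `pol`, `env`) are present in that
#' positional order at no less than the panel's per-gene minimum length
#' (80\% of the shortest panel ORF) without premature stop codons, the Pol
#' peptide carries RT, RH and IN motifs in that order, and Env carries a
#' transmembrane stretch. Each violated rule appends a machine-readable
#' reason code: `missing_gene:X`, `short_orf:X`, `premature_stop:X`,
#' `order_violation`, `domain_missing:Y`, `not_retroviral`.
#'
#' A short gene ORF is diagnosed as a premature stop (rather than mere
#' truncation) when in-frame read-through translation past its stop still
#' aligns to the gene reference over at least the minimum intact length,
#' i.e. the gene body is present but interrupted.
#'
#' @param record an `ervi_record` from [annotate_element()].
#' @param panel an `ervi_panel`.
#' @return the record with `verdict` and `fail_reasons` filled.
#' @export
check_intactness <- function(record, panel) {
  stopifnot(inherits(record, "ervi_record"), inherits(panel, "ervi_panel"))
  reasons <- character()
  if (record$classification != "retrovirus") {
    reasons <- c(reasons, "not_retroviral")
  }
  orfs <- record$orfs
  gene_start <- rep(NA_integer_, 4L)
  names(gene_start) <- c("gag", "pro", "pol", "env")
  for (gene in names(gene_start)) {
    gi <- which(orfs$gene == gene)
    if (length(gi) == 0L) {
      reasons <- c(reasons, paste0("missing_gene:", gene))
      next
    }
    gene_start[gene] <- orfs$start[gi]
    if (orfs$aa_len[gi] < panel$orf_min_len[[gene]]) {
      if (.is_premature_stop(record$sense_seq, orfs[gi, ], gene, panel)) {
        record$orfs$has_premature_stop[gi] <- TRUE
        reasons <- c(reasons, paste0("premature_stop:", gene))
      } else {
        reasons <- c(reasons, paste0("short_orf:", gene))
      }
    }
  }
  if (!anyNA(gene_start) && is.unsorted(gene_start)) {
    reasons <- c(reasons, "order_violation")
  }
  for (dom in c("RT", "RH", "IN", "TM")) {
    if (!record$domain_flags[[dom]]) {
      reasons <- c(reasons, paste0("domain_missing:", dom))
    }
  }
  if (!record$pol_order_ok) reasons <- c(reasons, "order_violation")
  record$fail_reasons <- unique(reasons)
  record$verdict <- if (length(record$fail_reasons) == 0L) "pass" else "fail"
  record
}

# read-through diagnosis: translate in the ORF's frame past its stop for up
# to the longest reference length, stops rendered X, and test whether the
# gene body still aligns over at least the intact minimum
.is_premature_stop <- function(sense_seq, orf, gene, panel) {
  refs <- panel$gene_refs[[gene]]
  max_ref <- max(nchar(refs))
  if (orf$strand == "+") {
    st <- orf$start
    en <- min(nchar(sense_seq), st + 3L * (max_ref + 10L) - 1L)
    nt <- substr(sense_seq, st, en)
  } else {
    en <- orf$end
    st <- max(1L, en - 3L * (max_ref + 10L) + 1L)
    nt <- .revcomp(substr(sense_seq, st, en))
  }
  n <- nchar(nt) - (nchar(nt) %% 3L)
  if (n < 3L) return(FALSE)
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)), if.fuzzy.codon = "X"))
  has_stop <- grepl("*", substr(pep, 1L, orf$aa_len + 1L), fixed = TRUE)
  pep_x <- gsub("*", "X", pep, fixed = TRUE)
  al <- .align_protein_batch(refs, pep_x)
  # matched residues (not alignment columns): a gap-bridged alignment of a
  # genuinely truncated gene must not masquerade as an interrupted one
  has_stop && max(al$matches) >= panel$orf_min_len[[gene]]
}

#' @export
print.ervi_record <- function(x, ...) {
  cat("Element record:", x$candidate$contig, x$candidate$start, "-",
      x$candidate$end, "(", x$strand, ")\n")
  cat("  classification:", x$classification,
      if (!is.null(x$rt_hit)) sprintf("(RT hit %s, %.0f aa, e=%.2g)",
                                      x$rt_hit$query_id, x$rt_hit$aa_len,
                                      x$rt_hit$e_value) else "(no RT hit)",
      "\n")
  lab <- x$orfs[x$orfs$gene != "other", , drop = FALSE]
  cat("  labeled ORFs:", if (nrow(lab)) paste(lab$gene, lab$aa_len, "aa",
                                              collapse = "; ") else "none", "\n")
  cat("  domains:", paste(names(x$domain_flags),
                          ifelse(x$domain_flags, "+", "-"),
                          sep = "", collapse = " "), "\n")
  cat("  verdict:", x$verdict,
      if (length(x$fail_reasons)) paste0("[", paste(x$fail_reasons,
                                                    collapse = ", "), "]")
      else "", "\n")
  invisible(x)
}
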