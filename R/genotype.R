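# Insertional-polymorphism genotyping from junction queries: build the
# initial-state and 5'/3' insertion-state queries for a locus, classify
# population reads as insertion- or empty-locus-supporting, and infer diploid
# genotypes and group-level allele/genotype frequencies.

#' Build the three junction queries for a candidate locus
#'
#' The candidate is bidirectionally extended by `flank_len` bases. The
#' initial-state query joins the 5' and 3' flanks with one copy of the
#' target-site duplication removed (the pre-insertion locus); the 5' and 3'
#' insertion-state queries join each flank with the adjacent end of the
#' element. The junction window is `[flank_len - 10, flank_len + 10]` on
#' every query (positions 190-210 at the default flank of 200).
#'
#' @param genome as in [find_identical_ltr_pairs()].
#' @param candidate one-row candidate data.frame (after [detect_tsd()]; a
#'   missing TSD is treated as length 0).
#' @param flank_len flank length in bases (default 200).
#' @param locus_id identifier for the locus.
#' @return object of class `junction_queries`: a list with `locus_id`,
#'   `initial`, `ins5`, `ins3` (query sequences), `window` (inclusive
#'   1-based junction window), `flank_len`, `tsd_len`.
#' @export
build_junction_queries <- function(genome, candidate, flank_len = 200L,
                                   locus_id = NULL) {
  g <- .as_genome(genome)
  s <- g[[candidate$contig]]
  st <- candidate$start; en <- candidate$end
  if (is.null(locus_id)) locus_id <- sprintf("%s:%d-%d", candidate$contig, st, en)
  if (st - flank_len < 1L || en + flank_len > nchar(s)) {
    stop("locus ", locus_id, ": insufficient flank on contig for flank_len = ",
         flank_len)
  }
  if (en - st + 1L < flank_len) {
    stop("locus ", locus_id, ": element shorter than flank_len")
  }
  tsd_len <- if (is.na(candidate$tsd_seq)) 0L else nchar(candidate$tsd_seq)
  flank5 <- substr(s, st - flank_len, st - 1L)
  flank3 <- substr(s, en + 1L, en + flank_len)
  element <- substr(s, st, en)
  structure(list(
    locus_id = locus_id,
    initial = paste0(flank5, substr(flank3, tsd_len + 1L, flank_len)),
    ins5 = paste0(flank5, substr(element, 1L, flank_len)),
    ins3 = paste0(substr(element, nchar(element) - flank_len + 1L,
                         nchar(element)), flank3),
    window = c(flank_len - 10L, flank_len + 10L),
    flank_len = as.integer(flank_len),
    tsd_len = as.integer(tsd_len)
  ), class = "junction_queries")
}

# k-mer prefilter over the three queries (optimization only: reads with no
# shared k-mer in either orientation cannot reach 99% full-length identity
# on a query)
.query_kmers <- function(queries, k = 20L) {
  unique(unlist(lapply(c(queries$initial, queries$ins5, queries$ins3),
                       function(q) {
    L <- nchar(q)
    if (L < k) character() else substring(q, 1:(L - k + 1L), k:L)
  })))
}

# vectorized: TRUE for reads sharing at least one sampled k-mer (either
# orientation) with the query set
.prefilter_reads <- function(reads, rc, kmers, k = 20L, stride = 10L) {
  L <- nchar(reads)
  starts <- lapply(L, function(l) {
    if (l < k) integer() else unique(c(seq(1L, l - k + 1L, by = stride),
                                       l - k + 1L))
  })
  n_st <- lengths(starts)
  ri <- rep.int(seq_along(reads), n_st)
  st <- unlist(starts)
  hit <- substring(reads[ri], st, st + k - 1L) %in% kmers |
    substring(rc[ri], st, st + k - 1L) %in% kmers
  as.logical(tapply(hit, factor(ri, levels = seq_along(reads)), any))
}

# Core mapper: best local alignment of each read (both orientations) against
# each query; a mapping is reported iff e-value <= e_max and identity >=
# min_identity. Identity = matches / aligned columns (gaps count as
# mismatches); full_length means every read base is aligned.
.map_reads_batch <- function(reads, queries, e_max = 1e-5,
                             min_identity = 99, prefilter = TRUE) {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  keep <- nchar(reads) >= 21L  # junction window width: shorter reads can
                               # never be meaningful
  reads <- reads[keep]
  if (length(reads) == 0L) return(.empty_mappings())
  rc <- .revcomp(reads)
  if (prefilter) {
    pf <- .prefilter_reads(reads, rc, .query_kmers(queries))
    reads <- reads[pf]; rc <- rc[pf]
    if (length(reads) == 0L) return(.empty_mappings())
  }
  qs <- c(initial = queries$initial, ins5 = queries$ins5, ins3 = queries$ins3)
  rl <- nchar(reads)
  out <- list()
  for (qn in names(qs)) {
    q <- qs[[qn]]
    # fast path: a perfect full-length substring match needs no alignment
    pos_f <- vapply(reads, function(r) regexpr(r, q, fixed = TRUE)[[1L]],
                    integer(1))
    pos_r <- vapply(rc, function(r) regexpr(r, q, fixed = TRUE)[[1L]],
                    integer(1))
    exact <- pos_f > 0L | pos_r > 0L
    s_start <- ifelse(pos_f > 0L, pos_f, pos_r)
    s_end <- s_start + rl - 1L
    score <- 2 * rl  # match reward on every base
    identity <- rep(100, length(reads))
    full <- rep(TRUE, length(reads))
    use_rev <- pos_f <= 0L & pos_r > 0L
    # slow path: full local alignment in both orientations
    dp <- which(!exact)
    if (length(dp)) {
      fwd <- .align_dna_local(reads[dp], q)
      rev <- .align_dna_local(rc[dp], q)
      take_rev <- rev$score > fwd$score
      al <- fwd
      al[take_rev, ] <- rev[take_rev, ]
      s_start[dp] <- al$s_start
      s_end[dp] <- al$s_end
      score[dp] <- al$score
      identity[dp] <- 100 * al$matches / al$columns
      full[dp] <- al$p_start == 1L & al$p_end == rl[dp]
      use_rev[dp] <- take_rev
    }
    ev <- .ka_evalue(score, rl, nchar(q), .KA_DNA$lambda, .KA_DNA$K)
    ok <- ev <= e_max & identity >= min_identity
    if (any(ok)) {
      out[[qn]] <- data.frame(
        read_id = names(reads)[ok], query_id = qn,
        q_start = s_start[ok], q_end = s_end[ok],
        identity = identity[ok], e_value = ev[ok],
        full_length = full[ok],
        orientation = ifelse(use_rev[ok], "-", "+"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(.empty_mappings())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Full-length-only mapper used for presence counting. A full-length mapping
# at >= min_identity admits only floor(L (1 - id/100)) substitutions (the
# junction queries contain no repeats, and gapped full-length mappings are
# impossible at 99% identity for reads much shorter than 100 gaps), so
# C-level mismatch matching replaces the dynamic-programming aligner.
.map_reads_full <- function(reads, queries, e_max = 1e-5,
                            min_identity = 99) {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  reads <- reads[nchar(reads) >= 21L]
  if (length(reads) == 0L) return(.empty_mappings())
  rc <- .revcomp(reads)
  pf <- .prefilter_reads(reads, rc, .query_kmers(queries))
  reads <- reads[pf]; rc <- rc[pf]
  if (length(reads) == 0L) return(.empty_mappings())
  qs <- c(initial = queries$initial, ins5 = queries$ins5, ins3 = queries$ins3)
  out <- list()
  for (qn in names(qs)) {
    qdna <- Biostrings::DNAString(qs[[qn]])
    for (i in seq_along(reads)) {
      L <- nchar(reads[[i]])
      mm_max <- floor(L * (1 - min_identity / 100))
      hit <- NULL
      for (orient in c("+", "-")) {
        r <- if (orient == "+") reads[[i]] else rc[[i]]
        m <- Biostrings::matchPattern(r, qdna, max.mismatch = mm_max)
        if (length(m) > 0L) {
          pos <- Biostrings::start(m)[1L]
          mm <- Biostrings::neditStartingAt(Biostrings::DNAString(r), qdna,
                                            starting.at = pos,
                                            with.indels = FALSE)
          score <- 2 * (L - mm) - 3 * mm
          ev <- .ka_evalue(score, L, nchar(qs[[qn]]),
                           .KA_DNA$lambda, .KA_DNA$K)
          if (ev <= e_max) {
            hit <- data.frame(
              read_id = names(reads)[i], query_id = qn,
              q_start = pos, q_end = pos + L - 1L,
              identity = 100 * (L - mm) / L, e_value = ev,
              full_length = TRUE, orientation = orient,
              stringsAsFactors = FALSE
            )
          }
          break
        }
      }
      if (!is.null(hit)) out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0L) return(.empty_mappings())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_mappings <- function() {
  data.frame(read_id = character(), query_id = character(),
             q_start = integer(), q_end = integer(), identity = numeric(),
             e_value = numeric(), full_length = logical(),
             orientation = character(), stringsAsFactors = FALSE)
}

#' Map a single read onto the three junction queries
#'
#' @param read DNA string of length at least 21 (the junction window width).
#' @param queries a [build_junction_queries()] object.
#' @param e_max,min_identity mapping cutoffs (defaults 1e-5 and 99).
#' @return data.frame of qualifying mappings (possibly empty): `read_id`,
#'   `query_id`, `q_start`, `q_end` (1-based query span), `identity`,
#'   `e_value`, `full_length`, `orientation`.
#' @export
map_read <- function(read, queries, e_max = 1e-5, min_identity = 99) {
  stopifnot(inherits(queries, "junction_queries"))
  .map_reads_batch(c(read = read), queries, e_max, min_identity,
                   prefilter = FALSE)
}

#' Is a read mapping meaningful evidence for its query state?
#'
#' A mapping is meaningful only when the read is full-length aligned and its
#' query span fully covers the junction window.
#'
#' @param mapping one or more mapping rows from [map_read()].
#' @param queries the [build_junction_queries()] object they refer to.
#' @return logical vector.
#' @export
is_meaningful <- function(mapping, queries) {
  stopifnot(inherits(queries, "junction_queries"))
  mapping$full_length &
    mapping$q_start <= queries$window[1L] &
    mapping$q_end >= queries$window[2L]
}

#' Count insertion- and empty-locus-supporting reads at a locus
#'
#' Each read is counted at most once: as insertion-supporting when it is
#' meaningful on either insertion-state query, or empty-locus-supporting
#' when meaningful on the initial-state query. A read meaningful on both an
#' insertion-state query and the initial-state query (possible only under
#' pathological query overlap) is discarded with a message.
#'
#' @param reads character vector of read sequences (named by read id).
#' @param queries a [build_junction_queries()] object.
#' @param e_max,min_identity mapping cutoffs.
#' @return named integer vector `c(n_ins, n_empty)`.
#' @export
call_presence <- function(reads, queries, e_max = 1e-5, min_identity = 99) {
  stopifnot(inherits(queries, "junction_queries"))
  if (length(reads) == 0L) return(c(n_ins = 0L, n_empty = 0L))
  maps <- .map_reads_full(reads, queries, e_max, min_identity)
  if (nrow(maps) == 0L) return(c(n_ins = 0L, n_empty = 0L))
  maps <- maps[is_meaningful(maps, queries), , drop = FALSE]
  if (nrow(maps) == 0L) return(c(n_ins = 0L, n_empty = 0L))
  by_read <- split(maps$query_id, maps$read_id)
  n_ins <- 0L; n_empty <- 0L
  for (qids in by_read) {
    ins <- any(qids %in% c("ins5", "ins3"))
    emp <- "initial" %in% qids
    if (ins && emp) {
      message("read meaningful on both insertion and initial queries at ",
              queries$locus_id, ": discarded")
    } else if (ins) {
      n_ins <- n_ins + 1L
    } else if (emp) {
      n_empty <- n_empty + 1L
    }
  }
  c(n_ins = n_ins, n_empty = n_empty)
}

#' Infer a genotype call from meaningful read counts
#'
#' Individuals: `ii` with only insertion evidence, `--` with only
#' empty-locus evidence, `i-` with both, `nocall` with neither. Pools yield
#' a call usable for frequency math only under single-state evidence (every
#' pooled individual inferred homozygous); mixed evidence in a pool is
#' recorded as pool-level heterozygosity evidence (`i-`) and excluded from
#' individual-based frequencies.
#'
#' @param counts `c(n_ins, n_empty)` from [call_presence()].
#' @param sample_id,locus_id identifiers carried into the call.
#' @param sample_kind one of `"individual"`, `"pool_with_size"`,
#'   `"pool_unsized"`, `"unknown"`.
#' @param pool_size number of pooled individuals (required for
#'   `pool_with_size`).
#' @return one-row data.frame: `sample_id`, `locus_id`, `n_ins_reads`,
#'   `n_empty_reads`, `genotype` (`ii`, `i-`, `--`, `nocall`),
#'   `sample_kind`, `pool_size`.
#' @export
genotype_sample <- function(counts, sample_id = "sample", locus_id = "locus",
                            sample_kind = "individual", pool_size = NA) {
  sample_kind <- match.arg(sample_kind,
                           c("individual", "pool_with_size", "pool_unsized",
                             "unknown"))
  if (sample_kind == "pool_with_size" && (is.na(pool_size) || pool_size < 1)) {
    stop("pool_with_size sample lacking pool_size")
  }
  n_ins <- as.integer(counts[[1L]]); n_empty <- as.integer(counts[[2L]])
  genotype <- if (n_ins == 0L && n_empty == 0L) {
    "nocall"
  } else if (n_ins > 0L && n_empty == 0L) {
    "ii"
  } else if (n_ins == 0L && n_empty > 0L) {
    "--"
  } else {
    "i-"
  }
  data.frame(sample_id = sample_id, locus_id = locus_id,
             n_ins_reads = n_ins, n_empty_reads = n_empty,
             genotype = genotype, sample_kind = sample_kind,
             pool_size = if (sample_kind == "pool_with_size")
               as.integer(pool_size) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Per-group allele and genotype frequencies for a locus
#'
#' Counts are taken over called individuals plus homozygous pools of known
#' size (each contributing `pool_size` individuals of the inferred
#' genotype). The insertion allele frequency is
#' `(2 n_ii + n_het) / (2 n_individuals)`. Frequencies are withheld
#' (`reported = FALSE`, NA values) for groups with 4 or fewer contributing
#' individuals; `n_samples_total` additionally counts every called sample of
#' any kind (the total-data tally), including unsized pools and mixed-
#' evidence pools that never enter the frequency math.
#'
#' @param calls data.frame of genotype calls for one locus (rows as from
#'   [genotype_sample()]).
#' @param groups named character vector mapping `sample_id` to group label.
#' @return data.frame with one row per group: `locus_id`, `group_id`,
#'   `n_individuals`, `n_samples_total`, `n_ii`, `n_het`, `n_empty`,
#'   `freq_i`, `freq_empty`, `freq_ii`, `freq_het`, `freq_mm`, `reported`.
#' @export
population_frequencies <- function(calls, groups) {
  stopifnot(is.data.frame(calls), length(unique(calls$locus_id)) <= 1L)
  calls$group <- unname(groups[calls$sample_id])
  out <- lapply(split(calls, calls$group), function(cg) {
    called <- cg[cg$genotype != "nocall", , drop = FALSE]
    n_ii <- 0L; n_het <- 0L; n_mm <- 0L
    for (i in seq_len(nrow(called))) {
      r <- called[i, ]
      if (r$sample_kind == "individual") {
        if (r$genotype == "ii") n_ii <- n_ii + 1L
        else if (r$genotype == "i-") n_het <- n_het + 1L
        else n_mm <- n_mm + 1L
      } else if (r$sample_kind == "pool_with_size" && r$genotype != "i-") {
        # single-state pool: every pooled individual inferred homozygous
        if (r$genotype == "ii") n_ii <- n_ii + r$pool_size
        else n_mm <- n_mm + r$pool_size
      }
    }
    n <- n_ii + n_het + n_mm
    reported <- n > 4L
    freq_i <- if (reported) (2 * n_ii + n_het) / (2 * n) else NA_real_
    data.frame(
      locus_id = if (nrow(cg)) cg$locus_id[1L] else NA_character_,
      group_id = cg$group[1L],
      n_individuals = n, n_samples_total = nrow(called),
      n_ii = n_ii, n_het = n_het, n_empty = n_mm,
      freq_i = freq_i,
      freq_empty = if (reported) 1 - freq_i else NA_real_,
      freq_ii = if (reported) n_ii / n else NA_real_,
      freq_het = if (reported) n_het / n else NA_real_,
      freq_mm = if (reported) n_mm / n else NA_real_,
      reported = reported,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype one locus across a set of samples
#'
#' Convenience driver: builds the junction queries for a candidate and runs
#' [call_presence()] and [genotype_sample()] for every sample.
#'
#' @param genome as in [find_identical_ltr_pairs()].
#' @param candidate one-row candidate data.frame (with TSD detected).
#' @param sample_reads named list: per sample, a character vector of reads.
#' @param sample_info optional data.frame with `sample_id`, `sample_kind`,
#'   `pool_size`; defaults to all individuals.
#' @param flank_len flank length for query construction.
#' @param e_max,min_identity mapping cutoffs.
#' @return list with `queries` and `calls` (data.frame, one row per sample).
#' @export
genotype_locus <- function(genome, candidate, sample_reads,
                           sample_info = NULL, flank_len = 200L,
                           e_max = 1e-5, min_identity = 99) {
  queries <- build_junction_queries(genome, candidate, flank_len)
  ids <- names(sample_reads)
  if (is.null(sample_info)) {
    sample_info <- data.frame(sample_id = ids, sample_kind = "individual",
                              pool_size = NA_integer_,
                              stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, lapply(ids, function(sid) {
    cnt <- call_presence(sample_reads[[sid]], queries, e_max, min_identity)
    info <- sample_info[sample_info$sample_id == sid, , drop = FALSE]
    genotype_sample(cnt, sample_id = sid, locus_id = queries$locus_id,
                    sample_kind = info$sample_kind[1L],
                    pool_size = info$pool_size[1L])
  }))
  list(queries = queries, calls = calls)
}
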