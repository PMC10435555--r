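# Identical-LTR provirus scanning: k-mer seeded, exact bidirectional extension.

#' Scan parameters for identical-LTR provirus detection
#'
#' Bundles the tunable bounds of the identical-LTR scanner. The similarity
#' threshold is fixed at 100\% (only exact repeat pairs are reported);
#' degenerate LTR pairs are out of scope. Defaults follow common LTR-miner
#' conventions: LTRs 100-2000 bp, elements 1-15 kb, 20-mer seeds, target-site
#' duplications of 4-20 bp.
#'
#' @param min_ltr_len,max_ltr_len allowed LTR length range (bases).
#' @param min_element_span,max_element_span allowed full element span
#'   (5' LTR start to 3' LTR end, bases).
#' @param ltr_similarity_pct required LTR identity; only 100 is supported.
#' @param tsd_min,tsd_max target-site duplication search range (bases).
#' @param seed_kmer exact seed length (bases); must not exceed `min_ltr_len`.
#' @return an object of class `scan_params` (a validated list).
#' @export
scan_params <- function(min_ltr_len = 100L, max_ltr_len = 2000L,
                        min_element_span = 1000L, max_element_span = 15000L,
                        ltr_similarity_pct = 100, tsd_min = 4L, tsd_max = 20L,
                        seed_kmer = 20L) {
  p <- list(
    min_ltr_len = as.integer(min_ltr_len),
    max_ltr_len = as.integer(max_ltr_len),
    min_element_span = as.integer(min_element_span),
    max_element_span = as.integer(max_element_span),
    ltr_similarity_pct = as.numeric(ltr_similarity_pct),
    tsd_min = as.integer(tsd_min),
    tsd_max = as.integer(tsd_max),
    seed_kmer = as.integer(seed_kmer)
  )
  stopifnot(
    p$min_ltr_len >= p$seed_kmer,
    p$min_element_span > 2L * p$min_ltr_len,
    p$min_element_span <= p$max_element_span,
    p$min_ltr_len <= p$max_ltr_len,
    p$ltr_similarity_pct > 0, p$ltr_similarity_pct <= 100,
    p$tsd_min <= p$tsd_max, p$tsd_min >= 1L,
    p$seed_kmer >= 8L
  )
  if (p$ltr_similarity_pct != 100) {
    stop("only ltr_similarity_pct = 100 (exact LTR pairs) is supported")
  }
  structure(p, class = "scan_params")
}

# Coerce genome input (character vector / DNAStringSet) to a named uppercase
# character vector.
.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome)) {
    g <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (length(g) && is.null(names(g))) {
    names(g) <- paste0("contig", seq_along(g))
  }
  g
}

#' Find candidate proviruses bounded by identical LTR pairs
#'
#' Detects pairs of exactly identical direct repeats compatible with the
#' LTR-pair geometry of a recently inserted provirus. Seeds are shared exact
#' k-mers; each seed pair is extended base by base in both directions as far
#' as the two copies stay identical (N never matches), so every reported
#' repeat pair is maximal. Pairs are kept when the repeat length and the
#' enclosing element span fall within the configured bounds. Overlapping
#' candidates from nested repeats are resolved by keeping the longest element
#' (ties: leftmost start).
#'
#' Orientation cannot be inferred from two identical direct repeats, so
#' `strand` is reported as `"+"`; it is refined from the reverse-transcriptase
#' reading frame during annotation.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   uppercase contig sequences over A/C/G/T/N.
#' @param params a [scan_params()] object.
#' @return data.frame with one row per candidate: `contig`, `start`, `end`
#'   (element span, 1-based inclusive), `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end`, `ltr_len`, `ltr_identity` (always 100),
#'   `tsd_seq` (NA until [detect_tsd()]), `strand`. Sorted by contig then
#'   start.
#' @export
find_identical_ltr_pairs <- function(genome, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  g <- .as_genome(genome)
  if (length(g) == 0L) return(.empty_candidates())
  out <- lapply(names(g), function(cn) {
    s <- g[[cn]]
    if (nchar(s) < params$min_element_span) {
      message("skipping contig '", cn, "': shorter than min_element_span")
      return(.empty_candidates())
    }
    .scan_contig(cn, s, params)
  })
  res <- do.call(rbind, c(out, list(.empty_candidates())))
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_candidates <- function() {
  data.frame(
    contig = character(), start = integer(), end = integer(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    ltr_len = integer(), ltr_identity = numeric(),
    tsd_seq = character(), strand = character(),
    stringsAsFactors = FALSE
  )
}

.scan_contig <- function(contig, s, params) {
  L <- nchar(s)
  k <- params$seed_kmer
  n_kmers <- L - k + 1L
  kmers <- substring(s, 1:n_kmers, k:L)
  has_n <- grepl("N", kmers, fixed = TRUE)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  idx <- which(dup & !has_n)
  if (length(idx) == 0L) return(.empty_candidates())
  groups <- split(idx, kmers[idx])

  # all ordered position pairs per repeated k-mer, filtered by plausible
  # seed distance for an in-bounds element
  p1 <- integer(0); p2 <- integer(0)
  for (pos in groups) {
    if (length(pos) > 12L) next  # low-complexity seed: ignore
    cmb <- utils::combn(sort(pos), 2L)
    p1 <- c(p1, cmb[1L, ]); p2 <- c(p2, cmb[2L, ])
  }
  if (length(p1) == 0L) return(.empty_candidates())
  d <- p2 - p1
  keep <- d >= (params$min_element_span - params$max_ltr_len) &
    d <= params$max_element_span
  p1 <- p1[keep]; p2 <- p2[keep]; d <- d[keep]
  if (length(p1) == 0L) return(.empty_candidates())

  # one representative seed per diagonal run (seeds inside the same repeat
  # pair share a diagonal and consecutive offsets -> same maximal extension)
  ord <- order(d, p1)
  p1 <- p1[ord]; p2 <- p2[ord]; d <- d[ord]
  new_run <- c(TRUE, diff(d) != 0L | diff(p1) != 1L)
  p1 <- p1[new_run]; p2 <- p2[new_run]

  sv <- strsplit(s, "", fixed = TRUE)[[1L]]
  seen <- new.env(hash = TRUE)
  rows <- list()
  for (i in seq_along(p1)) {
    span <- .extend_pair(sv, p1[i], p2[i], k, L)
    if (is.null(span)) next
    s1 <- span[1L]; e1 <- span[2L]; s2 <- span[3L]; e2 <- span[4L]
    len <- e1 - s1 + 1L
    if (len < params$min_ltr_len || len > params$max_ltr_len) next
    if (e1 >= s2) next  # repeats must not overlap
    el_span <- e2 - s1 + 1L
    if (el_span < params$min_element_span || el_span > params$max_element_span) next
    key <- paste(s1, e1, s2, e2, sep = ":")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, start = s1, end = e2,
      ltr5_start = s1, ltr5_end = e1, ltr3_start = s2, ltr3_end = e2,
      ltr_len = len, ltr_identity = 100,
      tsd_seq = NA_character_, strand = "+",
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(.empty_candidates())
  res <- do.call(rbind, rows)
  .resolve_overlaps(res)
}

# maximal exact bidirectional extension of a seed pair; N stops extension
.extend_pair <- function(sv, p1, p2, k, L) {
  s1 <- p1; s2 <- p2
  while (s1 > 1L && s2 > 1L) {
    a <- sv[s1 - 1L]
    if (a == "N" || a != sv[s2 - 1L]) break
    s1 <- s1 - 1L; s2 <- s2 - 1L
  }
  e1 <- p1 + k - 1L; e2 <- p2 + k - 1L
  while (e2 < L && e1 < s2 - 1L) {
    a <- sv[e1 + 1L]
    if (a == "N" || a != sv[e2 + 1L]) break
    e1 <- e1 + 1L; e2 <- e2 + 1L
  }
  c(s1, e1, s2, e2)
}

# keep the longest element among mutually overlapping candidates (ties:
# leftmost start), deterministically
.resolve_overlaps <- function(res) {
  if (nrow(res) <= 1L) return(res)
  ord <- order(-(res$end - res$start), res$start)
  res <- res[ord, , drop = FALSE]
  kept <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    if (any(kept)) {
      kd <- res[kept, , drop = FALSE]
      if (any(kd$start <= res$end[i] & kd$end >= res$start[i])) ok <- FALSE
    }
    kept[i] <- ok
  }
  res <- res[kept, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Detect the target-site duplication flanking a candidate
#'
#' Looks for the longest exact match (within `tsd_min`..`tsd_max` bases, no N)
#' between the bases immediately 5' of the element and those immediately 3'
#' of it. Candidates too close to a contig edge get `tsd_seq = NA` and are
#' flagged in the `tsd_flag` column.
#'
#' @param genome as in [find_identical_ltr_pairs()].
#' @param candidates candidate data.frame (one or more rows).
#' @param params a [scan_params()] object.
#' @return the candidate data.frame with `tsd_seq` filled (NA when no match
#'   of at least `tsd_min` bases exists) and a `tsd_flag` column
#'   (`"ok"`, `"none"`, or `"contig_edge"`).
#' @export
detect_tsd <- function(genome, candidates, params = scan_params()) {
  g <- .as_genome(genome)
  stopifnot(is.data.frame(candidates))
  tsd <- rep(NA_character_, nrow(candidates))
  flag <- rep("none", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- g[[candidates$contig[i]]]
    st <- candidates$start[i]; en <- candidates$end[i]
    if (st - params$tsd_max < 1L || en + params$tsd_max > nchar(s)) {
      flag[i] <- "contig_edge"
      next
    }
    for (len in seq(params$tsd_max, params$tsd_min)) {
      left <- substr(s, st - len, st - 1L)
      right <- substr(s, en + 1L, en + len)
      if (left == right && !grepl("N", left, fixed = TRUE)) {
        tsd[i] <- left
        flag[i] <- "ok"
        break
      }
    }
  }
  candidates$tsd_seq <- tsd
  candidates$tsd_flag <- flag
  candidates
}

#' Percent identity between two LTR sequences
#'
#' Equal-length inputs are compared position by position
#' (`100 * matches / length`; N matches nothing). Unequal lengths are
#' compared over a global alignment (match +1, mismatch -1, gap -2) and
#' identity is reported over alignment columns.
#'
#' @param ltr_a,ltr_b non-empty DNA strings.
#' @return percent identity (numeric scalar in \[0, 100\]).
#' @export
#' @examples
#' ltr_identity("ACGTACGT", "ACGTACGT")  # 100
ltr_identity <- function(ltr_a, ltr_b) {
  .validate_dna(ltr_a, "ltr_a"); .validate_dna(ltr_b, "ltr_b")
  if (nchar(ltr_a) == 0L || nchar(ltr_b) == 0L) {
    stop("invalid LTR: empty sequence")
  }
  if (nchar(ltr_a) == nchar(ltr_b)) {
    a <- strsplit(ltr_a, "", fixed = TRUE)[[1L]]
    b <- strsplit(ltr_b, "", fixed = TRUE)[[1L]]
    return(100 * sum(a == b & a != "N") / length(a))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ltr_a),
    subject = Biostrings::DNAString(ltr_b),
    type = "global",
    substitutionMatrix = .dna_submat(1L, -1L),
    gapOpening = 0, gapExtension = 2
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  100 * sum(pa == pb & pa != "-" & pa != "N") / length(pa)
}

#' Write scan candidates to GFF3 and TSV
#'
#' Emits `LTR_retrotransposon`, `long_terminal_repeat` and
#' `target_site_duplication` features (1-based inclusive coordinates) plus a
#' TSV mirror of the candidate table.
#'
#' @param candidates candidate data.frame (after [detect_tsd()] if TSD
#'   features are wanted).
#' @param prefix output path prefix; writes `<prefix>.gff3` and
#'   `<prefix>.tsv`.
#' @return invisibly, the two file paths.
#' @export
write_candidates <- function(candidates, prefix) {
  gff <- paste0(prefix, ".gff3")
  tsv <- paste0(prefix, ".tsv")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    id <- sprintf("ERVI_%s_%d", cc$contig, cc$start)
    lines <- c(lines,
      sprintf("%s\tervi\tLTR_retrotransposon\t%d\t%d\t.\t%s\t.\tID=%s;ltr_identity=%g",
              cc$contig, cc$start, cc$end, cc$strand, id, cc$ltr_identity),
      sprintf("%s\tervi\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
              cc$contig, cc$ltr5_start, cc$ltr5_end, cc$strand, id),
      sprintf("%s\tervi\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
              cc$contig, cc$ltr3_start, cc$ltr3_end, cc$strand, id))
    if (!is.na(cc$tsd_seq)) {
      tl <- nchar(cc$tsd_seq)
      lines <- c(lines,
        sprintf("%s\tervi\ttarget_site_duplication\t%d\t%d\t.\t%s\t.\tParent=%s;seq=%s",
                cc$contig, cc$start - tl, cc$start - 1L, cc$strand, id, cc$tsd_seq),
        sprintf("%s\tervi\ttarget_site_duplication\t%d\t%d\t.\t%s\t.\tParent=%s;seq=%s",
                cc$contig, cc$end + 1L, cc$end + tl, cc$strand, id, cc$tsd_seq))
    }
  }
  writeLines(lines, gff)
  utils::write.table(candidates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gff3 = gff, tsv = tsv))
}

#' Extract the element sequence of a candidate
#'
#' @param genome as in [find_identical_ltr_pairs()].
#' @param candidate one-row candidate data.frame.
#' @return the element sequence (5' LTR start to 3' LTR end) as a string.
#' @export
element_seq <- function(genome, candidate) {
  g <- .as_genome(genome)
  substr(g[[candidate$contig]], candidate$start, candidate$end)
}
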