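# Shared alignment kernels: thin wrappers around Biostrings::pairwiseAlignment
# plus Karlin-Altschul e-values for the bundled search backend.

# Substitution matrix over A/C/G/T/N in which N never matches anything
# (assembly gaps must not create spurious identity).
.dna_submat <- function(match = 2L, mismatch = -3L) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

# Karlin-Altschul expect value E = K m n exp(-lambda S).
# Defaults are the standard gapped parameters for the scoring schemes used
# here: BLOSUM62 with open 11 / extend 1 (lambda 0.267, K 0.041) and
# match 2 / mismatch -3 with open 5 / extend 2 (lambda 0.625, K 0.41).
.ka_evalue <- function(score, m, n, lambda, K) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

.KA_PROT <- list(lambda = 0.267, K = 0.041, gap_open = 11, gap_ext = 1)
.KA_DNA  <- list(lambda = 0.625, K = 0.41,  gap_open = 5,  gap_ext = 2)

# Batched local protein alignment: one or more queries against one subject
# peptide. Returns a data.frame with one row per query.
.align_protein_batch <- function(queries, subject) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = .KA_PROT$gap_open,
    gapExtension = .KA_PROT$gap_ext
  )
  sub <- as.character(Biostrings::alignedSubject(aln))
  data.frame(
    score = Biostrings::score(aln),
    columns = nchar(sub),
    matches = Biostrings::nmatch(aln),
    q_start = Biostrings::start(Biostrings::pattern(aln)),
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)),
    s_end = Biostrings::end(Biostrings::subject(aln)),
    subject_block = sub,
    stringsAsFactors = FALSE
  )
}

# single-pair convenience wrapper
.align_protein_local <- function(query, subject) {
  as.list(.align_protein_batch(query, subject)[1L, ])
}

# seed prescreen: number of distinct k-mers of `a` that occur in `b`.
# Pairs sharing fewer than a handful of 5-mers cannot reach the e-value
# cutoffs used here, so full alignment is skipped for them.
.shared_kmer_count <- function(a, b, k = 5L) {
  if (nchar(a) < k || nchar(b) < k) return(0L)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
  sum(ka %in% kb)
}

# Batched local DNA alignment: many patterns against one subject.
# Returns a data.frame with one row per pattern.
.align_dna_local <- function(patterns, subject, match = 2L, mismatch = -3L,
                             gap_open = .KA_DNA$gap_open,
                             gap_ext = .KA_DNA$gap_ext) {
  pats <- Biostrings::DNAStringSet(patterns)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pats,
    subject = Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = .dna_submat(match, mismatch),
    gapOpening = gap_open,
    gapExtension = gap_ext
  )
  cols <- nchar(as.character(Biostrings::alignedSubject(aln)))
  data.frame(
    score = Biostrings::score(aln),
    columns = cols,
    matches = Biostrings::nmatch(aln),
    p_start = Biostrings::start(Biostrings::pattern(aln)),
    p_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)),
    s_end = Biostrings::end(Biostrings::subject(aln))
  )
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string")
  }
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " contains characters outside {A,C,G,T,N}")
  }
  invisible(seq)
}
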