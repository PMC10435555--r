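# Viral OTU clustering: all-to-all nucleotide similarity edges under the
# coverage >= 80% / identity >= 95% / e-value <= 1e-5 criteria, from-scratch
# Markov clustering (MCL) of the similarity graph, and orthologous /
# paralogous locus search for an element's flanked LTRs.

#' All-to-all similarity edges between elements
#'
#' For every unordered pair of elements the best local alignment is
#' computed; an edge is emitted only when alignment coverage (aligned span
#' as a fraction of the shorter sequence), identity and e-value all satisfy
#' their thresholds. Coverage is symmetrized over the shorter sequence so
#' edges do not depend on query direction.
#'
#' @param elements named character vector or `DNAStringSet` of element
#'   sequences (ids must be unique).
#' @param min_coverage,min_identity,e_max edge thresholds
#'   (defaults 80, 95, 1e-5).
#' @return data.frame with columns `element_a`, `element_b`, `coverage`,
#'   `identity`, `e_value` (one row per unordered pair that qualifies).
#' @export
pairwise_similarity <- function(elements, min_coverage = 80,
                                min_identity = 95, e_max = 1e-5) {
  els <- .as_genome(elements)
  if (anyDuplicated(names(els))) stop("duplicate element ids")
  if (length(els) < 2L) stop("need at least 2 elements")
  ids <- names(els)
  rows <- list()
  for (i in seq_len(length(els) - 1L)) {
    for (j in (i + 1L):length(els)) {
      shorter <- min(nchar(els[[i]]), nchar(els[[j]]))
      al <- .align_dna_local(els[[i]], els[[j]])
      span <- min(al$p_end - al$p_start + 1L, al$s_end - al$s_start + 1L)
      coverage <- 100 * span / shorter
      identity <- 100 * al$matches / al$columns
      ev <- .ka_evalue(al$score, nchar(els[[i]]), nchar(els[[j]]),
                       .KA_DNA$lambda, .KA_DNA$K)
      if (coverage >= min_coverage && identity >= min_identity &&
          ev <= e_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          element_a = ids[i], element_b = ids[j],
          coverage = coverage, identity = identity, e_value = ev,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(element_a = character(), element_b = character(),
                      coverage = numeric(), identity = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Markov clustering of a similarity graph
#'
#' From-scratch dense-matrix MCL. The weighted adjacency matrix (default
#' weight `identity * coverage / 1e4`, or binary) is given unit self-loops
#' and column-normalized, then expansion (matrix squaring) alternates with
#' inflation (entrywise power `inflation`, renormalization); entries below
#' `prune` are zeroed each cycle. Iteration stops when the largest entry
#' change falls below `tol` or after `max_iter` cycles (then the current
#' matrix is interpreted with `converged = FALSE`). Clusters are the
#' connected components of the limit matrix's support; isolated nodes form
#' singleton clusters. Nodes are put in canonical (sorted id) order before
#' matrix construction so the partition is invariant to input order.
#'
#' @param edges data.frame from [pairwise_similarity()] (may have 0 rows).
#' @param node_ids character vector of all element ids (so isolated nodes
#'   are included).
#' @param inflation inflation exponent, must be > 1 (default 1.4).
#' @param weights `"identity_coverage"` or `"binary"`.
#' @param prune,tol,max_iter numerical controls.
#' @return object of class `votu_partition`: list with `clusters` (list of
#'   id vectors, ordered by size then first member), `membership` (named
#'   integer), `inflation`, `method = "mcl"`, `weights`, `converged`,
#'   `iterations`.
#' @export
mcl_cluster <- function(edges, node_ids, inflation = 1.4,
                        weights = c("identity_coverage", "binary"),
                        prune = 1e-8, tol = 1e-6, max_iter = 200L) {
  stopifnot(inflation > 1)
  weights <- match.arg(weights)
  ids <- sort(unique(as.character(node_ids)))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges) > 0L) {
    if (!all(c(edges$element_a, edges$element_b) %in% ids)) {
      stop("edge endpoints not in node_ids")
    }
    w <- if (weights == "identity_coverage") {
      edges$identity * edges$coverage / 1e4
    } else {
      rep(1, nrow(edges))
    }
    ia <- match(edges$element_a, ids)
    ib <- match(edges$element_b, ids)
    M[cbind(ia, ib)] <- w
    M[cbind(ib, ia)] <- w
  }
  diag(M) <- 1
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M                # expansion
    M2 <- M2^inflation           # inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2L, pmax(colSums(M2), .Machine$double.xmin), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current matrix")
  }
  # clusters = connected components of the limit matrix support
  adj <- (M > tol) | (t(M) > tol)
  diag(adj) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  clusters <- unname(split(ids, comp))
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) x[[1L]], character(1)))
  clusters <- clusters[ord]
  membership <- integer(n)
  names(membership) <- ids
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  structure(list(clusters = clusters, membership = membership,
                 inflation = inflation, method = "mcl", weights = weights,
                 converged = converged, iterations = it),
            class = "votu_partition")
}

#' @export
print.votu_partition <- function(x, ...) {
  cat("vOTU partition (MCL, inflation ", x$inflation, "): ",
      length(x$clusters), " clusters over ", length(x$membership),
      " elements\n", sep = "")
  sizes <- lengths(x$clusters)
  cat("  sizes:", paste(sizes, collapse = " "), "\n")
  if (!x$converged) cat("  warning: not converged\n")
  invisible(x)
}

#' Cluster elements into vOTUs
#'
#' Convenience wrapper: [pairwise_similarity()] then [mcl_cluster()].
#'
#' @inheritParams pairwise_similarity
#' @inheritParams mcl_cluster
#' @return a `votu_partition`.
#' @export
cluster_votus <- function(elements, min_coverage = 80, min_identity = 95,
                          e_max = 1e-5, inflation = 1.4) {
  els <- .as_genome(elements)
  edges <- pairwise_similarity(els, min_coverage, min_identity, e_max)
  mcl_cluster(edges, names(els), inflation)
}

#' Locate orthologous and paralogous copies of an element's flanked LTRs
#'
#' Each LTR is bidirectionally extended by `flank` bases and searched
#' against whole assemblies (seed-and-extend: exact 30-mer seeds, then a
#' full-query alignment in the seeded window). A locus qualifies when the
#' entire query aligns (100\% query coverage) at `min_identity` or better.
#' Hits in the source assembly overlapping the element's own locus are
#' labeled `self`, other same-assembly hits `paralog`, and hits in
#' `other_assemblies` `ortholog`.
#'
#' @param candidate one-row candidate data.frame.
#' @param genome source assembly (as in [find_identical_ltr_pairs()]).
#' @param other_assemblies optional named list of assemblies
#'   (`name -> genome`).
#' @param flank flank length in bases (default 500).
#' @param min_identity identity threshold (default 95).
#' @return data.frame with columns `assembly`, `contig`, `start`, `end`,
#'   `query` (`ltr5`/`ltr3`), `identity`, `label`
#'   (`self`/`paralog`/`ortholog`).
#' @export
find_ortho_para <- function(candidate, genome, other_assemblies = NULL,
                            flank = 500L, min_identity = 95) {
  g <- .as_genome(genome)
  s <- g[[candidate$contig]]
  if (candidate$start - flank < 1L || candidate$end + flank > nchar(s)) {
    stop("flanks unavailable: element within ", flank, " bases of contig edge")
  }
  queries <- c(
    ltr5 = substr(s, candidate$start - flank, candidate$ltr5_end),
    ltr3 = substr(s, candidate$ltr3_start, candidate$end + flank)
  )
  assemblies <- c(list(source = g),
                  lapply(other_assemblies, .as_genome))
  if (!is.null(other_assemblies) && is.null(names(other_assemblies))) {
    names(assemblies)[-1L] <- paste0("assembly", seq_along(other_assemblies))
  }
  rows <- list()
  for (an in names(assemblies)) {
    for (cn in names(assemblies[[an]])) {
      subj <- assemblies[[an]][[cn]]
      for (qn in names(queries)) {
        hits <- .seeded_full_query_hits(queries[[qn]], subj, min_identity)
        for (h in hits) {
          label <- if (an == "source" && cn == candidate$contig &&
                       h$start <= candidate$end + flank &&
                       h$end >= candidate$start - flank) {
            "self"
          } else if (an == "source") "paralog" else "ortholog"
          rows[[length(rows) + 1L]] <- data.frame(
            assembly = an, contig = cn, start = h$start, end = h$end,
            query = qn, identity = h$identity, label = label,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(assembly = character(), contig = character(),
                      start = integer(), end = integer(), query = character(),
                      identity = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, rows))
  rownames(res) <- NULL
  res
}

# seed-and-extend search for full-query matches: exact 30-mer seeds sampled
# along the query locate candidate windows; the query is then aligned
# globally in the pattern / locally in the subject window
.seeded_full_query_hits <- function(query, subject, min_identity,
                                    seed_len = 30L, seed_stride = 100L) {
  qlen <- nchar(query)
  if (qlen < seed_len) return(list())
  starts <- unique(c(seq(1L, qlen - seed_len + 1L, by = seed_stride),
                     qlen - seed_len + 1L))
  wins <- list()
  for (st in starts) {
    seed <- substr(query, st, st + seed_len - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    m <- Biostrings::matchPattern(seed, Biostrings::DNAString(subject))
    for (p in Biostrings::start(m)) {
      w_start <- max(1L, p - st - 200L)
      w_end <- min(nchar(subject), p - st + qlen + 200L)
      wins[[length(wins) + 1L]] <- c(w_start, w_end)
    }
  }
  if (length(wins) == 0L) return(list())
  # merge overlapping windows
  wm <- do.call(rbind, wins)
  wm <- wm[order(wm[, 1L]), , drop = FALSE]
  merged <- list(wm[1L, ])
  for (i in seq_len(nrow(wm))[-1L]) {
    last <- merged[[length(merged)]]
    if (wm[i, 1L] <= last[2L]) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], wm[i, 2L]))
    } else {
      merged[[length(merged) + 1L]] <- wm[i, ]
    }
  }
  hits <- list()
  for (w in merged) {
    win <- substr(subject, w[1L], w[2L])
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query),
      subject = Biostrings::DNAString(win),
      type = "global-local",
      substitutionMatrix = .dna_submat(2L, -3L),
      gapOpening = .KA_DNA$gap_open, gapExtension = .KA_DNA$gap_ext
    )
    cols <- nchar(as.character(Biostrings::alignedSubject(aln)))
    identity <- 100 * Biostrings::nmatch(aln) / cols
    if (identity >= min_identity) {
      hits[[length(hits) + 1L]] <- list(
        start = w[1L] + Biostrings::start(Biostrings::subject(aln)) - 1L,
        end = w[1L] + Biostrings::end(Biostrings::subject(aln)) - 1L,
        identity = identity
      )
    }
  }
  hits
}

#' Write similarity edges and a vOTU partition to disk
#'
#' Emits an edges TSV, a clusters TSV (`element_id`, `votu_id`) and an ABC
#' graph file (`a b weight`) for interoperability.
#'
#' @param edges data.frame from [pairwise_similarity()].
#' @param partition a `votu_partition`.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_votus <- function(edges, partition, prefix) {
  ef <- paste0(prefix, ".edges.tsv")
  cf <- paste0(prefix, ".clusters.tsv")
  af <- paste0(prefix, ".abc")
  utils::write.table(edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- data.frame(element_id = names(partition$membership),
                   votu_id = sprintf("vOTU_%03d", partition$membership),
                   stringsAsFactors = FALSE)
  utils::write.table(cl, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  abc <- if (nrow(edges)) {
    sprintf("%s\t%s\t%.6g", edges$element_a, edges$element_b,
            edges$identity * edges$coverage / 1e4)
  } else {
    character()
  }
  writeLines(abc, af)
  invisible(c(edges = ef, clusters = cf, abc = af))
}
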