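# Independent oracles and shared fixtures for the test suite.

# ---- fixture cache (worlds are deterministic in seed; build once) ---------
.fixtures <- new.env(parent = emptyenv())

cached_world <- function(seed, ...) {
  key <- paste0("world_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make_world(seed, ...)
  .fixtures[[key]]
}

cached_panel <- function(seed = 1L) {
  key <- paste0("panel_", seed)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make_reference_panel(seed)
  .fixtures[[key]]
}

# ---- independent dense-matrix MCL oracle ----------------------------------
# Written independently of ervi::mcl_cluster: explicit normalization via
# apply, attractor-based cluster read-out (rows with positive diagonal mass
# claim the columns they dominate; overlapping attractor sets are merged).
oracle_mcl <- function(adj, inflation, prune = 1e-8, tol = 1e-6,
                       max_iter = 200L) {
  n <- nrow(adj)
  M <- adj
  diag(M) <- 1
  M <- apply(M, 2L, function(col) col / sum(col))
  for (it in seq_len(max_iter)) {
    nxt <- (M %*% M)^inflation
    nxt[nxt < prune] <- 0
    nxt <- apply(nxt, 2L, function(col) col / max(sum(col), 1e-300))
    if (max(abs(nxt - M)) < tol) { M <- nxt; break }
    M <- nxt
  }
  attractors <- which(diag(M) > tol)
  sets <- lapply(attractors, function(a) sort(unique(c(a, which(M[a, ] > tol)))))
  # merge overlapping attractor systems
  merged <- list()
  for (s in sets) {
    hit <- which(vapply(merged, function(m) length(intersect(m, s)) > 0,
                        logical(1)))
    if (length(hit)) {
      merged[[hit[1L]]] <- sort(unique(c(unlist(merged[hit]), s)))
      merged[setdiff(hit, hit[1L])] <- NULL
    } else {
      merged[[length(merged) + 1L]] <- s
    }
  }
  leftover <- setdiff(seq_len(n), unlist(merged))
  for (v in leftover) merged[[length(merged) + 1L]] <- v
  # canonical form: sort members, order clusters by first member
  merged <- lapply(merged, sort)
  merged[order(vapply(merged, `[`, numeric(1), 1L))]
}

# canonical form of an ervi partition over integer node ids "1".."n"
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(as.integer(x)))
  cl[order(vapply(cl, `[`, integer(1), 1L))]
}

# ---- BCa oracle -----------------------------------------------------------
# Direct transliteration of the BCa definition, with its own type-7
# quantile interpolation.
oracle_bca <- function(boots, obs, jack, alpha = 0.05) {
  B <- length(boots)
  z0 <- qnorm((sum(boots < obs) + 0.5 * sum(boots == obs)) / B)
  d <- mean(jack) - jack
  a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  lev <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  c(low = q7(boots, lev(qnorm(alpha / 2))),
    high = q7(boots, lev(qnorm(1 - alpha / 2))),
    z0 = z0, a = a)
}

# ---- misc brute-force helpers --------------------------------------------
# longest shared flank duplication by direct window enumeration
oracle_tsd <- function(left_flank, right_flank, tsd_min, tsd_max) {
  best <- NA_character_
  for (len in tsd_min:tsd_max) {
    l <- substr(left_flank, nchar(left_flank) - len + 1L, nchar(left_flank))
    r <- substr(right_flank, 1L, len)
    if (l == r && !grepl("N", l)) best <- l
  }
  best
}

rand_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, positions) {
  sv <- strsplit(seq, "")[[1]]
  for (p in positions) sv[p] <- setdiff(c("A", "C", "G", "T"), sv[p])[1]
  paste(sv, collapse = "")
}
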