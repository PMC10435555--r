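# Downstream statistics: bootstrap richness extrapolation with BCa
# intervals, the phylogenetic-signal D statistic for binary traits with
# permutation and Brownian-threshold nulls, the G-test of independence, and
# prevalence summaries.

#' Prevalence as a percentage
#'
#' @param n_hit number of positive units (e.g. invaded species).
#' @param n_total total units surveyed (> 0).
#' @return list with `percent` (two decimals) and `fraction` (exact ratio).
#' @export
#' @examples
#' prevalence_summary(50, 123)  # 40.65 percent
prevalence_summary <- function(n_hit, n_total) {
  if (length(n_total) != 1L || n_total <= 0) stop("n_total must be positive")
  if (n_hit < 0 || n_hit > n_total) stop("need 0 <= n_hit <= n_total")
  list(percent = round(100 * n_hit / n_total, 2L),
       fraction = n_hit / n_total)
}

#' G-test of independence
#'
#' Log-likelihood-ratio test for a two-dimensional contingency table:
#' `G = 2 sum O log(O/E)` over nonzero cells, compared to the chi-square
#' distribution with `(r-1)(c-1)` degrees of freedom. Optional Williams
#' correction divides G by `1 + (a-1)/(6 n df)` style q factor
#' (off by default).
#'
#' @param table numeric matrix of counts, at least 2x2, with no zero row or
#'   column margin.
#' @param williams apply the Williams small-sample correction.
#' @return an object of class `htest` with `statistic` (G), `parameter`
#'   (df) and `p.value`.
#' @export
g_test <- function(table, williams = FALSE) {
  x <- as.matrix(table)
  if (length(dim(x)) != 2L || nrow(x) < 2L || ncol(x) < 2L) {
    stop("need a two-dimensional table (at least 2x2)")
  }
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be non-negative")
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  E <- outer(rs, cs) / n
  nz <- x > 0
  G <- 2 * sum(x[nz] * log(x[nz] / E[nz]))
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  if (williams) {
    q <- 1 + ((n * sum(1 / rs) - 1) * (n * sum(1 / cs) - 1)) / (6 * n * df)
    G <- G / q
  }
  p <- stats::pchisq(G, df, lower.tail = FALSE)
  structure(list(
    statistic = c(G = G), parameter = c(df = df), p.value = p,
    method = if (williams) "G-test of independence (Williams-corrected)"
             else "G-test of independence",
    data.name = deparse(substitute(table))
  ), class = "htest")
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Given precomputed bootstrap statistics, the observed statistic and
#' jackknife statistics, computes the BCa interval: bias correction
#' `z0 = qnorm(#\{theta* < theta_hat\}/B)` with ties counted half,
#' acceleration `a` from the jackknife skewness, and interval endpoints at
#' the bootstrap quantiles of the adjusted levels
#' `pnorm(z0 + (z0 + z_alpha)/(1 - a (z0 + z_alpha)))`. Quantiles use the
#' default (type 7) interpolation.
#'
#' @param bootstrap_stats numeric vector of bootstrap replicates
#'   (at least 100).
#' @param observed the observed statistic.
#' @param jackknife_stats leave-one-out statistics (at least 3).
#' @param alpha two-sided miss probability (default 0.05 for a 95\%
#'   interval).
#' @return list with `low`, `high`, `z0`, `a`.
#' @export
bca_interval <- function(bootstrap_stats, observed, jackknife_stats,
                         alpha = 0.05) {
  B <- length(bootstrap_stats)
  if (B < 100L) stop("need at least 100 bootstrap statistics")
  if (length(jackknife_stats) < 3L) stop("need at least 3 jackknife statistics")
  if (stats::sd(bootstrap_stats) == 0) {
    # degenerate bootstrap distribution: zero-width interval at the constant
    return(list(low = bootstrap_stats[1L], high = bootstrap_stats[1L],
                z0 = 0, a = 0))
  }
  prop <- (sum(bootstrap_stats < observed) +
             0.5 * sum(bootstrap_stats == observed)) / B
  if (prop <= 0 || prop >= 1) {
    stop("observed statistic outside the bootstrap range: z0 infinite")
  }
  z0 <- stats::qnorm(prop)
  jm <- mean(jackknife_stats)
  d <- jm - jackknife_stats
  denom <- sum(d^2)
  if (denom == 0) {
    warning("zero jackknife variance: acceleration set to 0")
    a <- 0
  } else {
    a <- sum(d^3) / (6 * denom^1.5)
  }
  zlo <- stats::qnorm(alpha / 2)
  zhi <- stats::qnorm(1 - alpha / 2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  lo <- stats::quantile(bootstrap_stats, adj(zlo), names = FALSE, type = 7)
  hi <- stats::quantile(bootstrap_stats, adj(zhi), names = FALSE, type = 7)
  list(low = lo, high = hi, z0 = z0, a = a)
}

#' Extrapolate total vOTU richness to an unsurveyed species pool
#'
#' The point estimate is the closed-form rate scaling
#' `theta = mean(per-species vOTU count) * n_total_species`; uncertainty
#' comes from bootstrapping species with replacement (`reps` resamples) and
#' a 95\% BCa interval via [bca_interval()]. Zeros for surveyed species
#' without elements must be included in `per_species_votus`.
#'
#' @param per_species_votus named numeric vector: distinct vOTU count per
#'   surveyed species (zeros included).
#' @param n_total_species size of the species pool extrapolated to.
#' @param reps bootstrap replicates (default 10000).
#' @param seed integer seed; the estimate is reproducible bit for bit.
#' @param alpha two-sided miss probability for the interval.
#' @return object of class `ervi_boot`: list with `point`, `ci_low`,
#'   `ci_high`, `z0`, `a`, `reps`, `seed`, `n_surveyed`, `n_total_species`,
#'   `flag` (`"ok"` or `"degenerate"`).
#' @export
estimate_total_votus <- function(per_species_votus, n_total_species,
                                 reps = 10000L, seed = 1L, alpha = 0.05) {
  x <- as.numeric(per_species_votus)
  n <- length(x)
  if (n < 2L) stop("need at least 2 surveyed species")
  if (any(x < 0)) stop("counts must be non-negative")
  point <- mean(x) * n_total_species
  if (all(x == x[1L])) {
    # no resampling variance (includes the all-zero case)
    return(structure(list(point = point, ci_low = point, ci_high = point,
                          z0 = 0, a = 0, reps = as.integer(reps),
                          seed = as.integer(seed), n_surveyed = n,
                          n_total_species = n_total_species,
                          flag = "degenerate"),
                     class = "ervi_boot"))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  boots <- numeric(reps)
  chunk <- max(1L, min(reps, floor(2e7 / n)))
  done <- 0L
  while (done < reps) {
    b <- min(chunk, reps - done)
    idx <- sample.int(n, n * b, replace = TRUE)
    boots[(done + 1L):(done + b)] <-
      colMeans(matrix(x[idx], nrow = n, ncol = b)) * n_total_species
    done <- done + b
  }
  jack <- (sum(x) - x) / (n - 1) * n_total_species
  ci <- bca_interval(boots, point, jack, alpha)
  structure(list(point = point, ci_low = ci$low, ci_high = ci$high,
                 z0 = ci$z0, a = ci$a, reps = as.integer(reps),
                 seed = as.integer(seed), n_surveyed = n,
                 n_total_species = n_total_species,
                 flag = if (ci$low <= point && point <= ci$high) "ok"
                        else "ci_excludes_point"),
            class = "ervi_boot")
}

#' @export
print.ervi_boot <- function(x, ...) {
  cat(sprintf(
    "Richness extrapolation: %.1f vOTUs in %d species (95%% BCa %.1f-%.1f)\n",
    x$point, x$n_total_species, x$ci_low, x$ci_high))
  cat(sprintf("  surveyed n=%d, B=%d, seed=%d, z0=%.4f, a=%.4f [%s]\n",
              x$n_surveyed, x$reps, x$seed, x$z0, x$a, x$flag))
  invisible(x)
}

# ---- phylogenetic-signal D ------------------------------------------------

# Nodal-value reconstruction and sum of edgewise changes, vectorized over
# columns of a tip-state matrix. Contrasts-style two-pass weighted average:
# postorder, each internal node takes the branch-length-weighted average of
# its two daughters and its own stem is prolonged by t1 t2/(t1 + t2).
.d_sum_changes <- function(tree, states_mat) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  edge <- tree$edge
  val <- matrix(0, nn, ncol(states_mat))
  val[seq_len(nt), ] <- states_mat
  ext <- tree$edge.length
  # nodes in children-before-parents order: each parent at the position of
  # its last daughter edge in the postorder edge sequence
  par_seq <- ape::reorder.phylo(tree, "postorder")$edge[, 1L]
  node_order <- par_seq[!duplicated(par_seq, fromLast = TRUE)]
  daughters <- split(seq_len(nrow(edge)), edge[, 1L])
  parent_edge <- match(seq_len(nn), edge[, 2L])  # edge above node, NA at root
  for (node in node_order) {
    de <- daughters[[as.character(node)]]
    e1 <- de[1L]; e2 <- de[2L]
    t1 <- ext[e1]; t2 <- ext[e2]
    val[node, ] <- (val[edge[e1, 2L], ] / t1 + val[edge[e2, 2L], ] / t2) /
      (1 / t1 + 1 / t2)
    pe <- parent_edge[node]
    if (!is.na(pe)) ext[pe] <- ext[pe] + t1 * t2 / (t1 + t2)
  }
  colSums(abs(val[edge[, 1L], , drop = FALSE] -
                val[edge[, 2L], , drop = FALSE]))
}

# unit-rate Brownian motion on the tree, returned as a tips x nsim matrix
.simulate_brownian_tips <- function(tree, nsim) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  edge <- tree$edge
  val <- matrix(0, nn, nsim)
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  eo <- match(paste(pre$edge[, 1L], pre$edge[, 2L]),
              paste(edge[, 1L], edge[, 2L]))
  for (e in eo) {
    val[edge[e, 2L], ] <- val[edge[e, 1L], ] +
      stats::rnorm(nsim, sd = sqrt(tree$edge.length[e]))
  }
  val[seq_len(nt), , drop = FALSE]
}

#' Phylogenetic-signal D for a binary trait
#'
#' Estimates the D statistic of a binary trait on a rooted bifurcating
#' phylogeny. The observed sum of edgewise changes in reconstructed nodal
#' values (`d_obs`) is standardized against two simulated nulls:
#' phylogenetic randomness (tip-state permutations preserving prevalence)
#' and Brownian clumping (unit-rate Brownian motion thresholded to the
#' observed prevalence):
#' `D = (d_obs - mean d_Brownian) / (mean d_random - mean d_Brownian)`.
#' D near 1 indicates a phylogenetically random trait, near 0 Brownian-like
#' clumping. `p_gt0` is the fraction of Brownian-null sums at or above
#' `d_obs` (small means D departs upward from 0); `p_lt1` the fraction of
#' permutation-null sums at or below `d_obs` (small means D departs
#' downward from 1).
#'
#' @param tree an `ape::phylo`, rooted and bifurcating, all branch lengths
#'   positive.
#' @param states named 0/1 vector over the tip labels (both states must
#'   occur).
#' @param n_perm,n_brownian null-simulation sizes (default 1000 each).
#' @param seed integer seed.
#' @return object of class `ervi_d`: list with `D`, `d_obs`, `mean_random`,
#'   `mean_brownian`, `p_gt0`, `p_lt1`, `n_perm`, `n_brownian`, `seed`,
#'   `n_tips`, `prevalence`.
#' @export
d_statistic <- function(tree, states, n_perm = 1000L, n_brownian = 1000L,
                        seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) {
    stop("tree must be bifurcating; resolve polytomies first")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("all branch lengths must be positive; resolve zero-length branches")
  }
  nt <- length(tree$tip.label)
  if (is.null(names(states))) {
    if (length(states) != nt) stop("states must be named by tip label")
    names(states) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(states))) {
    stop("every tip needs a state")
  }
  x <- as.numeric(states[tree$tip.label])
  if (!all(x %in% c(0, 1))) stop("states must be binary 0/1")
  k <- sum(x)
  if (k < 2 || k > nt - 2) {
    stop("D undefined: need at least 2 tips in each state")
  }
  if (nt < 50L) {
    warning("fewer than 50 tips: D depends on prevalence and tree shape")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  d_obs <- .d_sum_changes(tree, matrix(x, ncol = 1L))
  perm <- vapply(seq_len(n_perm), function(i) sample(x), numeric(nt))
  d_rand <- .d_sum_changes(tree, perm)
  bm <- .simulate_brownian_tips(tree, n_brownian)
  thr <- apply(bm, 2L, function(col) {
    as.numeric(rank(-col, ties.method = "first") <= k)
  })
  d_brown <- .d_sum_changes(tree, thr)

  D <- (d_obs - mean(d_brown)) / (mean(d_rand) - mean(d_brown))
  structure(list(
    D = unname(D), d_obs = unname(d_obs),
    mean_random = mean(d_rand), mean_brownian = mean(d_brown),
    p_gt0 = mean(d_brown >= d_obs), p_lt1 = mean(d_rand <= d_obs),
    n_perm = as.integer(n_perm), n_brownian = as.integer(n_brownian),
    seed = as.integer(seed), n_tips = nt, prevalence = k / nt
  ), class = "ervi_d")
}

#' @export
print.ervi_d <- function(x, ...) {
  cat(sprintf("Phylogenetic signal D = %.4f (%d tips, prevalence %.3f)\n",
              x$D, x$n_tips, x$prevalence))
  cat(sprintf("  p(D > 0) = %.4g   p(D < 1) = %.4g   (%d perm, %d Brownian, seed %d)\n",
              x$p_gt0, x$p_lt1, x$n_perm, x$n_brownian, x$seed))
  invisible(x)
}
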