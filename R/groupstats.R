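#' @title Group-level sensor statistics
#' @description
#' Cluster-based permutation comparison of per-channel accuracy maps
#' between groups (nonparametric family-wise error control over
#' electrodes), and rank-based comparisons (Kruskal-Wallis with Dunn
#' post-hoc) across conditions or lags.
#' @name groupstats
NULL

# connected components of a channel set under the adjacency graph
components_of <- function(chans, adjacency) {
  comps <- list()
  remaining <- chans
  while (length(remaining) > 0) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(adjacency[v, ]), remaining)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# clusters (>= min_size, same sign) and their t-mass for one t map
cluster_masses <- function(t_vals, thr, adjacency, min_size = 2) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_vals > thr)
    if (length(supra) < min_size) next
    for (comp in components_of(supra, adjacency)) {
      if (length(comp) >= min_size)
        out[[length(out) + 1]] <- list(channels = comp,
                                       mass = sum(t_vals[comp]),
                                       polarity = sgn)
    }
  }
  out
}

# two-sample pooled-variance t per column, vectorized over permutations:
# P is [n x n_perm] of 0/1 group-1 indicators
perm_t_matrix <- function(X, P, n1, n2) {
  S <- colSums(X); Q <- colSums(X^2)
  S1 <- crossprod(P, X)                # n_perm x p
  Q1 <- crossprod(P, X^2)
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, S, `+`) / n2
  ssq1 <- Q1 - n1 * m1^2
  ssq2 <- sweep(-Q1, 2, Q, `+`) - n2 * m2^2
  sp2 <- (ssq1 + ssq2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Cluster-based permutation test on sensor maps
#'
#' Per-electrode two-sample t statistics are thresholded at the
#' two-sided parametric critical value (`alpha_cluster`); connected
#' supra-threshold sets of at least two adjacent electrodes (per sign)
#' form clusters whose mass is the summed t.  Group labels are permuted
#' `n_perm` times to build the null distribution of the maximum absolute
#' cluster mass; cluster p-values are (1 + #\{null >= observed\}) /
#' (n_perm + 1).
#'
#' @param maps_group1,maps_group2 matrices [subjects x channels].
#' @param adjacency symmetric logical channel adjacency.
#' @param n_perm permutations (>= 500, default 1000).
#' @param alpha_cluster cluster-forming alpha (two-sided, default 0.05).
#' @param seed RNG seed.
#' @param min_size minimum electrodes per cluster (default 2).
#' @return list (`cluster_result`): `clusters` (channel sets), `mass`,
#'   `p_perm`, `polarity`, `t_observed`, `n_perm`.
#' @export
cluster_permutation <- function(maps_group1, maps_group2, adjacency,
                                n_perm = 1000, alpha_cluster = 0.05,
                                seed = 1, min_size = 2) {
  n1 <- nrow(maps_group1); n2 <- nrow(maps_group2)
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 subjects")
  stopifnot(ncol(maps_group1) == ncol(maps_group2), n_perm >= 500)
  if (any(rowSums(adjacency) == 0))
    warning("adjacency contains isolated channels")
  X <- rbind(maps_group1, maps_group2)
  n <- n1 + n2
  thr <- stats::qt(1 - alpha_cluster / 2, df = n - 2)
  t_obs <- as.numeric(perm_t_matrix(
    X, matrix(as.numeric(seq_len(n) <= n1), n, 1), n1, n2))
  obs <- cluster_masses(t_obs, thr, adjacency, min_size)
  set.seed(as.integer(seed))
  P <- matrix(0, n, n_perm)
  for (k in seq_len(n_perm)) P[sample.int(n, n1), k] <- 1
  Tn <- perm_t_matrix(X, P, n1, n2)    # n_perm x p
  null_max <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    cl <- cluster_masses(Tn[k, ], thr, adjacency, min_size)
    null_max[k] <- if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }
  p_perm <- vapply(obs, function(cl)
    (1 + sum(null_max >= abs(cl$mass))) / (n_perm + 1), 0)
  structure(list(clusters = lapply(obs, `[[`, "channels"),
                 mass = vapply(obs, `[[`, 0, "mass"),
                 polarity = vapply(obs, `[[`, 0, "polarity"),
                 p_perm = p_perm, t_observed = t_obs, n_perm = n_perm,
                 threshold = thr), class = "cluster_result")
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Tie-corrected H statistic (cross-checked against
#' `stats::kruskal.test`) and Dunn z statistics on pooled ranks, with
#' multiplicity adjustment (Holm by default; "bonferroni" gives the
#' classical Dunn-adjusted p).  With `control` set, only comparisons
#' against that group are made (used for per-lag profiles).
#'
#' @param samples list of numeric group vectors (>= 2 groups, n >= 3).
#' @param adjust p adjustment method (see [stats::p.adjust()]).
#' @param control optional index of a reference group.
#' @return list (`group_test`): `H`, `df`, `p_value`, `dunn_table`
#'   (pair, mean_rank_diff, z, p_adj, significant).
#' @export
kruskal_dunn <- function(samples, adjust = "holm", control = NULL) {
  k <- length(samples)
  stopifnot(k >= 2, all(vapply(samples, length, 0L) >= 3))
  x <- unlist(samples)
  g <- rep(seq_len(k), vapply(samples, length, 0L))
  N <- length(x)
  if (max(x) - min(x) == 0) {
    return(structure(list(H = 0, df = k - 1, p_value = 1,
                          dunn_table = NULL), class = "group_test"))
  }
  r <- rank(x)
  ns <- vapply(samples, length, 0L)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  H <- (12 / (N * (N + 1))) * sum(ns * (rbar - (N + 1) / 2)^2)
  H <- H / (1 - tie_term / (N^3 - N))
  p <- stats::pchisq(H, k - 1, lower.tail = FALSE)
  pairs <- if (is.null(control)) utils::combn(k, 2)
           else rbind(setdiff(seq_len(k), control), control)
  sig2 <- (N * (N + 1) / 12 - tie_term / (12 * (N - 1)))
  z <- diffs <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diffs[j] <- rbar[i1] - rbar[i2]
    z[j] <- diffs[j] / sqrt(sig2 * (1 / ns[i1] + 1 / ns[i2]))
  }
  p_raw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  tab <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    mean_rank_diff = diffs, z = z, p_adj = p_adj,
                    significant = p_adj < 0.05)
  structure(list(H = H, df = k - 1, p_value = p, dunn_table = tab),
            class = "group_test")
}
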