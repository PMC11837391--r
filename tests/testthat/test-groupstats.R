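test_that("kruskal-wallis H matches stats::kruskal.test exactly, with ties", {
  set.seed(1)
  g <- list(c(1, 2, 2, 3, 5), c(2, 2, 4, 6, 6), c(1, 1, 3, 3, 7))
  res <- kruskal_dunn(g)
  ref <- stats::kruskal.test(unlist(g), rep(1:3, each = 5))
  expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("dunn table is antisymmetric and schema-complete; identical data give H = 0", {
  set.seed(2)
  g <- list(stats::rnorm(10), stats::rnorm(10) + 1, stats::rnorm(10))
  res <- kruskal_dunn(g)
  expect_named(res$dunn_table,
               c("group1", "group2", "mean_rank_diff", "z", "p_adj",
                 "significant"))
  # swapping the groups flips the sign of the rank difference
  res_sw <- kruskal_dunn(g[c(2, 1, 3)])
  i12 <- which(res$dunn_table$group1 == 1 & res$dunn_table$group2 == 2)
  j12 <- which(res_sw$dunn_table$group1 == 1 & res_sw$dunn_table$group2 == 2)
  expect_equal(res$dunn_table$mean_rank_diff[i12],
               -res_sw$dunn_table$mean_rank_diff[j12], tolerance = 1e-12)
  same <- kruskal_dunn(list(rep(1, 5), rep(1, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
})

test_that("kruskal-dunn is calibrated and powered", {
  set.seed(3)
  rej0 <- mean(replicate(300, kruskal_dunn(
    lapply(1:3, function(i) stats::rnorm(20)))$p_value < 0.05))
  expect_gte(rej0, 0.02); expect_lte(rej0, 0.09)
  rej1 <- mean(replicate(100, kruskal_dunn(
    list(stats::rnorm(20), stats::rnorm(20) + 2))$p_value < 0.05))
  expect_gt(rej1, 0.95)
})

test_that("cluster permutation recovers an injected patch and reports valid p-values", {
  mont <- make_montage(16)
  d <- mont$positions %*% t(mont$positions)
  d[] <- acos(pmin(1, pmax(-1, d)))
  patch <- order(d[3, ])[1:5]
  set.seed(4)
  M1 <- matrix(stats::rnorm(15 * 16), 15)
  M2 <- matrix(stats::rnorm(15 * 16), 15)
  M2[, patch] <- M2[, patch] + 1.5
  res <- cluster_permutation(M1, M2, mont$adjacency, n_perm = 500, seed = 1)
  expect_gt(length(res$clusters), 0)
  best <- which.min(res$p_perm)
  expect_lt(res$p_perm[best], 0.05)
  expect_gte(length(intersect(res$clusters[[best]], patch)) /
               length(union(res$clusters[[best]], patch)), 0.5)
  expect_true(all(res$p_perm >= 1 / 501 & res$p_perm <= 1))
  expect_true(all(vapply(res$clusters, length, 0L) >= 2))
})

test_that("cluster detection is invariant to a consistent channel permutation", {
  mont <- make_montage(12)
  set.seed(5)
  M1 <- matrix(stats::rnorm(10 * 12), 10)
  M2 <- matrix(stats::rnorm(10 * 12), 10)
  M2[, 1:4] <- M2[, 1:4] + 2
  res <- cluster_permutation(M1, M2, mont$adjacency, n_perm = 500, seed = 7)
  perm <- sample(12)
  res_p <- cluster_permutation(M1[, perm], M2[, perm],
                               mont$adjacency[perm, perm], n_perm = 500,
                               seed = 7)
  remap <- lapply(res$clusters, function(cl) sort(match(cl, perm)))
  expect_setequal(vapply(remap, paste, "", collapse = ","),
                  vapply(lapply(res_p$clusters, sort), paste, "",
                         collapse = ","))
  expect_equal(sort(res$mass), sort(res_p$mass), tolerance = 1e-10)
})

test_that("cluster permutation rejects tiny groups and warns on isolated channels", {
  mont <- make_montage(8)
  M <- matrix(stats::rnorm(2 * 8), 2)
  expect_error(cluster_permutation(M, M, mont$adjacency), "3 subjects")
  adj <- mont$adjacency; adj[1, ] <- FALSE; adj[, 1] <- FALSE
  set.seed(8)
  M1 <- matrix(stats::rnorm(5 * 8), 5); M2 <- matrix(stats::rnorm(5 * 8), 5)
  expect_warning(cluster_permutation(M1, M2, adj, n_perm = 500), "isolated")
})
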