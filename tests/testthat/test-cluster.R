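test_that("two points merge at their Euclidean distance", {
  x <- rbind(c(0, 0), c(3, 4))
  tree <- ward_linkage(x)
  expect_equal(tree$heights, 5)
  expect_equal(tree$n_leaves, 2L)
  expect_error(ward_linkage(x[1, , drop = FALSE]), "at least 2")
})

test_that("two tight far-apart triplets join last and split at 50%", {
  set.seed(51)
  x <- rbind(matrix(rnorm(6, sd = 0.01), 3) + 0,
             matrix(rnorm(6, sd = 0.01), 3) + 10)
  tree <- ward_linkage(x)
  expect_equal(sort(tree$heights), oracle_ward_heights(x), tolerance = 1e-9)
  # final merge towers above within-triplet merges
  expect_gt(max(tree$heights), 100 * sort(tree$heights, TRUE)[2])
  sol <- cut_at_percent(tree, 50)
  expect_equal(sol$n_clusters, 2L)
  expect_equal(sol$labels, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("Ward merge heights match the naive O(n^3) reference", {
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    d <- sample(2:6, 1)
    x <- matrix(rnorm(n * d), n, d)
    tree <- ward_linkage(x)
    expect_equal(sort(tree$heights), oracle_ward_heights(x),
                 tolerance = 1e-9)
    # merge heights are monotone non-decreasing (Ward/Euclidean)
    expect_true(all(diff(tree$hclust$height) >= -1e-12))
  }
})

test_that("pruning-height cuts hit both degenerate limits", {
  set.seed(53)
  x <- matrix(rnorm(20 * 3), 20, 3)
  tree <- ward_linkage(x)
  expect_equal(cut_at_percent(tree, 0)$n_clusters, 20L)
  expect_equal(cut_at_percent(tree, 100)$n_clusters, 1L)
  # labels are numbered by first appearance in sign order
  sol <- cut_at_percent(tree, 40)
  expect_equal(sol$labels[1], 1L)
  expect_true(all(diff(cummax(sol$labels)) <= 1))
  # k-cut agrees with the corresponding percent cut
  solk <- cut_at_k(tree, sol$n_clusters)
  expect_equal(solk$labels, sol$labels)
})

test_that("n_clusters decreases and within-pair count increases with height", {
  set.seed(54)
  x <- matrix(rnorm(30 * 4), 30, 4)
  tree <- ward_linkage(x)
  ncl <- np <- numeric(0)
  for (h in seq(0, 100, by = 5)) {
    sol <- cut_at_percent(tree, h)
    ncl <- c(ncl, sol$n_clusters)
    np <- c(np, nrow(within_cluster_pairs(sol)))
  }
  expect_true(all(diff(ncl) <= 0))
  expect_true(all(diff(np) >= 0))
})

test_that("silhouette matches the direct per-point formula", {
  # two tight well-separated pairs score near 1
  x <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(silhouette_score(x, lab), oracle_silhouette(x, lab),
               tolerance = 1e-12)
  expect_gt(silhouette_score(x, lab), 0.9)

  set.seed(55)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    k <- sample(2:6, 1)
    lab <- cutree(hclust(dist(x), "ward.D2"), k = k)
    expect_equal(silhouette_score(x, lab), oracle_silhouette(x, lab),
                 tolerance = 1e-12)
  }
})

test_that("silhouette conventions: random labels near 0, invariance, undefined cases", {
  set.seed(56)
  x <- matrix(rnorm(200 * 2), 200, 2)          # one homogeneous blob
  lab <- sample(1:2, 200, replace = TRUE)
  expect_lt(abs(silhouette_score(x, lab)), 0.05)
  # label renaming leaves the score unchanged
  expect_equal(silhouette_score(x, lab), silhouette_score(x, 3L - lab))
  # singleton clusters contribute 0
  x4 <- rbind(c(0, 0), c(0, 1), c(9, 9), c(20, 20))
  lab4 <- c(1L, 1L, 2L, 3L)
  expect_equal(silhouette_score(x4, lab4), oracle_silhouette(x4, lab4),
               tolerance = 1e-12)
  # one cluster or all singletons: undefined
  expect_true(is.na(silhouette_score(x, rep(1L, 200))))
  expect_true(is.na(silhouette_score(x4, 1:4)))
})

test_that("within-cluster pairs obey the per-cluster closed form", {
  sol <- structure(list(labels = c(1L, 1L, 1L, 2L, 2L)),
                   class = "cluster_solution")
  wp <- within_cluster_pairs(sol)
  expect_equal(nrow(wp), 3 + 1)
  expect_equal(wp$i, c(1L, 1L, 2L, 4L))
  expect_equal(wp$j, c(2L, 3L, 3L, 5L))
  # all singletons -> zero pairs
  expect_equal(nrow(within_cluster_pairs(structure(list(labels = 1:5),
                                         class = "cluster_solution"))), 0L)
})

test_that("at 100% the within-cluster pair set is the full enumeration", {
  set.seed(57)
  x <- matrix(rnorm(25 * 3), 25, 3)
  tree <- ward_linkage(x)
  wp <- within_cluster_pairs(cut_at_percent(tree, 100))
  pt <- enumerate_pairs(25)
  expect_equal(wp$i, pt$i)
  expect_equal(wp$j, pt$j)
})

test_that("sweep at 100% reproduces the lexicon-wide pairwise correlations", {
  f <- small_aligned(seed = 58, n = 50, K = 4)
  pw <- suppressMessages(run_pairwise(f$al))
  sw <- run_sweep(f$al, heights = c(0, 100))
  top <- sw[sw$height_percent == 100, ]
  expect_equal(top$r[match(pw$scope, top$scope)], pw$r, tolerance = 1e-12)
  expect_equal(top$df[1], pw$df[1])
  # height 0: all singletons, correlations undefined
  bottom <- sw[sw$height_percent == 0, ]
  expect_true(all(bottom$degenerate))
  expect_true(all(is.na(bottom$r)))
  expect_true(all(is.na(bottom$silhouette)))
})

test_that("sweep grid is complete, consistent, and Bonferroni-aware", {
  f <- small_aligned(seed = 59, n = 60, K = 4)
  sw <- run_sweep(f$al, heights = c(5, 10, 20, 40, 80),
                  scopes = c("location", "entire"))
  expect_equal(nrow(sw), 5 * 2)
  expect_true(all(sw$df == sw$n_within_pairs - 2 | sw$degenerate))
  expect_true(all(sw$dimension == 100))
  swb <- run_sweep(f$al, heights = c(5, 10, 20, 40, 80),
                   scopes = c("location", "entire"), bonferroni = TRUE)
  expect_equal(swb$r, sw$r)
  expect_true(all(swb$significant <= sw$significant, na.rm = TRUE))
})

test_that("extract_cluster returns the right memberships and pair sims", {
  f <- small_aligned(seed = 61, n = 40, K = 4, coupling = 0.8)
  tree <- ward_linkage(f$al$sem_vectors)
  sol <- cut_at_k(tree, 4)
  g <- f$al$entries$gloss[c(1, 25)]
  ex <- extract_cluster(sol, f$al, g)
  expect_true(all(g %in% ex$membership$gloss))
  own <- sol$labels[match(g, f$al$entries$gloss)]
  expect_setequal(unique(ex$membership$cluster), unique(own))
  # pairs stay inside the matched clusters and carry similarity columns
  expect_true(all(sol$labels[ex$pairs$i] %in% own))
  expect_true(all(c("sem_sim", "phono_entire", "gloss_i") %in%
                  names(ex$pairs)))
  expect_warning(empty <- extract_cluster(sol, f$al, "not-a-gloss"),
                 "none of the query glosses")
  expect_equal(nrow(empty$membership), 0L)
})
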