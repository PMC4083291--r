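three_point_tree <- function() {
  d <- matrix(c(0, 1, 4,
                1, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  average_linkage_cluster(d)
}

test_that("group_distance is the mean of cross-group pairs", {
  d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3)
  expect_equal(group_distance(1, 2, d), 1)                # single pair
  expect_equal(group_distance(c(1, 2), 3, d), 4.5)        # (4 + 5) / 2
  expect_error(group_distance(c(1, 2), c(2, 3), d), "disjoint")
  expect_error(group_distance(integer(0), 1, d), "nonempty")

  set.seed(3)
  dm <- random_distance_matrix(12)
  for (rep in 1:10) {
    g1 <- sample(1:12, sample(1:5, 1))
    g2 <- sample(setdiff(1:12, g1), sample(1:5, 1))
    brute <- mean(vapply(g1, function(i) mean(dm[i, g2]), numeric(1)))
    expect_equal(group_distance(g1, g2, dm), brute, tolerance = 1e-12)
  }
})

test_that("tiny agglomerations match hand derivation", {
  t1 <- average_linkage_cluster(matrix(0, 1, 1))
  expect_identical(nrow(t1$merge), 0L)

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  t2 <- average_linkage_cluster(d2)
  expect_equal(t2$height, 0.3)

  t3 <- three_point_tree()
  expect_equal(t3$height, c(1, 4.5))     # merge (A,B) at 1, then +C at (4+5)/2
  expect_identical(t3$merged_size, c(2L, 3L))
})

test_that("agglomeration matches the from-scratch recomputation oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:30, 1)
    d <- random_distance_matrix(n)
    t <- average_linkage_cluster(d)
    orc <- oracle_average_linkage(d)
    expect_equal(t$height, orc$heights, tolerance = 1e-12)
    expect_identical(dendrogram_partitions(t), orc$partitions)
  }
})

test_that("merge heights agree with stats::hclust average linkage", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    d <- random_distance_matrix(n)
    t <- average_linkage_cluster(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(t$height, hc$height, tolerance = 1e-10)
  }
})

test_that("merge heights are non-decreasing", {
  set.seed(8)
  for (rep in 1:10) {
    t <- average_linkage_cluster(random_distance_matrix(sample(2:40, 1)))
    expect_true(all(diff(t$height) >= 0))
  }
})

test_that("count cuts partition the leaves into exactly k clusters", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    t <- average_linkage_cluster(random_distance_matrix(n))
    for (k in unique(c(1L, 2L, sample(1:n, 2), n))) {
      cs <- cut_dendrogram(t, k = k)
      expect_length(cs$clusters, k)
      all_members <- sort(unlist(cs$clusters))
      expect_identical(all_members, seq_len(n))   # disjoint and covering
    }
    expect_true(all(lengths(cut_dendrogram(t, k = n)$clusters) == 1L))
    expect_length(cut_dendrogram(t, k = 1)$clusters, 1L)
  }
  t3 <- three_point_tree()
  expect_identical(cut_dendrogram(t3, k = 2)$clusters, list(c(1L, 2L), 3L))
  expect_error(cut_dendrogram(t3, k = 0), "k must lie")
  expect_error(cut_dendrogram(t3, k = 4), "k must lie")
  expect_error(cut_dendrogram(t3, k = 2, h = 1), "exactly one")
})

test_that("height cuts use strict inequality", {
  t3 <- three_point_tree()
  expect_length(cut_dendrogram(t3, h = 0)$clusters, 3L)     # singletons
  expect_length(cut_dendrogram(t3, h = 1)$clusters, 3L)     # merge at 1 not < 1
  expect_length(cut_dendrogram(t3, h = 1.5)$clusters, 2L)
  expect_length(cut_dendrogram(t3, h = 10)$clusters, 1L)
})

test_that("leaf order is the constant minimal-index traversal", {
  t3 <- three_point_tree()
  ord <- leaf_order(t3)
  expect_identical(unname(ord), c(1L, 2L, 3L))
  expect_identical(names(ord), c("A", "B", "C"))
  expect_identical(leaf_order(t3), leaf_order(t3))  # deterministic

  set.seed(4)
  t <- average_linkage_cluster(random_distance_matrix(15))
  expect_identical(sort(unname(leaf_order(t))), 1:15)
})

test_that("relabeling genes permutes but does not change the partition", {
  set.seed(19)
  n <- 12
  d <- random_distance_matrix(n)
  perm <- sample(n)
  dp <- d[perm, perm]
  t1 <- average_linkage_cluster(d)
  t2 <- average_linkage_cluster(dp)
  for (k in c(2L, 5L, 9L)) {
    sig1 <- partition_signature(cut_dendrogram(t1, k = k)$clusters)
    # map permuted clusters back to original indices
    cl2 <- lapply(cut_dendrogram(t2, k = k)$clusters, function(g) perm[g])
    expect_identical(partition_signature(cl2), sig1)
  }
})

test_that("dendrograms export to Newick with all leaves", {
  t3 <- three_point_tree()
  nwk <- dendrogram_to_newick(t3)
  expect_match(nwk, "^\\(")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
})

test_that("invalid distance inputs are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)          # asymmetric
  expect_error(average_linkage_cluster(m), "symmetric")
  m2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(average_linkage_cluster(m2), "non-negative")
})
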