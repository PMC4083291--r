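#' Average-linkage distance between two gene groups
#'
#' The distance between two disjoint gene groups is the mean of all
#' cross-group pairwise distances,
#' \deqn{D(G_1, G_2) = \frac{1}{|G_1||G_2|} \sum_{i \in G_1} \sum_{j \in G_2} d_{ij}.}
#' This is the merge criterion of the agglomerative clustering step.
#'
#' @param g1,g2 disjoint, nonempty integer vectors of gene indices.
#' @param d a distance-mode [proximity_matrix()] (or plain symmetric,
#'   non-negative matrix with zero diagonal).
#' @return The mean cross-group distance, a non-negative number.
#' @examples
#' d <- matrix(c(0, 4, 5, 4, 0, 2, 5, 2, 0), 3, 3)
#' group_distance(c(1, 2), 3, d)  # (5 + 2) / 2 = 3.5
#' @export
group_distance <- function(g1, g2, d) {
  d <- check_distance_input(d)
  g1 <- as.integer(g1); g2 <- as.integer(g2)
  if (!length(g1) || !length(g2)) stop("groups must be nonempty", call. = FALSE)
  if (length(intersect(g1, g2))) stop("groups must be disjoint", call. = FALSE)
  if (any(c(g1, g2) < 1L) || any(c(g1, g2) > nrow(d))) {
    stop("group indices out of range for the distance matrix", call. = FALSE)
  }
  mean(d[g1, g2])
}

check_distance_input <- function(d) {
  if (inherits(d, "proximity_matrix")) {
    validate_proximity_matrix(d, mode = "distance")
    return(unclass(d))
  }
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !is.numeric(d)) {
    stop("distance input must be a square numeric matrix", call. = FALSE)
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be non-negative with zero diagonal",
         call. = FALSE)
  }
  d
}

#' Agglomerative average-linkage clustering
#'
#' Starting from singleton groups, repeatedly merges the pair of current
#' groups with the smallest [group_distance()], recording the merge height.
#' Pairwise group distances are maintained incrementally by the
#' Lance-Williams average-linkage update, which reproduces the full
#' cross-group mean exactly in exact arithmetic. When several pairs attain
#' the minimal distance, the pair whose (smaller minimal original leaf
#' index, larger minimal original leaf index) is lexicographically least is
#' merged, making the dendrogram fully deterministic.
#'
#' @param d a distance-mode [proximity_matrix()] or plain symmetric,
#'   non-negative matrix with zero diagonal; row/column names, if present,
#'   become leaf labels.
#' @return An object of class `"pcphc_dendrogram"`: a list with
#'   \describe{
#'     \item{n_leaves}{number of leaves.}
#'     \item{merge}{(n_leaves - 1) x 2 matrix in [stats::hclust()]
#'       convention: negative entries are leaves, positive entries earlier
#'       merges; the child with the smaller minimal original leaf index is
#'       in column 1.}
#'     \item{height}{merge heights, non-decreasing.}
#'     \item{merged_size}{leaf count of the group formed by each merge.}
#'     \item{labels}{leaf labels.}
#'   }
#' @seealso [cut_dendrogram()], [leaf_order()], [as.hclust.pcphc_dendrogram()]
#' @export
average_linkage_cluster <- function(d) {
  labels <- rownames(d)
  d <- check_distance_input(d)
  n <- nrow(d)
  if (is.null(labels)) labels <- paste0("g", seq_len(n))
  if (n < 1L) stop("distance matrix must have at least one row", call. = FALSE)

  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  merged_size <- integer(max(n - 1L, 0L))

  if (n >= 2L) {
    D <- d
    diag(D) <- Inf
    active <- rep(TRUE, n)
    size <- rep(1L, n)
    minidx <- seq_len(n)         # minimal original leaf index per group
    node <- -seq_len(n)          # hclust node id per active slot

    for (step in seq_len(n - 1L)) {
      idx <- which(active)
      sub <- D[idx, idx, drop = FALSE]
      mval <- min(sub)
      cand <- which(sub == mval, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      a <- idx[cand[, 1]]; b <- idx[cand[, 2]]
      lo <- pmin(minidx[a], minidx[b])
      hi <- pmax(minidx[a], minidx[b])
      pick <- order(lo, hi)[1]
      i <- a[pick]; j <- b[pick]
      if (minidx[j] < minidx[i]) { tmp <- i; i <- j; j <- tmp }

      merge[step, ] <- c(node[i], node[j])
      height[step] <- mval
      merged_size[step] <- size[i] + size[j]

      # Lance-Williams average-linkage update into slot i
      others <- idx[idx != i & idx != j]
      if (length(others)) {
        newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
          (size[i] + size[j])
        D[i, others] <- newd
        D[others, i] <- newd
      }
      size[i] <- size[i] + size[j]
      minidx[i] <- min(minidx[i], minidx[j])
      node[i] <- step
      active[j] <- FALSE
    }
  }

  structure(
    list(n_leaves = n, merge = merge, height = height,
         merged_size = merged_size, labels = labels),
    class = "pcphc_dendrogram"
  )
}

validate_dendrogram <- function(t) {
  if (!inherits(t, "pcphc_dendrogram")) {
    stop("expected a 'pcphc_dendrogram'", call. = FALSE)
  }
  if (nrow(t$merge) != t$n_leaves - 1L && t$n_leaves > 1L) {
    stop("dendrogram must record exactly n_leaves - 1 merges", call. = FALSE)
  }
  invisible(t)
}

#' @export
print.pcphc_dendrogram <- function(x, ...) {
  cat(sprintf("Average-linkage dendrogram: %d leaves, %d merges\n",
              x$n_leaves, nrow(x$merge)))
  if (length(x$height)) {
    cat(sprintf("Merge heights: %s\n",
                paste(format(range(x$height), digits = 4), collapse = " .. ")))
  }
  invisible(x)
}

#' Convert to a stats::hclust object
#'
#' @param x a `pcphc_dendrogram` with at least 2 leaves.
#' @param ... ignored.
#' @return An object of class `"hclust"` suitable for plotting and for
#'   conversion to `phylo` via [ape::as.phylo()].
#' @export
as.hclust.pcphc_dendrogram <- function(x, ...) {
  validate_dendrogram(x)
  if (x$n_leaves < 2L) {
    stop("an hclust object requires at least 2 leaves", call. = FALSE)
  }
  structure(
    list(merge = x$merge, height = x$height, order = leaf_order(x),
         labels = x$labels, method = "average",
         call = match.call(), dist.method = "1 - pearson"),
    class = "hclust"
  )
}

#' Cut a dendrogram into flat clusters
#'
#' Either into exactly `k` clusters (the k groups present after the first
#' `n_leaves - k` merges, i.e. after undoing the k - 1 highest merges), or
#' at height `h` (all maximal subtrees assembled by merges of height
#' strictly below `h`; `h = 0` therefore returns singletons).
#'
#' @param t a `pcphc_dendrogram`.
#' @param k target number of clusters, `1 <= k <= n_leaves`.
#' @param h non-negative height threshold. Give exactly one of `k`, `h`.
#' @return An object of class `"cluster_set"`: list with `clusters` (list
#'   of increasing integer vectors of leaf indices, ordered by smallest
#'   member), `ids` (the same as label vectors), and `cut_spec`.
#' @export
cut_dendrogram <- function(t, k = NULL, h = NULL) {
  validate_dendrogram(t)
  if (is.null(k) == is.null(h)) {
    stop("give exactly one of 'k' or 'h'", call. = FALSE)
  }
  n <- t$n_leaves
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > n) {
      stop(sprintf("k must lie in [1, %d]", n), call. = FALSE)
    }
    n_apply <- n - k
  } else {
    if (!is.finite(h) || h < 0) stop("h must be >= 0", call. = FALSE)
    n_apply <- sum(t$height < h)
  }

  group <- seq_len(n)
  node_group <- integer(nrow(t$merge))   # group id of each applied merge node
  for (s in seq_len(n_apply)) {
    ch <- t$merge[s, ]
    ga <- if (ch[1] < 0) group[-ch[1]] else node_group[ch[1]]
    gb <- if (ch[2] < 0) group[-ch[2]] else node_group[ch[2]]
    keep <- min(ga, gb); drop <- max(ga, gb)
    if (keep != drop) group[group == drop] <- keep
    node_group[s] <- keep
  }
  cl <- split(seq_len(n), group)
  cl <- cl[order(vapply(cl, min, integer(1)))]
  names(cl) <- NULL
  cl <- lapply(cl, sort)
  structure(
    list(clusters = cl,
         ids = lapply(cl, function(ix) t$labels[ix]),
         cut_spec = if (!is.null(k)) list(k = k) else list(h = h)),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("Cluster set: %d clusters (sizes %s)\n", length(sizes),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Deterministic dendrogram leaf ordering
#'
#' Left-to-right leaf traversal with a constant node-ordering rule: at
#' every internal node the child whose minimal original leaf index is
#' smaller is placed on the left. Running it twice on the same dendrogram
#' always yields the same permutation, so a reordered heatmap of the
#' matrix is reproducible.
#'
#' @param t a `pcphc_dendrogram`.
#' @return An integer permutation of `1:n_leaves` (original leaf indices),
#'   named by the leaf labels.
#' @export
leaf_order <- function(t) {
  validate_dendrogram(t)
  n <- t$n_leaves
  if (n == 1L) return(stats::setNames(1L, t$labels))
  leaves_of <- vector("list", nrow(t$merge))
  for (s in seq_len(nrow(t$merge))) {
    ch <- t$merge[s, ]
    left <- if (ch[1] < 0) -ch[1] else leaves_of[[ch[1]]]
    right <- if (ch[2] < 0) -ch[2] else leaves_of[[ch[2]]]
    if (min(left) <= min(right)) leaves_of[[s]] <- c(left, right)
    else leaves_of[[s]] <- c(right, left)
  }
  ord <- leaves_of[[nrow(t$merge)]]
  stats::setNames(as.integer(ord), t$labels[ord])
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights (via the `hclust` ->
#' `phylo` conversion), so ultrametric tree viewers reproduce the merge
#' structure.
#'
#' @param t a `pcphc_dendrogram` with >= 2 leaves.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return The Newick string (invisibly if written to `path`).
#' @export
dendrogram_to_newick <- function(t, path = NULL) {
  phy <- ape::as.phylo(as.hclust.pcphc_dendrogram(t))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write a cluster set as two-column TSV
#'
#' Columns: `gene_id`, `cluster_id` (1-based, in cluster-set order).
#'
#' @param cs a `cluster_set`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_cluster_set <- function(cs, path) {
  if (!inherits(cs, "cluster_set")) stop("expected a 'cluster_set'",
                                         call. = FALSE)
  gene <- unlist(cs$ids, use.names = FALSE)
  cluster <- rep(seq_along(cs$ids), lengths(cs$ids))
  utils::write.table(
    data.frame(gene_id = gene, cluster_id = cluster),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
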