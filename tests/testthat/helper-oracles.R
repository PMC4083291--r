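# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Pearson correlation straight from the definition
oracle_pearson <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / (sqrt(sum(da^2)) * sqrt(sum(db^2)))
}

# Full agglomeration recomputing the mean cross-group distance from the
# original matrix at every step (no incremental updates). Tie-break:
# lexicographically least (smaller minimal original index, larger minimal
# original index). Returns merge heights and the partition after each
# merge as a canonical string signature.
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  groups <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- character(0)
  while (length(groups) > 1L) {
    g <- length(groups)
    best <- NULL
    for (i in seq_len(g - 1L)) {
      for (j in seq(i + 1L, g)) {
        dist_ij <- mean(d[groups[[i]], groups[[j]]])
        lo <- min(min(groups[[i]]), min(groups[[j]]))
        hi <- max(min(groups[[i]]), min(groups[[j]]))
        if (is.null(best) || dist_ij < best$d ||
            (dist_ij == best$d &&
             (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
          best <- list(d = dist_ij, i = i, j = j, lo = lo, hi = hi)
        }
      }
    }
    merged <- sort(c(groups[[best$i]], groups[[best$j]]))
    groups <- c(groups[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$d)
    partitions <- c(partitions, partition_signature(groups))
  }
  list(heights = heights, partitions = partitions)
}

# canonical string for a set of index groups
partition_signature <- function(groups) {
  sig <- vapply(groups, function(g) paste(sort(g), collapse = ","),
                character(1))
  paste(sort(sig), collapse = ";")
}

# partition sequence implied by a pcphc dendrogram's merge table
dendrogram_partitions <- function(t) {
  n <- t$n_leaves
  members <- lapply(seq_len(n), identity)   # leaves
  node_members <- vector("list", nrow(t$merge))
  current <- lapply(seq_len(n), identity)
  out <- character(0)
  for (s in seq_len(nrow(t$merge))) {
    ch <- t$merge[s, ]
    a <- if (ch[1] < 0) members[[-ch[1]]] else node_members[[ch[1]]]
    b <- if (ch[2] < 0) members[[-ch[2]]] else node_members[[ch[2]]]
    node_members[[s]] <- sort(c(a, b))
    keep <- vapply(current, function(g) !any(g %in% node_members[[s]]),
                   logical(1))
    current <- c(current[keep], list(node_members[[s]]))
    out <- c(out, partition_signature(current))
  }
  out
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  if (n > 1L) {
    v <- runif(n * (n - 1) / 2, 0.05, 2)
    d[upper.tri(d)] <- v
    d <- d + t(d)
  }
  d
}

# scalar order-support check written as an explicit loop
oracle_supports <- function(row, ord, e_max = 0, tie_tol = 1e-9) {
  viol <- 0L
  for (i in seq_len(length(ord) - 1L)) {
    if (row[ord[i]] >= row[ord[i + 1L]] - tie_tol) viol <- viol + 1L
  }
  viol / (length(ord) - 1L) <= e_max
}

# exhaustive maximality re-check: no absent row supports the order, and
# no (column, insertion position) reaches the row-support requirement
oracle_is_maximal <- function(p, x, e_max = 0, h_min = 0, tie_tol = 1e-9) {
  for (r in setdiff(seq_len(nrow(x)), p$rows)) {
    if (oracle_supports(x[r, ], p$order, e_max, tie_tol)) return(FALSE)
  }
  nr <- length(p$rows)
  required <- if (h_min <= 0) nr else ceiling(h_min * nr)
  for (col in setdiff(seq_len(ncol(x)), p$order)) {
    for (pos in seq_len(length(p$order) + 1L)) {
      ext <- append(p$order, col, after = pos - 1L)
      supp <- sum(vapply(p$rows, function(r) {
        oracle_supports(x[r, ], ext, e_max, tie_tol)
      }, logical(1)))
      if (supp >= required) return(FALSE)
    }
  }
  TRUE
}

# small helper: random expression matrix with row-distinct values
random_expression_matrix <- function(n, m, sd = 1) {
  expression_matrix(matrix(rnorm(n * m, sd = sd), n, m))
}
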