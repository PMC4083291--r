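#' Growth thresholds for pattern expansion
#'
#' @param e_max tolerated fraction of order-violating adjacent column pairs
#'   per row, in `[0, 1]`. `0` demands a strictly order-preserving row.
#' @param h_min minimum fraction of current pattern rows that must support
#'   a candidate column addition, in `[0, 1]`. `0` (the default, matching
#'   strict pattern mining) is interpreted as the all-rows rule: every
#'   pattern row must support the addition. A literal "0 rows" rule would
#'   admit every column and make growth meaningless.
#' @param tie_tol two values closer than this are treated as tied; a tie
#'   counts against a strict ordering.
#' @return A list of class `"pcphc_thresholds"`.
#' @export
thresholds <- function(e_max = 0, h_min = 0, tie_tol = 1e-9) {
  if (!is.finite(e_max) || e_max < 0 || e_max > 1) {
    stop("e_max must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(h_min) || h_min < 0 || h_min > 1) {
    stop("h_min must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(tie_tol) || tie_tol < 0) {
    stop("tie_tol must be a non-negative number", call. = FALSE)
  }
  structure(list(e_max = e_max, h_min = h_min, tie_tol = tie_tol),
            class = "pcphc_thresholds")
}

as_thresholds <- function(th) {
  if (inherits(th, "pcphc_thresholds")) return(th)
  do.call(thresholds, as.list(th))
}

check_order <- function(order, m) {
  order <- as.integer(order)
  if (length(order) < 2L) stop("a column order needs length >= 2",
                               call. = FALSE)
  if (anyDuplicated(order)) stop("column order contains duplicates",
                                 call. = FALSE)
  if (any(order < 1L) || any(order > m)) {
    stop("column order indices out of range", call. = FALSE)
  }
  order
}

# per-row count of adjacent order violations; x is a numeric matrix
order_violation_counts <- function(x, order, tie_tol) {
  a <- x[, order[-length(order)], drop = FALSE]
  b <- x[, order[-1L], drop = FALSE]
  rowSums(a >= b - tie_tol)
}

#' Does a row support a column order?
#'
#' A row supports a linear order of columns when its values increase
#' strictly along the order, up to a tolerated fraction `e_max` of
#' violating adjacent pairs. An adjacent pair `(c_a, c_b)` is a violation
#' when `row[c_a] >= row[c_b] - tie_tol`, i.e. ties count as violations.
#'
#' @param row_values numeric vector of one gene row.
#' @param order integer vector of column indices, length >= 2, no
#'   duplicates.
#' @param e_max tolerated violation fraction (see [thresholds()]).
#' @param tie_tol tie tolerance.
#' @return `TRUE` iff `violations / (length(order) - 1) <= e_max`.
#' @examples
#' supports_order(c(1, 2, 3), c(1, 2, 3))        # TRUE
#' supports_order(c(3, 1, 2), c(1, 2, 3))        # FALSE
#' @export
supports_order <- function(row_values, order, e_max = 0, tie_tol = 1e-9) {
  order <- check_order(order, length(row_values))
  x <- matrix(as.numeric(row_values), nrow = 1L)
  v <- order_violation_counts(x, order, tie_tol)
  v / (length(order) - 1L) <= e_max
}

#' Consensus column order of a gene set
#'
#' Orders all columns by their mean value over the given rows, ascending;
#' ties broken by column index. For a tight cluster of co-expressed genes
#' this is the consensus linear order its members most nearly follow.
#'
#' @param rows integer vector of gene (row) indices, nonempty.
#' @param em an `expr_matrix` or numeric matrix.
#' @return Integer vector of all column indices in consensus order.
#' @export
derive_seed_order <- function(rows, em) {
  x <- unclass(as_expression_matrix(em))
  rows <- as.integer(rows)
  if (!length(rows)) stop("seed row set must be nonempty", call. = FALSE)
  if (any(rows < 1L) || any(rows > nrow(x))) {
    stop("seed row indices out of range", call. = FALSE)
  }
  mu <- colMeans(x[rows, , drop = FALSE])
  order(mu, seq_along(mu))
}

#' Count rows supporting a column order
#'
#' @param em an `expr_matrix` or numeric matrix.
#' @param order integer column order, length >= 2.
#' @param e_max tolerated violation fraction.
#' @param tie_tol tie tolerance.
#' @return Number of gene rows satisfying [supports_order()].
#' @export
count_order_support <- function(em, order, e_max = 0, tie_tol = 1e-9) {
  x <- unclass(as_expression_matrix(em))
  if (nrow(x) == 0L) return(0L)
  order <- check_order(order, ncol(x))
  v <- order_violation_counts(x, order, tie_tol)
  sum(v / (length(order) - 1L) <= e_max)
}

#' Construct a pattern
#'
#' A pattern (a GL-PCPHC bicluster) is a set of gene rows together with a
#' linear order over a subset of columns such that the rows' values
#' increase along the order within the thresholds.
#'
#' @param rows integer vector of gene indices, >= 2 of them.
#' @param order integer vector of column indices in pattern order,
#'   length >= 2.
#' @param em the `expr_matrix` the indices refer to.
#' @param th [thresholds()] the pattern is held to.
#' @param maximal logical maximality flag (set by [grow_to_maximal()]).
#' @return A list of class `"pcphc_pattern"` with elements `rows`, `order`,
#'   `gene_ids`, `sample_order`, `support` (number of rows fully
#'   satisfying [supports_order()] under `e_max`), `maximal`, and the
#'   thresholds used.
#' @export
new_pattern <- function(rows, order, em, th = thresholds(), maximal = FALSE) {
  em <- as_expression_matrix(em)
  th <- as_thresholds(th)
  rows <- sort(unique(as.integer(rows)))
  order <- check_order(order, ncol(em))
  if (length(rows) < 2L) stop("a pattern needs >= 2 rows", call. = FALSE)
  if (any(rows < 1L) || any(rows > nrow(em))) {
    stop("pattern row indices out of range", call. = FALSE)
  }
  x <- unclass(em)
  v <- order_violation_counts(x[rows, , drop = FALSE], order, th$tie_tol)
  support <- sum(v / (length(order) - 1L) <= th$e_max)
  structure(
    list(rows = rows, order = order,
         gene_ids = rownames(em)[rows],
         sample_order = colnames(em)[order],
         support = support, maximal = isTRUE(maximal), thresholds = th),
    class = "pcphc_pattern"
  )
}

#' @export
print.pcphc_pattern <- function(x, ...) {
  cat(sprintf(
    "Pattern: %d rows x %d columns, support %d/%d%s\n",
    length(x$rows), length(x$order), x$support, length(x$rows),
    if (x$maximal) ", maximal" else ""))
  cat("Column order:", paste(x$sample_order, collapse = " < "), "\n")
  invisible(x)
}

# support counts for inserting column `col` at position `pos` (1 = front)
# into p$order, for each row of `x` (a matrix already subset to the rows
# of interest); base_v = violation counts of the current order.
insertion_violations <- function(x, ord, base_v, col, pos, tie_tol) {
  len <- length(ord)
  v <- base_v
  if (pos > 1L && pos <= len) {
    # existing adjacency (ord[pos-1], ord[pos]) is replaced
    v <- v - (x[, ord[pos - 1L]] >= x[, ord[pos]] - tie_tol)
  }
  if (pos > 1L) v <- v + (x[, ord[pos - 1L]] >= x[, col] - tie_tol)
  if (pos <= len) v <- v + (x[, col] >= x[, ord[pos]] - tie_tol)
  v
}

#' Expand a pattern by its best column
#'
#' Considers every column not yet in the pattern order and every insertion
#' position, and selects the candidate supported (under `e_max`) by the
#' largest number of pattern rows. The candidate qualifies only if that
#' number reaches the row-support requirement: all pattern rows under the
#' default `h_min = 0`, otherwise `ceiling(h_min * |rows|)`. Ties are
#' broken toward the smallest column index, then the earliest insertion
#' position. If no candidate qualifies the pattern is returned unchanged.
#'
#' @param p a `pcphc_pattern`.
#' @param em the `expr_matrix` the pattern lives in.
#' @param th [thresholds()].
#' @return The (possibly) extended pattern.
#' @export
column_expand <- function(p, em, th = p$thresholds) {
  em <- as_expression_matrix(em)
  th <- as_thresholds(th)
  check_pattern_against(p, em)
  ord <- p$order
  m <- ncol(em)
  remaining <- setdiff(seq_len(m), ord)
  if (!length(remaining)) return(p)

  x <- unclass(em)[p$rows, , drop = FALSE]
  nr <- nrow(x)
  required <- if (th$h_min <= 0) nr else ceiling(th$h_min * nr)
  base_v <- order_violation_counts(x, ord, th$tie_tol)
  new_len <- length(ord) + 1L

  best <- NULL  # list(support, col, pos)
  for (col in remaining) {
    for (pos in seq_len(new_len)) {
      v <- insertion_violations(x, ord, base_v, col, pos, th$tie_tol)
      supp <- sum(v / (new_len - 1L) <= th$e_max)
      if (supp >= required &&
          (is.null(best) || supp > best$support)) {
        best <- list(support = supp, col = col, pos = pos)
      }
    }
  }
  if (is.null(best)) return(p)
  new_ord <- append(ord, best$col, after = best$pos - 1L)
  new_pattern(p$rows, new_ord, em, th)
}

#' Expand a pattern by all supporting rows
#'
#' Adds every gene not yet in the pattern whose row satisfies
#' [supports_order()] for the pattern's column order under `e_max`.
#'
#' @inheritParams column_expand
#' @return The (possibly) extended pattern.
#' @export
row_expand <- function(p, em, th = p$thresholds) {
  em <- as_expression_matrix(em)
  th <- as_thresholds(th)
  check_pattern_against(p, em)
  x <- unclass(em)
  outside <- setdiff(seq_len(nrow(x)), p$rows)
  if (!length(outside)) return(p)
  v <- order_violation_counts(x[outside, , drop = FALSE], p$order, th$tie_tol)
  add <- outside[v / (length(p$order) - 1L) <= th$e_max]
  if (!length(add)) return(p)
  new_pattern(c(p$rows, add), p$order, em, th)
}

check_pattern_against <- function(p, em) {
  if (!inherits(p, "pcphc_pattern")) stop("expected a 'pcphc_pattern'",
                                          call. = FALSE)
  if (any(p$rows > nrow(em)) || any(p$order > ncol(em))) {
    stop("pattern indices exceed matrix dimensions", call. = FALSE)
  }
  invisible(p)
}

#' Grow a seed pattern to maximality
#'
#' Alternates [column_expand()] and [row_expand()] until neither changes
#' the pattern. The column-centric strategy drives column insertion to a
#' fixpoint before each row sweep; the row-centric strategy sweeps rows
#' first. Growth is monotone: the seed's rows are a subset of the result's
#' rows and the seed's order is a subsequence of the result's order. Each
#' step enlarges the pattern, so the loop terminates after at most
#' `nrow + ncol` expansions.
#'
#' @inheritParams column_expand
#' @param strategy `"column_centric"` or `"row_centric"`.
#' @return The grown pattern with `maximal = TRUE`.
#' @export
grow_to_maximal <- function(p, em,
                            th = p$thresholds,
                            strategy = c("column_centric", "row_centric")) {
  strategy <- match.arg(strategy)
  em <- as_expression_matrix(em)
  th <- as_thresholds(th)
  check_pattern_against(p, em)

  col_fix <- function(q) {
    repeat {
      q2 <- column_expand(q, em, th)
      if (length(q2$order) == length(q$order)) return(q)
      q <- q2
    }
  }
  repeat {
    before <- c(length(p$rows), length(p$order))
    if (strategy == "column_centric") {
      p <- col_fix(p)
      p <- row_expand(p, em, th)
    } else {
      p <- row_expand(p, em, th)
      p <- col_fix(p)
    }
    if (identical(before, c(length(p$rows), length(p$order)))) break
  }
  p$maximal <- TRUE
  p
}

#' Re-check a pattern's maximality exhaustively
#'
#' Confirms that no absent row supports the pattern's order and that no
#' (column, insertion position) candidate meets the row-support
#' requirement. Used to validate the `maximal` flag.
#'
#' @inheritParams column_expand
#' @return `TRUE` or `FALSE`.
#' @export
pattern_is_maximal <- function(p, em, th = p$thresholds) {
  em <- as_expression_matrix(em)
  th <- as_thresholds(th)
  check_pattern_against(p, em)
  x <- unclass(em)
  outside <- setdiff(seq_len(nrow(x)), p$rows)
  if (length(outside)) {
    v <- order_violation_counts(x[outside, , drop = FALSE], p$order,
                                th$tie_tol)
    if (any(v / (length(p$order) - 1L) <= th$e_max)) return(FALSE)
  }
  xr <- x[p$rows, , drop = FALSE]
  nr <- nrow(xr)
  required <- if (th$h_min <= 0) nr else ceiling(th$h_min * nr)
  new_len <- length(p$order) + 1L
  for (col in setdiff(seq_len(ncol(x)), p$order)) {
    for (pos in seq_len(new_len)) {
      ext <- append(p$order, col, after = pos - 1L)
      v <- order_violation_counts(xr, ext, th$tie_tol)
      if (sum(v / (new_len - 1L) <= th$e_max) >= required) return(FALSE)
    }
  }
  TRUE
}

#' Order-consistency quality of a pattern
#'
#' The fraction of (row, adjacent column pair) comparisons that satisfy
#' the pattern's ordering: 1 means every row follows the order strictly.
#' Patterns mined with `e_max = 0` always score 1.
#'
#' @inheritParams column_expand
#' @return A number in `[0, 1]`.
#' @export
pattern_quality <- function(p, em) {
  em <- as_expression_matrix(em)
  check_pattern_against(p, em)
  th <- as_thresholds(p$thresholds)
  x <- unclass(em)[p$rows, , drop = FALSE]
  v <- order_violation_counts(x, p$order, th$tie_tol)
  total <- nrow(x) * (length(p$order) - 1L)
  1 - sum(v) / total
}

# Build the seed pattern for one dendrogram cluster.
#
# The cluster's consensus (mean) column order is almost never supported by
# every member row under a strict e_max -- hierarchical clusters carry the
# odd stray gene -- so the seed is distilled in two moves. First, the
# adjacent pair of the consensus order supported by the most cluster rows
# becomes the initial order, and the seed rows shrink to its supporters.
# Second, the order is extended greedily: at each step the (column,
# position) insertion supported by the most current seed rows is accepted
# while that support reaches at least `seed_support` of them, and the seed
# rows shrink to the supporters of the extended order. A stray row that
# supports one pair by chance rarely supports the next insertion, so the
# seed converges to the coherent core of the cluster; the strict
# grow_to_maximal() expansion then starts from rows that all support a
# long order. Returns NULL when the cluster yields no pair with >= 2
# supporting rows.
seed_pattern <- function(rows, em, th, seed_support = 0.85) {
  x <- unclass(em)
  ord_full <- derive_seed_order(rows, em)
  xr <- x[rows, , drop = FALSE]
  best <- NULL
  for (i in seq_len(length(ord_full) - 1L)) {
    pair <- ord_full[c(i, i + 1L)]
    ok <- xr[, pair[1]] < xr[, pair[2]] - th$tie_tol
    supp <- sum(ok)
    if (supp >= 2L && (is.null(best) || supp > best$supp)) {
      best <- list(supp = supp, pair = pair, ok = ok)
    }
  }
  if (is.null(best)) return(NULL)

  ord <- best$pair
  r <- rows[best$ok]
  m <- ncol(x)
  repeat {
    xs <- x[r, , drop = FALSE]
    base_v <- order_violation_counts(xs, ord, th$tie_tol)
    new_len <- length(ord) + 1L
    cand <- NULL
    for (col in setdiff(seq_len(m), ord)) {
      for (pos in seq_len(new_len)) {
        v <- insertion_violations(xs, ord, base_v, col, pos, th$tie_tol)
        keep <- v / (new_len - 1L) <= th$e_max
        supp <- sum(keep)
        if (supp >= 2L && (is.null(cand) || supp > cand$supp)) {
          cand <- list(supp = supp, col = col, pos = pos, keep = keep)
        }
      }
    }
    if (is.null(cand) || cand$supp < ceiling(seed_support * length(r))) break
    ord <- append(ord, cand$col, after = cand$pos - 1L)
    r <- r[cand$keep]
  }
  new_pattern(r, ord, em, th)
}

#' Mine maximal order-preserving patterns from an expression matrix
#'
#' The full pipeline: Pearson proximity -> `1 - r` distance ->
#' average-linkage dendrogram -> cut into `k_seeds` clusters -> each
#' cluster of size >= 2 seeds a pattern (its best-supported adjacent pair
#' from the cluster's consensus column order) -> [grow_to_maximal()] ->
#' deduplicate identical patterns -> sort by pattern area
#' (`rows x order length`) descending, ties by first gene index.
#'
#' @param em an `expr_matrix` (or coercible) with >= 2 genes and >= 2
#'   samples.
#' @param k_seeds number of dendrogram clusters used as seeds; default
#'   `max(1, floor(n_genes / 3))` so the mean cluster holds >= 3 genes.
#' @param th [thresholds()].
#' @param strategy growth strategy, see [grow_to_maximal()].
#' @param zero_var policy for constant gene rows, see [proximity_matrix()].
#' @param seed_support consensus fraction used while distilling a cluster
#'   into its seed order: an insertion is accepted during seed
#'   construction while at least this fraction of the current seed rows
#'   supports it (the seed rows then shrink to the supporters). Strict
#'   all-rows growth only starts from the distilled seed.
#' @return A list of `pcphc_pattern` objects (possibly empty), of class
#'   `"pcphc_patterns"`.
#' @export
mine_patterns <- function(em, k_seeds = NULL, th = thresholds(),
                          strategy = c("column_centric", "row_centric"),
                          zero_var = c("error", "drop"),
                          seed_support = 0.85) {
  strategy <- match.arg(strategy)
  em <- as_expression_matrix(em)
  th <- as_thresholds(th)
  if (nrow(em) < 2L || ncol(em) < 2L) {
    stop("pattern mining needs >= 2 genes and >= 2 samples", call. = FALSE)
  }
  if (is.null(k_seeds)) k_seeds <- max(1L, nrow(em) %/% 3L)
  k_seeds <- as.integer(k_seeds)

  pr <- proximity_matrix(em, zero_var = zero_var)
  d <- correlation_to_distance(pr)
  dend <- average_linkage_cluster(d)
  k_seeds <- min(k_seeds, dend$n_leaves)
  cs <- cut_dendrogram(dend, k = k_seeds)

  # proximity_matrix may have dropped rows: map back to em indices
  idx_map <- match(rownames(pr), rownames(em))

  patterns <- list()
  for (cl in cs$clusters) {
    rows <- idx_map[cl]
    if (length(rows) < 2L) next
    seed <- seed_pattern(rows, em, th, seed_support = seed_support)
    if (is.null(seed)) next
    patterns[[length(patterns) + 1L]] <-
      grow_to_maximal(seed, em, th, strategy)
  }

  if (length(patterns)) {
    key <- vapply(patterns, function(p) {
      paste(paste(p$rows, collapse = ","), paste(p$order, collapse = ","),
            sep = "|")
    }, character(1))
    patterns <- patterns[!duplicated(key)]
    area <- vapply(patterns, function(p) length(p$rows) * length(p$order),
                   numeric(1))
    first_gene <- vapply(patterns, function(p) p$rows[1], numeric(1))
    patterns <- patterns[order(-area, first_gene)]
  }
  structure(patterns, class = "pcphc_patterns")
}

#' @export
print.pcphc_patterns <- function(x, ...) {
  cat(sprintf("%d maximal pattern(s)\n", length(x)))
  for (i in seq_along(utils::head(x, 10L))) {
    p <- x[[i]]
    cat(sprintf("  [%d] %d rows x %d cols, support %d\n",
                i, length(p$rows), length(p$order), p$support))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Write patterns as JSON lines
#'
#' One JSON object per line:
#' `{"rows": [...], "column_order": [...], "support": n, "quality": q}`
#' with gene and sample identifiers.
#'
#' @param patterns a `pcphc_patterns` list.
#' @param em the matrix they were mined from (for [pattern_quality()]).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_patterns_jsonl <- function(patterns, em, path) {
  em <- as_expression_matrix(em)
  lines <- vapply(patterns, function(p) {
    jsonlite::toJSON(
      list(rows = p$gene_ids, column_order = p$sample_order,
           support = p$support, quality = pattern_quality(p, em)),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pattern summary table
#'
#' TSV with columns `pattern_id`, `n_rows`, `n_cols`, `quality`.
#'
#' @inheritParams write_patterns_jsonl
#' @return `path` invisibly.
#' @export
write_pattern_summary <- function(patterns, em, path) {
  em <- as_expression_matrix(em)
  df <- data.frame(
    pattern_id = seq_along(patterns),
    n_rows = vapply(patterns, function(p) length(p$rows), integer(1)),
    n_cols = vapply(patterns, function(p) length(p$order), integer(1)),
    quality = vapply(patterns, function(p) pattern_quality(p, em),
                     numeric(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
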