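#' Fit the full correlation-proximity pattern-mining pipeline
#'
#' The one-call interface: computes the Pearson proximity matrix of the
#' gene rows, converts it to the `1 - r` dissimilarity, builds the
#' average-linkage dendrogram, cuts it into `k` seed clusters, and grows
#' each cluster seed into a maximal order-preserving pattern with the
#' Seed-Augment procedure. All intermediates are kept on the returned
#' object so the dendrogram, the flat clusters and the mined patterns can
#' be inspected, plotted and exported.
#'
#' @param x an `expr_matrix`, or a numeric matrix / data.frame coercible
#'   via [as_expression_matrix()]; rows are genes, columns samples.
#' @param k number of dendrogram clusters used as pattern seeds; default
#'   `max(1, floor(n_genes / 3))` (mean seed cluster of >= 3 genes).
#' @param e_max tolerated per-row fraction of order-violating adjacent
#'   column pairs (default 0: strict order preservation).
#' @param h_min minimum fraction of pattern rows that must support a
#'   column addition; 0 (default) means all rows must support.
#' @param tie_tol tie tolerance for value comparisons.
#' @param strategy `"column_centric"` (default) or `"row_centric"` growth.
#' @param zero_var policy for constant gene rows (`"error"` or `"drop"`).
#' @param seed_support consensus fraction for seed distillation, see
#'   [mine_patterns()].
#' @return An object of class `"pcphc"`: list with `matrix`, `proximity`,
#'   `distance`, `dendrogram`, `clusters`, `patterns`, `thresholds`,
#'   `strategy`, `k`, and `call`.
#' @examples
#' sim <- generate_matrix(synthetic_spec(30, 8, list(list(n_rows = 8, n_cols = 4)),
#'                                       noise_sd = 0.05, rng_seed = 42))
#' fit <- pcphc(sim$matrix)
#' fit
#' summary(fit)
#' @export
pcphc <- function(x, k = NULL, e_max = 0, h_min = 0, tie_tol = 1e-9,
                  strategy = c("column_centric", "row_centric"),
                  zero_var = c("error", "drop"), seed_support = 0.85) {
  strategy <- match.arg(strategy)
  zero_var <- match.arg(zero_var)
  em <- as_expression_matrix(x)
  th <- thresholds(e_max = e_max, h_min = h_min, tie_tol = tie_tol)
  if (is.null(k)) k <- max(1L, nrow(em) %/% 3L)
  k <- as.integer(k)

  pr <- proximity_matrix(em, zero_var = zero_var)
  d <- correlation_to_distance(pr)
  dend <- average_linkage_cluster(d)
  cs <- cut_dendrogram(dend, k = min(k, dend$n_leaves))
  pats <- mine_patterns(em, k_seeds = k, th = th, strategy = strategy,
                        zero_var = zero_var, seed_support = seed_support)

  structure(
    list(matrix = em, proximity = pr, distance = d, dendrogram = dend,
         clusters = cs, patterns = pats, thresholds = th,
         strategy = strategy, k = k, call = match.call()),
    class = "pcphc"
  )
}

#' @export
print.pcphc <- function(x, ...) {
  cat("Correlation-proximity hierarchical pattern mining\n")
  cat(sprintf("  %d genes x %d samples; %d seed clusters (%s strategy)\n",
              nrow(x$matrix), ncol(x$matrix), x$k, x$strategy))
  cat(sprintf("  thresholds: e_max = %g, h_min = %g\n",
              x$thresholds$e_max, x$thresholds$h_min))
  cat(sprintf("  %d maximal pattern(s) mined\n", length(x$patterns)))
  invisible(x)
}

#' Summarize a fitted pattern-mining object
#'
#' @param object a `pcphc` fit.
#' @param ... ignored.
#' @return A data.frame (class `"summary.pcphc"` attached to a list) with
#'   one row per mined pattern: size, column order length, support and
#'   order-consistency quality.
#' @export
summary.pcphc <- function(object, ...) {
  pats <- object$patterns
  tab <- data.frame(
    pattern = seq_along(pats),
    n_rows = vapply(pats, function(p) length(p$rows), integer(1)),
    n_cols = vapply(pats, function(p) length(p$order), integer(1)),
    support = vapply(pats, function(p) p$support, integer(1)),
    quality = vapply(pats, function(p) pattern_quality(p, object$matrix),
                     numeric(1))
  )
  structure(list(fit = object, table = tab), class = "summary.pcphc")
}

#' @export
print.summary.pcphc <- function(x, ...) {
  print(x$fit)
  if (nrow(x$table)) {
    cat("\nPatterns:\n")
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted pattern-mining object
#'
#' Draws the average-linkage dendrogram with the deterministic leaf
#' ordering; the cut producing the seed clusters is marked when it falls
#' at a finite height.
#'
#' @param x a `pcphc` fit.
#' @param ... passed to [plot.hclust()].
#' @return `x` invisibly.
#' @export
plot.pcphc <- function(x, ...) {
  hc <- as.hclust.pcphc_dendrogram(x$dendrogram)
  plot(hc, xlab = "genes", sub = "", main = "Average-linkage dendrogram",
       ...)
  n <- x$dendrogram$n_leaves
  if (x$k > 1L && x$k < n) {
    h <- mean(x$dendrogram$height[(n - x$k):(n - x$k + 1L)])
    graphics::abline(h = h, lty = 2, col = "grey40")
  }
  invisible(x)
}
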