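#' Pearson correlation proximity between two gene vectors
#'
#' The proximity between two genes is the Pearson correlation of their
#' expression vectors,
#' \deqn{r(a, b) = \frac{\sum_j (a_j - \bar a)(b_j - \bar b)}
#'   {\|a - \bar a\| \, \|b - \bar b\|},}
#' clamped to \eqn{[-1, 1]} against floating-point overshoot. Both vectors
#' must have length at least 2 and nonzero variance.
#'
#' @param a,b numeric vectors of equal length.
#' @return The correlation, a number in `[-1, 1]`.
#' @examples
#' pearson_proximity(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pearson_proximity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop(sprintf("vector lengths differ (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  }
  if (length(a) < 2L) stop("vectors must have length >= 2", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("vectors must be finite", call. = FALSE)
  }
  da <- a - mean(a); db <- b - mean(b)
  na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
  if (na == 0 || nb == 0) {
    stop("zero-variance vector: correlation is undefined for a constant ",
         "gene profile", call. = FALSE)
  }
  r <- sum(da * db) / (na * nb)
  min(1, max(-1, r))
}

#' Pairwise gene proximity matrix
#'
#' Applies [pearson_proximity()] to every pair of gene rows of an
#' expression matrix, giving a symmetric correlation matrix with unit
#' diagonal. Constant (zero-variance) gene rows are undefined under the
#' correlation; they are either rejected or dropped with a warning.
#'
#' @param em an `expr_matrix` (or coercible matrix) with >= 2 samples.
#' @param zero_var `"error"` (default) rejects constant rows, naming them;
#'   `"drop"` removes them with a warning.
#' @return A matrix of class `"proximity_matrix"` with
#'   `attr(, "mode") == "correlation"`.
#' @export
proximity_matrix <- function(em, zero_var = c("error", "drop")) {
  zero_var <- match.arg(zero_var)
  em <- as_expression_matrix(em)
  if (ncol(em) < 2L) {
    stop("at least 2 samples are required to correlate gene profiles",
         call. = FALSE)
  }
  x <- unclass(em)
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(x)[v == 0]
    if (zero_var == "error") {
      stop("zero-variance gene rows: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping zero-variance gene rows: ",
            paste(bad, collapse = ", "), call. = FALSE)
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 1L) stop("no gene rows left to correlate", call. = FALSE)
  ctr <- x - rowMeans(x)
  ctr <- ctr / sqrt(rowSums(ctr^2))
  r <- tcrossprod(ctr)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  new_proximity_matrix(r, mode = "correlation")
}

new_proximity_matrix <- function(entries, mode) {
  attr(entries, "mode") <- mode
  class(entries) <- c("proximity_matrix", class(unclass(entries)))
  entries
}

#' Validate a proximity matrix
#'
#' @param p object to validate.
#' @param mode if given, additionally require this mode
#'   (`"correlation"` or `"distance"`).
#' @return `p` invisibly, or an error.
#' @export
validate_proximity_matrix <- function(p, mode = NULL) {
  if (!is.matrix(p) || !is.numeric(p) || nrow(p) != ncol(p)) {
    stop("proximity matrix must be a square numeric matrix", call. = FALSE)
  }
  pm <- attr(p, "mode")
  if (is.null(pm) || !pm %in% c("correlation", "distance")) {
    stop("proximity matrix must carry mode 'correlation' or 'distance'",
         call. = FALSE)
  }
  if (!is.null(mode) && pm != mode) {
    stop(sprintf("expected a %s-mode proximity matrix, got %s mode",
                 mode, pm), call. = FALSE)
  }
  if (!isTRUE(all.equal(unclass(p), t(unclass(p)), tolerance = 1e-10))) {
    stop("proximity matrix must be symmetric", call. = FALSE)
  }
  if (pm == "correlation") {
    if (any(p < -1 | p > 1) || any(abs(diag(p) - 1) > 1e-12)) {
      stop("correlation mode requires entries in [-1, 1] and unit diagonal",
           call. = FALSE)
    }
  } else {
    if (any(p < 0) || any(abs(diag(p)) > 1e-12)) {
      stop("distance mode requires non-negative entries and zero diagonal",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' Convert a correlation matrix to a dissimilarity matrix
#'
#' Applies `d = 1 - r`, so perfectly correlated genes are at distance 0
#' and perfectly anticorrelated genes at distance 2. `1 - r` is not a
#' metric (no triangle inequality), which average-linkage clustering does
#' not require.
#'
#' @param p a correlation-mode `proximity_matrix`.
#' @return A distance-mode `proximity_matrix`.
#' @export
correlation_to_distance <- function(p) {
  validate_proximity_matrix(p, mode = "correlation")
  d <- 1 - unclass(p)
  diag(d) <- 0
  new_proximity_matrix(d, mode = "distance")
}

#' Write a proximity matrix as square TSV
#'
#' @param p a `proximity_matrix`.
#' @param path output path.
#' @param digits significant digits for formatting.
#' @return `path` invisibly.
#' @export
write_proximity_matrix <- function(p, path, digits = 6L) {
  validate_proximity_matrix(p)
  ids <- rownames(p)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(p)))
  txt <- format(unclass(p), digits = digits, trim = TRUE, scientific = NA)
  lines <- c(
    paste(c("id", ids), collapse = "\t"),
    vapply(seq_len(nrow(p)), function(i) {
      paste(c(ids[i], txt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
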