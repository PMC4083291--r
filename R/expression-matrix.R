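#' Construct an expression matrix
#'
#' An expression matrix holds the measured expression level \eqn{w_{ij}} of
#' gene \eqn{i} in sample \eqn{j}: rows are genes, columns are
#' samples/conditions. Values are either raw intensities or two-channel
#' log-ratios (\code{log2(test/reference)}).
#'
#' @param values numeric matrix (genes x samples), all values finite.
#' @param gene_ids character vector of unique row identifiers; defaults to
#'   existing rownames or \code{g1..gn}.
#' @param sample_ids character vector of unique column identifiers; defaults
#'   to existing colnames or \code{s1..sm}.
#' @param value_kind `"raw_intensity"` or `"log_ratio"`.
#'
#' @return A numeric matrix of class `"expr_matrix"` with row/column names
#'   set and a `value_kind` attribute.
#' @examples
#' em <- expression_matrix(matrix(1:6, 3, 2), value_kind = "raw_intensity")
#' dim(em)
#' @export
expression_matrix <- function(values,
                              gene_ids = NULL,
                              sample_ids = NULL,
                              value_kind = c("raw_intensity", "log_ratio")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- if (!is.null(rownames(values))) rownames(values)
                else paste0("g", seq_len(nrow(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(colnames(values))) colnames(values)
                  else paste0("s", seq_len(ncol(values)))
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  attr(values, "value_kind") <- value_kind
  class(values) <- c("expr_matrix", class(unclass(values)))
  validate_expression_matrix(values)
}

#' Validate an expression matrix
#'
#' Checks the structural invariants: matching identifier lengths, no
#' duplicate gene or sample IDs, and all values finite.
#'
#' @param em object to validate.
#' @return `em`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(em) {
  if (!is.matrix(em) || !is.numeric(em)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(em); sid <- colnames(em)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix must carry gene and sample identifiers",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene IDs: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(em))) {
    bad <- which(!is.finite(em), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  vk <- attr(em, "value_kind")
  if (is.null(vk) || !vk %in% c("raw_intensity", "log_ratio")) {
    stop("value_kind must be 'raw_intensity' or 'log_ratio'", call. = FALSE)
  }
  invisible(em)
}

#' Coerce to an expression matrix
#'
#' @param x a numeric matrix or data.frame of expression values.
#' @param ... passed to [expression_matrix()].
#' @return An `expr_matrix`.
#' @export
as_expression_matrix <- function(x, ...) {
  if (inherits(x, "expr_matrix")) return(validate_expression_matrix(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  expression_matrix(x, ...)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "value_kind")))
  n <- min(nrow(x), 6L); m <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) {
    cat(sprintf("... (%d rows, %d columns not shown)\n",
                nrow(x) - n, ncol(x) - m))
  }
  invisible(x)
}

#' Read an expression matrix from a TSV file
#'
#' Expects a tab-separated file whose first (header) line lists the sample
#' IDs and whose subsequent lines are a gene ID followed by one numeric
#' field per sample. Lines starting with `#` are skipped. The header may
#' carry either m fields (sample IDs only) or m+1 fields (a leading label
#' for the gene-ID column).
#'
#' @param path file path.
#' @param value_kind declared kind of the stored values.
#' @param na_action `"reject"` (default) errors on cells equal to `NA`;
#'   `"impute_row_mean"` replaces them by the mean of the remaining finite
#'   values in the same gene row.
#' @param comment_char lines starting with this character are skipped.
#' @return An `expr_matrix` with row/column order as in the file.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   value_kind = c("raw_intensity", "log_ratio"),
                                   na_action = c("reject", "impute_row_mean"),
                                   comment_char = "#") {
  value_kind <- match.arg(value_kind)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  raw <- readLines(path)
  keep <- !startsWith(raw, comment_char) & nzchar(trimws(raw))
  lineno <- which(keep)                      # original line numbers
  lines <- raw[keep]
  if (length(lines) < 2L) {
    stop("file must contain a header line and at least one gene row",
         call. = FALSE)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  body_lineno <- lineno[-1]

  widths <- lengths(body)
  m <- widths[1] - 1L
  if (m < 1L) {
    stop(sprintf("line %d: expected a gene ID and at least one value",
                 body_lineno[1]), call. = FALSE)
  }
  bad <- which(widths != m + 1L)
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields, found %d",
                 body_lineno[bad[1]], m + 1L, widths[bad[1]]), call. = FALSE)
  }
  sample_ids <- if (length(header) == m + 1L) header[-1] else header
  if (length(sample_ids) != m) {
    stop(sprintf("header has %d sample IDs but rows carry %d values",
                 length(sample_ids), m), call. = FALSE)
  }

  gene_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }

  cells <- t(vapply(body, function(f) f[-1], character(m)))
  if (m == 1L) cells <- matrix(cells, ncol = 1L)
  is_na_cell <- cells == "NA"
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))

  bad_cell <- which(is.na(vals) & !is_na_cell, arr.ind = TRUE)
  if (nrow(bad_cell)) {
    i <- bad_cell[1, 1]; j <- bad_cell[1, 2]
    stop(sprintf("line %d: non-numeric value '%s' (gene '%s', sample '%s')",
                 body_lineno[i], cells[i, j], gene_ids[i], sample_ids[j]),
         call. = FALSE)
  }
  if (any(is_na_cell)) {
    if (na_action == "reject") {
      w <- which(is_na_cell, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "missing value (NA) at gene '%s', sample '%s'; use na_action = 'impute_row_mean' to impute",
        gene_ids[w[1]], sample_ids[w[2]]), call. = FALSE)
    }
    for (i in which(rowSums(is_na_cell) > 0)) {
      ok <- !is_na_cell[i, ]
      if (!any(ok)) {
        stop(sprintf("gene '%s' has no observed values to impute from",
                     gene_ids[i]), call. = FALSE)
      }
      vals[i, !ok] <- mean(vals[i, ok])
    }
  }
  if (!all(is.finite(vals))) {
    w <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[w[1]], sample_ids[w[2]]), call. = FALSE)
  }

  expression_matrix(vals, gene_ids, sample_ids, value_kind)
}

#' Write an expression matrix to a TSV file
#'
#' Writes the dialect accepted by [read_expression_matrix()]: a header line
#' `gene_id<TAB>sample ids...`, then one line per gene. Values are printed
#' with `digits` significant digits so that write/read round-trips are
#' stable at the declared precision.
#'
#' @param em an `expr_matrix`.
#' @param path output file path.
#' @param digits significant digits used for numeric formatting.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, digits = 6L) {
  validate_expression_matrix(em)
  txt <- format(unclass(em), digits = digits, trim = TRUE, scientific = NA)
  lines <- c(
    paste(c("gene_id", colnames(em)), collapse = "\t"),
    vapply(seq_len(nrow(em)), function(i) {
      paste(c(rownames(em)[i], txt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export an expression matrix as dense JSON
#'
#' Writes `{"gene_ids": [...], "sample_ids": [...], "values": [[...]]}` for
#' pipeline interchange.
#'
#' @inheritParams write_expression_matrix
#' @return `path`, invisibly.
#' @export
write_expression_json <- function(em, path) {
  validate_expression_matrix(em)
  obj <- list(
    gene_ids = rownames(em),
    sample_ids = colnames(em),
    value_kind = attr(em, "value_kind"),
    values = unclass(em)
  )
  dimnames(obj$values) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Two-channel log ratio
#'
#' The canonical two-channel microarray value: `log2(C / R)` where `C` is
#' the expression level in the test sample and `R` the level in the
#' reference sample.
#'
#' @param test_level positive test-channel level C.
#' @param reference_level positive reference-channel level R.
#' @return `log2(test_level / reference_level)`.
#' @examples
#' log_ratio(4, 2)  # 1
#' @export
log_ratio <- function(test_level, reference_level) {
  if (!all(is.finite(test_level)) || !all(is.finite(reference_level))) {
    stop("levels must be finite", call. = FALSE)
  }
  if (any(test_level <= 0) || any(reference_level <= 0)) {
    stop("log ratio requires strictly positive levels; ",
         "use log_ratio_matrix() with a pseudocount for zero-inflated data",
         call. = FALSE)
  }
  log2(test_level / reference_level)
}

#' Elementwise log-ratio transform of two expression matrices
#'
#' Computes `log2((C + pseudocount) / (R + pseudocount))` cell by cell for
#' a test and a reference matrix with identical gene and sample IDs.
#'
#' @param test,reference `expr_matrix` objects with identical identifiers.
#' @param pseudocount non-negative shift added to both channels before the
#'   ratio; 0 (default) demands strictly positive values.
#' @return An `expr_matrix` with `value_kind = "log_ratio"`.
#' @export
log_ratio_matrix <- function(test, reference, pseudocount = 0) {
  validate_expression_matrix(test)
  validate_expression_matrix(reference)
  if (!identical(dim(test), dim(reference)) ||
      !identical(rownames(test), rownames(reference)) ||
      !identical(colnames(test), colnames(reference))) {
    stop("test and reference matrices must share gene and sample IDs ",
         "in the same order", call. = FALSE)
  }
  if (!is.finite(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a non-negative number", call. = FALSE)
  }
  ct <- unclass(test) + pseudocount
  cr <- unclass(reference) + pseudocount
  bad <- ct <= 0 | cr <= 0
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)
    show <- utils::head(sprintf("(%s, %s)", rownames(test)[w[, 1]],
                         colnames(test)[w[, 2]]), 5L)
    stop("nonpositive shifted values at: ", paste(show, collapse = ", "),
         if (nrow(w) > 5L) " ..." else "", call. = FALSE)
  }
  expression_matrix(log2(ct / cr), rownames(test), colnames(test),
                    value_kind = "log_ratio")
}
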