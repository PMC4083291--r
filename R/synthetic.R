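#' Specification of a synthetic planted-pattern matrix
#'
#' Describes a genes x samples matrix of i.i.d. Gaussian background noise
#' with one or more planted order-preserving blocks: each block is a row
#' set and an ordered column list along which every block row steps
#' upward, so the block rows share a common linear ordering of column
#' values.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param blocks list of blocks, each a list/vector with `n_rows`,
#'   `n_cols`, and optionally `base_level` (default 0, the background
#'   log-ratio level) and `step` (default 1, the increment between
#'   consecutive columns of the planted order).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (background cells and block cells alike).
#' @param rng_seed integer seed; generation is fully deterministic given
#'   the spec.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes, n_samples,
                           blocks = list(list(n_rows = 20, n_cols = 6)),
                           noise_sd = 0.1, rng_seed = 1L) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  if (n_genes < 1L || n_samples < 1L) {
    stop("matrix dimensions must be positive", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  blocks <- lapply(blocks, function(b) {
    b <- as.list(b)
    b$n_rows <- as.integer(b$n_rows)
    b$n_cols <- as.integer(b$n_cols)
    if (is.null(b$base_level)) b$base_level <- 0
    if (is.null(b$step)) b$step <- 1
    if (b$n_rows < 1L || b$n_cols < 2L) {
      stop("each block needs n_rows >= 1 and n_cols >= 2", call. = FALSE)
    }
    if (!is.finite(b$step) || b$step <= 0) {
      stop("block step must be positive", call. = FALSE)
    }
    b
  })
  if (sum(vapply(blocks, `[[`, integer(1), "n_rows")) > n_genes) {
    stop("planted block rows exceed n_genes (rows must be disjoint)",
         call. = FALSE)
  }
  if (any(vapply(blocks, `[[`, integer(1), "n_cols") > n_samples)) {
    stop("a planted block is wider than the matrix", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, n_samples = n_samples, blocks = blocks,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic expression matrix with planted patterns
#'
#' Background cells are drawn `Normal(0, noise_sd^2)`. For each planted
#' block, disjoint row sets and an ordered column subset are sampled; cell
#' `(i, j_k)` of a block is `base_level + k * step + Normal(0, noise_sd^2)`
#' where `k` is the column's 1-based rank in the planted order, so with
#' the default `base_level = 0` every block column sits at least one step
#' above the background level. With `noise_sd = 0` every block row is an
#' exact arithmetic progression along the planted order; with
#' `step >> noise_sd` the rows still support the planted order strictly.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `matrix` (an `expr_matrix`, `value_kind =
#'   "log_ratio"`) and `truth`, a list of class `"synthetic_truth"`:
#'   one element per block with `rows` (integer set) and `cols` (integer
#'   vector in planted order).
#' @export
generate_matrix <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("expected a 'synthetic_spec'", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$rng_seed)

  n <- spec$n_genes; m <- spec$n_samples
  vals <- matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)

  free_rows <- seq_len(n)
  truth <- vector("list", length(spec$blocks))
  for (b in seq_along(spec$blocks)) {
    bl <- spec$blocks[[b]]
    rows <- sort(sample(free_rows, bl$n_rows))
    free_rows <- setdiff(free_rows, rows)
    cols <- sample(seq_len(m), bl$n_cols)   # sampled order = planted order
    signal <- bl$base_level + seq_len(bl$n_cols) * bl$step
    vals[rows, cols] <- vals[rows, cols] +
      matrix(signal, length(rows), bl$n_cols, byrow = TRUE)
    truth[[b]] <- list(rows = rows, cols = cols)
  }

  em <- expression_matrix(vals, value_kind = "log_ratio")
  structure(
    list(matrix = em, truth = structure(truth, class = "synthetic_truth")),
    class = "synthetic_dataset"
  )
}

#' Write planted-pattern ground truth as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param em the generated `expr_matrix` (for identifiers).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_truth_json <- function(truth, em, path) {
  em <- as_expression_matrix(em)
  obj <- lapply(truth, function(b) {
    list(rows = rownames(em)[b$rows], cols = colnames(em)[b$cols])
  })
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

truth_from_ids <- function(obj, em) {
  structure(lapply(obj, function(b) {
    list(rows = match(unlist(b$rows), rownames(em)),
         cols = match(unlist(b$cols), colnames(em)))
  }), class = "synthetic_truth")
}

#' Association accuracy against planted truth
#'
#' Each predicted pattern is matched to the truth block with which it
#' shares the most rows. A planted gene counts as correctly associated
#' when some predicted pattern both contains it and is matched to the
#' block it was planted in. Accuracy is the ratio of correctly associated
#' genes over the denominator:
#' `"planted"` (default) counts only genes belonging to some truth block,
#' `"all"` counts every gene of the matrix.
#'
#' @param predicted a `pcphc_patterns` list (may be empty).
#' @param truth a `synthetic_truth` (nonempty).
#' @param denominator `"planted"` or `"all"`.
#' @param n_genes total gene count; required for `denominator = "all"`.
#' @return A list of class `"accuracy_result"` with `n_correct`,
#'   `n_total`, and `accuracy = n_correct / n_total`.
#' @export
association_accuracy <- function(predicted, truth,
                                 denominator = c("planted", "all"),
                                 n_genes = NULL) {
  denominator <- match.arg(denominator)
  if (!length(truth)) stop("truth must contain at least one block",
                           call. = FALSE)
  planted <- sort(unique(unlist(lapply(truth, `[[`, "rows"))))
  n_total <- if (denominator == "planted") length(planted) else {
    if (is.null(n_genes)) {
      stop("n_genes is required for denominator = 'all'", call. = FALSE)
    }
    as.integer(n_genes)
  }

  correct <- integer(0)
  for (p in predicted) {
    overlap <- vapply(truth, function(b) length(intersect(p$rows, b$rows)),
                      integer(1))
    best <- which.max(overlap)          # ties -> first block
    if (overlap[best] > 0L) {
      correct <- union(correct, intersect(p$rows, truth[[best]]$rows))
    }
  }
  n_correct <- length(correct)
  structure(
    list(n_correct = n_correct, n_total = n_total,
         accuracy = n_correct / n_total),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("Association accuracy: %d / %d = %.3f\n",
              x$n_correct, x$n_total, x$accuracy))
  invisible(x)
}

pattern_cells <- function(rows, cols) {
  as.vector(outer(rows, cols, function(r, c) paste0(r, "_", c)))
}

#' Planted-block recovery score
#'
#' The standard planted-bicluster benchmark: for each truth block, the
#' maximum Jaccard index between its cell set (rows x columns) and any
#' predicted pattern's cell set; the score is the mean over truth blocks.
#' An empty prediction list scores 0.
#'
#' @param predicted a `pcphc_patterns` list.
#' @param truth a `synthetic_truth`.
#' @return A number in `[0, 1]`.
#' @export
recovery_score <- function(predicted, truth) {
  if (!length(truth)) stop("truth must contain at least one block",
                           call. = FALSE)
  if (!length(predicted)) return(0)
  pred_cells <- lapply(predicted, function(p) pattern_cells(p$rows, p$order))
  per_block <- vapply(truth, function(b) {
    tc <- pattern_cells(b$rows, b$cols)
    max(vapply(pred_cells, function(pc) {
      length(intersect(pc, tc)) / length(union(pc, tc))
    }, numeric(1)))
  }, numeric(1))
  mean(per_block)
}
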