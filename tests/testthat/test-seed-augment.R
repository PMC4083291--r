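# deterministic matrix with a planted strictly increasing block:
# rows 1..3 follow columns 1<2<3<4; rows 4..6 are constant background
planted_6x4 <- function() {
  vals <- matrix(0, 6, 4)
  vals[1:3, ] <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4) +
    matrix(c(0, 0.1, 0.2), 3, 4)
  expression_matrix(vals)
}

test_that("supports_order applies the strict adjacent-pair rule", {
  expect_true(supports_order(c(1, 2, 3), c(1, 2, 3)))
  expect_false(supports_order(c(3, 1, 2), c(1, 2, 3)))
  # a tie within tie_tol counts as one violation of two pairs
  row <- c(1, 1 + 1e-12, 2)
  expect_false(supports_order(row, c(1, 2, 3), e_max = 0))
  expect_true(supports_order(row, c(1, 2, 3), e_max = 0.5))
  expect_error(supports_order(c(1, 2), c(1L)), "length >= 2")
  expect_error(supports_order(c(1, 2), c(1L, 1L)), "duplicates")
})

test_that("supports_order agrees with the explicit-loop oracle", {
  set.seed(23)
  for (rep in 1:50) {
    m <- sample(3:8, 1)
    row <- rnorm(m)
    ord <- sample(m, sample(2:m, 1))
    e <- sample(c(0, 0.25, 0.5), 1)
    expect_identical(supports_order(row, ord, e_max = e),
                     oracle_supports(row, ord, e_max = e))
  }
})

test_that("derive_seed_order is the argsort of column means", {
  em <- expression_matrix(rbind(c(3, 1, 2), c(3, 1, 2)))
  expect_identical(derive_seed_order(1:2, em), c(2L, 3L, 1L))
  em2 <- expression_matrix(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_identical(derive_seed_order(1:2, em2), c(1L, 2L, 3L))

  set.seed(29)
  for (rep in 1:10) {
    em3 <- random_expression_matrix(10, 6)
    rows <- sample(10, sample(2:6, 1))
    mu <- vapply(1:6, function(j) mean(unclass(em3)[rows, j]), numeric(1))
    expect_identical(derive_seed_order(rows, em3), order(mu))
  }
  expect_error(derive_seed_order(integer(0), em), "nonempty")
})

test_that("count_order_support matches a row-by-row loop", {
  set.seed(37)
  em <- random_expression_matrix(20, 6)
  for (rep in 1:10) {
    ord <- sample(6, sample(2:6, 1))
    brute <- sum(vapply(seq_len(20), function(i) {
      oracle_supports(unclass(em)[i, ], ord)
    }, logical(1)))
    expect_identical(count_order_support(em, ord), as.integer(brute))
  }
  # length-2 order on a matrix where every row increases
  inc <- expression_matrix(cbind(1:5, 2:6))
  expect_identical(count_order_support(inc, c(1L, 2L)), 5L)
})

test_that("column_expand inserts the missing block column", {
  em <- planted_6x4()
  p <- new_pattern(1:3, c(1L, 2L, 3L), em)
  p2 <- column_expand(p, em)
  expect_identical(p2$order, c(1L, 2L, 3L, 4L))
  expect_identical(p2$rows, 1:3)
  # already spanning all columns -> unchanged
  expect_identical(column_expand(p2, em)$order, p2$order)
})

test_that("column_expand leaves the pattern alone when nothing qualifies", {
  # background columns are constant: ties violate strictness for all rows
  vals <- cbind(c(1, 1.1, 1.2), c(2, 2.1, 2.2), c(5, 5, 5))
  em <- expression_matrix(rbind(vals, vals + 0.01))
  p <- new_pattern(1:6, c(1L, 2L), em)
  # column 3 can only extend at the end but is constant across rows? it
  # increases over column 2 for every row, so it does qualify; block it
  # by making it tie with column 2 for one row
  vals2 <- unclass(em); vals2[1, 3] <- vals2[1, 2]
  em2 <- expression_matrix(vals2)
  p2 <- new_pattern(1:6, c(1L, 2L), em2)
  expect_identical(column_expand(p2, em2)$order, c(1L, 2L))
})

test_that("row_expand adds exactly the supporting outside rows", {
  em <- planted_6x4()
  p <- new_pattern(1:2, c(1L, 2L, 3L, 4L), em)
  p2 <- row_expand(p, em)
  expect_identical(p2$rows, 1:3)       # row 3 follows, constants do not
  expect_identical(row_expand(p2, em)$rows, 1:3)
  expect_identical(p2$support, 3L)
})

test_that("growth is monotone and reaches a verified fixpoint", {
  # 5-row block, strictly increasing over columns 1..4; decoy columns
  # 5..8 alternate sign between adjacent block rows so no decoy can be
  # inserted at any position; background rows are flat (ties never
  # support a strict order)
  vals <- matrix(0, 20, 8)
  for (r in 1:5) {
    vals[r, 1:4] <- 1:4 + r / 100
    vals[r, 5:8] <- 10 * (-1)^(r + (5:8))
  }
  em <- expression_matrix(vals)
  tr <- list(rows = 1:5, cols = 1:4)
  seed <- new_pattern(tr$rows[1:2], tr$cols[1:3], em)
  grown <- grow_to_maximal(seed, em)
  expect_true(grown$maximal)
  expect_true(all(tr$rows %in% grown$rows))
  expect_true(all(tr$cols %in% grown$order))
  # seed order survives as a subsequence
  expect_identical(intersect(grown$order, seed$order), seed$order)
  expect_true(pattern_is_maximal(grown, em))
  expect_true(oracle_is_maximal(grown, unclass(em)))
})

test_that("both strategies agree on an unambiguous planted block", {
  vals <- matrix(0, 8, 5)
  vals[1:4, 1:4] <- matrix(rep(1:4, each = 4), 4, 4) +
    seq(0, 0.3, length.out = 4)
  em <- expression_matrix(vals)
  seed <- new_pattern(1:2, c(1L, 2L), em)
  g_col <- grow_to_maximal(seed, em, strategy = "column_centric")
  g_row <- grow_to_maximal(seed, em, strategy = "row_centric")
  expect_identical(g_col$rows, g_row$rows)
  expect_identical(g_col$order, g_row$order)
  expect_true(all(1:4 %in% g_col$rows))
  expect_true(all(1:4 %in% g_col$order))
})

test_that("pattern_quality is the order-consistency ratio", {
  em <- planted_6x4()
  p <- new_pattern(1:3, c(1L, 2L, 3L, 4L), em)
  expect_equal(pattern_quality(p, em), 1)
  # flip one adjacent pair in one row: 1 violation out of 9 comparisons
  vals <- unclass(em)
  vals[1, 2] <- vals[1, 1] - 0.5
  em2 <- expression_matrix(vals)
  p2 <- new_pattern(1:3, c(1L, 2L, 3L, 4L), em2)
  expect_equal(pattern_quality(p2, em2), 1 - 1 / 9)
})

test_that("mine_patterns recovers a planted block and deduplicates", {
  sim <- generate_matrix(synthetic_spec(40, 10,
    list(list(n_rows = 10, n_cols = 5)), noise_sd = 0.05, rng_seed = 5))
  pats <- mine_patterns(sim$matrix)
  expect_gt(length(pats), 0)
  keys <- vapply(pats, function(p) {
    paste(paste(p$rows, collapse = ","), paste(p$order, collapse = ","))
  }, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # ranked by area, descending
  areas <- vapply(pats, function(p) length(p$rows) * length(p$order),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  # the top pattern contains the planted block
  tr <- sim$truth[[1]]
  top <- pats[[1]]
  expect_true(all(tr$rows %in% top$rows))
  expect_true(all(tr$cols %in% top$order))
  # every emitted pattern passes the maximality re-check
  for (p in pats) expect_true(pattern_is_maximal(p, sim$matrix))
})

test_that("patterns export as JSON lines and summary TSV", {
  sim <- generate_matrix(synthetic_spec(30, 8,
    list(list(n_rows = 8, n_cols = 4)), noise_sd = 0.05, rng_seed = 9))
  pats <- mine_patterns(sim$matrix)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_patterns_jsonl(pats, sim$matrix, f1)
  write_pattern_summary(pats, sim$matrix, f2)
  lines <- readLines(f1)
  expect_length(lines, length(pats))
  obj <- jsonlite::fromJSON(lines[1])
  expect_named(obj, c("rows", "column_order", "support", "quality"),
               ignore.order = TRUE)
  tab <- utils::read.delim(f2)
  expect_identical(nrow(tab), length(pats))
})

test_that("threshold constructor validates its domain", {
  expect_error(thresholds(e_max = 1.5), "e_max")
  expect_error(thresholds(h_min = -0.1), "h_min")
  th <- thresholds(e_max = 0.2, h_min = 0.5)
  expect_s3_class(th, "pcphc_thresholds")
})
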