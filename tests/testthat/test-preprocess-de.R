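# Normalisation, the low-count filter, fold changes, tests, BH and DET calls.

make_counts <- function(m, ids = NULL, libs = NULL) {
  rownames(m) <- ids %||% sprintf("t%d", seq_len(nrow(m)))
  colnames(m) <- libs %||% sprintf("L%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

two_group_sheet <- function(n2, n4) {
  data.frame(
    library_id = sprintf("L%d", seq_len(n2 + n4)),
    genotype_id = rep(c("gA", "gB"), c(n2, n4)),
    ploidy = rep(c("2x", "4x"), c(n2, n4)),
    replicate = c(seq_len(n2), seq_len(n4)))
}

test_that("library-size normalisation rescales columns to the target total", {
  m <- make_counts(matrix(c(500L, 999500L, 20L, 80L), ncol = 2))
  norm <- normalize_library_size(m)
  expect_equal(norm[1, 1], 500)
  expect_equal(unname(colSums(norm)), c(1e6, 1e6), tolerance = 1e-9)
  # proportional columns become identical
  m2 <- make_counts(cbind(c(10L, 30L, 60L), c(30L, 90L, 180L)))
  norm2 <- normalize_library_size(m2)
  expect_equal(norm2[, 1], norm2[, 2])
  # zero-total libraries are rejected by name
  m3 <- make_counts(cbind(c(1L, 2L), c(0L, 0L)))
  expect_error(normalize_library_size(m3), "L2")
})

test_that("the low-count filter removes transcripts below min_count everywhere", {
  m <- make_counts(rbind(rep(2L, 18), c(3L, rep(0L, 17)), rep(0L, 18),
                         rep(50L, 18)))
  kept <- filter_low_counts(m, min_count = 3)
  expect_identical(kept, c("t2", "t4"))
  # min_count = 0 keeps everything
  expect_length(filter_low_counts(m, min_count = 0), 4)
})

test_that("the per-genotype filter reading requires a full replicate group", {
  samples <- data.frame(library_id = sprintf("L%d", 1:4),
                        genotype_id = c("g1", "g1", "g2", "g2"),
                        ploidy = c("2x", "2x", "4x", "4x"),
                        replicate = c(1, 2, 1, 2))
  m <- make_counts(rbind(c(5L, 0L, 5L, 0L),   # never a complete genotype
                         c(3L, 3L, 0L, 0L),   # complete in g1
                         c(9L, 9L, 9L, 9L)))
  expect_identical(filter_low_counts(m, per_group = TRUE, samples = samples),
                   c("t2", "t3"))
  expect_identical(filter_low_counts(m), c("t1", "t2", "t3"))
})

test_that("log2 fold changes follow the 4x-minus-2x convention", {
  samples <- two_group_sheet(3, 3)
  norm <- matrix(c(rep(100, 3), rep(100, 3),
                   rep(100, 3), rep(300, 3)), nrow = 2, byrow = TRUE)
  rownames(norm) <- c("same", "up3"); colnames(norm) <- samples$library_id
  lfc <- log2_fold_change(norm, samples)
  expect_equal(unname(lfc["same"]), 0)
  expect_equal(unname(lfc["up3"]), log2(301 / 101))
  expect_equal(unname(lfc["up3"]), log2(3), tolerance = 0.02)
  # swapping group labels flips the sign
  flipped <- samples
  flipped$ploidy <- ifelse(samples$ploidy == "2x", "4x", "2x")
  expect_equal(log2_fold_change(norm, flipped), -lfc)
  # missing ploidy group errors
  only2x <- samples; only2x$ploidy <- "2x"
  expect_error(log2_fold_change(norm, only2x), "ploidy")
})

test_that("scaling the 4x columns of the normalized matrix shifts log2FC by ~2", {
  d <- simulate_ploidy_experiment(tiny_config(seed = 7))
  norm <- normalize_library_size(d$counts)
  is4x <- d$samples$ploidy[match(colnames(norm), d$samples$library_id)] == "4x"
  # keep both group means well away from the pseudocount
  norm <- norm[rowMeans(norm[, is4x]) > 100 & rowMeans(norm[, !is4x]) > 100, ]
  scaled <- norm
  scaled[, is4x] <- scaled[, is4x] * 4
  shift <- log2_fold_change(scaled, d$samples) -
    log2_fold_change(norm, d$samples)
  expect_true(all(abs(shift - 2) < 0.1))
})

test_that("welch_log p-values match the textbook Welch formula", {
  samples <- two_group_sheet(3, 3)
  set.seed(42)
  norm <- matrix(exp(rnorm(30, 4)), nrow = 5)
  rownames(norm) <- sprintf("t%d", 1:5); colnames(norm) <- samples$library_id
  p <- de_test(norm, samples, method = "welch_log")
  x <- log2(norm + 1)
  expected <- vapply(1:5, function(i) welch_oracle(x[i, 4:6], x[i, 1:3]),
                     numeric(1))
  expect_equal(unname(p), expected, tolerance = 1e-12)
  # a transcript identical in all samples gets p = 1 by convention
  flat <- matrix(100, nrow = 1, ncol = 6,
                 dimnames = list("flat", samples$library_id))
  expect_equal(unname(de_test(flat, samples)), 1)
})

test_that("exhaustive permutation p follows the add-one convention", {
  samples <- two_group_sheet(3, 3)
  # extreme separation: the observed statistic beats all other relabelings
  norm <- matrix(c(1, 1.1, 0.9, 1000, 1100, 900), nrow = 1,
                 dimnames = list("t1", samples$library_id))
  p <- de_test(norm, samples, method = "permutation", exhaustive = TRUE)
  expect_equal(unname(p), (0 + 1) / (factorial(6) + 1))
  # random-permutation p lies in (0, 1] and is seed-reproducible
  set.seed(1); norm2 <- matrix(runif(12, 1, 2), nrow = 2,
                               dimnames = list(c("a", "b"),
                                               samples$library_id))
  p1 <- de_test(norm2, samples, method = "permutation", n_perm = 99, seed = 3)
  p2 <- de_test(norm2, samples, method = "permutation", n_perm = 99, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_error(de_test(norm2, samples, method = "permutation", n_perm = 5),
               "10")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_identical(bh_adjust(p), bh_oracle(p))
  }
  # elementwise p_adj >= p_raw and permutation invariance
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
  perm <- sample(100)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DET selection applies strict thresholds and is monotone", {
  det <- data.frame(transcript_id = c("a", "b", "c", "d"),
                    log2FC = c(2.5, 2.0, 5.0, -2.5),
                    p_adj = c(0.04, 0.04, 0.06, 0.01))
  expect_setequal(select_dets(det), c("a", "d"))         # strict on both
  expect_false("b" %in% select_dets(det))                # |lfc| = 2 excluded
  expect_false("c" %in% select_dets(det))                # p_adj >= 0.05
  # threshold monotonicity on a simulated table
  d <- simulate_ploidy_experiment(tiny_config(seed = 2))
  de <- de_analysis(d$counts, d$samples)
  expect_true(all(select_dets(de, lfc_min = 2) %in%
                    select_dets(de, lfc_min = 1)))
})

test_that("consensus DETs are the exact order-independent intersection", {
  expect_setequal(consensus_dets(list(c("a", "b", "c"), c("b", "c", "d"))),
                  c("b", "c"))
  expect_identical(consensus_dets(list(c("x", "y"), c("x", "y"))), c("x", "y"))
  expect_length(consensus_dets(list(c("a"), c("b"))), 0)
  expect_setequal(
    consensus_dets(list(c("a", "b"), c("b", "a"), c("b", "a", "z"))),
    consensus_dets(list(c("b", "a", "z"), c("a", "b"), c("b", "a"))))
  expect_error(consensus_dets(list(c("a"))), "two")
})

test_that("no differential expression is called under a global null", {
  # 200 replicate null datasets: the share with any DET at FDR 0.05 must be
  # consistent with FDR control.
  samples <- two_group_sheet(4, 4)
  set.seed(2024)
  n_hit <- 0L
  for (r in 1:200) {
    norm <- matrix(2^rnorm(500 * 8, 6, 1), nrow = 500)
    rownames(norm) <- sprintf("g%d", 1:500)
    colnames(norm) <- samples$library_id
    p_adj <- bh_adjust(de_test(norm, samples))
    lfc <- log2_fold_change(norm, samples)
    if (any(p_adj < 0.05 & abs(lfc) > 2)) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
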