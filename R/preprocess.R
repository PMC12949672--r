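## Library-size normalisation, low-count filtering, fold changes, p-values,
## FDR adjustment and consensus differential-expression calls.

#' Normalize a count matrix by library size
#'
#' Scales each library (column) to a common total, counts-per-million by
#' default: `entry = count / library_total * scale`.
#'
#' @param counts Nonnegative integer matrix, transcripts x libraries.
#' @param scale Target column total (default `1e6`, i.e. CPM).
#' @return A numeric matrix of the same shape whose columns each sum to
#'   `scale`.
#' @export
normalize_library_size <- function(counts, scale = 1e6) {
  validate_count_matrix(counts)
  abort_if(scale <= 0, "`scale` must be > 0")
  totals <- colSums(counts)
  zero <- totals == 0
  abort_if(any(zero), "library with zero total count: %s",
           paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2L, totals / scale, `/`)
}

#' Filter transcripts with uniformly low counts
#'
#' Default rule: a transcript is removed iff its count is below `min_count` in
#' every library (`max over libraries < min_count`). With `per_group = TRUE`
#' the stricter per-genotype reading is used: a transcript is kept iff at least
#' one genotype has all of its replicate libraries at or above `min_count`.
#'
#' @param counts Raw count matrix.
#' @param min_count Minimum count (default 3).
#' @param per_group Use the per-genotype reading (requires `samples`).
#' @param samples Sample sheet; only needed when `per_group = TRUE`.
#' @return Character vector of retained transcript ids, in input order.
#' @export
filter_low_counts <- function(counts, min_count = 3L, per_group = FALSE,
                              samples = NULL) {
  validate_count_matrix(counts)
  abort_if(min_count < 0, "`min_count` must be >= 0")
  if (!per_group) {
    keep <- apply(counts, 1L, max) >= min_count
  } else {
    abort_if(is.null(samples), "`samples` is required when per_group = TRUE")
    validate_samples(samples, colnames(counts))
    geno <- split(samples$library_id, samples$genotype_id)
    keep_mat <- vapply(geno, function(libs) {
      apply(counts[, libs, drop = FALSE], 1L, min) >= min_count
    }, logical(nrow(counts)))
    keep <- rowSums(keep_mat) > 0
  }
  rownames(counts)[keep]
}

#' Per-transcript log2 fold change between ploidy groups
#'
#' `log2FC = log2(mean_4x + pseudocount) - log2(mean_2x + pseudocount)` on
#' normalized counts; positive values mean higher expression in the tetraploid
#' group.
#'
#' @param norm Normalized expression matrix (see [normalize_library_size()]).
#' @param samples Sample sheet mapping libraries to ploidy groups.
#' @param pseudocount Added to both group means before taking logs (default 1),
#'   bounding the fold change for transcripts absent from one group.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(norm, samples, pseudocount = 1) {
  validate_samples(samples, colnames(norm))
  ploidy <- samples$ploidy[match(colnames(norm), samples$library_id)]
  abort_if(!any(ploidy == "2x") || !any(ploidy == "4x"),
           "both ploidy groups must be present")
  m2 <- rowMeans(norm[, ploidy == "2x", drop = FALSE])
  m4 <- rowMeans(norm[, ploidy == "4x", drop = FALSE])
  setNames(log2(m4 + pseudocount) - log2(m2 + pseudocount), rownames(norm))
}

#' Per-transcript p-values for the ploidy contrast
#'
#' A deliberately simple, pluggable test statistic used to order transcripts
#' before the thresholding/consensus logic (which is where the calling rules
#' live). Two reference methods:
#' \describe{
#'   \item{`welch_log`}{two-sided Welch t-test on `log2(norm + 1)` between the
#'     ploidy groups (via [stats::t.test()]). When both groups have zero
#'     variance, the p-value is 1 if the group means are equal and
#'     `.Machine$double.eps` otherwise.}
#'   \item{`permutation`}{two-sided permutation p for the difference of group
#'     means of `log2(norm + 1)`, with add-one smoothing:
#'     `p = (1 + #\{|t*| > |t|\}) / (B + 1)` where `B` is the number of
#'     permutations (ties count as non-exceeding). With `exhaustive = TRUE`
#'     (only for 8 or fewer libraries) all `n!` label orderings are enumerated;
#'     otherwise `n_perm` random permutations are drawn from the seeded
#'     stream.}
#' }
#'
#' @param norm Normalized expression matrix.
#' @param samples Sample sheet.
#' @param method `"welch_log"` (default) or `"permutation"`.
#' @param n_perm Number of random permutations (permutation method).
#' @param exhaustive Enumerate all label orderings (permutation method,
#'   `n <= 8`).
#' @param seed Seed for the permutation stream.
#' @return Named numeric vector of p-values in `(0, 1]`.
#' @export
de_test <- function(norm, samples, method = c("welch_log", "permutation"),
                    n_perm = 999L, exhaustive = FALSE, seed = 1L) {
  method <- match.arg(method)
  validate_samples(samples, colnames(norm))
  ploidy <- samples$ploidy[match(colnames(norm), samples$library_id)]
  x <- log2(norm + 1)
  i2 <- ploidy == "2x"
  i4 <- ploidy == "4x"
  abort_if(!any(i2) || !any(i4), "both ploidy groups must be present")

  if (method == "welch_log") {
    abort_if(sum(i2) < 2L || sum(i4) < 2L,
             "welch_log requires >= 2 libraries per ploidy group")
    p <- apply(x, 1L, function(v) welch_p(v[i4], v[i2]))
    return(setNames(p, rownames(norm)))
  }

  ## permutation
  n <- ncol(x)
  contrast <- as.numeric(i4) / sum(i4) - as.numeric(i2) / sum(i2)
  obs <- abs(as.vector(x %*% contrast))
  if (exhaustive) {
    abort_if(n > 8L, "exhaustive permutation supported only for n <= 8")
    perms <- all_permutations(n)          # n! x n index matrix
    B <- nrow(perms)
    stat <- abs(x %*% t(matrix(contrast[as.vector(perms)], nrow = B)))
  } else {
    abort_if(n_perm < 10L, "permutation requires at least 10 relabelings")
    B <- as.integer(n_perm)
    cm <- with_seed(derive_seed(seed, "ploidynet.de.perm"),
                    vapply(seq_len(B), function(b) contrast[sample.int(n)],
                           numeric(n)))
    stat <- abs(x %*% cm)
  }
  exceed <- rowSums(stat > obs + 0)       # strict exceedance
  setNames((exceed + 1) / (B + 1), rownames(norm))
}

# Welch p-value with the degenerate-variance convention documented in de_test().
welch_p <- function(a, b) {
  va <- var(a); vb <- var(b)
  if (va + vb < 1e-24) {
    if (abs(mean(a) - mean(b)) < 1e-12) return(1)
    return(.Machine$double.eps)
  }
  tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
           error = function(e) 1)
}

# All permutations of 1..n as an n! x n matrix (lexicographic by recursion).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' with input validation.
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_raw) {
  abort_if(!is.numeric(p_raw), "`p_raw` must be numeric")
  abort_if(anyNA(p_raw) || any(p_raw < 0 | p_raw > 1),
           "p-values must all lie in [0, 1]")
  p.adjust(p_raw, method = "BH")
}

#' Differential-expression table for a ploidy contrast
#'
#' Convenience wrapper: normalize, filter low counts, compute log2 fold
#' changes, p-values and BH-adjusted p-values, and flag differentially
#' expressed transcripts.
#'
#' @param counts Raw count matrix.
#' @param samples Sample sheet.
#' @param method Test statistic passed to [de_test()].
#' @param fdr_max,lfc_min Thresholds for the `de_flag` column (strict
#'   inequalities: `p_adj < fdr_max` and `|log2FC| > lfc_min`).
#' @param min_count Low-count filter threshold (see [filter_low_counts()]).
#' @param pseudocount Passed to [log2_fold_change()].
#' @param ... Further arguments to [de_test()].
#' @return Data frame with columns `transcript_id`, `log2FC`, `p_raw`,
#'   `p_adj`, `de_flag` (one row per retained transcript).
#' @export
de_analysis <- function(counts, samples, method = "welch_log",
                        fdr_max = 0.05, lfc_min = 2.0, min_count = 3L,
                        pseudocount = 1, ...) {
  norm <- normalize_library_size(counts)
  keep <- filter_low_counts(counts, min_count = min_count)
  norm <- norm[keep, , drop = FALSE]
  lfc <- log2_fold_change(norm, samples, pseudocount = pseudocount)
  p <- de_test(norm, samples, method = method, ...)
  padj <- bh_adjust(p)
  data.frame(transcript_id = keep,
             log2FC = unname(lfc),
             p_raw = unname(p),
             p_adj = unname(padj),
             de_flag = unname(padj < fdr_max & abs(lfc) > lfc_min),
             stringsAsFactors = FALSE)
}

#' Select differentially expressed transcripts
#'
#' Ids with `p_adj < fdr_max` and `|log2FC| > lfc_min` (both strict). The
#' default thresholds give the stringent DET call; `lfc_min = 1.0` gives the
#' network node-selection rule.
#'
#' @param det A table from [de_analysis()] (columns `transcript_id`, `log2FC`,
#'   `p_adj`).
#' @param fdr_max,lfc_min Thresholds (both must be positive).
#' @return Character vector of selected transcript ids.
#' @export
select_dets <- function(det, fdr_max = 0.05, lfc_min = 2.0) {
  abort_if(fdr_max <= 0 || lfc_min <= 0, "thresholds must be positive")
  need <- c("transcript_id", "log2FC", "p_adj")
  abort_if(!all(need %in% names(det)), "`det` must have columns %s",
           paste(need, collapse = ", "))
  det$transcript_id[det$p_adj < fdr_max & abs(det$log2FC) > lfc_min]
}

#' Consensus ("true") differentially expressed transcripts
#'
#' Exact intersection of two or more DET id sets, mirroring the practice of
#' retaining only transcripts called by every analysis route.
#'
#' @param sets A list of two or more character vectors of transcript ids.
#' @return Character vector of ids present in every set.
#' @export
consensus_dets <- function(sets) {
  abort_if(!is.list(sets) || length(sets) < 2L,
           "`sets` must be a list of at least two id sets")
  Reduce(intersect, sets)
}
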