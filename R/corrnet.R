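## Genotype-centered, shrinkage-regularised Pearson correlation and the
## unweighted co-expression network built from it.

#' Center an expression matrix within genotypes
#'
#' Subtracts, per transcript, the mean over each genotype's libraries, so that
#' genotype acts as a nested blocking factor within ploidy: correlations
#' computed downstream reflect co-fluctuation around genotype means rather than
#' genotype (or ploidy) main effects.
#'
#' @param mat Numeric expression matrix (typically `log2(CPM + 1)`),
#'   transcripts x libraries.
#' @param samples Sample sheet mapping libraries to genotypes.
#' @return An object of class `centered_matrix`: list with `values` (the
#'   centered matrix), `zero_variance` (named logical; transcripts flat after
#'   centering, excluded from correlation), and `samples`.
#' @export
genotype_center <- function(mat, samples) {
  abort_if(!is.matrix(mat) || !is.numeric(mat), "`mat` must be a numeric matrix")
  validate_samples(samples, colnames(mat))
  geno <- samples$genotype_id[match(colnames(mat), samples$library_id)]
  centered <- mat
  for (g in unique(geno)) {
    idx <- which(geno == g)
    centered[, idx] <- mat[, idx, drop = FALSE] -
      rowMeans(mat[, idx, drop = FALSE])
  }
  zv <- apply(centered, 1L, function(v) sd(v) < 1e-12)
  structure(list(values = centered,
                 zero_variance = setNames(zv, rownames(mat)),
                 samples = samples[match(colnames(mat), samples$library_id), ,
                                   drop = FALSE]),
            class = "centered_matrix")
}

#' Shrinkage Pearson correlation (James-Stein / Schafer-Strimmer)
#'
#' Computes the sample Pearson correlation `R` of the (genotype-centered)
#' expression rows and shrinks it toward the identity target:
#' `R*_ij = (1 - lambda) * r_ij` off-diagonal, with the analytic
#' Schafer-Strimmer intensity
#' `lambda* = clip( sum Var(r_ij) / sum r_ij^2 , 0, 1 )` over `i != j`, where
#' `Var(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2` and
#' `w_kij = z_ki z_kj` are products of row-standardized observations.
#'
#' Correlations are computed over all libraries without a degrees-of-freedom
#' correction for the genotype means subtracted beforehand; setting
#' `df_correct = TRUE` rescales the variance estimate by `(n - 1) / (n - g)`
#' (`g` = number of genotypes) to account for them.
#'
#' @param centered A `centered_matrix` from [genotype_center()] (or a plain
#'   numeric matrix, taken as already centered).
#' @param lambda Optional override of the shrinkage intensity in `[0, 1]`
#'   (e.g. `0` for the plain sample correlation).
#' @param df_correct Apply the `(n - 1)/(n - g)` variance rescaling.
#' @return An object of class `shrunk_correlation`: list with `r_star`,
#'   `r_sample`, `lambda`, `n` (libraries) and `dropped` (zero-variance
#'   transcript ids excluded).
#' @export
shrinkage_correlation <- function(centered, lambda = NULL, df_correct = FALSE) {
  if (inherits(centered, "centered_matrix")) {
    X <- centered$values[!centered$zero_variance, , drop = FALSE]
    dropped <- names(which(centered$zero_variance))
    n_groups <- length(unique(centered$samples$genotype_id))
  } else {
    abort_if(!is.matrix(centered) || !is.numeric(centered),
             "`centered` must be a centered_matrix or numeric matrix")
    zv <- apply(centered, 1L, function(v) sd(v) < 1e-12)
    X <- centered[!zv, , drop = FALSE]
    dropped <- rownames(centered)[zv]
    n_groups <- 1L
  }
  n <- ncol(X)
  p <- nrow(X)
  abort_if(n < 3L, "need at least 3 libraries")
  abort_if(p < 2L, "need at least 2 transcripts with non-zero variance")
  if (length(dropped) > 0L) {
    message(sprintf("dropping %d zero-variance transcript(s): %s",
                    length(dropped),
                    paste(head(dropped, 5L), collapse = ", ")))
  }

  Z <- (X - rowMeans(X)) / apply(X, 1L, sd)
  R <- tcrossprod(Z) / (n - 1)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1

  if (is.null(lambda)) {
    wbar <- tcrossprod(Z) / n
    m2 <- tcrossprod(Z^2)                      # sum_k w_kij^2
    v_hat <- n / (n - 1)^3 * (m2 - n * wbar^2) # sum_k (w - wbar)^2 scaled
    if (df_correct && n > n_groups) {
      v_hat <- v_hat * (n - 1) / (n - n_groups)
    }
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    if (denom == 0) {
      message("all off-diagonal correlations are zero; lambda set to 1")
      lambda <- 1
    } else {
      lambda <- min(1, max(0, sum(v_hat[off]) / denom))
    }
  } else {
    abort_if(!is.numeric(lambda) || length(lambda) != 1L ||
               lambda < 0 || lambda > 1, "`lambda` must lie in [0, 1]")
  }

  r_star <- (1 - lambda) * R
  diag(r_star) <- 1
  structure(list(r_star = r_star, r_sample = R, lambda = lambda,
                 n = n, dropped = dropped),
            class = "shrunk_correlation")
}

#' Threshold a shrunk correlation matrix into an unweighted network
#'
#' Nodes are all transcripts retained in the correlation; an undirected edge
#' joins `i` and `j` iff `|R*_ij| >= tau`. Isolated nodes are kept. The edge
#' list is sorted canonically so the network is invariant to transcript
#' ordering.
#'
#' @param sc A `shrunk_correlation` (or a symmetric correlation matrix).
#' @param tau Absolute-correlation threshold in `(0, 1]`.
#' @return An object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data frame `node_a`, `node_b`, `r_star`), `tau`.
#' @export
build_network <- function(sc, tau = 0.7) {
  abort_if(!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1,
           "`tau` must lie in (0, 1]")
  R <- if (inherits(sc, "shrunk_correlation")) sc$r_star else sc
  abort_if(!is.matrix(R) || nrow(R) != ncol(R),
           "correlation input must be a square matrix")
  nodes <- rownames(R)
  hit <- which(upper.tri(R) & abs(R) >= tau, arr.ind = TRUE)
  if (nrow(hit) > 0L) {
    a <- nodes[hit[, 1L]]
    b <- nodes[hit[, 2L]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- data.frame(node_a = a, node_b = b,
                        r_star = R[hit], stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        r_star = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, tau = tau),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (tau = %g)\n",
              length(x$nodes), nrow(x$edges), x$tau))
  invisible(x)
}

#' @export
print.shrunk_correlation <- function(x, ...) {
  cat(sprintf("<shrunk_correlation> %d transcripts, %d libraries, lambda = %.4f\n",
              nrow(x$r_star), x$n, x$lambda))
  invisible(x)
}

# Adjacency list (named list of neighbour character vectors) for a network.
neighbour_list <- function(network) {
  nb <- setNames(vector("list", length(network$nodes)), network$nodes)
  for (nm in network$nodes) nb[[nm]] <- character(0)
  if (nrow(network$edges) > 0L) {
    sp_a <- split(network$edges$node_b, network$edges$node_a)
    sp_b <- split(network$edges$node_a, network$edges$node_b)
    for (nm in names(sp_a)) nb[[nm]] <- c(nb[[nm]], sp_a[[nm]])
    for (nm in names(sp_b)) nb[[nm]] <- c(nb[[nm]], sp_b[[nm]])
  }
  nb
}
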