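## Module detection, heat-cartography metrics and switch-gene classification.

#' Detect network modules by k-means on correlation profiles
#'
#' Clusters the rows of the shrunk correlation matrix (each node's correlation
#' profile) with [stats::kmeans()] for `k = 1..k_max` (10 restarts each, fixed
#' seed) and selects `k` from the inertia curve. Two rules are provided:
#' \describe{
#'   \item{`"gain"` (default)}{diminishing returns: the smallest `k` whose
#'     next refinement improves total within-cluster inertia by less than
#'     `gain_min` (relative). Robust when the correlation structure is
#'     hierarchical (a few large modules plus small satellite groups, the
#'     typical shape when anti-correlated hubs are present), where the
#'     curvature-based elbow is unstable.}
#'   \item{`"elbow"`}{the `k` with the largest second difference of
#'     log-inertia, ties broken toward the smaller `k` (the log scale makes
#'     the curvature scale-free).}
#' }
#' With `k` fixed via the `k` argument the search is skipped (used by the
#' robustness harness, where the module count is part of the reference
#' configuration).
#'
#' @param x A `shrunk_correlation` or a numeric matrix whose rows are node
#'   profiles.
#' @param k_max Largest number of modules to consider (capped at the number of
#'   nodes, with a warning).
#' @param seed Seed for the k-means restarts.
#' @param k Optional fixed number of modules, bypassing selection.
#' @param k_select Selection rule, `"gain"` or `"elbow"`.
#' @param gain_min Relative inertia-gain cutoff for the `"gain"` rule.
#' @return An object of class `module_partition`: list with `labels` (named
#'   integer vector, values `1..k`), `k`, and `inertia` (total within-cluster
#'   sum of squares per candidate `k`; `NA` when `k` was fixed).
#' @export
detect_modules <- function(x, k_max = 12L, seed = 1L, k = NULL,
                           k_select = c("gain", "elbow"), gain_min = 0.1) {
  k_select <- match.arg(k_select)
  M <- if (inherits(x, "shrunk_correlation")) x$r_star else x
  abort_if(!is.matrix(M) || !is.numeric(M), "`x` must be numeric matrix-like")
  n <- nrow(M)
  abort_if(n < 2L, "need at least 2 nodes")
  nodes <- rownames(M)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))

  fit_k <- function(kk) {
    if (kk == 1L) {
      list(cluster = rep(1L, n),
           tot.withinss = sum(sweep(M, 2L, colMeans(M))^2))
    } else if (kk >= n) {
      list(cluster = seq_len(n), tot.withinss = 0)
    } else {
      with_seed(derive_seed(seed, sprintf("ploidynet.kmeans.%d", kk)),
                kmeans(M, centers = kk, nstart = 10L, iter.max = 50L))
    }
  }

  if (!is.null(k)) {
    abort_if(k < 1L || k > n, "`k` must be in [1, number of nodes]")
    fit <- fit_k(as.integer(k))
    return(structure(list(labels = setNames(as.integer(fit$cluster), nodes),
                          k = as.integer(k), inertia = NA_real_),
                     class = "module_partition"))
  }

  abort_if(k_max < 1L, "`k_max` must be >= 1")
  if (k_max > n) {
    warning(sprintf("k_max = %d exceeds the %d nodes; capped", k_max, n),
            call. = FALSE)
    k_max <- n
  }
  fits <- lapply(seq_len(k_max), fit_k)
  inertia <- vapply(fits, `[[`, numeric(1), "tot.withinss")

  if (k_max <= 2L) {
    k_best <- k_max
  } else if (any(inertia <= 0)) {
    k_best <- which(inertia <= 0)[1L]    # perfect clustering reached
  } else if (k_select == "gain") {
    gain <- (inertia[-k_max] - inertia[-1L]) / inertia[-k_max]
    small <- which(gain < gain_min)
    k_best <- if (length(small) > 0L) small[1L] else k_max
  } else {
    li <- log(inertia)
    cand <- 2:(k_max - 1L)
    d2 <- li[cand - 1L] - 2 * li[cand] + li[cand + 1L]
    k_best <- cand[which.max(d2)]        # which.max: first maximum = smaller k
  }
  structure(list(labels = setNames(as.integer(fits[[k_best]]$cluster), nodes),
                 k = k_best, inertia = inertia),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules\n",
              length(x$labels), x$k))
  invisible(x)
}

#' Heat-cartography metrics per node
#'
#' For each node: total degree `k_g`, within-module degree `k_in`, the
#' within-module degree z-score `z = (k_in - mean k_in) / sd` (computed inside
#' the node's module; `z = 0` when the module sd is zero), and the
#' clusterphobic coefficient `K_pi = 1 - (k_in / k_g)^2` (`0` for isolated
#' nodes). `K_pi` is near 1 when a node's edges mostly leave its own module.
#'
#' @param network A `coexpression_network`.
#' @param partition A `module_partition` covering the network's nodes.
#' @return Data frame with columns `node`, `module`, `degree`, `k_in`, `z`,
#'   `kpi`.
#' @export
cartography <- function(network, partition) {
  abort_if(!inherits(network, "coexpression_network"),
           "`network` must be a coexpression_network")
  labels <- partition$labels
  miss <- setdiff(network$nodes, names(labels))
  abort_if(length(miss) > 0L, "partition does not cover node(s): %s",
           paste(head(miss, 5L), collapse = ", "))
  nb <- neighbour_list(network)
  nodes <- network$nodes
  k_g <- vapply(nb, length, integer(1))[nodes]
  k_in <- vapply(nodes, function(nm) {
    sum(labels[nb[[nm]]] == labels[[nm]])
  }, integer(1))
  z <- numeric(length(nodes))
  for (m in unique(labels[nodes])) {
    idx <- which(labels[nodes] == m)
    mu <- mean(k_in[idx])
    s <- sd(k_in[idx])
    z[idx] <- if (length(idx) < 2L || is.na(s) || s == 0) 0 else (k_in[idx] - mu) / s
  }
  kpi <- ifelse(k_g == 0L, 0, 1 - (k_in / k_g)^2)
  data.frame(node = nodes, module = as.integer(labels[nodes]),
             degree = as.integer(k_g), k_in = as.integer(k_in),
             z = z, kpi = kpi, stringsAsFactors = FALSE, row.names = NULL)
}

#' Average Pearson correlation with network neighbours (APCC)
#'
#' `APCC(g)` is the mean sample Pearson correlation between node `g` and its
#' network neighbours, computed on the genotype-centered expression matrix.
#' Isolated nodes get `NA` (they can never be switch genes).
#'
#' @param centered A `centered_matrix` (or plain numeric matrix) whose rows
#'   include all network nodes.
#' @param network A `coexpression_network`.
#' @return Named numeric vector of APCC values (`NA` for isolated nodes).
#' @export
apcc <- function(centered, network) {
  X <- if (inherits(centered, "centered_matrix")) centered$values else centered
  miss <- setdiff(network$nodes, rownames(X))
  abort_if(length(miss) > 0L, "expression matrix lacks node(s): %s",
           paste(head(miss, 5L), collapse = ", "))
  R <- suppressWarnings(cor(t(X[network$nodes, , drop = FALSE])))
  nb <- neighbour_list(network)
  out <- setNames(rep(NA_real_, length(network$nodes)), network$nodes)
  for (nm in network$nodes) {
    if (length(nb[[nm]]) > 0L) out[[nm]] <- mean(R[nm, nb[[nm]]])
  }
  out
}

#' Classify switch genes from cartography and APCC
#'
#' A node is a switch gene iff it is non-isolated, `K_pi > kpi_min`,
#' `z < z_max` and `APCC < apcc_max`: a clusterphobic hub whose edges point
#' away from its own module and whose neighbours it anti-correlates with — the
#' signature of a candidate master regulator of the ploidy transition. Hub role
#' classes are also reported: `"fight-club"` (APCC < 0), `"party"`
#' (APCC >= 0.8), `"date"` (otherwise), `"isolated"` (no edges).
#'
#' @param carto Data frame from [cartography()].
#' @param apcc Named APCC vector from [apcc()].
#' @param kpi_min,z_max,apcc_max Switch-region thresholds (defaults 0.8, 2.5,
#'   0).
#' @return The cartography data frame extended with `apcc`, `role`,
#'   `is_switch`.
#' @export
classify_switch <- function(carto, apcc, kpi_min = 0.8, z_max = 2.5,
                            apcc_max = 0) {
  abort_if(!all(carto$node %in% names(apcc)),
           "`apcc` does not cover every cartography node")
  a <- unname(apcc[carto$node])
  role <- ifelse(is.na(a), "isolated",
                 ifelse(a < 0, "fight-club",
                        ifelse(a >= 0.8, "party", "date")))
  is_switch <- carto$degree > 0L &
    carto$kpi > kpi_min &
    carto$z < z_max &
    !is.na(a) & a < apcc_max
  out <- carto
  out$apcc <- a
  out$role <- role
  out$is_switch <- is_switch
  out
}

#' Switch gene ids from a classification table
#'
#' @param classified Data frame from [classify_switch()].
#' @return Character vector of switch node ids.
#' @export
switch_ids <- function(classified) {
  classified$node[classified$is_switch]
}
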