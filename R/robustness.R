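## Leave-one-out and subsampling stability of the network/switch layer.

# One full network+switch pass on a library subset: centering -> shrinkage
# correlation -> thresholded network -> modules -> cartography/APCC -> switch
# classification. `k` fixes the module count; `k_max` triggers elbow selection.
network_switch_run <- function(logexpr, samples, tau = 0.45, k = NULL,
                               k_max = 12L, seed = 1L, kpi_min = 0.8,
                               z_max = 2.5, apcc_max = 0, lambda = NULL) {
  centered <- genotype_center(logexpr, samples)
  sc <- suppressMessages(shrinkage_correlation(centered, lambda = lambda))
  net <- build_network(sc, tau = tau)
  part <- detect_modules(sc, k_max = k_max, seed = seed, k = k)
  carto <- cartography(net, part)
  ap <- apcc(centered, net)
  cls <- classify_switch(carto, ap, kpi_min = kpi_min, z_max = z_max,
                         apcc_max = apcc_max)
  list(network = net, partition = part, classification = cls,
       switches = switch_ids(cls), lambda = sc$lambda)
}

#' Re-run the network/switch layer under library perturbations
#'
#' Executes one leave-one-out (LOO) run per removable unit (library by
#' default, whole genotype with `loo_unit = "genotype"`) plus
#' `n_subsample_runs` subsampling runs that retain `subsample_frac` of each
#' ploidy group's libraries (without replacement, stratified so both groups
#' survive). Each run repeats the full centering, shrinkage-correlation,
#' thresholding, module and switch computation on the retained libraries, with
#' the module count fixed at the reference run's `k`. Runs that would leave a
#' ploidy group with fewer than 2 libraries are skipped with a warning.
#'
#' @param logexpr Log-scale normalized expression matrix restricted to the
#'   network node set (rows) and all libraries (columns).
#' @param samples Sample sheet.
#' @param reference A reference run; if `NULL` it is computed from all
#'   libraries (module count selected by elbow up to `k_max`).
#' @param tau,k_max,kpi_min,z_max,apcc_max Pipeline thresholds (see
#'   [build_network()], [detect_modules()], [classify_switch()]).
#' @param n_subsample_runs Number of subsampling runs (default 91, which with
#'   18 libraries gives 109 runs in total).
#' @param subsample_frac Retained fraction per ploidy group (default 0.8).
#' @param loo_unit Remove one `"library"` (default) or one `"genotype"` per
#'   LOO run.
#' @param seed Master seed; each subsample draws from its own derived stream.
#' @return An object of class `perturbation_runs`: list with `reference` (the
#'   reference run) and `runs`, a list whose elements carry `run_id`, `type`
#'   (`"LOO"` or `"subsample80"`), `retained` library ids, and the run's
#'   network, partition and switch set.
#' @export
run_perturbations <- function(logexpr, samples, reference = NULL, tau = 0.45,
                              k_max = 12L, n_subsample_runs = 91L,
                              subsample_frac = 0.8,
                              loo_unit = c("library", "genotype"),
                              kpi_min = 0.8, z_max = 2.5, apcc_max = 0,
                              seed = 1L) {
  loo_unit <- match.arg(loo_unit)
  validate_samples(samples, colnames(logexpr))
  libs <- colnames(logexpr)
  abort_if(length(libs) < 4L, "need at least 4 libraries")
  samples <- samples[match(libs, samples$library_id), , drop = FALSE]
  ploidy <- setNames(samples$ploidy, samples$library_id)

  if (is.null(reference)) {
    reference <- network_switch_run(logexpr, samples, tau = tau, k_max = k_max,
                                    seed = seed, kpi_min = kpi_min,
                                    z_max = z_max, apcc_max = apcc_max)
  }
  k_ref <- reference$partition$k

  group_ok <- function(retained) {
    all(table(factor(ploidy[retained], levels = c("2x", "4x"))) >= 2L)
  }
  do_run <- function(retained, type, run_id) {
    res <- network_switch_run(logexpr[, retained, drop = FALSE],
                              samples[samples$library_id %in% retained, ,
                                      drop = FALSE],
                              tau = tau, k = k_ref, seed = seed,
                              kpi_min = kpi_min, z_max = z_max,
                              apcc_max = apcc_max)
    c(list(run_id = run_id, type = type, retained = retained), res)
  }

  runs <- list()
  loo_sets <- if (loo_unit == "library") {
    lapply(libs, function(l) setdiff(libs, l))
  } else {
    lapply(unique(samples$genotype_id), function(g) {
      libs[samples$genotype_id != g]
    })
  }
  for (i in seq_along(loo_sets)) {
    retained <- loo_sets[[i]]
    if (!group_ok(retained)) {
      warning(sprintf("LOO run %d leaves a ploidy group with < 2 libraries; skipped", i),
              call. = FALSE)
      next
    }
    runs[[length(runs) + 1L]] <- do_run(retained, "LOO",
                                        sprintf("LOO_%02d", i))
  }

  if (n_subsample_runs > 0L) {
    by_group <- split(libs, ploidy[libs])
    keep_n <- vapply(by_group, function(g) as.integer(round(subsample_frac * length(g))),
                     integer(1))
    abort_if(any(keep_n < 2L),
             "subsample_frac leaves a ploidy group with < 2 libraries")
    for (b in seq_len(n_subsample_runs)) {
      retained <- with_seed(derive_seed(seed, sprintf("ploidynet.subsample.%d", b)), {
        unlist(lapply(names(by_group), function(g) {
          sample(by_group[[g]], keep_n[[g]])
        }), use.names = FALSE)
      })
      retained <- libs[libs %in% retained]   # preserve column order
      runs[[length(runs) + 1L]] <- do_run(retained, "subsample80",
                                          sprintf("SUB_%03d", b))
    }
  }

  structure(list(reference = reference, runs = runs),
            class = "perturbation_runs")
}

#' Edge-preservation Jaccard index
#'
#' `|E_ref intersect E_run| / |E_ref union E_run|` over canonical undirected
#' edge keys; 1 when both edge sets are empty.
#'
#' @param e_ref,e_run Edge data frames (`node_a`, `node_b`) or character
#'   vectors of edge keys.
#' @return A number in `[0, 1]`.
#' @export
edge_jaccard <- function(e_ref, e_run) {
  a <- unique(edge_keys(e_ref))
  b <- unique(edge_keys(e_run))
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Adjusted Rand index between two module partitions
#'
#' Chance-corrected pair-counting agreement, computed over the intersection of
#' the two node sets (label-invariant; 1 for identical partitions up to
#' relabelling, expected 0 for independent random partitions).
#'
#' @param p_ref,p_run `module_partition` objects or named label vectors.
#' @return The ARI, or `NA` if fewer than 2 nodes are shared.
#' @export
module_ari <- function(p_ref, p_run) {
  a <- if (inherits(p_ref, "module_partition")) p_ref$labels else p_ref
  b <- if (inherits(p_run, "module_partition")) p_run$labels else p_run
  common <- intersect(names(a), names(b))
  if (length(common) < 2L) return(NA_real_)
  res <- mclust::adjustedRandIndex(a[common], b[common])
  # degenerate case (both partitions all-singleton or both one-cluster):
  # the index is 0/0 but the partitions agree perfectly
  if (is.nan(res)) 1 else res
}

#' Switch-gene recovery
#'
#' Fraction of the reference switch set re-identified in a perturbed run:
#' `|S_ref intersect S_run| / |S_ref|`. `NA` when the reference set is empty
#' (excluded from summaries).
#'
#' @param s_ref,s_run Character vectors of switch gene ids.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
switch_recovery <- function(s_ref, s_run) {
  if (length(s_ref) == 0L) return(NA_real_)
  length(intersect(s_ref, s_run)) / length(unique(s_ref))
}

#' Consensus switch set across perturbation runs
#'
#' Per-gene recovery frequency over completed runs, and the set of genes at or
#' above `min_frac` (default: recovered in at least half of the runs).
#'
#' @param switch_sets List of character vectors (one per run), or a
#'   `perturbation_runs` object.
#' @param min_frac Minimum recovery frequency (default 0.5).
#' @return List with `consensus` (character vector) and `frequency` (data
#'   frame `gene`, `frequency`, sorted by decreasing frequency).
#' @export
consensus_switches <- function(switch_sets, min_frac = 0.5) {
  if (inherits(switch_sets, "perturbation_runs")) {
    switch_sets <- lapply(switch_sets$runs, `[[`, "switches")
  }
  abort_if(length(switch_sets) < 1L, "need at least one completed run")
  abort_if(min_frac < 0 || min_frac > 1, "`min_frac` must be in [0, 1]")
  n_runs <- length(switch_sets)
  genes <- sort(unique(unlist(switch_sets)))
  if (length(genes) == 0L) {
    return(list(consensus = character(0),
                frequency = data.frame(gene = character(0),
                                       frequency = numeric(0))))
  }
  freq <- rowSums(vapply(switch_sets, function(s) genes %in% s,
                         logical(length(genes)))) / n_runs
  ord <- order(-freq, genes)
  freq_df <- data.frame(gene = genes[ord], frequency = freq[ord],
                        stringsAsFactors = FALSE)
  list(consensus = freq_df$gene[freq_df$frequency >= min_frac],
       frequency = freq_df)
}

# Per-run metric table for a perturbation set.
evaluate_runs <- function(perturbations) {
  ref <- perturbations$reference
  rows <- lapply(perturbations$runs, function(r) {
    data.frame(run_id = r$run_id, type = r$type,
               retained_n = length(r$retained),
               jaccard = edge_jaccard(ref$network$edges, r$network$edges),
               ari = module_ari(ref$partition, r$partition),
               recovery = switch_recovery(ref$switches, r$switches),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize robustness metrics
#'
#' Per run-type mean, sample standard deviation and median of edge Jaccard,
#' module ARI and switch recovery, plus pooled medians across all runs.
#' Undefined metrics (`NA`) are excluded and counted.
#'
#' @param runs_df Per-run metric table (columns `type`, `jaccard`, `ari`,
#'   `recovery`), e.g. from [robustness_report()].
#' @return List with `per_type` (data frame: type, metric, n, mean, sd,
#'   median), `pooled` (data frame: metric, median), `n_runs` and
#'   `n_undefined`.
#' @export
summarize_robustness <- function(runs_df) {
  abort_if(!all(c("type", "jaccard", "ari", "recovery") %in% names(runs_df)),
           "`runs_df` must have columns type, jaccard, ari, recovery")
  metrics <- c("jaccard", "ari", "recovery")
  per_type <- do.call(rbind, lapply(split(runs_df, runs_df$type), function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]][!is.na(d[[m]])]
      data.frame(type = d$type[1L], metric = m, n = length(v),
                 mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_,
                 median = median(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_type) <- NULL
  pooled <- data.frame(
    metric = metrics,
    median = vapply(metrics, function(m) median(runs_df[[m]], na.rm = TRUE),
                    numeric(1)),
    stringsAsFactors = FALSE)
  list(per_type = per_type, pooled = pooled, n_runs = nrow(runs_df),
       n_undefined = sum(is.na(runs_df[metrics])))
}

#' Assemble a robustness report
#'
#' Computes the per-run metric table, the per-type/pooled summaries and the
#' consensus switch set for a set of perturbation runs.
#'
#' @param perturbations A `perturbation_runs` object from
#'   [run_perturbations()].
#' @param min_frac Consensus threshold (see [consensus_switches()]).
#' @return An object of class `robustness_report`: list with `runs` (per-run
#'   metrics), `summary` (from [summarize_robustness()]), `consensus` and
#'   `frequency`.
#' @export
robustness_report <- function(perturbations, min_frac = 0.5) {
  abort_if(!inherits(perturbations, "perturbation_runs"),
           "`perturbations` must come from run_perturbations()")
  runs_df <- evaluate_runs(perturbations)
  cons <- consensus_switches(perturbations, min_frac = min_frac)
  structure(list(runs = runs_df,
                 summary = summarize_robustness(runs_df),
                 consensus = cons$consensus,
                 frequency = cons$frequency,
                 min_frac = min_frac),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d runs, %d consensus switch genes (min_frac = %g)\n",
              nrow(x$runs), length(x$consensus), x$min_frac))
  print(x$summary$per_type)
  invisible(x)
}
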