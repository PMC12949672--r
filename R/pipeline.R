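## Seeded end-to-end orchestration: DE -> network -> switches -> robustness ->
## hotspots, with all stage outputs and a machine-readable run report.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the conventional
#' defaults: DET calling at FDR < 0.05 and |log2FC| > 2, network node entry at
#' FDR < 0.05 and |log2FC| > 1, 1-Mb hotspot bins, 80% subsampling, >= 50%
#' consensus. Parameters with no conventional value (the correlation threshold
#' `tau`, the rate model, `k_max`) are always echoed in the run report.
#'
#' @param fdr_max FDR threshold for DET calling and node selection.
#' @param lfc_det Absolute log2 fold-change threshold for DET calling.
#' @param lfc_node Absolute log2 fold-change threshold for network node entry.
#' @param tau Absolute-correlation edge threshold.
#' @param kpi_min,z_max,apcc_max Switch-region thresholds
#'   (see [classify_switch()]).
#' @param min_frac Consensus switch frequency threshold.
#' @param bin_size Hotspot bin width in bp.
#' @param hotspot_fdr FDR threshold for hotspot calling.
#' @param n_subsample_runs Number of subsampling robustness runs.
#' @param subsample_frac Retained fraction per ploidy group.
#' @param k_max Largest module count considered by the elbow rule.
#' @param de_method Test statistic for [de_test()].
#' @param rate_model Expected-rate model for [poisson_enrichment()].
#' @param loo_unit Leave-one-out unit (`"library"` or `"genotype"`).
#' @param min_count Low-count filter threshold.
#' @param seed Master seed for all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_max = 0.05, lfc_det = 2.0, lfc_node = 1.0,
                            tau = 0.45, kpi_min = 0.8, z_max = 2.5,
                            apcc_max = 0, min_frac = 0.5, bin_size = 1e6,
                            hotspot_fdr = 0.05, n_subsample_runs = 91L,
                            subsample_frac = 0.8, k_max = 12L,
                            de_method = "welch_log",
                            rate_model = "gene_density",
                            loo_unit = "library", min_count = 3L,
                            seed = 1L) {
  cfg <- structure(
    list(fdr_max = fdr_max, lfc_det = lfc_det, lfc_node = lfc_node, tau = tau,
         kpi_min = kpi_min, z_max = z_max, apcc_max = apcc_max,
         min_frac = min_frac, bin_size = bin_size, hotspot_fdr = hotspot_fdr,
         n_subsample_runs = as.integer(n_subsample_runs),
         subsample_frac = subsample_frac, k_max = as.integer(k_max),
         de_method = de_method, rate_model = rate_model, loo_unit = loo_unit,
         min_count = as.integer(min_count), seed = as.integer(seed)),
    class = "pipeline_config")
  abort_if(cfg$fdr_max <= 0 || cfg$fdr_max >= 1, "`fdr_max` must be in (0, 1)")
  abort_if(cfg$lfc_det <= 0 || cfg$lfc_node <= 0, "fold-change thresholds must be positive")
  abort_if(cfg$tau <= 0 || cfg$tau > 1, "`tau` must be in (0, 1]")
  abort_if(cfg$subsample_frac <= 0 || cfg$subsample_frac > 1,
           "`subsample_frac` must be in (0, 1]")
  abort_if(cfg$n_subsample_runs < 0L, "`n_subsample_runs` must be >= 0")
  cfg
}

#' Run the full ploidy-contrast network pipeline
#'
#' Executes, in order: library-size normalisation and low-count filtering;
#' differential expression with BH adjustment (DETs reported at the stringent
#' thresholds, node selection at the network-entry thresholds); genotype
#' centering, shrinkage correlation and network construction over the selected
#' nodes; module detection and switch classification; leave-one-out and
#' subsampling robustness with consensus switch calling; and a Poisson hotspot
#' scan of the switch loci. All artifacts are written under `out_dir` when
#' given; identical inputs, configuration and seed yield byte-identical
#' artifacts (the report's wall-clock fields aside).
#'
#' @param counts Count matrix or path to `counts.tsv`.
#' @param samples Sample sheet or path to `samples.tsv`.
#' @param loci BED data frame or path; `NULL` skips the hotspot stage.
#' @param genome Named chromosome-length vector or path; `NULL` skips the
#'   hotspot stage.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage artifacts (created; `NULL` writes
#'   nothing).
#' @return An object of class `pipeline_result`: list with `de` (DE table),
#'   `dets`, `nodes`, `reference` (network/partition/classification/switches),
#'   `robustness` (a `robustness_report`), `hotspots` (a `bin_table` or
#'   `NULL`) and `report` (the run report, also written as `report.json`).
#' @export
run_pipeline <- function(counts, samples, loci = NULL, genome = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  abort_if(!inherits(config, "pipeline_config"),
           "`config` must come from pipeline_config()")
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(loci)) loci <- read_bed(loci)
  if (is.character(genome)) genome <- read_genome(genome)
  validate_count_matrix(counts)
  validate_samples(samples, colnames(counts))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] ...", name))
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  ## -- differential expression ---------------------------------------------
  de <- stage("preprocess_de", {
    de_analysis(counts, samples, method = config$de_method,
                fdr_max = config$fdr_max, lfc_min = config$lfc_det,
                min_count = config$min_count,
                seed = derive_seed(config$seed, "ploidynet.pipeline.de"))
  })
  dets <- select_dets(de, config$fdr_max, config$lfc_det)
  nodes <- select_dets(de, config$fdr_max, config$lfc_node)
  abort_if(length(nodes) < 3L,
           "fewer than 3 transcripts pass the node-selection thresholds")

  ## -- network + switches on all libraries ---------------------------------
  norm <- normalize_library_size(counts)
  logexpr <- log2(norm[nodes, , drop = FALSE] + 1)
  reference <- stage("corrnet_swim", {
    network_switch_run(logexpr, samples, tau = config$tau,
                       k_max = config$k_max,
                       seed = derive_seed(config$seed, "ploidynet.pipeline.net"),
                       kpi_min = config$kpi_min, z_max = config$z_max,
                       apcc_max = config$apcc_max)
  })

  ## -- robustness -----------------------------------------------------------
  robustness <- stage("robustness", {
    pert <- run_perturbations(
      logexpr, samples, reference = reference, tau = config$tau,
      k_max = config$k_max, n_subsample_runs = config$n_subsample_runs,
      subsample_frac = config$subsample_frac, loo_unit = config$loo_unit,
      kpi_min = config$kpi_min, z_max = config$z_max,
      apcc_max = config$apcc_max,
      seed = derive_seed(config$seed, "ploidynet.pipeline.robustness"))
    robustness_report(pert, min_frac = config$min_frac)
  })

  ## -- hotspots -------------------------------------------------------------
  hotspots <- NULL
  if (!is.null(loci) && !is.null(genome)) {
    hotspots <- stage("hotspot", {
      bt <- bin_genome(loci, genome, bin_size = config$bin_size)
      mapped_switches <- intersect(reference$switches, loci$name)
      bt <- poisson_enrichment(bt, mapped_switches,
                               rate_model = config$rate_model)
      call_hotspots(bt, fdr_max = config$hotspot_fdr)
    })
  }

  report <- build_report(config, counts, de, dets, nodes, reference,
                         robustness, hotspots, timings)
  result <- structure(list(de = de, dets = dets, nodes = nodes,
                           reference = reference, robustness = robustness,
                           hotspots = hotspots, report = report,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

build_report <- function(config, counts, de, dets, nodes, reference,
                         robustness, hotspots, timings) {
  hotspot_rows <- if (!is.null(hotspots)) {
    hb <- hotspots$bins[hotspots$bins$is_hotspot, , drop = FALSE]
    lapply(seq_len(nrow(hb)), function(i) as.list(hb[i, , drop = FALSE]))
  } else NULL
  list(
    config = unclass(config),
    data = list(n_transcripts = nrow(counts), n_libraries = ncol(counts),
                n_retained = nrow(de)),
    de = list(n_dets = length(dets), n_nodes_selected = length(nodes)),
    network = list(n_nodes = length(reference$network$nodes),
                   n_edges = nrow(reference$network$edges),
                   lambda = reference$lambda,
                   tau = config$tau,
                   k_modules = reference$partition$k),
    switches = list(n_switches = length(reference$switches),
                    ids = reference$switches),
    robustness = list(summary_per_type = robustness$summary$per_type,
                      pooled_medians = robustness$summary$pooled,
                      n_runs = robustness$summary$n_runs,
                      n_consensus = length(robustness$consensus)),
    hotspots = list(n_hotspots = if (is.null(hotspots)) NA_integer_ else
      sum(hotspots$bins$is_hotspot),
      bins = hotspot_rows),
    software = list(package = "ploidynet",
                    version = as.character(packageVersion("ploidynet"))),
    wall_clock_sec = as.list(timings))
}

write_pipeline_outputs <- function(result, out_dir) {
  write_tsv(result$de, file.path(out_dir, "de_table.tsv"))
  writeLines(result$dets, file.path(out_dir, "consensus_dets.txt"))
  write_tsv(result$reference$network$edges, file.path(out_dir, "edges.tsv"))
  jsonlite::write_json(
    list(lambda = result$reference$lambda, tau = result$config$tau,
         n_nodes = length(result$reference$network$nodes),
         n_edges = nrow(result$reference$network$edges)),
    file.path(out_dir, "network_meta.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(result$reference$classification,
            file.path(out_dir, "cartography.tsv"))
  writeLines(result$reference$switches, file.path(out_dir, "switches.txt"))
  write_tsv(result$robustness$runs, file.path(out_dir, "robustness_runs.tsv"))
  write_tsv(result$robustness$summary$per_type,
            file.path(out_dir, "robustness_summary.tsv"))
  write_tsv(result$robustness$frequency,
            file.path(out_dir, "consensus_switches.tsv"))
  if (!is.null(result$hotspots)) {
    write_tsv(result$hotspots$bins, file.path(out_dir, "hotspots.tsv"))
  }
  report <- result$report
  report$wall_clock_sec <- NULL   # keep report.json byte-stable across reruns
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat(sprintf("  transcripts: %d (retained %d), libraries: %d\n",
              r$data$n_transcripts, r$data$n_retained, r$data$n_libraries))
  cat(sprintf("  DETs (FDR<%.2g, |log2FC|>%.2g): %d; network nodes: %d\n",
              x$config$fdr_max, x$config$lfc_det, r$de$n_dets,
              r$network$n_nodes))
  cat(sprintf("  edges: %d (tau = %.2f, lambda = %.3f), modules: %d\n",
              r$network$n_edges, r$network$tau, r$network$lambda,
              r$network$k_modules))
  cat(sprintf("  switch genes: %d (consensus: %d of %d runs' sets)\n",
              r$switches$n_switches, r$robustness$n_consensus,
              r$robustness$n_runs))
  if (!is.null(x$hotspots)) {
    cat(sprintf("  hotspot bins: %d\n", r$hotspots$n_hotspots))
  }
  invisible(x)
}
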