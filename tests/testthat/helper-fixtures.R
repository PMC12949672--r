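# Shared fixtures, built in code. The default dataset (the study-design-sized
# experiment) is simulated once per session and memoised.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- simulate_ploidy_experiment(sim_config())
  }
  .fixture_cache$default
}

# A small, fast configuration exercising all planted structure.
tiny_config <- function(...) {
  args <- list(n_genes = 80, n_modules = 2, module_size = 20, n_switch = 6,
               genome = c(chrA = 1e7),
               hotspot_bins = data.frame(chrom = "chrA", bin = 3L))
  over <- list(...)
  do.call(sim_config, c(over, args[setdiff(names(args), names(over))]))
}

# Log-CPM matrix restricted to network nodes, plus metadata, for a dataset.
node_expression <- function(dataset, lfc_node = 1) {
  de <- de_analysis(dataset$counts, dataset$samples)
  nodes <- select_dets(de, fdr_max = 0.05, lfc_min = lfc_node)
  norm <- normalize_library_size(dataset$counts)
  list(de = de, nodes = nodes,
       logexpr = log2(norm[nodes, , drop = FALSE] + 1))
}

# A deterministic toy network: two modules {a1..a4}, {b1..b4}, dense inside,
# plus a hub "h" connected across.
toy_network <- function() {
  edges <- rbind(
    t(combn(paste0("a", 1:4), 2)),
    t(combn(paste0("b", 1:4), 2)),
    cbind("h", c("a1", "a2", "b1", "b2")))
  net <- list(nodes = c(paste0("a", 1:4), paste0("b", 1:4), "h", "iso"),
              edges = data.frame(node_a = pmin(edges[, 1], edges[, 2]),
                                 node_b = pmax(edges[, 1], edges[, 2]),
                                 r_star = 0.9, stringsAsFactors = FALSE),
              tau = 0.5)
  class(net) <- "coexpression_network"
  net
}

toy_partition <- function() {
  labs <- c(rep(1L, 4), rep(2L, 4), 1L, 2L)
  names(labs) <- c(paste0("a", 1:4), paste0("b", 1:4), "h", "iso")
  structure(list(labels = labs, k = 2L, inertia = NA_real_),
            class = "module_partition")
}
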