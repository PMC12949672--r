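# Perturbation harness, stability metrics and consensus switch calling.

small_run_input <- function(seed = 21) {
  d <- simulate_ploidy_experiment(
    tiny_config(n_genes = 40, n_modules = 2, module_size = 12, n_switch = 4,
                seed = seed))
  norm <- normalize_library_size(d$counts)
  list(logexpr = log2(norm + 1), samples = d$samples)
}

test_that("the perturbation schedule yields one LOO run per library plus subsamples", {
  inp <- small_run_input()
  pert <- run_perturbations(inp$logexpr, inp$samples, n_subsample_runs = 5,
                            seed = 2)
  expect_length(pert$runs, 18 + 5)
  types <- vapply(pert$runs, `[[`, character(1), "type")
  expect_equal(sum(types == "LOO"), 18L)
  expect_equal(sum(types == "subsample80"), 5L)
  # LOO retains n-1; subsample80 retains round(0.8 * n), stratified by ploidy
  for (r in pert$runs) {
    if (r$type == "LOO") expect_length(r$retained, 17L)
    else {
      expect_length(r$retained, 14L)
      pl <- inp$samples$ploidy[match(r$retained, inp$samples$library_id)]
      expect_equal(as.integer(table(pl)), c(7L, 7L))
    }
  }
  # no subsamples: LOO only
  pert0 <- run_perturbations(inp$logexpr, inp$samples, n_subsample_runs = 0,
                             seed = 2)
  expect_length(pert0$runs, 18L)
  # seeded reproducibility of the retained-library lists
  pert2 <- run_perturbations(inp$logexpr, inp$samples, n_subsample_runs = 5,
                             seed = 2)
  expect_identical(lapply(pert$runs, `[[`, "retained"),
                   lapply(pert2$runs, `[[`, "retained"))
  # genotype-level LOO removes whole genotypes
  pg <- run_perturbations(inp$logexpr, inp$samples, n_subsample_runs = 0,
                          loo_unit = "genotype", seed = 2)
  expect_length(pg$runs, 6L)
  expect_true(all(vapply(pg$runs, function(r) length(r$retained), integer(1)) == 15L))
})

test_that("edge Jaccard matches set arithmetic", {
  e1 <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"))
  e2 <- data.frame(node_a = c("b", "c"), node_b = c("c", "d"))
  expect_equal(edge_jaccard(e1, e1), 1)
  expect_equal(edge_jaccard(e1, e2), 1 / 3)
  expect_equal(edge_jaccard(e1, data.frame(node_a = "x", node_b = "y")), 0)
  expect_equal(edge_jaccard(e1[0, ], e2[0, ]), 1)   # both empty
  # orientation of the pairs does not matter
  e3 <- data.frame(node_a = c("b", "c"), node_b = c("a", "b"))
  expect_equal(edge_jaccard(e1, e3), 1)
})

test_that("module ARI is label-invariant and matches pair counting", {
  a <- setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(module_ari(a, a), 1)
  expect_equal(module_ari(a, setNames(c(9, 9, 4, 4), letters[1:4])), 1)
  expect_equal(module_ari(a, setNames(c(1, 2, 1, 2), letters[1:4])), -0.5)
  expect_true(is.na(module_ari(a, setNames(1, "z"))))
  set.seed(17)
  for (r in 1:40) {
    n <- sample(4:9, 1)
    x <- setNames(sample(1:3, n, replace = TRUE), sprintf("n%d", 1:n))
    y <- setNames(sample(1:4, n, replace = TRUE), sprintf("n%d", 1:n))
    expect_equal(module_ari(x, y), ari_oracle(unname(x), unname(y)),
                 tolerance = 1e-12)
  }
})

test_that("ARI of independent random partitions is centred on zero", {
  set.seed(10)
  vals <- replicate(200, {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:4, 60, replace = TRUE)
    names(x) <- names(y) <- sprintf("n%d", 1:60)
    module_ari(x, y)
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("switch recovery is the recovered fraction of the reference set", {
  expect_equal(switch_recovery(c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(switch_recovery(c("g1", "g2"), c("g2", "g9")), 0.5)
  expect_equal(switch_recovery(c("g1", "g2"), character(0)), 0)
  expect_true(is.na(switch_recovery(character(0), c("g1"))))
})

test_that("consensus switches honour the frequency threshold", {
  sets <- list(c("a", "b"), c("a", "c"), c("a", "b", "d"))
  cons <- consensus_switches(sets, min_frac = 0.5)
  expect_setequal(cons$consensus, c("a", "b"))     # b: 2/3 in, c/d: 1/3 out
  expect_equal(cons$frequency$frequency[cons$frequency$gene == "a"], 1)
  expect_setequal(consensus_switches(sets, min_frac = 0)$consensus,
                  c("a", "b", "c", "d"))
  expect_length(consensus_switches(list(character(0)))$consensus, 0)
})

test_that("robustness summaries reproduce hand-computed statistics", {
  runs_df <- data.frame(run_id = c("L1", "L2", "S1"),
                        type = c("LOO", "LOO", "subsample80"),
                        retained_n = c(17, 17, 14),
                        jaccard = c(0.8, 1.0, 0.6),
                        ari = c(1, 1, NA),
                        recovery = c(1, 0.5, 0.25))
  s <- summarize_robustness(runs_df)
  loo_j <- s$per_type[s$per_type$type == "LOO" & s$per_type$metric == "jaccard", ]
  expect_equal(loo_j$mean, 0.9)
  expect_equal(loo_j$sd, sd(c(0.8, 1)))
  expect_equal(loo_j$sd, 0.1414, tolerance = 1e-3)
  # pooled medians match a sort-based oracle; NAs are excluded and counted
  med_oracle <- function(v) { v <- sort(v[!is.na(v)]); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1]) }
  expect_equal(s$pooled$median[s$pooled$metric == "jaccard"],
               med_oracle(runs_df$jaccard))
  expect_equal(s$pooled$median[s$pooled$metric == "recovery"],
               med_oracle(runs_df$recovery))
  expect_equal(s$n_undefined, 1L)
})

test_that("metrics all equal one when a run reproduces the reference", {
  inp <- small_run_input()
  ref <- ploidynet:::network_switch_run(inp$logexpr, inp$samples, tau = 0.45,
                                        k_max = 6)
  expect_equal(edge_jaccard(ref$network$edges, ref$network$edges), 1)
  expect_equal(module_ari(ref$partition, ref$partition), 1)
  if (length(ref$switches) > 0) {
    expect_equal(switch_recovery(ref$switches, ref$switches), 1)
  }
  # and the full report's metrics stay within their ranges
  pert <- run_perturbations(inp$logexpr, inp$samples, n_subsample_runs = 4,
                            k_max = 6, seed = 5)
  rep <- robustness_report(pert)
  expect_true(all(rep$runs$jaccard >= 0 & rep$runs$jaccard <= 1))
  expect_true(all(is.na(rep$runs$ari) | abs(rep$runs$ari) <= 1))
  expect_true(all(is.na(rep$runs$recovery) |
                    (rep$runs$recovery >= 0 & rep$runs$recovery <= 1)))
  expect_true(all(rep$frequency$frequency > 0 & rep$frequency$frequency <= 1))
})
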