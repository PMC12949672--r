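# Module detection, cartography metrics, APCC and the switch rule.

test_that("module detection recovers planted blocks and is deterministic", {
  # two near-perfectly intra-correlated blocks
  set.seed(4)
  f <- matrix(rnorm(2 * 12), nrow = 2)
  m <- rbind(f[rep(1, 8), ] + matrix(rnorm(96, sd = 0.05), 8),
             f[rep(2, 7), ] + matrix(rnorm(84, sd = 0.05), 7))
  dimnames(m) <- list(sprintf("t%02d", 1:15), sprintf("L%d", 1:12))
  truth <- rep(1:2, c(8, 7))
  sc <- shrinkage_correlation(m)
  part <- detect_modules(sc, k_max = 6, seed = 9)
  expect_equal(part$k, 2L)
  expect_equal(mclust::adjustedRandIndex(part$labels, truth), 1)
  part2 <- detect_modules(sc, k_max = 6, seed = 9)
  expect_identical(part$labels, part2$labels)

  expect_equal(detect_modules(sc, k_max = 1)$k, 1L)
  expect_true(all(detect_modules(sc, k_max = 1)$labels == 1L))
  expect_equal(detect_modules(sc, k = 3)$k, 3L)
  expect_warning(p <- detect_modules(sc, k_max = 50), "capped")
})

test_that("cartography computes degree, within-module z and K_pi", {
  carto <- cartography(toy_network(), toy_partition())
  rownames(carto) <- carto$node
  # a-nodes: 3 edges inside module 1; a1/a2 also touch hub h (module 1)
  expect_equal(carto["a3", "degree"], 3L)
  expect_equal(carto["a3", "k_in"], 3L)
  expect_equal(carto["a3", "kpi"], 0)
  # hub h: 4 edges, 2 inside its module (a1, a2) -> K_pi = 1 - (2/4)^2
  expect_equal(carto["h", "degree"], 4L)
  expect_equal(carto["h", "k_in"], 2L)
  expect_equal(carto["h", "kpi"], 0.75)
  # isolated node: degree 0, K_pi 0 by convention
  expect_equal(carto["iso", "degree"], 0L)
  expect_equal(carto["iso", "kpi"], 0)
  # z-standardisation identity: within-module z sums to 0 where sd > 0
  for (mod in unique(carto$module)) {
    z <- carto$z[carto$module == mod]
    if (any(z != 0)) expect_equal(sum(z), 0, tolerance = 1e-12)
  }
})

test_that("K_pi boundaries and monotonicity hold", {
  kpi <- function(k_in, k_g) 1 - (k_in / k_g)^2
  expect_equal(kpi(4, 4), 0)    # all edges inside
  expect_equal(kpi(0, 4), 1)    # all edges outside
  expect_equal(kpi(2, 4), 0.75)
  for (k_g in c(3, 7, 20)) {
    vals <- kpi(0:k_g, k_g)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("APCC is the mean neighbour correlation on the centered matrix", {
  base <- c(1, -2, 0.5, 3, -1, 0.3, 2, -2.5)
  m <- rbind(g = base,
             copy1 = base, copy2 = base,   # exact copies
             neg = -base)                  # exact negation
  colnames(m) <- sprintf("L%d", 1:8)
  edges <- data.frame(node_a = c("copy1", "copy2", "g"),
                      node_b = c("g", "g", "neg"),
                      r_star = c(1, 1, -1))
  net <- structure(list(nodes = rownames(m), edges = edges, tau = 0.5),
                   class = "coexpression_network")
  a <- apcc(m, net)
  expect_equal(unname(a["copy1"]), 1)
  expect_equal(unname(a["neg"]), -1)
  # two neighbours at r = +1 and -1 average to APCC = 0... and mixing in the
  # two copies gives (1 + 1 - 1)/3
  expect_equal(unname(a["g"]), 1 / 3)
  iso_net <- structure(list(nodes = c(rownames(m), "lonely"), edges = edges,
                            tau = 0.5), class = "coexpression_network")
  m2 <- rbind(m, lonely = rnorm(8))
  expect_true(is.na(apcc(m2, iso_net)[["lonely"]]))
})

test_that("the switch rule combines K_pi, z, APCC and non-isolation", {
  carto <- data.frame(node = c("s", "pos", "lowkpi", "highz", "iso"),
                      module = 1L, degree = c(10L, 10L, 10L, 10L, 0L),
                      k_in = c(1L, 1L, 9L, 1L, 0L),
                      z = c(1.0, 1.0, 1.0, 3.0, 0),
                      kpi = c(0.9, 0.9, 0.19, 0.9, 0))
  a <- c(s = -0.3, pos = 0.3, lowkpi = -0.5, highz = -0.5, iso = NA)
  cls <- classify_switch(carto, a)
  expect_identical(switch_ids(cls), "s")
  expect_identical(cls$role,
                   c("fight-club", "date", "fight-club", "fight-club",
                     "isolated"))
  # the switch set shrinks (weakly) as apcc_max decreases
  d <- default_dataset()
  nx <- node_expression(d)
  run <- ploidynet:::network_switch_run(nx$logexpr, d$samples)
  cls_loose <- classify_switch(run$classification, setNames(run$classification$apcc, run$classification$node),
                               apcc_max = 0)
  cls_tight <- classify_switch(run$classification, setNames(run$classification$apcc, run$classification$node),
                               apcc_max = -0.3)
  expect_true(all(switch_ids(cls_tight) %in% switch_ids(cls_loose)))
  # switches are never isolated
  expect_true(all(cls_loose$degree[cls_loose$is_switch] > 0))
})

test_that("planted switch genes are recovered on the default fixture", {
  d <- default_dataset()
  nx <- node_expression(d)
  run <- ploidynet:::network_switch_run(nx$logexpr, d$samples)
  truth <- d$truth$switch_ids
  hits <- length(intersect(run$switches, truth))
  precision <- hits / length(run$switches)
  recall <- hits / length(truth)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.8)
})
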