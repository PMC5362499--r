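test_that("correlation shift spans [1, 3]", {
  expect_equal(correlation_shift(0.4, 0.4), 1)
  expect_equal(correlation_shift(0.69, -0.49), 2.18)
  expect_equal(correlation_shift(1, -1), 3)
  expect_error(correlation_shift(1.2, 0), class = "lsp_error_input")
})

test_that("node weights mix gene and lncRNA differentiality", {
  expect_equal(node_weight(0), 0)
  expect_equal(node_weight(log2(4), log2(2), d = 1.5, alpha = 0.5), 1.75)
  # |log2| symmetry of the gene term
  expect_equal(node_weight(log2(1 / 4)), node_weight(log2(4)))
  # alpha = 1 makes the lncRNA layer inert
  expect_equal(node_weight(log2(3), log2(8), d = 2.5, alpha = 1),
               abs(log2(3)))
  # monotone in the gene fold change
  expect_gt(node_weight(2, 1, 1.5), node_weight(1.5, 1, 1.5))
})

test_that("prize normalization follows the printed max rule", {
  expect_equal(normalize_node_weights(c(1, 2, 5), beta = 15), c(0, 3, 12))
  expect_equal(normalize_node_weights(c(3, 3, 3)), c(0, 0, 0))
  expect_equal(normalize_node_weights(c(0, 0)), c(0, 0))
  # prizes depend on raw weights only through (w - wmin) and wmax
  w <- c(1, 2, 5)
  expect_equal(normalize_node_weights(w),
               15 * (w - min(w)) / max(w))
  expect_equal(normalize_node_weights(c(1, 2, 5), range_normalize = TRUE),
               15 * c(0, 1, 4) / 4)
  expect_true(all(normalize_node_weights(runif(10, 0, 9)) <= 15))
})

test_that("edge weights and costs track the correlation change", {
  expect_equal(edge_weight(0.5, 0.5), 1)
  expect_equal(edge_weight(0.3, 0.7), 0.6)
  expect_gt(edge_weight(0.5, 0.4), edge_weight(0.5, 0.1))  # monotone
  expect_equal(normalize_edge_weights(c(0.2, 0.6, 1.0)), c(0, 0.4, 0.8))
  expect_equal(normalize_edge_weights(c(0, 0)), c(0, 0))
})

test_that("weight_pathway handles skips, degenerate data and missing genes", {
  pg <- pathway_graph("p1", paste0("g", 1:4),
                      data.frame(from = paste0("g", 1:3),
                                 to = paste0("g", 2:4)))
  pair <- tiny_pair(nl = 3, np = 4, n_per = 6, seed = 2)
  net <- association_network(tibble::tibble(lncrna = "L1", pcg = "g2"))

  # no risk lncRNA associated with the pathway -> skipped
  expect_message(
    expect_null(weight_pathway(pg, pair, risk_lncrnas = character(),
                               network = net)),
    "skipped")

  wp <- weight_pathway(pg, pair, "L1", net, quiet = TRUE)
  expect_s3_class(wp, "weighted_pathway")
  expect_true(all(wp$nodes$prize >= 0 & wp$nodes$prize <= 15))
  expect_true(all(wp$edges$w >= -1 & wp$edges$w <= 1))
  expect_true(all(wp$lnc_links$d >= 1 & wp$lnc_links$d <= 3))

  # a pathway gene absent from the matrices: w = 0, incident edge neutral
  pg2 <- pathway_graph("p2", c(paste0("g", 1:4), "ghost"),
                       data.frame(from = c(paste0("g", 1:3), "g4"),
                                  to = c(paste0("g", 2:4), "ghost")))
  wp2 <- weight_pathway(pg2, pair, "L1", net, quiet = TRUE)
  expect_equal(wp2$nodes$w[wp2$nodes$node == "ghost"], 0)
  ghost_edge <- wp2$edges$from == "ghost" | wp2$edges$to == "ghost"
  expect_equal(wp2$edges$w[ghost_edge], 1)
})

test_that("identical groups give zero prizes and unit edge weights", {
  # case samples are an exact copy of control samples
  set.seed(4)
  samples <- c(paste0("c", 1:5), paste0("t", 1:5))
  groups <- setNames(rep(c("control", "case"), each = 5), samples)
  base_l <- matrix(2^rnorm(2 * 5, 6), 2, 5)
  base_g <- matrix(2^rnorm(3 * 5, 6), 3, 5)
  lnc <- cbind(base_l, base_l)
  pcg <- cbind(base_g, base_g)
  dimnames(lnc) <- list(c("L1", "L2"), samples)
  dimnames(pcg) <- list(c("g1", "g2", "g3"), samples)
  pair <- expression_pair(lnc, pcg, groups)
  pg <- pathway_graph("p", c("g1", "g2", "g3"),
                      data.frame(from = c("g1", "g2"), to = c("g2", "g3")))
  net <- association_network(tibble::tibble(lncrna = "L1", pcg = "g1"))
  wp <- weight_pathway(pg, pair, "L1", net, quiet = TRUE)
  expect_equal(wp$nodes$prize, rep(0, 3))
  expect_equal(wp$edges$w, rep(1, 2))
})

test_that("planted nodes receive larger prizes than background", {
  # moderate planted signal; the separation should hold in nearly every
  # replicate
  sc <- simulation_scenario(topology = "linear", n = 4, e = 0.5, p = 0.2,
                            N = 250)
  fx <- fixture_pathways()
  ok <- vapply(1:25, function(i) {
    ds <- simulate_dataset(sc, seed = 5000 + i, quiet = TRUE)
    lt <- differential_table(ds$pair$lnc, ds$pair$groups)
    risk <- select_risk_lncrnas(lt)
    wp <- weight_pathway(fx$linear, ds$pair, risk, ds$network, quiet = TRUE)
    if (is.null(wp)) return(NA)
    planted <- wp$nodes$node %in% ds$truth$altered_nodes
    mean(wp$nodes$prize[planted]) > mean(wp$nodes$prize[!planted])
  }, NA)
  expect_gte(sum(ok, na.rm = TRUE), 24)
})
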