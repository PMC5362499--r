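test_that("objective sums tree costs minus prizes", {
  inst <- list(prizes = c(a = 5, b = 5, c = 0),
               edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                  cost = c(0.3, 0.9)))
  sol <- pcst_solve(inst)
  expect_setequal(sol$nodes, c("a", "b"))
  expect_equal(sol$objective, 0.3 - 10)
  expect_equal(pcst_objective(sol, inst), -9.7)
  expect_equal(pcst_objective(list(nodes = character(), tree = NULL), inst), 0)

  single <- list(prizes = c(a = 12), edges = data.frame(from = character(),
                 to = character(), cost = numeric()))
  s <- pcst_solve(single)
  expect_equal(s$objective, -12)
  expect_equal(nrow(s$tree), 0L)
})

test_that("the exhaustive oracle solves hand-checked instances", {
  # path a-b-c-d: taking everything wins despite the weak middle
  inst <- list(prizes = c(a = 10, b = 0.1, c = 0.1, d = 10),
               edges = data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "d"), cost = 0.5))
  sol <- pcst_solve_exact(inst)
  expect_setequal(sol$nodes, c("a", "b", "c", "d"))
  expect_equal(sol$objective, 1.5 - 20.2)

  # all prizes 0: every single node ties at 0; lexicographic winner
  zero <- list(prizes = c(b = 0, a = 0, c = 0),
               edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                  cost = 1))
  expect_identical(pcst_solve_exact(zero)$nodes, "a")

  # one rewarding node among expensive edges: that node alone
  lone <- list(prizes = c(a = 0, b = 1, c = 0),
               edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                  cost = 1.5))
  expect_identical(pcst_solve_exact(lone)$nodes, "b")

  expect_error(pcst_solve_exact(random_pcst_instance(16)),
               class = "lsp_error_too_large")
})

test_that("a costly bridge between clusters is not crossed", {
  nodes <- c(paste0("a", 1:5), paste0("b", 1:5))
  edges <- data.frame(
    from = c(paste0("a", 1:4), paste0("b", 1:4), "a5"),
    to = c(paste0("a", 2:5), paste0("b", 2:5), "b1"),
    cost = c(rep(0.1, 8), 30))
  inst <- list(prizes = setNames(c(rep(5, 5), rep(4, 5)), nodes),
               edges = edges)
  sol <- pcst_solve(inst)
  expect_setequal(sol$nodes, paste0("a", 1:5))   # richer cluster only
  expect_equal(sol$objective, pcst_solve_exact(inst, max_nodes = 10)$objective)
})

test_that("all-zero prizes give an explicit no-region result", {
  inst <- list(prizes = c(a = 0, b = 0),
               edges = data.frame(from = "a", to = "b", cost = 0.2))
  sol <- pcst_solve(inst)
  expect_identical(sol$status, "no_region")
  expect_length(sol$nodes, 0L)
  expect_equal(sol$objective, 0)
})

test_that("heuristic matches the oracle on seeded random instances", {
  set.seed(42)
  for (i in 1:40) {
    inst <- random_pcst_instance(12)
    a <- pcst_solve(inst)
    b <- pcst_solve_exact(inst, max_nodes = 12)
    oa <- if (a$status == "no_region") 0 else a$objective
    expect_equal(oa, min(b$objective, 0), tolerance = 1e-9,
                 label = paste("instance", i))
  }
})

test_that("objective responds monotonically to prize and cost scaling", {
  set.seed(7)
  for (i in 1:10) {
    inst <- random_pcst_instance(12)
    base <- pcst_solve(inst)$objective
    up_p <- inst; up_p$prizes <- up_p$prizes * 2
    up_c <- inst; up_c$edges$cost <- up_c$edges$cost * 2
    expect_lte(pcst_solve(up_p)$objective, base + 1e-9)
    sol_c <- pcst_solve(up_c)
    oc <- if (sol_c$status == "no_region") 0 else sol_c$objective
    expect_gte(oc, base - 1e-9)
  }
})

test_that("reported edges are a spanning tree of the region", {
  set.seed(11)
  for (i in 1:10) {
    inst <- random_pcst_instance(12)
    sol <- pcst_solve(inst)
    if (sol$status == "no_region") next
    expect_equal(nrow(sol$tree), length(sol$nodes) - 1L)
    g <- igraph::graph_from_data_frame(sol$tree, directed = FALSE,
                                       vertices = data.frame(name = sol$nodes))
    expect_equal(igraph::components(g)$no, 1L)
    # objective recomputable from parts
    expect_equal(sol$objective,
                 sum(sol$tree$cost) -
                   sum(inst$prizes[sol$nodes]), tolerance = 1e-9)
  }
})

test_that("iterative extraction returns disjoint profitable regions", {
  nodes <- data.frame(node = c(paste0("a", 1:4), "x", paste0("b", 1:4)),
                      w = c(rep(6, 4), 0, rep(5, 4)))
  edges <- data.frame(
    from = c(paste0("a", 1:3), "a4", "x", paste0("b", 1:3)),
    to = c(paste0("a", 2:4), "x", "b1", paste0("b", 2:4)),
    w = c(rep(0.2, 3), 1, 1, rep(0.2, 3)))
  wp <- manual_weighted_pathway(nodes, edges)

  one <- extract_subpathways(wp, max_regions = 1)
  expect_length(one, 1L)
  sol1 <- pcst_solve(list(prizes = setNames(wp$nodes$prize, wp$nodes$node),
                          edges = wp$edges[, c("from", "to", "cost")]))
  expect_identical(sort(one[[1]]$nodes), sort(sol1$nodes))

  many <- extract_subpathways(wp, max_regions = 5)
  expect_lte(length(many), 5L)
  all_nodes <- unlist(lapply(many, `[[`, "nodes"))
  expect_equal(anyDuplicated(all_nodes), 0L)
  expect_named(many, paste0("toy_", seq_along(many)))
})
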