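# prize/cost extraction shared by the solvers
pcst_instance <- function(x) {
  if (inherits(x, "weighted_pathway")) {
    nodes <- sort(x$nodes$node, method = "radix")
    prizes <- setNames(x$nodes$prize, x$nodes$node)[nodes]
    edges <- x$edges |> select("from", "to", "cost")
  } else {
    stopifnot(is.list(x), !is.null(x$prizes), !is.null(x$edges))
    nodes <- sort(unique(c(names(x$prizes), x$edges$from, x$edges$to)),
                  method = "radix")
    prizes <- setNames(rep(0, length(nodes)), nodes)
    prizes[names(x$prizes)] <- x$prizes
    edges <- as_tibble(x$edges)
    if (!"cost" %in% names(edges)) names(edges)[3] <- "cost"
  }
  list(nodes = nodes, prizes = unname(prizes),
       ei = cbind(match(edges$from, nodes), match(edges$to, nodes)) - 1L,
       costs = edges$cost, edges = edges)
}

pcst_solution <- function(nodes, inst, status = "ok") {
  tree <- tibble(from = character(), to = character(), cost = numeric())
  if (length(nodes) > 1L) {
    sub <- inst$edges |> filter(.data$from %in% nodes, .data$to %in% nodes)
    g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    mt <- igraph::mst(g, weights = sub$cost)
    td <- igraph::as_data_frame(mt)
    tree <- tibble(from = pmin(td$from, td$to), to = pmax(td$from, td$to),
                   cost = td$cost) |>
      arrange(.data$from, .data$to)
  }
  obj <- sum(tree$cost) - sum(inst$prizes[match(nodes, inst$nodes)])
  if (!length(nodes)) obj <- 0
  structure(list(nodes = nodes, tree = tree, objective = obj,
                 status = status),
            class = "pcst_solution")
}

#' @export
print.pcst_solution <- function(x, ...) {
  if (x$status == "no_region") {
    cat("<pcst_solution> no region\n")
  } else {
    cat("<pcst_solution> ", length(x$nodes), " nodes, ", nrow(x$tree),
        " tree edges, objective ", format(x$objective, digits = 6), "\n",
        sep = "")
  }
  invisible(x)
}

#' Objective value of a subgraph solution
#'
#' Sum of the solution's tree-edge costs minus the sum of its node prizes;
#' the empty solution scores 0.
#'
#' @param solution A `pcst_solution` (or a list with `nodes` and `tree`).
#' @param x A `weighted_pathway` or a `list(prizes = , edges = )` instance.
#' @return The objective value (lower is better).
#' @export
pcst_objective <- function(solution, x) {
  inst <- pcst_instance(x)
  if (!length(solution$nodes)) return(0)
  sum(solution$tree$cost) - sum(inst$prizes[match(solution$nodes, inst$nodes)])
}

#' Exhaustive prize-collecting Steiner subgraph oracle
#'
#' Enumerates every non-empty connected node subset, takes the
#' minimum-spanning-tree edge cost of each, and returns the subset
#' minimizing cost minus prize. Ties broken by smaller objective, then
#' fewer nodes, then lexicographically smallest node ids. Intended as a
#' testing oracle for small graphs.
#'
#' @param x A `weighted_pathway` or `list(prizes = named numeric,
#'   edges = data frame from/to/cost)`.
#' @param max_nodes Refusal threshold, default 15.
#' @return A `pcst_solution`.
#' @export
pcst_solve_exact <- function(x, max_nodes = 15) {
  inst <- pcst_instance(x)
  if (length(inst$nodes) > max_nodes) {
    abort(paste0("graph too large for exhaustive search (",
                 length(inst$nodes), " > ", max_nodes, " nodes)"),
          class = "lsp_error_too_large")
  }
  res <- pcst_enumerate_cpp(length(inst$nodes), inst$ei, inst$costs,
                            inst$prizes)
  pcst_solution(inst$nodes[res$nodes], inst)
}

#' Find the minimum-cost prize-collecting connected subgraph
#'
#' Minimizes `sum(c_e) - sum(b_v)` over connected subgraphs of the
#' weighted pathway. Disconnected inputs are solved per component and the
#' best component returned. When no subgraph attains a negative objective
#' (e.g. all prizes zero) an explicit "no region" result is returned.
#'
#' The search combines strong pruning of component minimum spanning trees
#' with a deterministic steepest-descent local search (node removals and
#' cheapest-path additions), so results are reproducible; on small graphs
#' it is validated against the exhaustive [pcst_solve_exact()] oracle.
#'
#' @inheritParams pcst_solve_exact
#' @return A `pcst_solution`; `status` is `"no_region"` when nothing
#'   profitable exists.
#' @export
pcst_solve <- function(x) {
  inst <- pcst_instance(x)
  if (!length(inst$nodes)) return(pcst_solution(character(), inst, "no_region"))
  res <- pcst_local_search_cpp(length(inst$nodes), inst$ei, inst$costs,
                               inst$prizes)
  sol <- pcst_solution(inst$nodes[res$nodes], inst)
  if (sol$objective >= -.lsp_tol) {
    return(pcst_solution(character(), inst, "no_region"))
  }
  sol
}

#' Iteratively extract node-disjoint subpathway regions
#'
#' Solves the prize-collecting search, removes the found region's nodes
#' from the pathway, and re-solves, up to `max_regions` times or until no
#' profitable region remains. Regions are node-disjoint and numbered
#' `<pathway id>_k` in discovery order.
#'
#' @param wp A `weighted_pathway`.
#' @param max_regions Maximum number of regions, default 1.
#' @return A named list of `pcst_solution`s (possibly empty).
#' @export
extract_subpathways <- function(wp, max_regions = 1) {
  stopifnot(inherits(wp, "weighted_pathway"))
  nodes <- wp$nodes
  edges <- wp$edges
  out <- list()
  for (k in seq_len(max_regions)) {
    inst <- list(prizes = setNames(nodes$prize, nodes$node),
                 edges = edges |> select("from", "to", "cost"))
    sol <- pcst_solve(inst)
    if (sol$status == "no_region") break
    out[[paste0(wp$pathway$id, "_", k)]] <- sol
    nodes <- nodes |> filter(!.data$node %in% sol$nodes)
    edges <- edges |> filter(!.data$from %in% sol$nodes,
                             !.data$to %in% sol$nodes)
    if (nrow(nodes) == 0L) break
  }
  out
}
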