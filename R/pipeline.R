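# evaluate code under a temporary RNG state seeded with `seed`
# (NULL seed = use the current RNG stream as-is)
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Identify risk lncRNA-associated dysregulated subpathways
#'
#' End-to-end run: differential expression of lncRNAs and genes, risk
#' lncRNA selection, per-pathway node prizes / edge costs, prize-collecting
#' connected-subgraph search, node- and edge-level permutation P-values
#' with a joint P, multiple-testing adjustment, and key-lncRNA selection.
#'
#' The node-level background pool holds the raw weights of every expressed
#' gene associated with at least one lncRNA of interest (it depends only
#' on the expression data and the association network); the edge-level
#' pool holds the differentialities of all edges across the supplied
#' pathway collection, so significance is defined over the collection,
#' not per pathway in isolation.
#'
#' @param pair An [expression_pair()] (already expression-filtered as
#'   desired; see [filter_low_expression()]).
#' @param pathways A [pathway_graph()] or list of them.
#' @param network A `lnc_assoc` association network
#'   ([association_network()]).
#' @param fdr_cut,fc_hi,fc_lo Risk-lncRNA thresholds
#'   ([select_risk_lncrnas()]).
#' @param alpha,beta Node-weighting constants (defaults 0.5, 15).
#' @param gamma,pert Key-lncRNA constants (defaults 0.3, 0.8).
#' @param pseudocount Abundance pseudocount, default 0.01.
#' @param permutations Randomizations per level, default 1000.
#' @param max_regions Regions extracted per pathway, default 1.
#' @param adjust_method `"BH"` (default) or `"bonferroni"`.
#' @param range_normalize,strict_tail,add_one,lnc_scope Switches passed to
#'   [weight_pathway()] / [permutation_p()].
#' @param seed Optional integer seed for the permutation draws (the run is
#'   then deterministic end to end).
#' @param quiet Suppress per-pathway skip messages and small-pool
#'   warnings.
#' @return A tibble of class `lnc_subpathway_result`, one row per reported
#'   subpathway: `pathway_id`, `region_id`, `n_nodes`, `n_edges`,
#'   `s_node`, `s_edge`, `p_node`, `p_edge`, `p_joint`, `p_adjusted`,
#'   `nodes`, `lncrnas`, `key_lncrnas` (last three are list-columns).
#'   Attributes: `all_regions` (including regions dropped from the
#'   report), `log` (risk-set size, pool sizes, skipped pathways),
#'   `params`.
#' @export
lnc_subpathway <- function(pair, pathways, network,
                           fdr_cut = 0.25, fc_hi = 1.5, fc_lo = 2 / 3,
                           alpha = 0.5, beta = 15, gamma = 0.3, pert = 0.8,
                           pseudocount = 0.01, permutations = 1000,
                           max_regions = 1,
                           adjust_method = "BH", range_normalize = FALSE,
                           strict_tail = FALSE, add_one = FALSE,
                           lnc_scope = c("risk", "all"), seed = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(pair, "expression_pair"))
  lnc_scope <- match.arg(lnc_scope)
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  ids <- vapply(pathways, function(p) p$id, "")
  names(pathways) <- ids

  pcg_table <- differential_table(pair$pcg, pair$groups, pseudocount)
  lnc_table <- differential_table(pair$lnc, pair$groups, pseudocount)
  risk <- select_risk_lncrnas(lnc_table, fdr_cut, fc_hi, fc_lo)
  scope <- if (lnc_scope == "risk") risk else
    intersect(unique(network$lncrna), rownames(pair$lnc))

  log <- list(n_risk = length(risk), risk_lncrnas = risk, seed = seed,
              skipped = character())
  if (length(scope) == 0L) {
    if (!quiet) inform("no risk lncRNAs: empty report")
    return(empty_result(log))
  }

  run <- function() {
    weighted <- list()
    for (p in pathways) {
      wp <- weight_pathway(p, pair, risk, network, alpha, beta, pseudocount,
                           range_normalize, lnc_scope,
                           pcg_table = pcg_table, lnc_table = lnc_table,
                           quiet = quiet)
      if (is.null(wp)) log$skipped <<- c(log$skipped, p$id) else
        weighted[[p$id]] <- wp
    }
    if (!length(weighted)) {
      if (!quiet) inform("no pathway involves a lncRNA-associated gene")
      return(empty_result(log))
    }

    # node background: raw weights of every expressed, associated gene
    links_all <- network |>
      as_tibble() |>
      filter(.data$lncrna %in% scope, .data$pcg %in% rownames(pair$pcg))
    lp <- group_correlations(pair, tibble(a = links_all$lncrna,
                                          b = links_all$pcg), pseudocount)
    lfc_lnc <- setNames(lnc_table$log2_fc, lnc_table$feature)
    lfc_pcg <- setNames(pcg_table$log2_fc, pcg_table$feature)
    node_pool <- tibble(node = links_all$pcg,
                        d = correlation_shift(lp$r_case, lp$r_control),
                        lfc = abs(lfc_lnc[links_all$lncrna])) |>
      group_by(.data$node) |>
      summarise(w = (1 - alpha) * sum(.data$d * .data$lfc)) |>
      mutate(w = .data$w + alpha * abs(lfc_pcg[.data$node])) |>
      pull("w")

    edge_pool <- bind_rows(lapply(weighted, function(w) {
      w$edges |> select("from", "to", "diff")
    })) |>
      distinct(.data$from, .data$to, .keep_all = TRUE) |>
      pull("diff")

    log$node_pool_size <<- length(node_pool)
    log$edge_pool_size <<- length(edge_pool)

    rows <- list()
    for (pid in sort(names(weighted), method = "radix")) {
      wp <- weighted[[pid]]
      regions <- extract_subpathways(wp, max_regions)
      for (rid in names(regions)) {
        sol <- regions[[rid]]
        sc <- observed_scores(sol$nodes, wp)
        p_node <- permutation_p(sc$s_node, node_pool, sc$n_nodes,
                                permutations, strict_tail, add_one)
        p_edge <- if (is.na(sc$s_edge)) 1 else
          permutation_p(sc$s_edge, edge_pool, sc$n_edges, permutations,
                        strict_tail, add_one)
        assoc <- sort(unique(
          wp$lnc_links$lncrna[wp$lnc_links$node %in% sol$nodes]),
          method = "radix")
        ranked <- importance_table(sol$nodes, wp, gamma)
        keys <- select_key_lncrnas(ranked, sol$nodes, pert)
        rows[[rid]] <- tibble(
          pathway_id = pid, region_id = rid,
          n_nodes = sc$n_nodes, n_edges = sc$n_edges,
          s_node = sc$s_node, s_edge = sc$s_edge,
          p_node = p_node, p_edge = p_edge,
          p_joint = joint_p(p_node, p_edge),
          objective = sol$objective,
          nodes = list(sol$nodes), lncrnas = list(assoc),
          key_lncrnas = list(keys)
        )
      }
    }
    if (!length(rows)) return(empty_result(log))
    all_regions <- adjust_subpathways(bind_rows(rows), adjust_method)
    report <- subpathway_report(all_regions)
    as_result(report, all_regions, log,
              params = list(alpha = alpha, beta = beta, gamma = gamma,
                            pert = pert, fdr_cut = fdr_cut, fc_hi = fc_hi,
                            fc_lo = fc_lo, pseudocount = pseudocount,
                            permutations = permutations,
                            max_regions = max_regions,
                            adjust_method = adjust_method,
                            range_normalize = range_normalize,
                            strict_tail = strict_tail, add_one = add_one,
                            lnc_scope = lnc_scope, seed = seed))
  }
  if (quiet) {
    withCallingHandlers(
      with_local_seed(seed, run()),
      lsp_warning_small_pool = function(w) invokeRestart("muffleWarning"),
      lsp_warning_zero_variance = function(w) invokeRestart("muffleWarning")
    )
  } else {
    with_local_seed(seed, run())
  }
}

empty_result <- function(log, params = list()) {
  empty <- tibble(
    pathway_id = character(), region_id = character(),
    n_nodes = integer(), n_edges = integer(),
    s_node = numeric(), s_edge = numeric(),
    p_node = numeric(), p_edge = numeric(), p_joint = numeric(),
    objective = numeric(), p_adjusted = numeric(),
    nodes = list(), lncrnas = list(), key_lncrnas = list()
  )
  as_result(empty, empty, log, params)
}

as_result <- function(report, all_regions, log, params) {
  attr(report, "all_regions") <- all_regions
  attr(report, "log") <- log
  attr(report, "params") <- params
  class(report) <- c("lnc_subpathway_result", class(report))
  report
}

#' Write a subpathway report to TSV
#'
#' List-columns (nodes, lncRNAs, key lncRNAs) are collapsed with `;`.
#'
#' @param result A `lnc_subpathway_result`.
#' @param file Output path.
#' @export
write_subpathway_report <- function(result, file) {
  flat <- result |>
    as_tibble() |>
    mutate(across(c("nodes", "lncrnas", "key_lncrnas"),
                  ~ purrr::map_chr(.x, paste, collapse = ";")))
  readr::write_tsv(flat, file)
  invisible(file)
}

#' @export
print.lnc_subpathway_result <- function(x, ...) {
  log <- attr(x, "log")
  cat("<lnc_subpathway_result> ", nrow(x), " reported subpathway(s); ",
      log$n_risk %||% 0, " risk lncRNA(s)\n", sep = "")
  if (nrow(x)) {
    fmt_p <- function(p) {
      R <- attr(x, "params")$permutations %||% NA
      ifelse(p == 0 & !is.na(R), paste0("<", format(signif(1 / R, 2))),
             format(p, digits = 3))
    }
    df <- x |>
      as_tibble() |>
      transmute(.data$region_id, .data$n_nodes, .data$n_edges,
                p_joint = fmt_p(.data$p_joint),
                p_adjusted = fmt_p(.data$p_adjusted),
                key_lncrnas = purrr::map_chr(.data$key_lncrnas, paste,
                                             collapse = ","))
    print(df, n = 20)
  }
  invisible(x)
}
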