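# shared study plumbing: run the full pipeline on one simulated dataset
# and return the best joint P per pathway (NA when a pathway reported
# no subpathway)
study_run_once <- function(ds, permutations, seed, max_regions = 1) {
  res <- lnc_subpathway(ds$pair, unname(ds$pair_pathways %||%
                                          fixture_pathways()),
                        ds$network, permutations = permutations,
                        max_regions = max_regions, seed = seed,
                        quiet = TRUE)
  tab <- as_tibble(res)
  if (nrow(tab) == 0L) {
    return(list(result = res, p_best = setNames(numeric(), character())))
  }
  best <- tab |>
    group_by(.data$pathway_id) |>
    summarise(p_best = min(.data$p_joint))
  list(result = res,
       p_best = setNames(best$p_best, best$pathway_id))
}

# derive a stream of per-replicate seeds from one master seed
derive_seeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Sensitivity study over a grid of dysregulation strengths
#'
#' For every cell of the `(n, e, p)` grid, simulates `replicates`
#' datasets with dysregulation planted in the target pathway, runs the
#' full identification pipeline, and records the fraction of replicates
#' whose best subpathway of that pathway attains a joint P below each
#' cutoff, along with mean scores.
#'
#' @param n_grid,e_grid,p_grid Numeric grids of node fold change, edge
#'   correlation change, and altered proportion.
#' @param N Sample size (two equal groups), default 250.
#' @param topology Pathway receiving the planted signal, default
#'   `"linear"`.
#' @param replicates Datasets per cell, default 30.
#' @param permutations Randomizations per significance level, default 500.
#' @param alphas Significance cutoffs, default `c(0.01, 0.05)`.
#' @param seed Master seed; every replicate's generator and permutation
#'   seeds derive from it.
#' @return A tibble of class `lsp_sensitivity`: one row per cell with
#'   `ratio_p01`, `ratio_p05`, `mean_p_joint`, `mean_s_node`,
#'   `mean_s_edge`.
#' @export
run_sensitivity_study <- function(n_grid = c(2, 4, 7),
                                  e_grid = c(0.1, 0.5, 0.9),
                                  p_grid = c(0.1, 0.5, 0.9),
                                  N = 250, topology = "linear",
                                  replicates = 30, permutations = 500,
                                  alphas = c(0.01, 0.05), seed = 1) {
  grid <- tidyr::expand_grid(n = n_grid, e = e_grid, p = p_grid)
  seeds <- derive_seeds(seed, nrow(grid) * replicates * 2)
  si <- 0L
  cells <- purrr::pmap(grid, function(n, e, p) {
    sc <- simulation_scenario(topology = topology, n = n, e = e, p = p, N = N)
    p_best <- s_node <- s_edge <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      si <<- si + 2L
      ds <- simulate_dataset(sc, seed = seeds[si - 1L], quiet = TRUE)
      run <- study_run_once(ds, permutations, seeds[si])
      p_best[r] <- unname(run$p_best[topology]) %||% NA_real_
      rows <- run$result |> as_tibble() |>
        filter(.data$pathway_id == topology)
      if (nrow(rows)) {
        s_node[r] <- rows$s_node[which.min(rows$p_joint)]
        s_edge[r] <- rows$s_edge[which.min(rows$p_joint)]
      }
    }
    sig <- function(a) mean(!is.na(p_best) & p_best < a)
    tibble(n = n, e = e, p = p, N = N, topology = topology,
           replicates = replicates,
           ratio_p01 = sig(alphas[1]), ratio_p05 = sig(alphas[2]),
           mean_p_joint = mean(p_best, na.rm = TRUE),
           mean_s_node = mean(s_node, na.rm = TRUE),
           mean_s_edge = mean(s_edge, na.rm = TRUE))
  })
  out <- bind_rows(cells)
  class(out) <- c("lsp_sensitivity", class(out))
  out
}

#' False-positive-rate study on null data
#'
#' Simulates null datasets (equal group means and covariances) under each
#' strategy preset, runs the full pipeline, and records per pathway model
#' the fraction of replicates whose best reported subpathway of that
#' pathway attains a joint P below `alpha`.
#'
#' @param strategies Null presets, default `c("choi", "goel")`.
#' @param topologies Pathway models scored, default both fixtures.
#' @param N Sample size, default 250.
#' @param replicates Null datasets per strategy, default 100.
#' @param permutations Randomizations per level, default 500.
#' @param alpha False-positive threshold on the joint P, default 0.01.
#' @param seed Master seed.
#' @return A tibble of class `lsp_fpr`: `strategy`, `topology`, `fpr`
#'   (in \[0, 1\]), `replicates`.
#' @export
run_fpr_study <- function(strategies = c("choi", "goel"),
                          topologies = c("linear", "erbb"), N = 250,
                          replicates = 100, permutations = 500,
                          alpha = 0.01, seed = 1) {
  sc <- simulation_scenario(topology = "both", p = 0, N = N)
  seeds <- derive_seeds(seed, length(strategies) * replicates * 2)
  si <- 0L
  out <- purrr::map(strategies, function(st) {
    hits <- matrix(FALSE, replicates, length(topologies),
                   dimnames = list(NULL, topologies))
    for (r in seq_len(replicates)) {
      si <<- si + 2L
      ds <- simulate_null(st, sc, seed = seeds[si - 1L])
      run <- study_run_once(ds, permutations, seeds[si])
      for (tp in topologies) {
        pb <- unname(run$p_best[tp])
        hits[r, tp] <- isTRUE(!is.na(pb) && pb < alpha)
      }
    }
    tibble(strategy = st, topology = topologies,
           fpr = colMeans(hits), replicates = replicates)
  })
  out <- bind_rows(out)
  class(out) <- c("lsp_fpr", class(out))
  out
}

#' Region-recovery (recall) study with planted subpathway regions
#'
#' Plants the four documented regions (one linear, three ERBB-like),
#' simulates replicate datasets, runs the identification pipeline, and
#' computes per region the mean fraction of region genes recovered by the
#' union of identified subpathways.
#'
#' @param n Node fold change, default 3.
#' @param e Edge correlation change, default 0.5.
#' @param N Sample size, default 300.
#' @param replicates Datasets, default 20.
#' @param permutations Randomizations per level, default 500.
#' @param regions Named list of planted regions, default
#'   [planted_regions()].
#' @param max_regions Regions extracted per pathway, default 3.
#' @param seed Master seed.
#' @return A tibble of class `lsp_recall`: `region`, `size`,
#'   `mean_recall`, `replicates`.
#' @export
run_recall_study <- function(n = 3, e = 0.5, N = 300, replicates = 20,
                             permutations = 500, regions = planted_regions(),
                             max_regions = 3, seed = 1) {
  sc <- simulation_scenario(topology = "both", n = n, e = e, N = N,
                            regions = regions)
  seeds <- derive_seeds(seed, replicates * 2)
  rec <- matrix(NA_real_, replicates, length(regions),
                dimnames = list(NULL, names(regions)))
  for (r in seq_len(replicates)) {
    ds <- simulate_dataset(sc, seed = seeds[2 * r - 1L], quiet = TRUE)
    run <- study_run_once(ds, permutations, seeds[2 * r],
                          max_regions = max_regions)
    found <- unique(unlist(as_tibble(run$result)$nodes, use.names = FALSE))
    for (rg in names(regions)) {
      rec[r, rg] <- length(intersect(found, regions[[rg]])) /
        length(regions[[rg]])
    }
  }
  out <- tibble(region = names(regions),
                size = unname(lengths(regions)[names(regions)]),
                mean_recall = unname(colMeans(rec)),
                replicates = replicates)
  class(out) <- c("lsp_recall", class(out))
  out
}
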