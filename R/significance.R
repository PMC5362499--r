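#' Observed node- and edge-level scores of a region
#'
#' The node score is the mean *raw* node weight `w_v` over the region's
#' nodes. The edge score is the mean edge differentiality `1 - w_e`
#' (i.e. `|delta correlation|`) over the region's induced edge set — all
#' pathway edges with both endpoints in the region, not only the search
#' tree — so that "larger = more dysregulated" holds at both levels. A
#' region without edges has an undefined edge score (`NA`), which maps to
#' an edge P-value of 1.
#'
#' @param region_nodes Character vector of region gene ids.
#' @param wp The `weighted_pathway` the region came from.
#' @return List with `s_node`, `s_edge`, `n_nodes`, `n_edges`.
#' @export
observed_scores <- function(region_nodes, wp) {
  nd <- wp$nodes |> filter(.data$node %in% region_nodes)
  ed <- wp$edges |> filter(.data$from %in% region_nodes,
                           .data$to %in% region_nodes)
  list(
    s_node = mean(nd$w),
    s_edge = if (nrow(ed)) mean(ed$diff) else NA_real_,
    n_nodes = nrow(nd), n_edges = nrow(ed)
  )
}

#' Permutation P-value of an observed score against a background pool
#'
#' Each of the `R` randomizations draws `k` values from the background
#' pool without replacement and records their mean; the P-value is the
#' fraction of randomizations whose mean is equal to or greater than the
#' observed score. If the pool holds fewer than `k` values, sampling falls
#' back to with-replacement with a classed warning. The resolution is
#' exactly `1/R`; a reported 0 means "below 1/R".
#'
#' @param s_obs Observed score; `NA` returns 1.
#' @param pool Numeric background values.
#' @param k Number of values per randomization (the region size).
#' @param R Number of randomizations, default 1000.
#' @param strict_tail Count only strictly greater random scores (the
#'   printed indicator) instead of the default equal-or-greater.
#' @param add_one Report `(count + 1) / (R + 1)` so P is never exactly 0.
#' @return The permutation P-value.
#' @export
permutation_p <- function(s_obs, pool, k, R = 1000, strict_tail = FALSE,
                          add_one = FALSE) {
  if (is.na(s_obs)) return(1)
  stopifnot(R >= 1, k >= 1, length(pool) >= 1)
  replace <- length(pool) < k
  if (replace) {
    warn(paste0("background pool (", length(pool),
                ") smaller than region size (", k,
                "); sampling with replacement"),
         class = "lsp_warning_small_pool")
  }
  s_rand <- if (k == 1L) {
    pool[sample.int(length(pool), R, replace = TRUE)]
  } else {
    vapply(seq_len(R), function(i) {
      mean(pool[sample.int(length(pool), k, replace = replace)])
    }, 0)
  }
  hits <- if (strict_tail) sum(s_rand > s_obs + .lsp_tol)
          else sum(s_rand >= s_obs - .lsp_tol)
  if (add_one) (hits + 1) / (R + 1) else hits / R
}

#' Joint node-edge P-value
#'
#' The product of the node-level and edge-level permutation P-values,
#' clamped to \[0, 1\]. Note the product of two independent uniforms is
#' not uniform (its CDF is `t * (1 - log t)`), so joint P-values are
#' anticonservative and are compared against permutation-calibrated
#' thresholds downstream.
#'
#' @param p_node,p_edge P-values in \[0, 1\].
#' @return The joint P-value.
#' @examples
#' joint_p(0.001, 0.344)
#' @export
joint_p <- function(p_node, p_edge) {
  pmin(1, pmax(0, p_node * p_edge))
}

#' Multiple-testing adjustment across subpathways
#'
#' Benjamini-Hochberg (default) or Bonferroni adjustment of the joint
#' P-values across all tested subpathways.
#'
#' @param results Tibble with a `p_joint` column.
#' @param method `"BH"` or `"bonferroni"`.
#' @return `results` with a `p_adjusted` column.
#' @export
adjust_subpathways <- function(results, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  results$p_adjusted <- p.adjust(results$p_joint, method = method)
  results
}

#' Final subpathway report table
#'
#' Retains subpathways with at least one associated risk lncRNA and sorts
#' by adjusted P, then joint P, then pathway id. Dropped regions remain
#' available in the `all_regions` attribute of the pipeline result.
#'
#' @param results Tibble of scored subpathways (one row per region, with
#'   `lncrnas` list-column).
#' @return The filtered, sorted report tibble.
#' @export
subpathway_report <- function(results) {
  results |>
    filter(purrr::map_int(.data$lncrnas, length) > 0L) |>
    arrange(.data$p_adjusted, .data$p_joint, .data$pathway_id,
            .data$region_id)
}
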