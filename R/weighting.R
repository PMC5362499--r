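#' Correlation-shift factor between two conditions
#'
#' `d = 1 + |r_case - r_control|`, the multiplier applied to an associated
#' lncRNA's differential expression when scoring a gene. Lies in
#' \[1, 3\]: 1 when the gene-lncRNA correlation is unchanged, 3 when it
#' flips between the extremes.
#'
#' @param r_case,r_control Pearson correlations in \[-1, 1\] computed
#'   within each sample group.
#' @return The shift factor(s).
#' @examples
#' correlation_shift(0.69, -0.49) # 2.18
#' @export
correlation_shift <- function(r_case, r_control) {
  if (any(abs(r_case) > 1, na.rm = TRUE) ||
      any(abs(r_control) > 1, na.rm = TRUE)) {
    abort("correlations must lie in [-1, 1]", class = "lsp_error_input")
  }
  1 + abs(r_case - r_control)
}

#' Raw node weight from differential expression and the lncRNA layer
#'
#' `w_v = alpha * |log2FC_v| + (1 - alpha) * sum_j d_j * |log2FC_Lj|`
#' over the risk lncRNAs associated with the gene. With no associated
#' lncRNAs the sum term is 0; with `alpha = 1` the lncRNA layer is inert.
#'
#' @param log2_fc_gene The gene's log2 fold change.
#' @param lnc_log2_fc Numeric vector of associated risk lncRNAs' log2 fold
#'   changes (may be empty).
#' @param d Correlation-shift factors, same length as `lnc_log2_fc`
#'   ([correlation_shift()]); missing correlations contribute `d = 1`.
#' @param alpha Mixing constant in \[0, 1\], default 0.5.
#' @return The raw weight `w_v >= 0`.
#' @examples
#' node_weight(log2(4), log2(2), d = 1.5, alpha = 0.5) # 1.75
#' @export
node_weight <- function(log2_fc_gene, lnc_log2_fc = numeric(), d = numeric(),
                        alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, length(lnc_log2_fc) == length(d))
  d[is.na(d)] <- 1
  alpha * abs(log2_fc_gene) + (1 - alpha) * sum(d * abs(lnc_log2_fc))
}

#' Normalize raw node weights into prizes
#'
#' `b_v = beta * (w_v - w_min) / w_max` within one pathway (the printed
#' rule); `range_normalize = TRUE` divides by `(w_max - w_min)` instead.
#' All-zero (or constant, under the default rule degenerate `w_max = 0`)
#' weights give all-zero prizes.
#'
#' @param w Raw node weights (non-negative).
#' @param beta Prize scale, default 15.
#' @param range_normalize Use `(max - min)` as the denominator.
#' @return Prizes `b_v` in \[0, beta\].
#' @examples
#' normalize_node_weights(c(1, 2, 5)) # 0 3 12
#' @export
normalize_node_weights <- function(w, beta = 15, range_normalize = FALSE) {
  stopifnot(beta > 0)
  if (!length(w)) return(numeric())
  wmin <- min(w)
  denom <- if (range_normalize) max(w) - wmin else max(w)
  if (denom <= 0) return(rep(0, length(w)))
  beta * (w - wmin) / denom
}

#' Raw edge weight from the between-group correlation change
#'
#' `w_e = 1 - |r_case - r_control|` for the two genes joined by the edge:
#' 1 for an unchanged interaction, smaller the more the co-expression
#' shifts. The complementary quantity `1 - w_e = |delta r|` is the edge
#' differentiality used for significance scoring.
#'
#' @inheritParams correlation_shift
#' @return Raw edge weight(s) in \[-1, 1\].
#' @export
edge_weight <- function(r_case, r_control) {
  2 - correlation_shift(r_case, r_control)
}

#' Normalize raw edge weights into costs
#'
#' `c_e = (w_e - w_emin) / w_emax` within one pathway (printed rule), or
#' divided by `(w_emax - w_emin)` when `range_normalize = TRUE`. Unchanged
#' edges are the most expensive to include. `w_emax <= 0` gives all-zero
#' costs.
#'
#' @param w Raw edge weights.
#' @inheritParams normalize_node_weights
#' @return Edge costs `c_e`.
#' @examples
#' normalize_edge_weights(c(0.2, 0.6, 1.0)) # 0 0.4 0.8
#' @export
normalize_edge_weights <- function(w, range_normalize = FALSE) {
  if (!length(w)) return(numeric())
  wmin <- min(w)
  denom <- if (range_normalize) max(w) - wmin else max(w)
  if (denom <= 0) return(rep(0, length(w)))
  (w - wmin) / denom
}

# Pearson correlations within each group on the log2(x + pseudocount)
# scale, for the requested (row of A, row of B) pairs. Returns the pairs
# tibble with r_case / r_control columns; groups with < 3 samples give NA
# with a classed warning.
group_correlations <- function(pair, pairs, pseudocount = 0.01) {
  ca <- pair$groups == "case"
  warn_small <- sum(ca) < 3 || sum(!ca) < 3
  if (warn_small) {
    warn("group with < 3 samples: correlations treated as 0",
         class = "lsp_warning_small_group")
  }
  lx <- log2(rbind(pair$lnc, pair$pcg) + pseudocount)
  one_group <- function(cols) {
    if (sum(cols) < 3) {
      return(rep(NA_real_, nrow(pairs)))
    }
    ids <- unique(c(pairs$a, pairs$b))
    cm <- suppressWarnings(cor(t(lx[ids, cols, drop = FALSE])))
    cm[is.na(cm)] <- 0  # zero-variance features: no co-variation signal
    cm[cbind(match(pairs$a, ids), match(pairs$b, ids))]
  }
  pairs$r_case <- one_group(ca)
  pairs$r_control <- one_group(!ca)
  pairs$r_case[is.na(pairs$r_case)] <- 0
  pairs$r_control[is.na(pairs$r_control)] <- 0
  pairs
}

#' Assign node prizes and edge costs to one pathway
#'
#' Computes, for every pathway gene, the raw weight `w_v` (differential
#' expression plus the correlation-shift-scaled differential expression of
#' its associated risk lncRNAs) and its normalized prize `b_v`, and for
#' every pathway edge the raw weight `w_e` and its normalized cost `c_e`.
#' Pathways with no gene associated with any risk lncRNA are skipped
#' (return `NULL`). Pathway genes absent from the expression matrix get
#' `w_v = 0`, and edges with an unexpressed endpoint get the neutral
#' `w_e = 1`, so topology is preserved.
#'
#' @param pathway A [pathway_graph()].
#' @param pair An [expression_pair()].
#' @param risk_lncrnas Character vector of risk lncRNA ids (see
#'   [select_risk_lncrnas()]).
#' @param network A `lnc_assoc` association network.
#' @param alpha,beta Weighting constants, defaults 0.5 and 15.
#' @param pseudocount Added before logs, default 0.01.
#' @param range_normalize Use range (max-min) denominators in the
#'   normalizations.
#' @param lnc_scope `"risk"` (default) restricts the lncRNA sum to risk
#'   lncRNAs; `"all"` uses every network lncRNA present in the data.
#' @param pcg_table,lnc_table Optional precomputed [differential_table()]s
#'   (computed from `pair` when `NULL`).
#' @param quiet Suppress the skip message.
#' @return A `weighted_pathway` object (or `NULL` if skipped) with tibbles
#'   `nodes` (`node`, `w`, `prize`, `n_lnc`, `in_expr`), `edges` (`from`,
#'   `to`, `w`, `cost`, `diff`) and `lnc_links` (`node`, `lncrna`, `d`,
#'   `lnc_log2_fc`).
#' @export
weight_pathway <- function(pathway, pair, risk_lncrnas, network,
                           alpha = 0.5, beta = 15, pseudocount = 0.01,
                           range_normalize = FALSE,
                           lnc_scope = c("risk", "all"),
                           pcg_table = NULL, lnc_table = NULL, quiet = FALSE) {
  lnc_scope <- match.arg(lnc_scope)
  scope <- if (lnc_scope == "risk") risk_lncrnas else
    unique(network$lncrna)
  scope <- intersect(scope, rownames(pair$lnc))

  links <- network |>
    as_tibble() |>
    filter(.data$lncrna %in% scope, .data$pcg %in% pathway$nodes,
           .data$pcg %in% rownames(pair$pcg))
  if (nrow(links) == 0L) {
    if (!quiet) {
      inform(paste0("pathway ", pathway$id,
                    ": no gene associated with a lncRNA of interest; skipped"))
    }
    return(NULL)
  }

  if (is.null(pcg_table)) pcg_table <- differential_table(pair$pcg, pair$groups,
                                                          pseudocount)
  if (is.null(lnc_table)) lnc_table <- differential_table(pair$lnc, pair$groups,
                                                          pseudocount)
  lfc_pcg <- setNames(pcg_table$log2_fc, pcg_table$feature)
  lfc_lnc <- setNames(lnc_table$log2_fc, lnc_table$feature)

  link_pairs <- group_correlations(
    pair, tibble(a = links$lncrna, b = links$pcg), pseudocount)
  lnc_links <- tibble(
    node = links$pcg, lncrna = links$lncrna,
    d = correlation_shift(link_pairs$r_case, link_pairs$r_control),
    lnc_log2_fc = unname(lfc_lnc[links$lncrna])
  )

  lnc_term <- lnc_links |>
    group_by(.data$node) |>
    summarise(term = sum(.data$d * abs(.data$lnc_log2_fc)),
              n_lnc = dplyr::n())
  nodes <- tibble(node = pathway$nodes) |>
    mutate(in_expr = .data$node %in% names(lfc_pcg)) |>
    left_join(lnc_term, by = "node") |>
    mutate(
      term = coalesce(.data$term, 0),
      n_lnc = coalesce(.data$n_lnc, 0L),
      w = ifelse(.data$in_expr,
                 alpha * abs(lfc_pcg[.data$node]) + (1 - alpha) * .data$term,
                 0),
      prize = normalize_node_weights(.data$w, beta, range_normalize)
    ) |>
    select("node", "w", "prize", "n_lnc", "in_expr")

  edges <- pathway$edges
  if (nrow(edges)) {
    expressed <- edges$from %in% names(lfc_pcg) & edges$to %in% names(lfc_pcg)
    w_e <- rep(1, nrow(edges))
    if (any(expressed)) {
      ep <- group_correlations(
        pair, tibble(a = edges$from[expressed], b = edges$to[expressed]),
        pseudocount)
      w_e[expressed] <- edge_weight(ep$r_case, ep$r_control)
    }
    edges <- edges |>
      mutate(w = w_e, cost = normalize_edge_weights(w_e, range_normalize),
             diff = 1 - w_e)
  } else {
    edges <- edges |> mutate(w = numeric(), cost = numeric(), diff = numeric())
  }

  structure(
    list(pathway = pathway, nodes = nodes, edges = edges,
         lnc_links = lnc_links,
         params = list(alpha = alpha, beta = beta, pseudocount = pseudocount,
                       range_normalize = range_normalize,
                       lnc_scope = lnc_scope)),
    class = "weighted_pathway"
  )
}

#' @export
print.weighted_pathway <- function(x, ...) {
  cat("<weighted_pathway> ", x$pathway$id, ": ", nrow(x$nodes), " nodes (",
      sum(x$nodes$n_lnc > 0), " lncRNA-associated), ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}
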