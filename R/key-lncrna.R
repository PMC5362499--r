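#' Importance scores of a region's associated lncRNAs
#'
#' For each lncRNA associated with at least one region gene,
#' `IS = gamma * |log2FC_L| + (1 - gamma) * sum_j d_LGj * D_Gj`, where the
#' sum runs over the region genes associated with the lncRNA, `D_Gj` is
#' the gene's degree within the region's induced subgraph (its topological
#' importance) and `d_LGj` is the gene-lncRNA correlation-shift factor
#' ([correlation_shift()]; 1 when the correlation is unavailable).
#'
#' @param region_nodes Character vector of region gene ids.
#' @param wp The `weighted_pathway` the region came from (supplies
#'   `lnc_links` with `d` and lncRNA fold changes).
#' @param gamma Mixing constant in \[0, 1\], default 0.3.
#' @return Tibble `lncrna`, `importance`, `lnc_log2_fc`, `covered`
#'   (list-column of associated region genes), ranked by importance
#'   (ties: larger |log2FC|, then id).
#' @examples
#' # a 4-fold lncRNA tied to region genes of degree 2 and 3 with shifts
#' # 1.2 / 1.5 scores 0.3*2 + 0.7*(2.4 + 4.5) = 5.43 at gamma = 0.3
#' @export
importance_table <- function(region_nodes, wp, gamma = 0.3) {
  stopifnot(gamma >= 0, gamma <= 1)
  deg <- region_degrees(region_nodes, wp$edges)
  links <- wp$lnc_links |> filter(.data$node %in% region_nodes)
  if (nrow(links) == 0L) {
    return(tibble(lncrna = character(), importance = numeric(),
                  lnc_log2_fc = numeric(), covered = list()))
  }
  links |>
    mutate(d = coalesce(.data$d, 1)) |>
    group_by(.data$lncrna) |>
    summarise(
      importance = gamma * abs(.data$lnc_log2_fc[1]) +
        (1 - gamma) * sum(.data$d * deg[.data$node]),
      lnc_log2_fc = .data$lnc_log2_fc[1],
      covered = list(unique(.data$node))
    ) |>
    arrange(desc(.data$importance), desc(abs(.data$lnc_log2_fc)),
            .data$lncrna)
}

region_degrees <- function(region_nodes, edges) {
  ed <- edges |> filter(.data$from %in% region_nodes,
                        .data$to %in% region_nodes)
  deg <- setNames(rep(0, length(region_nodes)), region_nodes)
  tab <- table(c(ed$from, ed$to))
  deg[names(tab)] <- as.numeric(tab)
  deg
}

#' Greedy selection of the key (core) lncRNA set
#'
#' Seeds the core set with the top-importance lncRNA, then walks down the
#' ranking: a candidate is added only when it strictly increases the
#' fraction `q` of region genes associated with the core set (union
#' coverage); rejected candidates are permanently discarded. The walk
#' stops once `q >= pert` or the ranking is exhausted.
#'
#' @param ranked Tibble from [importance_table()] (must be ranked).
#' @param region_nodes Character vector of the region's gene ids (the
#'   denominator of the coverage fraction).
#' @param pert Coverage target in (0, 1\], default 0.8.
#' @return Character vector of key lncRNA ids (empty when the region has
#'   no associated lncRNAs).
#' @export
select_key_lncrnas <- function(ranked, region_nodes, pert = 0.8) {
  stopifnot(pert > 0, pert <= 1)
  if (nrow(ranked) == 0L) return(character())
  denom <- length(unique(region_nodes))
  keys <- ranked$lncrna[1]
  covered <- ranked$covered[[1]]
  q <- length(covered) / denom
  i <- 2L
  while (q < pert && i <= nrow(ranked)) {
    cand <- union(covered, ranked$covered[[i]])
    q_new <- length(cand) / denom
    if (q_new > q) {
      keys <- c(keys, ranked$lncrna[i])
      covered <- cand
      q <- q_new
    }
    i <- i + 1L
  }
  keys
}
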