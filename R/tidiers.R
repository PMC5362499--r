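#' Tidy a subpathway result
#'
#' One row per reported subpathway with list-columns collapsed to
#' `;`-separated strings, suitable for writing or joining.
#'
#' @param x A `lnc_subpathway_result`.
#' @param ... Unused.
#' @return A plain tibble.
#' @exportS3Method
tidy.lnc_subpathway_result <- function(x, ...) {
  x |>
    as_tibble() |>
    mutate(
      n_lncrnas = purrr::map_int(.data$lncrnas, length),
      n_key_lncrnas = purrr::map_int(.data$key_lncrnas, length),
      across(c("nodes", "lncrnas", "key_lncrnas"),
             ~ purrr::map_chr(.x, paste, collapse = ";"))
    )
}

#' One-line summary of a subpathway run
#'
#' @param x A `lnc_subpathway_result`.
#' @param ... Unused.
#' @return A one-row tibble: risk lncRNA count, tested and reported
#'   region counts, significant count at adjusted P < 0.05, and pool
#'   sizes.
#' @exportS3Method
glance.lnc_subpathway_result <- function(x, ...) {
  log <- attr(x, "log")
  all <- attr(x, "all_regions")
  tibble(
    n_risk_lncrnas = log$n_risk %||% 0L,
    n_tested = nrow(all %||% x),
    n_reported = nrow(x),
    n_significant = sum(x$p_adjusted < 0.05),
    node_pool_size = log$node_pool_size %||% NA_integer_,
    edge_pool_size = log$edge_pool_size %||% NA_integer_
  )
}

#' @exportS3Method
tidy.weighted_pathway <- function(x, ...) {
  x$nodes |> mutate(pathway_id = x$pathway$id, .before = 1)
}

#' @exportS3Method
tidy.pcst_solution <- function(x, ...) {
  tibble(node = x$nodes, objective = x$objective, status = x$status)
}
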