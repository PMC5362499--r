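#' Plot node prizes and edge costs of a weighted pathway
#'
#' Nodes are laid out with a force-directed embedding of the pathway
#' graph; point size maps to the prize, edge darkness to the cost.
#'
#' @param object A `weighted_pathway`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.weighted_pathway <- function(object, ...) {
  g <- as_igraph(object$pathway)
  xy <- igraph::layout_with_fr(g, niter = 200)
  lay <- tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(object$nodes, by = "node")
  seg <- object$edges |>
    left_join(lay |> select("node", "x", "y"), by = c(from = "node")) |>
    left_join(lay |> select("node", xend = "x", yend = "y"),
              by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$cost)) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$prize,
                   colour = .data$n_lnc > 0)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "lncRNA-associated") +
    ggplot2::labs(title = paste0("Pathway ", object$pathway$id),
                  size = "prize b", alpha = "cost c") +
    ggplot2::theme_void()
}

#' Plot sensitivity surfaces
#'
#' Significant-replicate ratio against the node fold change, one line per
#' edge change, faceted by altered proportion.
#'
#' @param object An `lsp_sensitivity` tibble from
#'   [run_sensitivity_study()].
#' @param cutoff Which ratio to draw: `"0.01"` or `"0.05"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.lsp_sensitivity <- function(object, cutoff = "0.01", ...) {
  y <- if (cutoff == "0.01") "ratio_p01" else "ratio_p05"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data[[y]],
                               colour = factor(.data$e),
                               group = factor(.data$e))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~p, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "node fold change n",
                  y = paste0("ratio with joint P < ", cutoff),
                  colour = "edge change e") +
    ggplot2::theme_minimal()
}

#' Plot false-positive rates per null preset and pathway model
#'
#' @param object An `lsp_fpr` tibble from [run_fpr_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.lsp_fpr <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$topology, y = .data$fpr,
                               fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(y = "false positive rate") +
    ggplot2::theme_minimal()
}

#' Plot per-region recall of the planted-region study
#'
#' @param object An `lsp_recall` tibble from [run_recall_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.lsp_recall <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$region, y = .data$mean_recall)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.85, linetype = 2) +
    ggplot2::labs(y = "mean recall") +
    ggplot2::theme_minimal()
}
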