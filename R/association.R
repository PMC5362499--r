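#' lncRNA-PCG association network
#'
#' A bipartite edge table between lncRNAs and protein-coding genes. Each
#' row is one association with its provenance (`coexpr`, `cerna` or `both`),
#' the sign of the underlying co-expression (`+`, `-`, or `NA` for
#' ceRNA-only edges), and the number of supporting expression datasets.
#'
#' @param edges A data frame with columns `lncrna`, `pcg` and optionally
#'   `provenance`, `sign`, `support`.
#' @return A tibble of class `lnc_assoc`.
#' @export
association_network <- function(edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("lncrna", "pcg") %in% names(edges)))
  if (!"provenance" %in% names(edges)) edges$provenance <- "coexpr"
  if (!"sign" %in% names(edges)) edges$sign <- NA_character_
  if (!"support" %in% names(edges)) edges$support <- NA_integer_
  if (!all(edges$provenance %in% c("coexpr", "cerna", "both"))) {
    abort("provenance must be coexpr, cerna or both", class = "lsp_error_input")
  }
  if (anyDuplicated(edges[c("lncrna", "pcg")])) {
    abort("at most one edge per (lncRNA, PCG) pair", class = "lsp_error_input")
  }
  if (length(intersect(edges$lncrna, edges$pcg))) {
    abort("network must be bipartite: lncRNA and PCG id sets overlap",
          class = "lsp_error_input")
  }
  edges <- edges |>
    mutate(lncrna = as.character(.data$lncrna), pcg = as.character(.data$pcg),
           support = as.integer(.data$support)) |>
    select("lncrna", "pcg", "provenance", "sign", "support")
  class(edges) <- c("lnc_assoc", class(edges))
  edges
}

#' @export
#' @rdname association_network
#' @param file Path to a TSV with columns lncrna, pcg, provenance, sign,
#'   support.
read_association_network <- function(file) {
  association_network(readr::read_tsv(file, show_col_types = FALSE,
                                      progress = FALSE))
}

#' @export
#' @rdname association_network
#' @param network A `lnc_assoc` tibble to write.
write_association_network <- function(network, file) {
  readr::write_tsv(network, file)
  invisible(file)
}

#' Coefficient-of-variation filter for one expression dataset
#'
#' Keeps features whose coefficient of variation (sd/mean across samples)
#' is at least `cv_min` *and* falls within the top `top_frac` fraction of
#' all defined CVs in the dataset (ties at the cut included). Features with
#' mean zero have an undefined CV and are dropped.
#'
#' @param mat Numeric feature-by-sample matrix (>= 3 samples) or data frame
#'   with an id column.
#' @param cv_min Minimum CV, default 0.3.
#' @param top_frac Retained upper fraction of the CV distribution, default
#'   0.75 (i.e. CV at or above its 25th percentile).
#' @return Character vector of retained feature ids.
#' @export
variability_filter <- function(mat, cv_min = 0.3, top_frac = 0.75) {
  mat <- as_feature_matrix(mat)
  if (ncol(mat) < 3L) abort("need >= 3 samples", class = "lsp_error_input")
  mu <- rowMeans(mat)
  ok <- mu > 0
  cv <- sqrt(row_var(mat)) / mu
  cv[!ok] <- NA_real_
  if (!any(ok)) return(character())
  cut <- quantile(cv[ok], probs = 1 - top_frac, names = FALSE, type = 7)
  rownames(mat)[which(ok & cv >= cv_min & cv >= cut)]
}

#' Fisher asymptotic P-value for a Pearson correlation
#'
#' Two-sided P from the Fisher z-transform: `z = atanh(r) * sqrt(n - 3)`,
#' `P = 2 * (1 - Phi(|z|))`. `|r| = 1` returns 0 by convention.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @param n Sample count, > 3.
#' @return P-value(s), same length as `r`.
#' @examples
#' fisher_correlation_p(0.5, 28)
#' @export
fisher_correlation_p <- function(r, n) {
  if (any(n <= 3)) abort("need n > 3", class = "lsp_error_input")
  if (any(abs(r) > 1)) abort("|r| must be <= 1", class = "lsp_error_input")
  p <- 2 * pnorm(-abs(atanh(r)) * sqrt(n - 3))
  p[abs(r) == 1] <- 0
  p
}

#' Build the multi-dataset lncRNA-PCG co-expression network
#'
#' Per dataset: both matrices pass the [variability_filter()]; Pearson
#' correlations are computed for every retained lncRNA-PCG pair; Fisher
#' asymptotic P-values are Bonferroni-adjusted over the tested pairs of
#' that dataset; a pair is retained when its adjusted P is below
#' `adj_p_cut` *and* its correlation lies in the global top or bottom
#' `extreme_frac` of that dataset's pair correlations. Across datasets, a
#' pair enters the network when the same correlation sign was retained in
#' at least `min_support` datasets.
#'
#' @param datasets A list of [expression_pair()] objects or of
#'   `list(lnc = , pcg = )` matrix pairs (groups are not needed).
#' @param adj_p_cut Bonferroni-adjusted P cutoff, default 0.01.
#' @param extreme_frac Tail fraction of the per-dataset correlation
#'   distribution, default 0.001 (top/bottom 0.1%).
#' @param min_support Minimum number of sign-consistent datasets, default 3.
#' @param cv_min,top_frac Passed to [variability_filter()].
#' @return A `lnc_assoc` tibble with provenance `coexpr`, the common sign
#'   and the supporting dataset count.
#' @export
build_coexpression_network <- function(datasets, adj_p_cut = 0.01,
                                       extreme_frac = 0.001, min_support = 3,
                                       cv_min = 0.3, top_frac = 0.75) {
  if (length(datasets) < min_support) {
    abort("fewer datasets than min_support", class = "lsp_error_input")
  }
  per_dataset <- purrr::imap(datasets, function(d, i) {
    lnc <- as_feature_matrix(if (inherits(d, "expression_pair")) d$lnc else d$lnc)
    pcg <- as_feature_matrix(if (inherits(d, "expression_pair")) d$pcg else d$pcg)
    keep_l <- variability_filter(lnc, cv_min, top_frac)
    keep_p <- variability_filter(pcg, cv_min, top_frac)
    if (!length(keep_l) || !length(keep_p)) return(NULL)
    r <- cor(t(lnc[keep_l, , drop = FALSE]), t(pcg[keep_p, , drop = FALSE]))
    n <- ncol(lnc)
    p <- fisher_correlation_p(as.vector(r), n)
    padj <- pmin(1, p * length(r))
    lo <- quantile(r, extreme_frac, names = FALSE)
    hi <- quantile(r, 1 - extreme_frac, names = FALSE)
    sel <- padj < adj_p_cut & (as.vector(r) <= lo | as.vector(r) >= hi)
    if (!any(sel)) return(NULL)
    idx <- which(matrix(sel, nrow(r), ncol(r)), arr.ind = TRUE)
    tibble(lncrna = rownames(r)[idx[, 1]], pcg = colnames(r)[idx[, 2]],
           sign = ifelse(r[idx] > 0, "+", "-"))
  })
  hits <- bind_rows(per_dataset)
  if (nrow(hits) == 0L) {
    return(association_network(tibble(lncrna = character(), pcg = character(),
                                      provenance = character(),
                                      sign = character(),
                                      support = integer())))
  }
  edges <- hits |>
    count(.data$lncrna, .data$pcg, .data$sign, name = "support") |>
    group_by(.data$lncrna, .data$pcg) |>
    filter(.data$support == max(.data$support),
           sum(.data$support == max(.data$support)) == 1L) |>
    ungroup() |>
    filter(.data$support >= min_support) |>
    mutate(provenance = "coexpr", support = as.integer(.data$support))
  association_network(edges)
}

#' Merge co-expression and ceRNA association networks
#'
#' Set union on (lncRNA, PCG); pairs present in both carry provenance
#' `both` and keep the co-expression sign and support.
#'
#' @param coexpr,cerna `lnc_assoc` tibbles.
#' @return A merged `lnc_assoc` tibble.
#' @export
merge_networks <- function(coexpr, cerna) {
  merged <- full_join(
    coexpr |> as_tibble() |> select("lncrna", "pcg", "sign", "support") |>
      mutate(.co = TRUE),
    cerna |> as_tibble() |> select("lncrna", "pcg") |> mutate(.ce = TRUE),
    by = c("lncrna", "pcg")
  ) |>
    mutate(
      provenance = case_when(
        !is.na(.data$.co) & !is.na(.data$.ce) ~ "both",
        !is.na(.data$.co) ~ "coexpr",
        TRUE ~ "cerna"
      )
    ) |>
    select(-".co", -".ce")
  association_network(merged)
}
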