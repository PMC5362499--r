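#' Hypergeometric pathway-set overlap test
#'
#' Upper-tail probability `P(X >= overlap)` that two pathway sets of the
#' given sizes, drawn from a common universe, share at least the observed
#' number of pathways; the tail is accumulated in log space. Used to
#' quantify the reproducibility of result lists between datasets.
#'
#' @param universe Number of pathways in the universe (e.g. all retained
#'   pathways of the run).
#' @param size_a,size_b Sizes of the two pathway sets.
#' @param overlap Observed overlap; `overlap <= min(size_a, size_b)`.
#' @return The upper-tail P-value.
#' @examples
#' overlap_p(214, 32, 18, 11)
#' @export
overlap_p <- function(universe, size_a, size_b, overlap) {
  if (any(size_a > universe | size_b > universe |
          overlap > pmin(size_a, size_b) | overlap < 0)) {
    abort("impossible overlap arguments", class = "lsp_error_input")
  }
  hyper_upper_tail(universe, size_b, size_a, overlap, inclusive = TRUE)
}

#' Top-k rank-overlap ratio
#'
#' The fraction of the top `k` entries shared by two rankings,
#' `|top-k(A) intersect top-k(B)| / k`. Symmetric in its arguments.
#'
#' @param ranked_a,ranked_b Character vectors ordered best-first.
#' @param k Depth of the comparison, default 20.
#' @return The overlap ratio in \[0, 1\].
#' @export
topk_overlap <- function(ranked_a, ranked_b, k = 20) {
  stopifnot(k >= 1)
  length(intersect(head(ranked_a, k), head(ranked_b, k))) / k
}
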