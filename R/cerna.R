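#' Hypergeometric P-value for shared miRNAs
#'
#' For a lncRNA interacting with `n` of the `N` miRNAs in the universe and
#' an mRNA interacting with `M` of them, of which `m` are shared, computes
#' the upper tail `P = 1 - sum_{k=0}^{m} C(n,k) C(N-n,M-k) / C(N,M)`, i.e.
#' the probability of sharing *strictly more* than `m` miRNAs by chance.
#' The sum is accumulated in log space. Set `tail = "geq"` for the
#' inclusive tail `P(X >= m)`.
#'
#' @param N miRNA universe size (all miRNAs interacting with any lncRNA or
#'   mRNA).
#' @param M miRNAs interacting with the mRNA.
#' @param n miRNAs interacting with the lncRNA.
#' @param m shared miRNAs; `0 <= m <= min(n, M) <= N`.
#' @param tail `"greater"` (default, as the strictly-greater formula) or
#'   `"geq"`.
#' @return The tail probability.
#' @examples
#' shared_mirna_p(20, 5, 4, 2) # 496/15504
#' @export
shared_mirna_p <- function(N, M, n, m, tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  bad <- m < 0 | M < 0 | n < 0 | M > N | n > N | m > pmin(n, M) |
    m < pmax(0, n + M - N)
  if (any(bad)) {
    abort("combinatorially impossible hypergeometric arguments",
          class = "lsp_error_input")
  }
  hyper_upper_tail(N, M, n, m, inclusive = tail == "geq")
}

# P(X > m) (or >= m) for X ~ Hypergeom(N, n, M), by log-space summation of
# the upper-tail terms (summing the smaller tail directly keeps precision
# for extreme P-values).
hyper_upper_tail <- function(N, M, n, m, inclusive = FALSE) {
  mapply(function(N, M, n, m) {
    from <- if (inclusive) m else m + 1
    to <- min(n, M)
    if (from > to) return(0)
    k <- from:to
    lt <- lchoose(n, k) + lchoose(N - n, M - k) - lchoose(N, M)
    mx <- max(lt)
    min(1, exp(mx + log(sum(exp(lt - mx)))))
  }, N, M, n, m)
}

#' Jaccard coefficient of two sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param a,b Vectors treated as sets.
#' @return The coefficient in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Read a feature-to-miRNA interaction table
#'
#' Two-column TSV: feature id, miRNA id. One row per interaction.
#'
#' @param file Path.
#' @return Tibble with columns `feature`, `mirna`.
#' @export
read_mirna_table <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  names(x)[1:2] <- c("feature", "mirna")
  x
}

#' Build the ceRNA (shared-miRNA) lncRNA-PCG association network
#'
#' For each lncRNA, the candidate mRNAs are those sharing at least one
#' miRNA with it. A candidate becomes an edge when the shared-miRNA
#' hypergeometric test is significant (`shared_mirna_p < p_cut`) *and* its
#' Jaccard coefficient ranks within the top `top_frac` of that lncRNA's
#' candidate list (the cut keeps `ceiling(top_frac * n_candidates)`
#' candidates; ties at the threshold value are included).
#'
#' @param mrna_mirna,lnc_mirna Data frames with columns `feature`, `mirna`
#'   listing mRNA-miRNA and lncRNA-miRNA interactions.
#' @param p_cut Hypergeometric P cutoff, default 0.05.
#' @param top_frac Retained top fraction by Jaccard, default 0.20.
#' @param tail Passed to [shared_mirna_p()].
#' @return A `lnc_assoc` tibble with provenance `cerna`.
#' @export
build_cerna_network <- function(mrna_mirna, lnc_mirna, p_cut = 0.05,
                                top_frac = 0.20, tail = "greater") {
  mrna_sets <- split(as.character(mrna_mirna$mirna),
                     as.character(mrna_mirna$feature))
  lnc_sets <- split(as.character(lnc_mirna$mirna),
                    as.character(lnc_mirna$feature))
  mrna_sets <- lapply(mrna_sets, unique)
  lnc_sets <- lapply(lnc_sets, unique)
  N <- length(union(unlist(mrna_sets, use.names = FALSE),
                    unlist(lnc_sets, use.names = FALSE)))

  edges <- purrr::imap(lnc_sets, function(aset, l) {
    shared <- vapply(mrna_sets, function(b) length(intersect(aset, b)), 0L)
    cand <- names(mrna_sets)[shared > 0L]
    if (!length(cand)) return(NULL)
    p <- vapply(cand, function(g) {
      shared_mirna_p(N, length(mrna_sets[[g]]), length(aset),
                     length(intersect(aset, mrna_sets[[g]])), tail = tail)
    }, 0)
    jc <- vapply(cand, function(g) jaccard(aset, mrna_sets[[g]]), 0)
    k <- ceiling(top_frac * length(cand))
    jc_cut <- sort(jc, decreasing = TRUE)[k]
    keep <- p < p_cut & jc >= jc_cut
    if (!any(keep)) return(NULL)
    tibble(lncrna = l, pcg = cand[keep])
  })
  edges <- bind_rows(edges)
  if (nrow(edges) == 0L) {
    edges <- tibble(lncrna = character(), pcg = character())
  }
  association_network(edges |> mutate(provenance = "cerna",
                                      sign = NA_character_,
                                      support = NA_integer_))
}
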