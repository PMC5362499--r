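#' Matched lncRNA / protein-coding gene expression pair
#'
#' Bundles a lncRNA abundance matrix and a protein-coding gene (PCG)
#' abundance matrix measured on the identical, ordered sample set, together
#' with a two-group (`case` / `control`) sample annotation. Abundances are
#' non-negative linear-scale values such as FPKM.
#'
#' @param lnc,pcg Either a numeric matrix with feature ids as row names and
#'   sample ids as column names, or a data frame whose first column holds
#'   feature ids (remaining columns one per sample).
#' @param groups A named character vector mapping sample id to `"case"` or
#'   `"control"`, or a two-column data frame (sample id, group).
#'
#' @return An object of class `expression_pair` with elements `lnc`, `pcg`
#'   (numeric matrices), `samples` and `groups`.
#' @examples
#' lnc <- matrix(rpois(12, 10), 2, 6,
#'   dimnames = list(c("L1", "L2"), paste0("s", 1:6)))
#' pcg <- matrix(rpois(18, 10), 3, 6,
#'   dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:6)))
#' grp <- setNames(rep(c("case", "control"), each = 3), paste0("s", 1:6))
#' expression_pair(lnc, pcg, grp)
#' @export
expression_pair <- function(lnc, pcg, groups) {
  lnc <- as_feature_matrix(lnc)
  pcg <- as_feature_matrix(pcg)
  groups <- as_group_vector(groups)

  if (is.null(colnames(lnc)) || is.null(colnames(pcg))) {
    abort("both matrices need sample ids as column names",
          class = "lsp_error_input")
  }
  if (!identical(colnames(lnc), colnames(pcg))) {
    abort("lncRNA and PCG matrices must share an identical ordered sample set",
          class = "lsp_error_input")
  }
  missing <- setdiff(colnames(lnc), names(groups))
  if (length(missing)) {
    abort(paste0("samples without a group label: ",
                 paste(missing, collapse = ", ")),
          class = "lsp_error_input")
  }
  groups <- groups[colnames(lnc)]
  if (!all(groups %in% c("case", "control"))) {
    abort("groups must be 'case' or 'control'", class = "lsp_error_input")
  }
  if (!all(c("case", "control") %in% groups)) {
    abort("both groups must be non-empty", class = "lsp_error_input")
  }
  if (anyNA(lnc) || anyNA(pcg) || min(lnc) < 0 || min(pcg) < 0) {
    abort("abundance values must be non-negative and complete",
          class = "lsp_error_input")
  }
  shared <- intersect(rownames(lnc), rownames(pcg))
  if (length(shared)) {
    abort(paste0("lncRNA and PCG identifier sets must be disjoint; shared: ",
                 paste(head(shared, 5), collapse = ", ")),
          class = "lsp_error_input")
  }
  structure(
    list(lnc = lnc, pcg = pcg, samples = colnames(lnc), groups = groups),
    class = "expression_pair"
  )
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric matrix or a data frame with an id column",
          class = "lsp_error_input")
  }
  if (is.null(rownames(x))) {
    abort("feature matrix needs row names", class = "lsp_error_input")
  }
  x
}

as_group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  }
  if (is.factor(groups)) groups <- setNames(as.character(groups), names(groups))
  groups
}

#' Read a matched expression pair from TSV files
#'
#' Matrices are TSV with the feature id in the first column and a header row
#' of sample ids; the group file is a two-column TSV (sample id, group) with
#' groups `case` / `control`.
#'
#' @param lnc_file,pcg_file,group_file File paths.
#' @return An [expression_pair()].
#' @export
read_expression_pair <- function(lnc_file, pcg_file, group_file) {
  rd <- function(f) readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
  expression_pair(rd(lnc_file), rd(pcg_file), rd(group_file))
}

#' @export
print.expression_pair <- function(x, ...) {
  cat("<expression_pair> ", nrow(x$lnc), " lncRNAs x ", nrow(x$pcg),
      " PCGs x ", length(x$samples), " samples (",
      sum(x$groups == "case"), " case / ", sum(x$groups == "control"),
      " control)\n", sep = "")
  invisible(x)
}

#' Drop sparsely detected features
#'
#' Retains features whose expression is non-zero in at least
#' `min_nonzero_frac` of the samples ("at least": a feature detected in
#' exactly the threshold fraction is kept). Applied to the lncRNA and PCG
#' matrices independently; the sample set is untouched, so the matrices stay
#' matched.
#'
#' @param pair An [expression_pair()].
#' @param min_nonzero_frac Minimum fraction of samples with non-zero
#'   abundance, in (0, 1]. Default 0.2.
#' @return A filtered [expression_pair()].
#' @export
filter_low_expression <- function(pair, min_nonzero_frac = 0.2) {
  stopifnot(inherits(pair, "expression_pair"))
  if (!(min_nonzero_frac > 0 && min_nonzero_frac <= 1)) {
    abort("min_nonzero_frac must be in (0, 1]", class = "lsp_error_input")
  }
  keep <- function(m) rowMeans(m > 0) >= min_nonzero_frac
  lnc <- pair$lnc[keep(pair$lnc), , drop = FALSE]
  pcg <- pair$pcg[keep(pair$pcg), , drop = FALSE]
  if (nrow(lnc) == 0L || nrow(pcg) == 0L) {
    abort("no features survive filtering", class = "lsp_error_empty")
  }
  expression_pair(lnc, pcg, pair$groups)
}
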