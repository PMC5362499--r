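#' Two-group differential expression table
#'
#' Computes, per feature, the linear-scale fold change of group means
#' (case over control, after adding a pseudocount), a two-sided Welch
#' two-sample t-test on `log2(x + pseudocount)` values, and
#' Benjamini-Hochberg adjusted P-values over all rows.
#'
#' Features with zero variance in both groups cannot be tested; their
#' P-value is reported as 1 and flagged in `zero_variance` rather than as
#' `NaN`.
#'
#' @param mat Numeric feature-by-sample matrix (non-negative abundances), or
#'   a data frame with the feature id in the first column.
#' @param groups Named character vector (or two-column data frame) mapping
#'   each sample to `"case"` or `"control"`; at least 2 samples per group.
#' @param pseudocount Added before ratios and logs; default 0.01 (FPKM
#'   scale).
#' @return A tibble with columns `feature`, `mean_case`, `mean_control`,
#'   `log2_fc`, `fc`, `p_value`, `p_adjusted`, `zero_variance`.
#' @examples
#' m <- rbind(a = c(4, 4, 1, 1), b = c(1, 2, 1, 2))
#' colnames(m) <- paste0("s", 1:4)
#' g <- setNames(c("case", "case", "control", "control"), colnames(m))
#' differential_table(m, g, pseudocount = 0)
#' @export
differential_table <- function(mat, groups, pseudocount = 0.01) {
  mat <- as_feature_matrix(mat)
  groups <- as_group_vector(groups)
  groups <- groups[colnames(mat)]
  ca <- which(groups == "case")
  co <- which(groups == "control")
  if (length(ca) < 2L || length(co) < 2L) {
    abort("need at least 2 samples per group", class = "lsp_error_input")
  }

  mean_case <- rowMeans(mat[, ca, drop = FALSE])
  mean_control <- rowMeans(mat[, co, drop = FALSE])
  log2_fc <- log2((mean_case + pseudocount) / (mean_control + pseudocount))

  lx <- log2(mat + pseudocount)
  m1 <- rowMeans(lx[, ca, drop = FALSE])
  m2 <- rowMeans(lx[, co, drop = FALSE])
  v1 <- row_var(lx[, ca, drop = FALSE])
  v2 <- row_var(lx[, co, drop = FALSE])
  n1 <- length(ca)
  n2 <- length(co)
  se2 <- v1 / n1 + v2 / n2
  zero_var <- se2 <= 0
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[zero_var] <- 1
  if (any(zero_var)) {
    warn(paste0(sum(zero_var), " feature(s) with zero within-group variance;",
                " P reported as 1"),
         class = "lsp_warning_zero_variance")
  }
  tibble(
    feature = rownames(mat),
    mean_case = unname(mean_case),
    mean_control = unname(mean_control),
    log2_fc = unname(log2_fc),
    fc = unname(2^log2_fc),
    p_value = unname(p),
    p_adjusted = p.adjust(p, method = "BH"),
    zero_variance = unname(zero_var)
  )
}

row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Select risk lncRNAs from a differential table
#'
#' A feature qualifies as a risk lncRNA when its adjusted P-value is below
#' `fdr_cut` and its linear-scale fold change is either above `fc_hi` or
#' below `fc_lo`. All three comparisons are strict, so e.g. FC exactly 1.5
#' is excluded.
#'
#' @param table A tibble from [differential_table()].
#' @param fdr_cut Adjusted-P cutoff, default 0.25.
#' @param fc_hi Upper fold-change bound, default 1.5.
#' @param fc_lo Lower fold-change bound, default 2/3.
#' @return Character vector of risk feature ids (possibly empty).
#' @export
select_risk_lncrnas <- function(table, fdr_cut = 0.25, fc_hi = 1.5,
                                fc_lo = 2 / 3) {
  table |>
    filter(.data$p_adjusted < fdr_cut,
           .data$fc > fc_hi | .data$fc < fc_lo) |>
    pull("feature")
}
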