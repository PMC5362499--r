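test_that("expression_pair enforces its invariants", {
  p <- tiny_pair()
  expect_s3_class(p, "expression_pair")
  expect_identical(colnames(p$lnc), colnames(p$pcg))

  m <- p$lnc
  expect_error(expression_pair(m, p$pcg[, rev(p$samples)], p$groups),
               class = "lsp_error_input")
  neg <- p$pcg; neg[1, 1] <- -1
  expect_error(expression_pair(p$lnc, neg, p$groups),
               class = "lsp_error_input")
  shared <- p$pcg; rownames(shared)[1] <- rownames(p$lnc)[1]
  expect_error(expression_pair(p$lnc, shared, p$groups),
               class = "lsp_error_input")
  one_group <- setNames(rep("case", length(p$samples)), p$samples)
  expect_error(expression_pair(p$lnc, p$pcg, one_group),
               class = "lsp_error_input")
})

test_that("low-expression filtering keeps 'at least' the threshold fraction", {
  samples <- paste0("s", 1:10)
  groups <- setNames(rep(c("case", "control"), each = 5), samples)
  pcg <- rbind(
    allzero = rep(0, 10),
    exactly20 = c(1, 2, rep(0, 8)),   # 2/10 non-zero, threshold 0.2: kept
    one = c(3, rep(0, 9)),            # 1/10: removed
    dense = rpois(10, 5) + 1
  )
  colnames(pcg) <- samples
  lnc <- matrix(1, 2, 10, dimnames = list(c("L1", "L2"), samples))
  pair <- expression_pair(lnc, pcg, groups)
  filt <- filter_low_expression(pair, 0.2)
  expect_setequal(rownames(filt$pcg), c("exactly20", "dense"))

  # idempotence
  again <- filter_low_expression(filt, 0.2)
  expect_identical(rownames(again$pcg), rownames(filt$pcg))

  # nothing survives -> explicit error
  sparse_lnc <- matrix(c(0, rep(1, 9), 0, rep(1, 9)), 2, 10, byrow = TRUE,
                       dimnames = list(c("L1", "L2"), samples))
  sparse <- expression_pair(sparse_lnc, pcg, groups)
  expect_error(filter_low_expression(sparse, 1), class = "lsp_error_empty")
})

test_that("differential_table computes fold changes as specified", {
  samples <- paste0("s", 1:4)
  groups <- setNames(c("case", "case", "control", "control"), samples)
  m <- rbind(equal = c(5, 5, 5, 5), four = c(4, 4, 1, 1))
  colnames(m) <- samples
  suppressWarnings(tab <- differential_table(m, groups, pseudocount = 0))
  expect_equal(tab$log2_fc[tab$feature == "equal"], 0)
  expect_equal(tab$log2_fc[tab$feature == "four"], 2)

  # zero within-group variance: P = 1 and flagged, not NaN
  expect_warning(tab2 <- differential_table(m, groups, pseudocount = 0),
                 class = "lsp_warning_zero_variance")
  expect_equal(tab2$p_value[tab2$feature == "equal"], 1)
  expect_true(tab2$zero_variance[tab2$feature == "equal"])
  expect_false(anyNA(tab2$p_value))
})

test_that("swapping group labels negates every log2 fold change", {
  p <- tiny_pair(seed = 7)
  tab <- differential_table(p$pcg, p$groups)
  swapped <- ifelse(p$groups == "case", "control", "case")
  names(swapped) <- names(p$groups)
  tab2 <- differential_table(p$pcg, swapped)
  expect_equal(tab2$log2_fc, -tab$log2_fc)
})

test_that("BH adjustment is a monotone step-up over sorted raw P", {
  p <- tiny_pair(nl = 30, seed = 3)
  tab <- differential_table(p$lnc, p$groups) |> dplyr::arrange(p_value)
  expect_true(all(diff(tab$p_adjusted) >= -1e-12))
  expect_true(all(tab$p_adjusted >= tab$p_value))
})

test_that("the t-test matches stats::t.test and its theoretical power", {
  # 5 vs 5 samples, case mean 3 sd units higher on the log scale
  samples <- paste0("s", 1:10)
  groups <- setNames(rep(c("case", "control"), each = 5), samples)
  hits <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    m <- matrix(2^c(rnorm(5, 9), rnorm(5, 6)), 1, 10,
                dimnames = list("g", samples))
    p <- differential_table(m, groups)$p_value
    if (i <= 20) {
      lx <- log2(m + 0.01)
      expect_equal(p, t.test(lx[1, 1:5], lx[1, 6:10])$p.value,
                   tolerance = 1e-10)
    }
    p < 0.01
  }, TRUE)
  # empirical Welch power at delta = 3 sd, n = 5 per group, from the
  # stats::t.test oracle on plain normal draws
  power <- mean(vapply(1:1000, function(i) {
    set.seed(50000 + i)
    t.test(rnorm(5, 3), rnorm(5, 0))$p.value < 0.01
  }, TRUE))
  se <- sqrt(power * (1 - power)) * sqrt(1 / 100 + 1 / 1000)
  expect_lt(abs(mean(hits) - power), 3 * se)
})

test_that("risk selection uses strict FDR and fold-change bounds", {
  tab <- tibble::tibble(
    feature = c("a", "b", "c", "d", "e"),
    log2_fc = log2(c(1.0, 2.0, 1.5, 0.5, 2.0)),
    fc = c(1.0, 2.0, 1.5, 0.5, 2.0),
    p_value = rep(0.001, 5),
    p_adjusted = c(0.10, 0.10, 0.01, 0.20, 0.25)
  )
  risk <- select_risk_lncrnas(tab)
  expect_setequal(risk, c("b", "d"))   # fc 1.0 excluded; fc exactly 1.5
                                       # excluded; adjP exactly 0.25 excluded
  expect_identical(select_risk_lncrnas(tab[1, ]), character())
})
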