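test_that("variability filter combines the CV and percentile rules", {
  m <- rbind(
    constant = c(2, 2, 2),        # CV 0 -> dropped
    zero = c(0, 0, 0),            # mean 0 -> CV undefined -> dropped
    spread = c(1, 1, 4),          # CV ~0.866 -> passes CV rule
    mild = c(10, 11, 12)          # CV ~0.09 -> fails CV rule
  )
  colnames(m) <- paste0("s", 1:3)
  kept <- variability_filter(m)
  expect_identical(kept, "spread")
  expect_equal(sd(c(1, 1, 4)) / 2, 0.8660254, tolerance = 1e-6)

  # degenerate ties: identical CVs all pass the percentile rule
  m2 <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(10, 20, 30))
  colnames(m2) <- paste0("s", 1:3)
  expect_setequal(variability_filter(m2), c("a", "b", "c"))

  expect_error(variability_filter(m[, 1:2]), class = "lsp_error_input")
})

test_that("Fisher's asymptotic correlation test matches the z-transform", {
  expect_equal(fisher_correlation_p(0, 28), 1)
  # atanh(0.5) * sqrt(25) = 2.7465 -> two-sided normal tail
  expect_equal(fisher_correlation_p(0.5, 28), 0.006023, tolerance = 1e-4)
  expect_equal(fisher_correlation_p(-0.5, 28), fisher_correlation_p(0.5, 28))
  expect_equal(fisher_correlation_p(1, 10), 0)
  expect_error(fisher_correlation_p(0.5, 3), class = "lsp_error_input")
})

# three tiny datasets where one lncRNA-gene pair is strongly positively
# correlated (or flipped) by construction
coexpr_datasets <- function(signs, n = 30, seed = 5) {
  set.seed(seed)
  lapply(signs, function(s) {
    x <- rnorm(n)
    lnc <- rbind(L1 = x + rnorm(n, sd = 0.05), L2 = rnorm(n))
    pcg <- rbind(g1 = s * x + rnorm(n, sd = 0.05), g2 = rnorm(n),
                 g3 = rnorm(n))
    colnames(lnc) <- colnames(pcg) <- paste0("s", seq_len(n))
    list(lnc = 2^(lnc + 6), pcg = 2^(pcg + 6))
  })
}

test_that("co-expression edges need a sign consistent in >= 3 datasets", {
  expect_error(build_coexpression_network(coexpr_datasets(c(1, 1))),
               class = "lsp_error_input")

  net <- build_coexpression_network(coexpr_datasets(c(1, 1, 1, -1, 1)),
                                    extreme_frac = 0.2, cv_min = 0,
                                    top_frac = 1)
  e <- net[net$lncrna == "L1" & net$pcg == "g1", ]
  expect_equal(nrow(e), 1L)
  expect_identical(e$sign, "+")
  expect_gte(e$support, 3L)

  # +, +, - across three datasets: only 2 consistent -> excluded
  net2 <- build_coexpression_network(coexpr_datasets(c(1, 1, -1)),
                                     extreme_frac = 0.2, cv_min = 0,
                                    top_frac = 1)
  expect_false(any(net2$lncrna == "L1" & net2$pcg == "g1"))
})

test_that("co-expression networks shrink as min_support grows", {
  ds <- coexpr_datasets(c(1, 1, 1, 1), seed = 8)
  n3 <- build_coexpression_network(ds, extreme_frac = 0.2, cv_min = 0,
                                   top_frac = 1, min_support = 3)
  n4 <- build_coexpression_network(ds, extreme_frac = 0.2, cv_min = 0,
                                   top_frac = 1, min_support = 4)
  expect_lte(nrow(n4), nrow(n3))
  expect_true(all(paste(n4$lncrna, n4$pcg) %in% paste(n3$lncrna, n3$pcg)))
})

test_that("network merge is a union with provenance tracking", {
  co <- association_network(tibble::tibble(
    lncrna = c("L1", "L2"), pcg = c("g1", "g2"),
    provenance = "coexpr", sign = c("+", "-"), support = 3:4))
  ce <- association_network(tibble::tibble(
    lncrna = c("L2", "L3"), pcg = c("g2", "g3"), provenance = "cerna"))

  m <- merge_networks(co, ce)
  expect_equal(nrow(m), 3L)
  expect_identical(m$provenance[m$lncrna == "L2"], "both")
  expect_identical(m$sign[m$lncrna == "L2"], "-")   # coexpr sign retained

  # disjoint edge sets add up; identical sets keep their size
  dis <- merge_networks(co, association_network(
    tibble::tibble(lncrna = "L9", pcg = "g9", provenance = "cerna")))
  expect_equal(nrow(dis), 3L)
  same <- merge_networks(co, association_network(
    tibble::tibble(lncrna = co$lncrna, pcg = co$pcg, provenance = "cerna")))
  expect_equal(nrow(same), 2L)
  expect_true(all(same$provenance == "both"))
})

test_that("merged networks stay bipartite and duplicate-free", {
  co <- association_network(tibble::tibble(
    lncrna = c("L1", "L1"), pcg = c("g1", "g2"), provenance = "coexpr",
    sign = "+", support = 3L))
  ce <- association_network(tibble::tibble(
    lncrna = "L1", pcg = "g1", provenance = "cerna"))
  m <- merge_networks(co, ce)
  expect_equal(anyDuplicated(m[c("lncrna", "pcg")]), 0L)
  expect_length(intersect(m$lncrna, m$pcg), 0L)
  expect_error(association_network(tibble::tibble(
    lncrna = c("L1", "L1"), pcg = c("g1", "g1"))), class = "lsp_error_input")
})
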