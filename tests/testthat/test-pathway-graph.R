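test_that("pathway_graph normalizes edges", {
  pg <- pathway_graph("x", c("b", "a", "c"),
                      data.frame(from = c("b", "a", "a", "c"),
                                 to = c("a", "b", "a", "a")))
  expect_equal(nrow(pg$edges), 2L)              # dedup + self-loop dropped
  expect_true(all(pg$edges$from <= pg$edges$to))
  expect_error(pathway_graph("x", "a", data.frame(from = "a", to = "zz")),
               class = "lsp_error_input")
})

test_that("KGML protein relations expand entry gene sets bipartitely", {
  f <- kgml_file('
    <entry id="1" name="hsa:10 hsa:11" type="gene"/>
    <entry id="2" name="hsa:20" type="gene"/>
    <entry id="3" name="hsa:30" type="gene"/>
    <relation entry1="1" entry2="2" type="PPrel"/>
    <relation entry1="2" entry2="3" type="maplink"/>')
  g <- kgml_to_graph(f)
  expect_identical(g$origin, "kgml")
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("hsa:10 hsa:20", "hsa:11 hsa:20"))
  # maplink relations are ignored; hsa:30 stays isolated
  expect_true("hsa:30" %in% g$nodes)
})

test_that("enzymes sharing a metabolite are connected", {
  f <- kgml_file('
    <entry id="1" name="hsa:1" type="gene" reaction="rn:R1"/>
    <entry id="2" name="hsa:2" type="gene" reaction="rn:R2"/>
    <reaction id="11" name="rn:R1" type="irreversible">
      <substrate id="90" name="cpd:C01"/>
      <product id="91" name="cpd:C02"/>
    </reaction>
    <reaction id="12" name="rn:R2" type="irreversible">
      <substrate id="91" name="cpd:C02"/>
      <product id="92" name="cpd:C03"/>
    </reaction>')
  g <- kgml_to_graph(f)
  expect_equal(nrow(g$edges), 1L)
  expect_identical(c(g$edges$from, g$edges$to), c("hsa:1", "hsa:2"))
})

test_that("group entries and entry order do not change the edge set", {
  body1 <- '
    <entry id="1" name="hsa:1" type="gene"/>
    <entry id="2" name="hsa:2" type="gene"/>
    <entry id="3" type="group"><component id="1"/><component id="2"/></entry>
    <entry id="4" name="hsa:4" type="gene"/>
    <relation entry1="3" entry2="4" type="PPrel"/>'
  body2 <- '
    <entry id="4" name="hsa:4" type="gene"/>
    <entry id="2" name="hsa:2" type="gene"/>
    <entry id="1" name="hsa:1" type="gene"/>
    <entry id="3" type="group"><component id="2"/><component id="1"/></entry>
    <relation entry1="4" entry2="3" type="PPrel"/>'
  g1 <- kgml_to_graph(kgml_file(body1))
  g2 <- kgml_to_graph(kgml_file(body2))
  ord <- function(g) g$edges[order(g$edges$from, g$edges$to), ]
  expect_equal(ord(g1), ord(g2))
  expect_setequal(paste(g1$edges$from, g1$edges$to),
                  c("hsa:1 hsa:4", "hsa:2 hsa:4"))
})

test_that("structureless KGML is flagged and skipped in collections", {
  empty <- kgml_file('<entry id="1" name="hsa:1" type="gene"/>')
  expect_error(kgml_to_graph(empty), class = "lsp_error_unextractable")

  good <- kgml_file('
    <entry id="1" name="hsa:1" type="gene"/>
    <entry id="2" name="hsa:2" type="gene"/>
    <relation entry1="1" entry2="2" type="PPrel"/>')
  expect_message(col <- read_kgml_collection(c(good, empty)),
                 "not extractable")
  expect_length(col, 1L)
  # blocklist exclusion
  expect_message(col2 <- read_kgml_collection(good, blocklist = "00001"),
                 "blocklisted")
  expect_length(col2, 0L)
})

test_that("fixture topologies have the documented shapes", {
  fx <- fixture_pathways()
  expect_length(fx$linear$nodes, 20L)
  expect_equal(nrow(fx$linear$edges), 19L)
  deg <- igraph::degree(as_igraph(fx$linear))
  expect_equal(sort(as.integer(deg)), sort(c(1, 1, rep(2L, 18))))

  g <- as_igraph(fx$erbb)
  expect_equal(igraph::components(g)$no, 1L)

  reg <- planted_regions()
  expect_named(reg, c("erbb_1", "erbb_2", "erbb_3", "linear_1"),
               ignore.order = TRUE)
  er <- reg[c("erbb_1", "erbb_2", "erbb_3")]
  expect_equal(anyDuplicated(unlist(er)), 0L)           # disjoint
  expect_true(all(lengths(er) >= 5 & lengths(er) <= 8))
  for (r in er) {
    sub <- igraph::induced_subgraph(g, r)
    expect_equal(igraph::components(sub)$no, 1L)        # connected
  }
  expect_true(all(reg$linear_1 %in% fx$linear$nodes))
})

test_that("pathway edge lists round-trip through TSV", {
  fx <- fixture_pathways()
  f <- tempfile(fileext = ".tsv")
  write_pathway_edges(fx, f)
  back <- read_pathway_edges(f)
  expect_setequal(names(back), c("linear", "erbb"))
  for (id in names(back)) {
    a <- fx[[id]]$edges[order(fx[[id]]$edges$from, fx[[id]]$edges$to), ]
    b <- back[[id]]$edges[order(back[[id]]$edges$from, back[[id]]$edges$to), ]
    expect_equal(a, b)
  }
})
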