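# shared in-code fixtures for the test suite

# small matched expression pair: nl lncRNAs, np genes, n_per samples/group
tiny_pair <- function(nl = 4, np = 6, n_per = 5, seed = 1,
                      lnc_shift = NULL, pcg_shift = NULL) {
  set.seed(seed)
  samples <- c(paste0("c", seq_len(n_per)), paste0("t", seq_len(n_per)))
  groups <- setNames(rep(c("control", "case"), each = n_per), samples)
  mk <- function(k, prefix, shift) {
    x <- matrix(rnorm(k * 2 * n_per, mean = 6), k, 2 * n_per,
                dimnames = list(paste0(prefix, seq_len(k)), samples))
    if (!is.null(shift)) {
      x[names(shift), groups == "case"] <-
        x[names(shift), groups == "case"] + shift
    }
    2^x
  }
  expression_pair(mk(nl, "L", lnc_shift), mk(np, "g", pcg_shift), groups)
}

# random prize-collecting instance on n nodes (connected-ish random graph)
random_pcst_instance <- function(n = 15, p_edge = 0.25) {
  repeat {
    m <- matrix(runif(n * n) < p_edge, n, n)
    el <- which(m & upper.tri(m), arr.ind = TRUE)
    if (nrow(el) >= n - 1) break
  }
  nodes <- sprintf("v%02d", seq_len(n))
  list(prizes = setNames(runif(n, 0, 15), nodes),
       edges = data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                          cost = runif(nrow(el))))
}

# minimal hand-written KGML document
kgml_text <- function(body) {
  paste0('<?xml version="1.0"?>\n',
         '<pathway name="path:test" number="00001" title="test pathway">\n',
         body, '\n</pathway>\n')
}

kgml_file <- function(body) {
  f <- tempfile(fileext = ".xml")
  writeLines(kgml_text(body), f)
  f
}

# a small deterministic weighted pathway built from explicit weights
manual_weighted_pathway <- function(nodes, edges, lnc_links = NULL,
                                    beta = 15) {
  pg <- pathway_graph("toy", nodes$node, edges[, c("from", "to")])
  edges <- dplyr::distinct(
    dplyr::mutate(edges, a = pmin(from, to), b = pmax(from, to),
                  from = a, to = b, a = NULL, b = NULL))
  nodes$prize <- normalize_node_weights(nodes$w, beta)
  edges$cost <- normalize_edge_weights(edges$w)
  edges$diff <- 1 - edges$w
  if (is.null(lnc_links)) {
    lnc_links <- tibble::tibble(node = character(), lncrna = character(),
                                d = numeric(), lnc_log2_fc = numeric())
  }
  structure(list(pathway = pg, nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges), lnc_links = lnc_links,
                 params = list(alpha = 0.5, beta = beta)),
            class = "weighted_pathway")
}
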