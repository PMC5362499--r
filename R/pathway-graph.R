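#' Undirected pathway gene graph
#'
#' A pathway as a simple undirected graph over gene identifiers: no
#' self-loops, no duplicate edges, every edge endpoint a node.
#'
#' @param id Pathway identifier (e.g. `"04012"`).
#' @param nodes Character vector of gene ids.
#' @param edges Two-column data frame / matrix of unordered gene pairs (may
#'   be empty).
#' @param name Human-readable pathway name.
#' @param origin `"kgml"` or `"fixture"`.
#' @return An object of class `pathway_graph` with elements `id`, `name`,
#'   `nodes`, `edges` (tibble `from`, `to`) and `origin`.
#' @export
pathway_graph <- function(id, nodes, edges = NULL, name = id,
                          origin = c("fixture", "kgml")) {
  origin <- match.arg(origin)
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- tibble(from = character(), to = character())
  } else {
    edges <- as_tibble(as.data.frame(edges, stringsAsFactors = FALSE))
    names(edges)[1:2] <- c("from", "to")
    a <- pmin(as.character(edges$from), as.character(edges$to))
    b <- pmax(as.character(edges$from), as.character(edges$to))
    edges <- tibble(from = a, to = b) |>
      filter(.data$from != .data$to) |>
      distinct()
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) {
    abort(paste0("edge endpoints missing from node set: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "lsp_error_input")
  }
  structure(list(id = as.character(id), name = name, nodes = nodes,
                 edges = edges, origin = origin),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$id, " (", x$origin, "): ", length(x$nodes),
      " genes, ", nrow(x$edges), " interactions\n", sep = "")
  invisible(x)
}

#' Convert a pathway graph to igraph
#'
#' @param pathway A [pathway_graph()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(pathway) {
  igraph::graph_from_data_frame(pathway$edges, directed = FALSE,
                                vertices = data.frame(name = pathway$nodes))
}

#' Convert a KGML (KEGG XML) document to an undirected gene graph
#'
#' Gene nodes come from `entry` elements of type `gene` (multi-gene entries
#' are expanded). For each relation between two gene entries (except
#' `maplink` relations) every gene of one entry is connected to every gene
#' of the other; `group` entries are expanded to the union of their
#' components' genes. For metabolic pathways, the genes of two enzyme
#' entries are connected whenever a product compound of one entry's
#' reactions is a substrate of the other's (shared metabolites). Direction
#' is dropped and duplicate edges collapsed.
#'
#' Documents from which no interaction structure can be extracted raise a
#' classed error (`lsp_error_unextractable`); [read_kgml_collection()]
#' skips such files with a message, mirroring the exclusion of pathways
#' whose structure cannot be extracted.
#'
#' @param x Path to a KGML file, or an `xml2` document.
#' @return A [pathway_graph()] with origin `"kgml"`.
#' @export
kgml_to_graph <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_find_first(doc, "/pathway")
  pid <- xml2::xml_attr(root, "number")
  if (is.na(pid)) pid <- xml2::xml_attr(root, "name")
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- pid

  entries <- xml2::xml_find_all(doc, "//entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  ereact <- xml2::xml_attr(entries, "reaction")

  genes_of <- setNames(vector("list", length(eid)), eid)
  for (i in seq_along(eid)) {
    if (identical(etype[i], "gene")) {
      genes_of[[i]] <- strsplit(ename[i], "\\s+")[[1]]
    }
  }
  # group entries: union of their components' genes
  for (i in which(etype == "group")) {
    comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], ".//component"),
                           "id")
    genes_of[[i]] <- unique(unlist(genes_of[comp], use.names = FALSE))
  }

  pairs <- list()
  add_pairs <- function(ga, gb) {
    if (length(ga) && length(gb)) {
      pairs[[length(pairs) + 1L]] <<- expand.grid(from = ga, to = gb,
                                                  stringsAsFactors = FALSE)
    }
  }

  rels <- xml2::xml_find_all(doc, "//relation")
  for (r in rels) {
    if (identical(xml2::xml_attr(r, "type"), "maplink")) next
    add_pairs(genes_of[[xml2::xml_attr(r, "entry1")]] %||% character(),
              genes_of[[xml2::xml_attr(r, "entry2")]] %||% character())
  }

  # enzyme entries linked through shared reaction metabolites
  reactions <- xml2::xml_find_all(doc, "//reaction")
  if (length(reactions)) {
    rname <- xml2::xml_attr(reactions, "name")
    subs <- lapply(reactions, function(r)
      xml2::xml_attr(xml2::xml_find_all(r, ".//substrate"), "name"))
    prods <- lapply(reactions, function(r)
      xml2::xml_attr(xml2::xml_find_all(r, ".//product"), "name"))
    names(subs) <- names(prods) <- rname
    enz <- which(!is.na(ereact) & ereact != "" & etype == "gene")
    if (length(enz) > 1L) {
      esub <- lapply(enz, function(i) {
        rs <- intersect(strsplit(ereact[i], "\\s+")[[1]], rname)
        unique(unlist(subs[rs], use.names = FALSE))
      })
      eprod <- lapply(enz, function(i) {
        rs <- intersect(strsplit(ereact[i], "\\s+")[[1]], rname)
        unique(unlist(prods[rs], use.names = FALSE))
      })
      for (a in seq_along(enz)) {
        for (b in seq_along(enz)) {
          if (a == b) next
          if (length(intersect(eprod[[a]], esub[[b]]))) {
            add_pairs(genes_of[[enz[a]]], genes_of[[enz[b]]])
          }
        }
      }
    }
  }

  all_genes <- sort(unique(unlist(genes_of[etype == "gene"],
                                  use.names = FALSE)))
  edges <- bind_rows(pairs)
  if (nrow(edges) == 0L) {
    abort(paste0("pathway ", pid, ": structure not extractable"),
          class = "lsp_error_unextractable")
  }
  pathway_graph(pid, all_genes, edges, name = pname, origin = "kgml")
}

#' Read a collection of KGML files
#'
#' @param paths Character vector of KGML file paths.
#' @param blocklist Pathway ids to exclude (e.g. disease pathways).
#' @return Named list of [pathway_graph()]s; unextractable files are
#'   skipped with a message.
#' @export
read_kgml_collection <- function(paths, blocklist = character()) {
  out <- list()
  for (p in paths) {
    g <- tryCatch(kgml_to_graph(p), lsp_error_unextractable = function(e) {
      inform(paste0("skipping ", basename(p), ": structure not extractable"))
      NULL
    })
    if (is.null(g)) next
    if (g$id %in% blocklist) {
      inform(paste0("skipping ", g$id, ": blocklisted"))
      next
    }
    out[[g$id]] <- g
  }
  out
}

#' Bundled simulation pathway topologies
#'
#' Two fixed topologies used by the synthetic-data engine: `linear`, a
#' 20-gene path graph `g1 - g2 - ... - g20`, and `erbb`, a bundled
#' 51-gene edge list encoding an ERBB-signalling-style topology (a
#' documented synthetic stand-in following the KEGG ERBB pathway
#' structure; see `inst/extdata/erbb_edges_synthetic.tsv`).
#'
#' @return Named list with `pathway_graph`s `linear` and `erbb`.
#' @export
fixture_pathways <- function() {
  linear <- pathway_graph(
    "linear",
    nodes = paste0("g", 1:20),
    edges = tibble(from = paste0("g", 1:19), to = paste0("g", 2:20)),
    name = "linear 20-gene pathway", origin = "fixture"
  )
  ef <- system.file("extdata", "erbb_edges_synthetic.tsv",
                    package = "lncsubpath", mustWork = TRUE)
  ee <- readr::read_tsv(ef, show_col_types = FALSE, progress = FALSE)
  erbb <- pathway_graph("erbb",
                        nodes = unique(c(ee$gene_a, ee$gene_b)),
                        edges = ee[, c("gene_a", "gene_b")],
                        name = "ERBB-like signalling pathway (synthetic)",
                        origin = "fixture")
  list(linear = linear, erbb = erbb)
}

#' Planted dysregulated regions for the recall study
#'
#' The four connected regions assumed dysregulated in the region-recovery
#' simulation: one 7-gene region of the linear pathway (`g6`-`g12`) and
#' three disjoint 5-8-gene regions of the bundled ERBB-like topology.
#'
#' @return Named list of character vectors of gene ids, with names
#'   `linear_1`, `erbb_1`, `erbb_2`, `erbb_3`.
#' @export
planted_regions <- function() {
  f <- system.file("extdata", "planted_regions.tsv", package = "lncsubpath",
                   mustWork = TRUE)
  x <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
  split(x$gene, x$region)
}

#' Read / write a pathway edge-list TSV
#'
#' Format: columns `pathway_id`, `gene_a`, `gene_b`; one row per
#' undirected edge. Reading returns one [pathway_graph()] per pathway id.
#'
#' @param file Path.
#' @return For `read_pathway_edges`, a named list of `pathway_graph`s.
#' @export
read_pathway_edges <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  lapply(split(x, x$pathway_id), function(d) {
    pathway_graph(d$pathway_id[1], nodes = unique(c(d$gene_a, d$gene_b)),
                  edges = d[, c("gene_a", "gene_b")], origin = "fixture")
  })
}

#' @rdname read_pathway_edges
#' @param pathways List of `pathway_graph`s to write.
#' @export
write_pathway_edges <- function(pathways, file) {
  rows <- bind_rows(lapply(pathways, function(p) {
    tibble(pathway_id = p$id, gene_a = p$edges$from, gene_b = p$edges$to)
  }))
  readr::write_tsv(rows, file)
  invisible(file)
}
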