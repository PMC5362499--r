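#' Synthetic-data scenario
#'
#' Parameters of one simulation condition. Every generated dataset holds
#' 150 protein-coding genes and 50 lncRNAs on a linear abundance scale:
#' the 20-gene linear fixture pathway, the 51-gene ERBB-like fixture
#' pathway (the two pathway systems share no interactions), and
#' independent noise genes. Log2-scale expression is multivariate normal
#' with unit variances, baseline level `mu0`, and baseline correlation
#' `rho0` on pathway edges and on lncRNA-gene association pairs; the
#' association network is a seeded random bipartite graph with mean
#' lncRNA degree `lnc_mean_degree` over all pathway genes.
#'
#' Dysregulation is planted in the `topology` pathway (or in explicit
#' `regions`): altered genes — a fraction `p` of that pathway's nodes —
#' and the lncRNAs associated with them gain a case-group mean shift of
#' `log2(n)` (so their expected linear fold change is `n`); a fraction
#' `p` of that pathway's edges, plus the associations of altered genes,
#' have their case-group correlation reduced by `e`. Non-positive-definite
#' correlation patterns are repaired to the nearest correlation matrix,
#' which shrinks the realized correlations somewhat below `rho0`.
#'
#' @param topology `"linear"`, `"erbb"`, or `"both"` — where dysregulation
#'   is planted (datasets always contain both pathway systems).
#' @param n Node fold change (>= 1); the planted log2 mean shift is
#'   `log2(n)`.
#' @param e Edge correlation change in \[0, 0.9\].
#' @param p Proportion of the target pathway's nodes and edges altered.
#' @param N Total sample size, split into two equal groups.
#' @param regions Optional named list of planted connected regions (gene id
#'   vectors); overrides `p` (all region nodes and within-region edges are
#'   altered), as in the region-recovery study.
#' @param n_genes,n_lnc Total gene / lncRNA counts (defaults 150 / 50).
#' @param rho0 Baseline within-edge / within-association correlation,
#'   default 0.6.
#' @param mu0 Baseline log2 abundance, default 6 (about 64 FPKM).
#' @param lnc_mean_degree Mean lncRNA attachment degree, default 2.
#' @return A `sim_scenario` object.
#' @export
simulation_scenario <- function(topology = c("linear", "erbb", "both"),
                                n = 2, e = 0.1, p = 0.1, N = 250,
                                regions = NULL, n_genes = 150, n_lnc = 50,
                                rho0 = 0.6, mu0 = 6, lnc_mean_degree = 2) {
  topology <- match.arg(topology)
  stopifnot(n >= 1, e >= 0, e <= 1, p >= 0, p <= 1, N >= 8, N %% 2 == 0)
  fx <- fixture_pathways()
  npg <- length(fx$linear$nodes) + length(fx$erbb$nodes)
  stopifnot(n_genes >= npg)
  if (!is.null(regions)) {
    allg <- c(fx$linear$nodes, fx$erbb$nodes)
    stopifnot(all(unlist(regions) %in% allg))
  }
  structure(list(topology = topology, n = n, e = e, p = p, N = N,
                 regions = regions, n_genes = n_genes, n_lnc = n_lnc,
                 rho0 = rho0, mu0 = mu0, lnc_mean_degree = lnc_mean_degree,
                 pathways = fx),
            class = "sim_scenario")
}

# ensure a correlation matrix is positive definite; repair with the
# nearest correlation matrix when needed
ensure_pd <- function(C, quiet = FALSE) {
  ok <- tryCatch({chol(C); TRUE}, error = function(e) FALSE)
  if (ok) return(C)
  if (!quiet) {
    warn("correlation pattern not positive definite; nearest-PD repair",
         class = "lsp_warning_nearpd")
  }
  as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
}

# draw k samples (columns) of a zero-mean MVN from a Cholesky factor
mvn_draw <- function(R, k) t(R) %*% matrix(rnorm(ncol(R) * k), ncol(R), k)

sim_attachment <- function(scenario) {
  genes <- c(scenario$pathways$linear$nodes, scenario$pathways$erbb$nodes)
  lncs <- paste0("lnc", seq_len(scenario$n_lnc))
  deg <- pmin(rpois(scenario$n_lnc, scenario$lnc_mean_degree), length(genes))
  edges <- purrr::map2(lncs, deg, function(l, d) {
    if (d == 0) return(NULL)
    tibble(lncrna = l, pcg = sample(genes, d))
  })
  bind_rows(edges)
}

sim_block_ids <- function(scenario, attach) {
  c(scenario$pathways$linear$nodes, scenario$pathways$erbb$nodes,
    intersect(paste0("lnc", seq_len(scenario$n_lnc)),
              unique(attach$lncrna)))
}

# correlation matrix over the correlated block for one group
sim_block_cor <- function(scenario, attach, altered_edges = NULL,
                          altered_assoc = NULL, quiet = FALSE) {
  ids <- sim_block_ids(scenario, attach)
  k <- length(ids)
  C <- diag(k)
  rownames(C) <- colnames(C) <- ids
  put <- function(a, b, v) {
    ij <- cbind(match(a, ids), match(b, ids))
    C[ij] <<- v
    C[ij[, 2:1, drop = FALSE]] <<- v
  }
  for (g in scenario$pathways) put(g$edges$from, g$edges$to, scenario$rho0)
  if (nrow(attach)) put(attach$lncrna, attach$pcg, scenario$rho0)
  r1 <- scenario$rho0 - scenario$e
  if (!is.null(altered_edges) && nrow(altered_edges)) {
    put(altered_edges$from, altered_edges$to, r1)
  }
  if (!is.null(altered_assoc) && nrow(altered_assoc)) {
    put(altered_assoc$lncrna, altered_assoc$pcg, r1)
  }
  ensure_pd(C, quiet = quiet)
}

sim_altered <- function(scenario) {
  fx <- scenario$pathways
  if (!is.null(scenario$regions)) {
    nodes <- unique(unlist(scenario$regions, use.names = FALSE))
    edges <- bind_rows(lapply(fx, function(g) g$edges)) |>
      filter(purrr::map2_lgl(.data$from, .data$to, function(a, b) {
        any(vapply(scenario$regions,
                   function(r) a %in% r && b %in% r, TRUE))
      }))
    return(list(nodes = nodes, edges = edges))
  }
  if (scenario$p <= 0) {
    return(list(nodes = character(),
                edges = tibble(from = character(), to = character())))
  }
  targets <- if (scenario$topology == "both") fx else fx[scenario$topology]
  nodes <- unlist(lapply(targets, function(g) {
    sample(g$nodes, ceiling(scenario$p * length(g$nodes)))
  }), use.names = FALSE)
  edges <- bind_rows(lapply(targets, function(g) {
    g$edges[sample.int(nrow(g$edges),
                       ceiling(scenario$p * nrow(g$edges))), ]
  }))
  list(nodes = nodes, edges = edges)
}

sim_assemble <- function(scenario, block_ctl, block_case, shift_ids) {
  fx <- scenario$pathways
  pathway_genes <- c(fx$linear$nodes, fx$erbb$nodes)
  genes <- c(pathway_genes,
             paste0("noise", seq_len(scenario$n_genes - length(pathway_genes))))
  lncs <- paste0("lnc", seq_len(scenario$n_lnc))
  half <- scenario$N / 2
  samples <- c(paste0("ctl_", seq_len(half)), paste0("case_", seq_len(half)))
  groups <- setNames(rep(c("control", "case"), each = half), samples)

  X <- matrix(rnorm(length(c(genes, lncs)) * scenario$N),
              length(genes) + length(lncs), scenario$N,
              dimnames = list(c(genes, lncs), samples))
  bid <- rownames(block_ctl$mat_ctl)
  X[bid, seq_len(half)] <- block_ctl$mat_ctl
  X[bid, half + seq_len(half)] <- block_case$mat_case
  X <- X + scenario$mu0
  X[shift_ids, half + seq_len(half)] <-
    X[shift_ids, half + seq_len(half)] + log2(scenario$n)

  A <- 2^X
  expression_pair(A[lncs, , drop = FALSE], A[genes, , drop = FALSE], groups)
}

#' Generate one matched lncRNA/mRNA dataset with planted dysregulation
#'
#' Draws the scenario's multivariate-normal log2 expression for both
#' groups, applies the planted mean shifts and correlation changes, and
#' returns linear-scale matrices. With `p = 0` and no regions the two
#' groups are drawn from the identical distribution.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Optional integer seed (same seed, same dataset, bitwise).
#' @param quiet Suppress the nearest-PD repair warning.
#' @return List with `pair` ([expression_pair()]), `network`
#'   (`lnc_assoc`), and `truth` (altered nodes / edges / lncRNAs and the
#'   planted regions).
#' @export
simulate_dataset <- function(scenario, seed = NULL, quiet = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_local_seed(seed, {
    attach <- sim_attachment(scenario)
    alt <- sim_altered(scenario)
    altered_lncs <- unique(attach$lncrna[attach$pcg %in% alt$nodes])
    altered_assoc <- attach |> filter(.data$pcg %in% alt$nodes)

    C0 <- sim_block_cor(scenario, attach, quiet = quiet)
    C1 <- if (length(alt$nodes) || nrow(alt$edges)) {
      sim_block_cor(scenario, attach, alt$edges, altered_assoc, quiet = quiet)
    } else C0
    half <- scenario$N / 2
    R0 <- chol(C0 + diag(1e-8, nrow(C0)))
    mat_ctl <- mvn_draw(R0, half)
    rownames(mat_ctl) <- rownames(C0)
    R1 <- if (identical(C0, C1)) R0 else chol(C1 + diag(1e-8, nrow(C1)))
    mat_case <- mvn_draw(R1, half)
    rownames(mat_case) <- rownames(C1)

    pair <- sim_assemble(scenario, list(mat_ctl = mat_ctl),
                         list(mat_case = mat_case),
                         shift_ids = c(alt$nodes, altered_lncs))
    net <- if (nrow(attach)) {
      association_network(attach |> distinct() |>
                            mutate(provenance = "coexpr", sign = "+",
                                   support = NA_integer_))
    } else {
      association_network(tibble(lncrna = character(), pcg = character()))
    }
    list(pair = pair, network = net,
         truth = list(altered_nodes = alt$nodes, altered_edges = alt$edges,
                      altered_lncrnas = altered_lncs,
                      regions = scenario$regions))
  })
}

#' Generate a null dataset (equal means and covariances)
#'
#' Both groups are drawn from one distribution: equal means and equal
#' correlation structure. Two presets differ in the covariance used:
#' `"choi"` fixes compound-symmetry correlation within each pathway block
#' (0.6) and within the lncRNA block (0.3); `"goel"` draws the two block
#' correlations afresh per dataset (U(0.2, 0.8) and U(0.1, 0.5)). Both
#' are positive definite by construction.
#'
#' @param strategy `"choi"` or `"goel"`.
#' @param scenario A [simulation_scenario()] (its `n`, `e`, `p` are
#'   ignored: nothing is planted).
#' @param seed Optional integer seed.
#' @return Same structure as [simulate_dataset()].
#' @export
simulate_null <- function(strategy = c("choi", "goel"), scenario,
                          seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(scenario, "sim_scenario"))
  with_local_seed(seed, {
    attach <- sim_attachment(scenario)
    r_path <- if (strategy == "choi") 0.6 else runif(1, 0.2, 0.8)
    r_lnc <- if (strategy == "choi") 0.3 else runif(1, 0.1, 0.5)
    fx <- scenario$pathways
    half <- scenario$N / 2

    cs_block <- function(ids, r, k) {
      shared <- rnorm(k)
      sweep(matrix(rnorm(length(ids) * k), length(ids), k) * sqrt(1 - r),
            2, shared * sqrt(r), `+`)
    }
    draw_group <- function(k) {
      blocks <- lapply(fx, function(g) {
        m <- cs_block(g$nodes, r_path, k)
        rownames(m) <- g$nodes
        m
      })
      lncs <- paste0("lnc", seq_len(scenario$n_lnc))
      lm <- cs_block(lncs, r_lnc, k)
      rownames(lm) <- lncs
      rbind(do.call(rbind, blocks), lm)
    }
    b_ctl <- draw_group(half)
    b_case <- draw_group(half)
    pair <- sim_assemble(scenario, list(mat_ctl = b_ctl),
                         list(mat_case = b_case), shift_ids = character())
    net <- if (nrow(attach)) {
      association_network(attach |> distinct() |>
                            mutate(provenance = "coexpr", sign = "+",
                                   support = NA_integer_))
    } else {
      association_network(tibble(lncrna = character(), pcg = character()))
    }
    list(pair = pair, network = net,
         truth = list(altered_nodes = character(),
                      altered_edges = tibble(from = character(),
                                             to = character()),
                      altered_lncrnas = character(), regions = NULL))
  })
}
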