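#' Specification for a synthetic benchmark fixture
#'
#' Bundles the parameters of the synthetic data generator: a scale-free
#' network grown by preferential attachment (mimicking the heavy-tailed
#' degree distribution of PPI networks), edge confidences drawn uniformly
#' from `weight_range`, and a planted disease module — a node subset
#' densified to `module_density` that stands in for a disease-affected
#' sub-network.
#'
#' @param n_nodes Number of nodes (default 500).
#' @param attachment Edges added per new node during growth (default 2).
#' @param weight_range Support of the edge-confidence distribution
#'   (default `c(0.9, 1)`, matching a high-confidence background build).
#' @param module_size Planted-module node count (default 30).
#' @param module_density Target within-module edge probability
#'   (default 0.5).
#' @param rng_seed Integer seed (default 1).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_nodes = 500L, attachment = 2L,
                         weight_range = c(0.9, 1), module_size = 30L,
                         module_density = 0.5, rng_seed = 1L) {
  stopifnot(n_nodes >= 3, attachment >= 1,
            length(weight_range) == 2L, weight_range[1] >= 0,
            weight_range[2] <= 1, weight_range[1] <= weight_range[2],
            module_size >= 1, module_size <= n_nodes,
            module_density > 0, module_density <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment = as.integer(attachment),
                 weight_range = as.numeric(weight_range),
                 module_size = as.integer(module_size),
                 module_density = as.numeric(module_density),
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

#' Generate a synthetic weighted network
#'
#' Grows a connected scale-free graph by preferential attachment
#' (Barabasi-Albert, via igraph) and assigns edge confidences uniformly
#' from `spec$weight_range`. Should the graph ever come out disconnected,
#' components are bridged by extra maximum-confidence edges (logged via
#' message) so propagation is well defined everywhere.
#'
#' @param spec A [fixture_spec()].
#' @return List with `edges` (canonical edge data frame) and `nodes`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_rng_seed(spec$rng_seed, {
    g <- igraph::sample_pa(spec$n_nodes, m = spec$attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("g%04d", seq_len(spec$n_nodes))
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      message("bridging ", comp$no, " components in generated network")
      reps <- vapply(seq_len(comp$no),
                     function(k) which(comp$membership == k)[1L], integer(1))
      g <- igraph::add_edges(g, as.vector(rbind(reps[-1L], reps[1L])))
    }
    el <- igraph::as_edgelist(g, names = TRUE)
    w <- stats::runif(nrow(el), spec$weight_range[1], spec$weight_range[2])
    edges <- canonical_edges(data.frame(node_a = el[, 1L], node_b = el[, 2L],
                                        weight = w, stringsAsFactors = FALSE))
    list(edges = edges, nodes = sprintf("g%04d", seq_len(spec$n_nodes)))
  })
}

#' Plant a disease module into a synthetic network
#'
#' Picks `module_size` nodes at random and adds within-module edges until
#' the module's internal edge probability reaches approximately
#' `module_density`, emulating the dense disease-affected sub-network
#' that propagation is expected to light up. The module node list doubles
#' as the fixture's disease gene set.
#'
#' @param fx Output of [generate_network()].
#' @param module_size,module_density See [fixture_spec()].
#' @param weight_range Confidence range for the added edges.
#' @param rng_seed Integer seed.
#' @return List with `edges`, `nodes`, `disease_genes`.
#' @export
plant_disease_module <- function(fx, module_size, module_density,
                                 weight_range = c(0.9, 1), rng_seed = 1L) {
  stopifnot(module_size >= 1, module_size <= length(fx$nodes),
            module_density > 0, module_density <= 1)
  with_rng_seed(rng_seed, {
    module <- sort(sample(fx$nodes, module_size))
    pairs <- if (module_size >= 2L) t(utils::combn(module, 2L)) else
      matrix(character(), ncol = 2L)
    have <- paste(fx$edges$node_a, fx$edges$node_b, sep = "\r")
    key <- paste(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]), sep = "\r")
    n_target <- round(module_density * nrow(pairs))
    missing <- which(!(key %in% have))
    n_add <- max(0L, min(length(missing), n_target - sum(key %in% have)))
    add <- if (n_add > 0L) sample(missing, n_add) else integer()
    new_edges <- if (length(add) > 0L) {
      data.frame(node_a = pairs[add, 1L], node_b = pairs[add, 2L],
                 weight = stats::runif(length(add), weight_range[1],
                                       weight_range[2]),
                 stringsAsFactors = FALSE)
    } else {
      empty_edge_table()
    }
    list(edges = canonical_edges(rbind(fx$edges, new_edges)),
         nodes = fx$nodes, disease_genes = module)
  })
}

#' Generate a synthetic pathway collection
#'
#' Builds `n_pathways` gene sets over the given node list. A fraction of
#' them is "enriched": roughly half of each enriched set is drawn from
#' the planted module genes, the rest uniformly; background sets are
#' drawn uniformly. Ground truth is recorded in the set names
#' (`enriched_###` / `background_###`) and descriptions, enabling
#' recovery tests.
#'
#' @param nodes Character vector of network node identifiers.
#' @param n_pathways Number of gene sets (default 100).
#' @param size_range Integer range of set sizes (default `c(10, 40)`).
#' @param module_genes Planted-module genes (may be empty).
#' @param enriched_fraction Fraction of module-enriched sets (default 0.2).
#' @param rng_seed Integer seed.
#' @return A `pathway_collection`.
#' @export
generate_pathway_collection <- function(nodes, n_pathways = 100L,
                                        size_range = c(10L, 40L),
                                        module_genes = character(),
                                        enriched_fraction = 0.2,
                                        rng_seed = 1L) {
  stopifnot(n_pathways >= 1, size_range[1] >= 1,
            size_range[1] <= size_range[2], size_range[2] <= length(nodes),
            enriched_fraction >= 0, enriched_fraction <= 1)
  if (length(module_genes) == 0L) enriched_fraction <- 0
  n_enr <- round(enriched_fraction * n_pathways)
  with_rng_seed(rng_seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                    replace = TRUE)
    sets <- lapply(seq_len(n_pathways), function(i) {
      s <- sizes[i]
      if (i <= n_enr) {
        k <- min(length(module_genes), max(1L, s %/% 2L))
        core <- sample(module_genes, k)
        rest <- sample(setdiff(nodes, core), s - k)
        sample(c(core, rest))
      } else {
        sample(nodes, s)
      }
    })
    nms <- c(sprintf("enriched_%03d", seq_len(n_enr)),
             sprintf("background_%03d", seq_len(n_pathways - n_enr)))
    desc <- stats::setNames(
      c(rep("module-enriched synthetic set", n_enr),
        rep("uniform synthetic set", n_pathways - n_enr)), nms)
    new_pathway_collection(stats::setNames(sets, nms), desc)
  })
}

#' Generate a synthetic differential-expression table
#'
#' Produces a ratio table over all nodes in which exactly `n_de` genes
#' are differentially expressed — ratios outside the (0.25, 4) band, half
#' induced (drawn from `fold_range`) and half repressed (reciprocals) —
#' while the remainder sit near 1 (uniform on `[0.8, 1.25]`).
#'
#' @param nodes Network node identifiers.
#' @param n_de Number of differentially expressed genes.
#' @param fold_range Induced fold-change range; its lower end must
#'   strictly exceed 4 so every planted gene passes the fold filter.
#' @param rng_seed Integer seed.
#' @return Data frame (`gene`, `ratio`) with attribute `de_genes`.
#' @export
generate_expression_table <- function(nodes, n_de = 40L,
                                      fold_range = c(5, 16), rng_seed = 1L) {
  stopifnot(n_de >= 1, n_de <= length(nodes),
            length(fold_range) == 2L, fold_range[1] <= fold_range[2])
  if (fold_range[1] <= 4) {
    stop("fold_range must lie strictly above the 4-fold threshold")
  }
  with_rng_seed(rng_seed, {
    de <- sample(nodes, n_de)
    n_up <- ceiling(n_de / 2)
    up <- stats::runif(n_up, fold_range[1], fold_range[2])
    down <- 1 / stats::runif(n_de - n_up, fold_range[1], fold_range[2])
    ratio <- stats::setNames(stats::runif(length(nodes), 0.8, 1.25), nodes)
    ratio[de] <- c(up, down)
    structure(data.frame(gene = nodes, ratio = as.numeric(ratio),
                         stringsAsFactors = FALSE),
              de_genes = sort(de))
  })
}
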