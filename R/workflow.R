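#' Build and export a background network from files
#'
#' Thin orchestration over [read_weighted_edges()], [read_gene_list()]
#' and [build_background_network()]; writes the network TSV and JSON
#' summary into `out_dir`.
#'
#' @param edge_path Raw weighted edge table.
#' @param gene_list_paths Character vector of gene-list files whose genes
#'   must be retained in the network.
#' @param threshold Confidence cutoff (default 0.9).
#' @param score_max Raw-score rescaling constant (default 1000).
#' @param out_dir Output directory (created if needed).
#' @return The `ppi_network`, invisibly.
#' @export
run_build_network <- function(edge_path, gene_list_paths = character(),
                              threshold = 0.9, score_max = 1000,
                              out_dir = ".") {
  edges <- read_weighted_edges(edge_path, score_max = score_max)
  required <- unique(unlist(lapply(gene_list_paths, read_gene_list)))
  net <- build_background_network(edges, required, threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_network(net, file.path(out_dir, "network.tsv"),
                file.path(out_dir, "network.summary.json"))
  invisible(net)
}

#' Run the full drug-disease assessment from files
#'
#' Reads the inputs, builds the background network (keeping all disease
#' and target genes the raw data supports), runs [assess_drug_disease()]
#' and writes `assessment.json`, `null_scores.tsv` and the two score
#' vectors into `out_dir`.
#'
#' @param edge_path,disease_path,targets_path Input files.
#' @param threshold,score_max Network construction parameters.
#' @param r,n_perm,rng_seed Propagation and permutation parameters.
#' @param out_dir Output directory.
#' @return The `drug_disease_assessment`, invisibly.
#' @export
run_assess <- function(edge_path, disease_path, targets_path,
                       threshold = 0.9, score_max = 1000,
                       r = 0.3, n_perm = 1000L, rng_seed, out_dir = ".") {
  edges <- read_weighted_edges(edge_path, score_max = score_max)
  disease <- read_gene_list(disease_path)
  targets <- read_gene_list(targets_path)
  net <- build_background_network(edges, c(disease, targets), threshold)
  res <- assess_drug_disease(net, disease, targets, r = r,
                             n_perm = n_perm, rng_seed = rng_seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assessment(res, file.path(out_dir, "assessment.json"),
                   file.path(out_dir, "null_scores.tsv"))
  write_score_vector(res$x_disease, file.path(out_dir, "scores_disease.tsv"))
  write_score_vector(res$x_drug, file.path(out_dir, "scores_drug.tsv"))
  invisible(res)
}

#' Score pathways for several score vectors and summarize overlaps
#'
#' Projects each named score vector onto the GMT collection, flags the
#' top fraction, and writes per-entity tables
#' (`pathways_<label>.tsv`) plus an overlap summary
#' (`pathway_overlap.json`) of the selected sets.
#'
#' @param score_vectors Named list of score vectors (2-4 entries for the
#'   overlap report; a single entry skips it).
#' @param gmt_path GMT collection file.
#' @param top_fraction Selection fraction (default 0.05).
#' @param out_dir Output directory.
#' @return List with `tables` (per-entity data frames including a
#'   `selected` column), `selections` and `overlap` (an
#'   `overlap_summary` or NULL), invisibly.
#' @export
run_pathways <- function(score_vectors, gmt_path, top_fraction = 0.05,
                         out_dir = ".") {
  stopifnot(is.list(score_vectors), !is.null(names(score_vectors)))
  collection <- read_gmt(gmt_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  selections <- list()
  for (label in names(score_vectors)) {
    tab <- score_pathways(score_vectors[[label]], collection)
    sel <- select_top_fraction(tab, top_fraction)
    tab$selected <- tab$pathway %in% sel
    utils::write.table(tab, file.path(out_dir, paste0("pathways_", label, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tables[[label]] <- tab
    selections[[label]] <- sel
  }
  overlap <- NULL
  if (length(selections) >= 2L && length(selections) <= 4L) {
    overlap <- overlap_counts(selections)
    jsonlite::write_json(
      list(sets = as.list(overlap$sets), sizes = as.list(overlap$sizes),
           regions = as.list(overlap$regions),
           intersections = as.list(overlap$intersections),
           union_size = overlap$union_size),
      file.path(out_dir, "pathway_overlap.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tables = tables, selections = selections, overlap = overlap))
}

#' Write a complete synthetic demo workspace
#'
#' Emits every input the pipeline reads — weighted edge table, disease
#' gene list, drug target list (sampled from the planted module),
#' pathway GMT and expression TSV — generated from one [fixture_spec()].
#' Useful for demos, tests and the command-line interface.
#'
#' @param dir Target directory (created).
#' @param spec A [fixture_spec()].
#' @param n_targets Drug targets sampled from the planted module
#'   (default 10).
#' @param n_pathways,enriched_fraction Pathway collection parameters.
#' @param n_de Differentially expressed genes in the synthetic table.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_demo_workspace <- function(dir, spec = fixture_spec(),
                                n_targets = 10L, n_pathways = 100L,
                                enriched_fraction = 0.2, n_de = 40L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_network(spec)
  fx <- plant_disease_module(fx, spec$module_size, spec$module_density,
                             spec$weight_range, rng_seed = spec$rng_seed + 1L)
  targets <- with_rng_seed(spec$rng_seed + 2L,
                           sample(fx$disease_genes, n_targets))
  collection <- generate_pathway_collection(
    fx$nodes, n_pathways = n_pathways, module_genes = fx$disease_genes,
    enriched_fraction = enriched_fraction, rng_seed = spec$rng_seed + 3L)
  expr <- generate_expression_table(fx$nodes, n_de = n_de,
                                    rng_seed = spec$rng_seed + 4L)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             disease = file.path(dir, "disease_genes.txt"),
             targets = file.path(dir, "drug_targets.txt"),
             gmt = file.path(dir, "pathways.gmt"),
             expression = file.path(dir, "expression.tsv"))
  # STRING dialect: integer combined_score 0-1000, header line
  utils::write.table(
    data.frame(protein1 = fx$edges$node_a, protein2 = fx$edges$node_b,
               combined_score = as.integer(round(fx$edges$weight * 1000))),
    paths[["edges"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("# synthetic disease genes (planted module)", fx$disease_genes),
             paths[["disease"]])
  writeLines(c("# synthetic drug targets (module subset)", targets),
             paths[["targets"]])
  write_gmt(collection, paths[["gmt"]])
  write_expression_table(expr, paths[["expression"]])
  invisible(paths)
}
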