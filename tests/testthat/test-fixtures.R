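test_that("generated networks are connected, weighted and reproducible", {
  spec <- fixture_spec(n_nodes = 50, attachment = 2, rng_seed = 3)
  fx1 <- generate_network(spec)
  fx2 <- generate_network(spec)
  expect_identical(fx1, fx2)
  expect_length(fx1$nodes, 50)
  # growth adds `attachment` edges per node after the seed vertices
  expect_gte(nrow(fx1$edges), 2 * (50 - 2))
  expect_true(all(fx1$edges$weight >= 0.9 & fx1$edges$weight <= 1))
  g <- igraph::graph_from_data_frame(fx1$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("planted modules densify and attract propagated mass", {
  spec <- fixture_spec(n_nodes = 200, module_size = 15, module_density = 1,
                       rng_seed = 8)
  fx <- generate_network(spec)
  planted <- plant_disease_module(fx, 15, 1, rng_seed = 9)
  expect_length(planted$disease_genes, 15)
  # density 1 -> module is a clique
  sub <- planted$edges[planted$edges$node_a %in% planted$disease_genes &
                         planted$edges$node_b %in% planted$disease_genes, ]
  expect_equal(nrow(sub), choose(15, 2))

  net <- build_background_network(planted$edges, threshold = 0)
  x <- rwr(column_normalize(net),
           disease_seed_vector(planted$disease_genes, net))
  inside <- mean(x[planted$disease_genes])
  outside <- mean(x[setdiff(net$nodes, planted$disease_genes)])
  expect_gt(inside, outside)
  expect_error(plant_disease_module(fx, 0, 1), "module_size")
})

test_that("synthetic expression tables plant exactly the DE genes", {
  nodes <- sprintf("g%03d", 1:80)
  tab <- generate_expression_table(nodes, n_de = 12, rng_seed = 4)
  expect_identical(tab, generate_expression_table(nodes, n_de = 12, rng_seed = 4))
  kept <- filter_de_genes(tab)
  expect_setequal(kept$gene, attr(tab, "de_genes"))
  expect_length(attr(tab, "de_genes"), 12)
  expect_error(generate_expression_table(nodes, 5, fold_range = c(4, 4)),
               "strictly above")
})

test_that("synthetic pathway collections record ground truth and round-trip", {
  nodes <- sprintf("g%03d", 1:100)
  module <- nodes[1:12]
  coll <- generate_pathway_collection(nodes, n_pathways = 30,
                                      module_genes = module,
                                      enriched_fraction = 0.2, rng_seed = 6)
  expect_length(coll, 30)
  expect_equal(sum(startsWith(names(coll), "enriched_")), 6)
  # no enrichment requested -> all background
  coll0 <- generate_pathway_collection(nodes, n_pathways = 10,
                                       enriched_fraction = 0, rng_seed = 6)
  expect_true(all(startsWith(names(coll0), "background_")))
  # enriched sets actually contain module genes
  enr <- coll[startsWith(names(coll), "enriched_")]
  expect_true(all(vapply(enr, function(s) sum(s %in% module) >= 1, logical(1))))
})

test_that("module-enriched pathways outrank background ones under propagation", {
  fx <- module_fixture(n = 300, module_size = 20, seed = 12)
  coll <- generate_pathway_collection(fx$nodes, n_pathways = 60,
                                      module_genes = fx$disease_genes,
                                      enriched_fraction = 0.2, rng_seed = 13)
  x <- rwr(column_normalize(fx$network),
           disease_seed_vector(fx$disease_genes, fx$network))
  tab <- score_pathways(x, coll)
  enriched <- startsWith(tab$pathway, "enriched_")
  expect_gt(median(tab$mean_score[enriched]),
            median(tab$mean_score[!enriched]))
})

test_that("demo workspaces contain every pipeline input and rebuild cleanly", {
  dir <- tempfile("demo")
  paths <- make_demo_workspace(dir, fixture_spec(n_nodes = 80, module_size = 10,
                                                 rng_seed = 21),
                               n_targets = 5, n_pathways = 20, n_de = 8)
  expect_true(all(file.exists(paths)))
  net <- run_build_network(paths[["edges"]],
                           c(paths[["disease"]], paths[["targets"]]),
                           threshold = 0.9, out_dir = file.path(dir, "out"))
  expect_s3_class(net, "ppi_network")
  expect_true(all(read_gene_list(paths[["disease"]]) %in% net$nodes))
  summary <- jsonlite::read_json(file.path(dir, "out", "network.summary.json"))
  expect_named(summary, c("n_nodes", "n_edges", "unmapped_required_genes"),
               ignore.order = TRUE)
  expect_equal(summary$n_nodes, length(net$nodes))
  coll <- read_gmt(paths[["gmt"]])
  expect_length(coll, 20)
  expect_equal(nrow(read_expression_table(paths[["expression"]])), 80)
})

test_that("file-level assessment and pathway runs write coherent artifacts", {
  dir <- tempfile("runs")
  paths <- make_demo_workspace(dir, fixture_spec(n_nodes = 100, module_size = 12,
                                                 rng_seed = 22),
                               n_targets = 6, n_pathways = 20, n_de = 10)
  res <- run_assess(paths[["edges"]], paths[["disease"]], paths[["targets"]],
                    n_perm = 40, rng_seed = 11, out_dir = file.path(dir, "a"))
  out <- jsonlite::read_json(file.path(dir, "a", "assessment.json"))
  expect_equal(out$z, res$z)
  expect_equal(out$n_perm, 40)

  pw <- run_pathways(list(disease = res$x_disease, drug = res$x_drug),
                     paths[["gmt"]], top_fraction = 0.2,
                     out_dir = file.path(dir, "p"))
  expect_length(pw$selections$disease, floor(0.2 * 20))
  expect_true(file.exists(file.path(dir, "p", "pathway_overlap.json")))
  ovj <- jsonlite::read_json(file.path(dir, "p", "pathway_overlap.json"))
  expect_equal(ovj$sets$A, "disease")
  expect_equal(sum(unlist(ovj$regions)), ovj$union_size)
})
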