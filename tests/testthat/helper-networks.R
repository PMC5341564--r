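# Small in-code fixtures shared across test files.

# Build a ppi_network straight from vectors of endpoints and weights.
toy_network <- function(a, b, w = rep(1, length(a))) {
  build_background_network(
    data.frame(node_a = a, node_b = b, weight = w), threshold = 0)
}

# Path graph n1 - n2 - ... - nk with unit weights.
path_network <- function(k) {
  nodes <- sprintf("n%02d", seq_len(k))
  toy_network(nodes[-k], nodes[-1])
}

# Random connected weighted graph via the package's own generator.
random_network <- function(n, seed, attachment = 2) {
  fx <- generate_network(fixture_spec(n_nodes = n, attachment = attachment,
                                      weight_range = c(0.5, 1),
                                      module_size = 1, rng_seed = seed))
  build_background_network(fx$edges, threshold = 0)
}

# Module-planted benchmark network plus its disease gene list.
module_fixture <- function(n = 500, module_size = 30, module_density = 0.5,
                           seed = 1) {
  spec <- fixture_spec(n_nodes = n, module_size = module_size,
                       module_density = module_density, rng_seed = seed)
  fx <- generate_network(spec)
  fx <- plant_disease_module(fx, spec$module_size, spec$module_density,
                             spec$weight_range, rng_seed = seed + 1000)
  net <- build_background_network(fx$edges, threshold = 0)
  list(network = net, disease_genes = fx$disease_genes, nodes = fx$nodes)
}

# Evaluate `code` under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
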