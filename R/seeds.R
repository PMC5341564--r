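#' Disease seed vector (uniform 1/m over mapped disease genes)
#'
#' Each disease gene present in the network receives `1/m`, where `m` is
#' the number of mapped disease genes, so the vector is a probability
#' distribution over the network. Genes absent from the network are
#' reported in the `unmapped` attribute, not silently dropped.
#'
#' @param genes Character vector of disease gene identifiers.
#' @param network A `ppi_network`.
#' @return Named numeric vector over `network$nodes` (sums to 1), with
#'   attributes `mapped`, `unmapped` and `mode = "disease_uniform"`.
#' @export
disease_seed_vector <- function(genes, network) {
  m <- map_seed_genes(genes, network, "disease gene")
  x0 <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  x0[m$mapped] <- 1 / length(m$mapped)
  structure(x0, mapped = m$mapped, unmapped = m$unmapped,
            mode = "disease_uniform")
}

#' Drug-target seed vector (fixed preference per target)
#'
#' Each mapped target receives a fixed small preference (default 0.01,
#' reflecting the comparatively weak per-target potency of natural-product
#' ingredients); the vector sums to `per_target * k` for `k` mapped
#' targets and is deliberately not renormalized — the walk is linear in
#' `x0`, and the permutation null uses the same per-node value, so scale
#' cancels in the Z-score.
#'
#' @param targets Character vector of target identifiers.
#' @param network A `ppi_network`.
#' @param per_target Initial value per mapped target (default 0.01).
#' @return Named numeric seed vector with attributes as in
#'   [disease_seed_vector()], `mode = "drug_fixed"`.
#' @export
drug_seed_vector <- function(targets, network, per_target = 0.01) {
  stopifnot(is.numeric(per_target), per_target > 0)
  m <- map_seed_genes(targets, network, "drug target")
  x0 <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  x0[m$mapped] <- per_target
  structure(x0, mapped = m$mapped, unmapped = m$unmapped, mode = "drug_fixed")
}

#' Expression-weighted seed vector
#'
#' Seeds the walk with differentially expressed genes, weighting each
#' mapped gene by its normalized differential expression ratio. The
#' default weighting is `|log2(ratio)|` rescaled to sum 1, which treats
#' k-fold induction and k-fold repression symmetrically; `weighting =
#' "raw"` uses the raw ratio instead (rescaled to sum 1), which weights
#' induced genes far more than repressed ones.
#'
#' @param table Expression data frame with columns `gene` and `ratio`
#'   (positive fold-ratios, treatment over control), normally already
#'   passed through [filter_de_genes()].
#' @param network A `ppi_network`.
#' @param weighting `"log2"` (default) or `"raw"`.
#' @return Named numeric seed vector summing to 1, attributes as in
#'   [disease_seed_vector()], `mode = "expression_weighted"`.
#' @export
expression_seed_vector <- function(table, network,
                                   weighting = c("log2", "raw")) {
  weighting <- match.arg(weighting)
  check_expression_table(table)
  m <- map_seed_genes(table$gene, network, "differentially expressed gene")
  rows <- table[match(m$mapped, table$gene), , drop = FALSE]
  w <- switch(weighting,
              log2 = abs(log2(rows$ratio)),
              raw = rows$ratio)
  if (sum(w) <= 0) {
    stop("all mapped genes have ratio 1: no expression signal to seed with")
  }
  x0 <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  x0[m$mapped] <- w / sum(w)
  structure(x0, mapped = m$mapped, unmapped = m$unmapped,
            mode = "expression_weighted")
}

map_seed_genes <- function(genes, network, what) {
  stopifnot(inherits(network, "ppi_network"))
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty ", what, " list")
  mapped <- genes[genes %in% network$nodes]
  if (length(mapped) == 0L) {
    stop("no ", what, " maps to the network; cannot build a seed vector")
  }
  list(mapped = mapped, unmapped = setdiff(genes, mapped))
}

check_expression_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("gene", "ratio") %in% names(table)))
  if (anyDuplicated(table$gene)) stop("duplicate genes in expression table")
  if (any(!is.finite(table$ratio) | table$ratio <= 0)) {
    stop("expression ratios must be positive and finite")
  }
  invisible(table)
}

#' Filter differentially expressed genes by fold-ratio
#'
#' Keeps genes whose expression ratio is strictly greater than `upper` or
#' strictly less than `lower`; boundary values are excluded.
#'
#' @param table Expression data frame (`gene`, `ratio`).
#' @param upper Upper fold threshold (default 4).
#' @param lower Lower fold threshold (default 0.25).
#' @return The filtered table (possibly zero rows, with a warning).
#' @export
filter_de_genes <- function(table, upper = 4, lower = 0.25) {
  stopifnot(upper > 1, lower < 1, lower > 0)
  check_expression_table(table)
  out <- table[table$ratio > upper | table$ratio < lower, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no gene passes the fold-ratio filter (", lower, ", ", upper, ")")
  }
  rownames(out) <- NULL
  out
}

#' Read / write an expression ratio table
#'
#' TSV with a `gene` and a `ratio` column (header required).
#'
#' @param path File path.
#' @return Data frame with columns `gene`, `ratio`.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "ratio") %in% names(tab))) {
    stop("expression table needs 'gene' and 'ratio' columns: ", path)
  }
  tab <- tab[, c("gene", "ratio")]
  check_expression_table(tab)
  tab
}

#' @rdname read_expression_table
#' @param table Expression data frame to write.
#' @export
write_expression_table <- function(table, path) {
  check_expression_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample random counterpart seed sets
#'
#' Draws `n_sets` node sets of the given size uniformly without
#' replacement from all network nodes; these size-matched random
#' counterparts define the permutation null for the effect score.
#'
#' @param network A `ppi_network`.
#' @param size Nodes per set (must not exceed the network size).
#' @param n_sets Number of sets.
#' @param rng_seed Integer seed; the draw is reproducible and does not
#'   disturb the caller's RNG state.
#' @return List of `n_sets` character vectors.
#' @export
sample_random_seed_sets <- function(network, size, n_sets, rng_seed) {
  stopifnot(inherits(network, "ppi_network"), size >= 1, n_sets >= 1)
  nodes <- network$nodes
  if (size > length(nodes)) {
    stop("requested set size ", size, " exceeds network size ", length(nodes))
  }
  with_rng_seed(rng_seed, {
    lapply(seq_len(n_sets), function(i) sample(nodes, size))
  })
}
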