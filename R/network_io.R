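#' Read a STRING-style weighted edge table
#'
#' Parses a whitespace- or tab-separated file with at least three columns
#' (node, node, confidence score). Raw scores are rescaled by `score_max`
#' (STRING's combined_score runs 0-1000) and clamped to `[0, 1]`. Edges are
#' canonicalized to undirected form: endpoint pairs are stored in sorted
#' order, self-edges are dropped, and duplicate pairs keep the maximum
#' weight (STRING files list both orientations of each interaction).
#'
#' A header line is auto-detected: if the third field of the first
#' non-empty line is not numeric, that line is skipped.
#'
#' @param path Path to the edge table.
#' @param score_max Positive number dividing raw scores (default 1000).
#' @return A data frame with columns `node_a`, `node_b`, `weight`, sorted
#'   by endpoints. An empty file yields a zero-row data frame.
#' @seealso [build_background_network()], [write_weighted_edges()]
#' @export
read_weighted_edges <- function(path, score_max = 1000) {
  stopifnot(is.numeric(score_max), length(score_max) == 1L, score_max > 0)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(empty_edge_table())
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  first <- fields[[1L]]
  start <- 1L
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))) {
    start <- 2L  # header
  }
  if (start > length(fields)) {
    return(empty_edge_table())
  }
  idx <- seq(start, length(fields))
  nf <- lengths(fields[idx])
  if (any(nf < 3L)) {
    bad <- keep[idx[which(nf < 3L)[1L]]]
    stop(sprintf("malformed edge line %d: fewer than 3 columns", bad))
  }
  node_a <- vapply(fields[idx], `[[`, character(1), 1L)
  node_b <- vapply(fields[idx], `[[`, character(1), 2L)
  raw <- suppressWarnings(as.numeric(vapply(fields[idx], `[[`, character(1), 3L)))
  if (anyNA(raw)) {
    bad <- keep[idx[which(is.na(raw))[1L]]]
    stop(sprintf("malformed edge line %d: non-numeric score", bad))
  }
  weight <- pmin(pmax(raw / score_max, 0), 1)
  canonical_edges(data.frame(node_a = node_a, node_b = node_b,
                             weight = weight, stringsAsFactors = FALSE))
}

empty_edge_table <- function() {
  data.frame(node_a = character(), node_b = character(),
             weight = numeric(), stringsAsFactors = FALSE)
}

# Sort endpoints within each row, drop self-edges, keep max weight per pair,
# order rows deterministically.
canonical_edges <- function(edges) {
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- edges$weight[keep]
  if (length(a) == 0L) return(empty_edge_table())
  ord <- order(a, b, -w)
  a <- a[ord]; b <- b[ord]; w <- w[ord]
  dup <- duplicated(paste(a, b, sep = "\r"))
  data.frame(node_a = a[!dup], node_b = b[!dup], weight = w[!dup],
             stringsAsFactors = FALSE)
}

#' Write an edge table or network to TSV
#'
#' Writes `node_a node_b weight` with a header; re-reading with
#' [read_weighted_edges()] at `score_max = 1` round-trips the edges.
#'
#' @param x An edge data frame or a `ppi_network`.
#' @param path Output path.
#' @export
write_weighted_edges <- function(x, path) {
  edges <- if (inherits(x, "ppi_network")) x$edges else x
  utils::write.table(
    data.frame(node_a = edges$node_a, node_b = edges$node_b,
               weight = format(edges$weight, digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list
#'
#' One identifier per line (or the first tab-separated column); lines
#' starting with `#` are comments. Identifiers are whitespace-trimmed and
#' deduplicated preserving first-seen order.
#'
#' @param path Path to the list.
#' @param name Optional label attached as the `"name"` attribute
#'   (defaults to the file name).
#' @return A character vector of unique identifiers.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L))
  if (length(genes) == 0L) {
    stop("gene list '", path, "' is empty: seed sets must be non-empty")
  }
  structure(genes, name = name)
}

#' Build the filtered background PPI network
#'
#' Keeps all edges with weight at or above `threshold`. For each required
#' gene that is present in the raw edge table but missing from the
#' thresholded graph, the per-gene threshold is lowered: the gene's raw
#' incident edges are admitted in descending weight order until the gene
#' is attached to the existing filtered network. If none of its raw
#' neighbours is in the network, only its single highest-weight edge is
#' kept (the gene enters as a small satellite component). Required genes
#' with no raw edges at all are reported in `unmapped`, never invented.
#'
#' @param edges Edge data frame as returned by [read_weighted_edges()].
#' @param required_genes Character vector of genes that must be present
#'   when the raw data allows (disease genes, drug targets).
#' @param threshold Confidence cutoff in `[0, 1]` (default 0.9).
#' @return A `ppi_network`: list with `nodes` (sorted identifiers),
#'   `edges` (canonical edge data frame), `unmapped` (required genes not
#'   in the raw data) and `threshold`.
#' @export
build_background_network <- function(edges, required_genes = character(),
                                     threshold = 0.9) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  raw <- canonical_edges(edges)
  core <- raw[raw$weight >= threshold, , drop = FALSE]
  nodes <- unique(c(core$node_a, core$node_b))
  required_genes <- unique(trimws(required_genes))
  required_genes <- required_genes[nzchar(required_genes)]
  raw_nodes <- unique(c(raw$node_a, raw$node_b))
  unmapped <- setdiff(required_genes, raw_nodes)
  if (length(unmapped) > 0L) {
    warning("required genes absent from the raw edge table: ",
            paste(unmapped, collapse = ", "))
  }
  todo <- setdiff(intersect(required_genes, raw_nodes), nodes)
  extra <- list()
  for (g in todo) {
    inc <- raw[raw$node_a == g | raw$node_b == g, , drop = FALSE]
    inc <- inc[order(-inc$weight, inc$node_a, inc$node_b), , drop = FALSE]
    others <- ifelse(inc$node_a == g, inc$node_b, inc$node_a)
    hit <- which(others %in% nodes)
    take <- if (length(hit) > 0L) seq_len(hit[1L]) else 1L
    extra[[g]] <- inc[take, , drop = FALSE]
    nodes <- unique(c(nodes, g, others[take]))
  }
  all_edges <- canonical_edges(rbind(core, do.call(rbind, extra)))
  if (nrow(all_edges) == 0L) {
    stop("background network is empty at threshold ", threshold)
  }
  new_ppi_network(all_edges, unmapped = unmapped, threshold = threshold)
}

new_ppi_network <- function(edges, unmapped = character(), threshold = NA_real_) {
  structure(
    list(nodes = sort(unique(c(edges$node_a, edges$node_b))),
         edges = edges, unmapped = unmapped, threshold = threshold),
    class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("Weighted PPI background network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (!is.na(x$threshold)) cat(sprintf("  confidence threshold: %g\n", x$threshold))
  if (length(x$unmapped)) {
    cat(sprintf("  unmapped required genes: %d (%s%s)\n", length(x$unmapped),
                paste(utils::head(x$unmapped, 5), collapse = ", "),
                if (length(x$unmapped) > 5) ", ..." else ""))
  }
  invisible(x)
}

#' Export a network with a JSON summary
#'
#' Writes the edge TSV plus a JSON summary
#' `{n_nodes, n_edges, unmapped_required_genes}`.
#'
#' @param network A `ppi_network`.
#' @param edges_path Output TSV path.
#' @param summary_path Output JSON path (default: edges path with
#'   `.summary.json` appended).
#' @export
write_network <- function(network, edges_path,
                          summary_path = paste0(edges_path, ".summary.json")) {
  stopifnot(inherits(network, "ppi_network"))
  write_weighted_edges(network, edges_path)
  jsonlite::write_json(
    list(n_nodes = length(network$nodes),
         n_edges = nrow(network$edges),
         unmapped_required_genes = as.list(network$unmapped)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(edges = edges_path, summary = summary_path))
}
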