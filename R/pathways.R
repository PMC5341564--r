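#' Read a GMT pathway collection
#'
#' MSigDB interchange dialect: one gene set per line,
#' `name TAB description TAB gene1 TAB gene2 ...`. Duplicate genes within
#' a set are deduplicated; a duplicate set name or a line with fewer than
#' three fields is an error.
#'
#' @param path GMT file path.
#' @return A `pathway_collection`: named list of character gene vectors
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", short[1L]))
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate pathway name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  descriptions <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nms)
  new_pathway_collection(stats::setNames(sets, nms), descriptions)
}

new_pathway_collection <- function(sets, descriptions = NULL) {
  if (any(lengths(sets) == 0L)) stop("empty gene set in pathway collection")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("Pathway collection: %d gene sets, sizes %d-%d (median %g)\n",
              length(x), min(lengths(x)), max(lengths(x)),
              stats::median(lengths(x))))
  invisible(x)
}

#' Write a pathway collection to GMT
#'
#' @param collection A `pathway_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Project node scores onto pathways
#'
#' For each pathway, maps the propagated node scores onto its member
#' genes — genes absent from the network are assigned score zero — and
#' averages. By default the denominator is the full pathway size
#' (zero-filled mean); `denominator = "mapped"` divides by the number of
#' mapped genes only.
#'
#' @param x Score vector from [rwr()] (named over network nodes).
#' @param collection A `pathway_collection`.
#' @param denominator `"all"` (default, zero-fill rule) or `"mapped"`.
#' @return Data frame with columns `pathway`, `n_genes`, `n_mapped`,
#'   `mean_score`.
#' @export
score_pathways <- function(x, collection, denominator = c("all", "mapped")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(collection, "pathway_collection"), !is.null(names(x)))
  rows <- lapply(names(collection), function(nm) {
    genes <- collection[[nm]]
    idx <- match(genes, names(x))
    mapped <- !is.na(idx)
    total <- sum(x[idx[mapped]])
    den <- if (denominator == "all") length(genes) else max(sum(mapped), 1L)
    data.frame(pathway = nm, n_genes = length(genes),
               n_mapped = sum(mapped), mean_score = total / den,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the top-scoring fraction of pathways
#'
#' Returns exactly `floor(fraction * n_pathways)` pathway names ranked by
#' `mean_score` descending; ties are broken by lexicographic pathway name
#' so the selection is deterministic across runs and platforms.
#'
#' @param table Output of [score_pathways()].
#' @param fraction Proportion in (0, 1); default 0.05 (top 5%).
#' @return Character vector of selected pathway names.
#' @export
select_top_fraction <- function(table, fraction = 0.05) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            fraction > 0, fraction < 1)
  k <- floor(fraction * nrow(table))
  if (k < 1L) {
    stop("floor(", fraction, " * ", nrow(table),
         ") = 0 pathways selected; use a larger fraction")
  }
  ord <- order(-table$mean_score, table$pathway)
  table$pathway[ord][seq_len(k)]
}

#' Venn-style overlap summary of 2-4 named sets
#'
#' Decomposes the union of the sets into exclusive Venn regions and also
#' reports inclusive intersection cardinalities for every combination.
#' Sets are aliased `A`, `B`, `C`, `D` in the order given; a region label
#' such as `"AB"` denotes elements in exactly A and B (regions) or in at
#' least A and B (intersections).
#'
#' @param named_sets Named list of 2-4 character vectors.
#' @return An `overlap_summary`: list with `sets` (alias -> label),
#'   `sizes`, `regions` (exclusive counts), `intersections` (inclusive
#'   counts), `union_size` and `region_members`.
#' @export
overlap_counts <- function(named_sets) {
  stopifnot(is.list(named_sets), !is.null(names(named_sets)))
  kk <- length(named_sets)
  if (kk < 2L || kk > 4L) stop("overlap report supports 2-4 sets, got ", kk)
  aliases <- LETTERS[seq_len(kk)]
  sets <- lapply(named_sets, unique)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe), ncol = kk)
  region_of <- apply(membership, 1L, function(m) paste(aliases[m], collapse = ""))

  combos <- unlist(lapply(seq_len(kk), function(sz) {
    utils::combn(aliases, sz, paste, collapse = "", simplify = FALSE)
  }))
  regions <- stats::setNames(
    vapply(combos, function(cb) sum(region_of == cb), integer(1)), combos)
  intersections <- stats::setNames(vapply(combos, function(cb) {
    members <- strsplit(cb, "")[[1L]]
    sum(rowSums(membership[, match(members, aliases), drop = FALSE]) ==
          length(members))
  }, integer(1)), combos)
  region_members <- split(universe, factor(region_of, levels = combos))

  structure(
    list(sets = stats::setNames(names(named_sets), aliases),
         sizes = stats::setNames(lengths(sets), aliases),
         regions = regions, intersections = intersections,
         union_size = length(universe),
         region_members = region_members),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Overlap of", length(x$sets), "sets (union size", x$union_size, "):\n")
  for (a in names(x$sets)) {
    cat(sprintf("  %s = %s (%d elements)\n", a, x$sets[[a]], x$sizes[[a]]))
  }
  nz <- x$regions[x$regions > 0]
  cat("  exclusive regions:",
      paste(sprintf("%s:%d", names(nz), nz), collapse = "  "), "\n")
  invisible(x)
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the convention used when reporting shared-pathway ratios.
#'
#' @param numerator,denominator Nonnegative count and positive count.
#' @param decimals Decimal places (default 1).
#' @return The rounded percentage.
#' @export
percent_shared <- function(numerator, denominator, decimals = 1) {
  stopifnot(numerator >= 0)
  if (denominator <= 0) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}
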