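#' Column-normalized transition matrix of a weighted network
#'
#' Builds the sparse column-stochastic operator P with
#' `p_ij = w_ij / sum_k w_kj` over the network's (sorted) node set, so a
#' walker at node j moves to neighbour i with probability proportional to
#' the edge weight. Rows and columns carry the node identifiers.
#'
#' @param network A `ppi_network` from [build_background_network()].
#' @return A `dgCMatrix` whose columns each sum to 1.
#' @export
column_normalize <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network$nodes
  n <- length(nodes)
  ia <- match(network$edges$node_a, nodes)
  ib <- match(network$edges$node_b, nodes)
  w <- network$edges$weight
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(w, w),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  cs <- Matrix::colSums(A)
  if (any(cs <= 0)) {
    stop("isolated node(s) with zero total edge weight: ",
         paste(utils::head(nodes[cs <= 0], 5), collapse = ", "),
         "; rebuild the network without isolated nodes")
  }
  P <- methods::as(A %*% Matrix::Diagonal(x = 1 / cs), "CsparseMatrix")
  dimnames(P) <- list(nodes, nodes)
  P
}

check_x0 <- function(P, x0) {
  X0 <- if (is.null(dim(x0))) matrix(x0, ncol = 1L, dimnames = list(names(x0), NULL))
        else as.matrix(x0)
  if (nrow(X0) != nrow(P)) {
    stop("initial vector length ", nrow(X0),
         " does not match network size ", nrow(P))
  }
  if (!is.null(rownames(X0)) && !is.null(rownames(P)) &&
      !identical(rownames(X0), rownames(P))) {
    stop("initial vector node names do not match the transition matrix")
  }
  if (any(!is.finite(X0))) stop("initial vector contains non-finite values")
  if (any(X0 < 0)) stop("initial vector must be nonnegative")
  if (any(colSums(X0) == 0)) {
    stop("initial vector must have at least one positive entry")
  }
  X0
}

#' Random walk with restart
#'
#' Iterates `x_{t+1} = (1 - r) P x_t + r x0` from `x0` until the L1 change
#' drops below `tol` or `max_iter` is reached. The fixed point scores each
#' node's proximity to the seed set: the restart pulls probability mass
#' back to the seeds with probability `r` at every step, so scores decay
#' with network distance from the seeds.
#'
#' `x0` may also be a matrix whose columns are independent seed vectors;
#' all walks are then advanced together (each column converges to exactly
#' the vector a one-column run would give, since columns never interact).
#'
#' @param P Column-stochastic transition matrix from [column_normalize()].
#' @param x0 Nonnegative seed (preference) vector, or a matrix of them.
#'   Not renormalized: the output scales linearly with `x0`.
#' @param r Restart probability in (0, 1]; default 0.3, the value
#'   standard in disease-gene prioritization.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return The converged score vector (named, with attributes
#'   `iterations`, `residual`, `converged`, `r`), or a matrix of score
#'   columns when `x0` is a matrix.
#' @seealso [rwr_closed_form()] for the exact linear-solve counterpart.
#' @export
rwr <- function(P, x0, r = 0.3, tol = 1e-10, max_iter = 1000L) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, r <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1)
  X0 <- check_x0(P, x0)
  X <- X0
  delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Xn <- (1 - r) * as.matrix(P %*% X) + r * X0
    delta <- max(colSums(abs(Xn - X)))
    X <- Xn
    if (delta < tol) break
  }
  if (any(!is.finite(X))) stop("propagation produced non-finite scores")
  finish_scores(X, x0, P, it, delta, delta < tol, r)
}

#' Closed-form random walk with restart
#'
#' Solves the fixed-point system `(I - (1 - r) P) x = r x0` directly by a
#' dense linear solve. Exact up to solver precision; used as the
#' verification oracle for the iterative walk. Guarded to networks of at
#' most `max_nodes` nodes because the solve is dense.
#'
#' @inheritParams rwr
#' @param max_nodes Dense-solve guard (default 2000).
#' @return Score vector (or matrix), as in [rwr()].
#' @export
rwr_closed_form <- function(P, x0, r = 0.3, max_nodes = 2000L) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, r <= 1)
  n <- nrow(P)
  if (n > max_nodes) {
    stop("closed-form solve is dense; network has ", n, " > ", max_nodes, " nodes")
  }
  X0 <- check_x0(P, x0)
  M <- diag(n) - (1 - r) * as.matrix(P)
  X <- solve(M, r * X0)
  if (any(!is.finite(X))) stop("singular propagation system")  # cannot occur for r > 0
  finish_scores(X, x0, P, NA_integer_, 0, TRUE, r)
}

finish_scores <- function(X, x0, P, iterations, residual, converged, r) {
  out <- if (is.null(dim(x0))) {
    stats::setNames(as.vector(X), rownames(P))
  } else {
    dimnames(X) <- list(rownames(P), colnames(x0))
    X
  }
  structure(out, iterations = iterations, residual = residual,
            converged = converged, r = r)
}

#' Export a score vector as TSV with JSON metadata
#'
#' @param x Score vector from [rwr()].
#' @param path Output TSV path (`gene` and `score` columns, full float
#'   precision); metadata (`r`, `iterations`, `residual`, `converged`)
#'   goes to `paste0(path, ".meta.json")`.
#' @export
write_score_vector <- function(x, path) {
  utils::write.table(
    data.frame(gene = names(x), score = format(as.vector(x), digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(r = attr(x, "r"), iterations = attr(x, "iterations"),
         residual = attr(x, "residual"), converged = attr(x, "converged")),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
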