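#' Drug-disease effect score
#'
#' The inner product of the disease-propagated and drug-propagated score
#' vectors, `S = sum_i x_disease(i) * x_drug(i)`. Both vectors must be
#' indexed over the same node set in the same order. S measures how much
#' the sub-network influenced by the drug overlaps the sub-network
#' affected by the disease; it is nonnegative for nonnegative inputs and
#' bilinear, so rescaling either seed vector rescales S by the same
#' factor.
#'
#' @param x_disease,x_drug Score vectors from [rwr()].
#' @return The scalar effect score.
#' @export
effect_score <- function(x_disease, x_drug) {
  if (length(x_disease) != length(x_drug)) {
    stop("score vectors have different lengths")
  }
  if (!is.null(names(x_disease)) && !is.null(names(x_drug)) &&
      !identical(names(x_disease), names(x_drug))) {
    stop("score vectors are indexed over different node sets")
  }
  sum(as.vector(x_disease) * as.vector(x_drug))
}

#' Permutation Z-score for an observed effect score
#'
#' Standardizes the observed score against the empirical null formed by
#' random counterpart seed sets: `z = (S - mean(null)) / sd(null)` with
#' the sample (n-1) standard deviation.
#'
#' @param observed Observed effect score.
#' @param null_scores Numeric vector of null effect scores (length >= 2,
#'   nonzero variance).
#' @return A `permutation_result`: list with `observed`, `null_mean`,
#'   `null_sd`, `z`, `n_perm`, `null_scores`.
#' @export
permutation_z <- function(observed, null_scores) {
  null_scores <- as.numeric(null_scores)
  if (length(null_scores) < 2L) {
    stop("need at least 2 null scores to estimate a standard deviation")
  }
  null_sd <- stats::sd(null_scores)
  if (!is.finite(null_sd) || null_sd == 0) {
    stop("null scores have zero variance; Z-score undefined")
  }
  null_mean <- mean(null_scores)
  structure(
    list(observed = observed, null_mean = null_mean, null_sd = null_sd,
         z = (observed - null_mean) / null_sd,
         n_perm = length(null_scores), null_scores = null_scores),
    class = "permutation_result")
}

#' Assess a drug's effect on a disease over the network
#'
#' Runs the full propagation protocol: a disease walk seeded uniformly at
#' the disease genes, a drug walk seeded at the drug targets, and
#' `n_perm` counterpart walks seeded at size-matched random node sets
#' (same per-node initial value as real targets, so null and observed
#' scores share a scale). The observed inner-product effect score is then
#' standardized against the null.
#'
#' All counterpart walks use the same iteration as the observed walk,
#' advanced together as columns of one matrix.
#'
#' @param network A `ppi_network`.
#' @param disease_genes,drug_targets Character vectors of identifiers.
#' @param r Restart probability (default 0.3).
#' @param tol,max_iter Convergence control, as in [rwr()].
#' @param n_perm Number of random counterpart sets (default 1000).
#' @param rng_seed Integer seed for the counterpart draw (required).
#' @param per_target Initial value per target node (default 0.01).
#' @param z_threshold Z value above which the result is flagged
#'   significant (default 3).
#' @return A `drug_disease_assessment` (extends `permutation_result`)
#'   adding `significant`, `z_threshold`, `rng_seed`, the mapped/unmapped
#'   seed genes and the two score vectors.
#' @export
assess_drug_disease <- function(network, disease_genes, drug_targets,
                                r = 0.3, tol = 1e-10, max_iter = 1000L,
                                n_perm = 1000L, rng_seed,
                                per_target = 0.01, z_threshold = 3) {
  P <- column_normalize(network)
  x0_dis <- disease_seed_vector(disease_genes, network)
  x0_drug <- drug_seed_vector(drug_targets, network, per_target = per_target)
  x_dis <- rwr(P, x0_dis, r = r, tol = tol, max_iter = max_iter)
  x_drug <- rwr(P, x0_drug, r = r, tol = tol, max_iter = max_iter)
  observed <- effect_score(x_dis, x_drug)

  k <- length(attr(x0_drug, "mapped"))
  sets <- sample_random_seed_sets(network, k, n_perm, rng_seed)
  X0 <- Matrix::sparseMatrix(
    i = match(unlist(sets), network$nodes),
    j = rep(seq_len(n_perm), each = k),
    x = per_target, dims = c(length(network$nodes), n_perm),
    dimnames = list(network$nodes, NULL))
  Xnull <- rwr(P, as.matrix(X0), r = r, tol = tol, max_iter = max_iter)
  null_scores <- as.vector(crossprod(as.vector(x_dis), Xnull))

  res <- permutation_z(observed, null_scores)
  res$significant <- res$z > z_threshold
  res$z_threshold <- z_threshold
  res$rng_seed <- rng_seed
  res$disease <- list(mapped = attr(x0_dis, "mapped"),
                      unmapped = attr(x0_dis, "unmapped"))
  res$drug <- list(mapped = attr(x0_drug, "mapped"),
                   unmapped = attr(x0_drug, "unmapped"),
                   per_target = per_target)
  res$x_disease <- x_dis
  res$x_drug <- x_drug
  class(res) <- c("drug_disease_assessment", class(res))
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Effect score S = %.6g\n", x$observed))
  cat(sprintf("Permutation null (n = %d): mean = %.6g, sd = %.6g\n",
              x$n_perm, x$null_mean, x$null_sd))
  cat(sprintf("Z-score = %.4f", x$z))
  if (!is.null(x$significant)) {
    cat(sprintf("  [%s at Z > %g]",
                if (x$significant) "significant" else "not significant",
                x$z_threshold))
  }
  cat("\n")
  invisible(x)
}

#' Serialize an assessment to JSON
#'
#' Writes `{observed, null_mean, null_sd, z, n_perm, rng_seed,
#' significant}`; optionally the full vector of null scores as TSV.
#'
#' @param result A `permutation_result` or `drug_disease_assessment`.
#' @param path Output JSON path.
#' @param null_scores_path Optional TSV path for all null scores.
#' @export
write_assessment <- function(result, path, null_scores_path = NULL) {
  jsonlite::write_json(
    list(observed = result$observed, null_mean = result$null_mean,
         null_sd = result$null_sd, z = result$z, n_perm = result$n_perm,
         rng_seed = result$rng_seed %||% NA,
         significant = result$significant %||% NA),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(null_scores_path)) {
    utils::write.table(
      data.frame(null_score = format(result$null_scores, digits = 17, trim = TRUE)),
      null_scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
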