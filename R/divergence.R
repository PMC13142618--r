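# Sample-to-sample divergence of cell-state distributions.
#
# Each sample is treated as an empirical distribution of its cells in a
# latent space (typically PCA scores). Pairwise Kullback-Leibler
# divergence is estimated with the k-nearest-neighbor estimator
#   D(P||Q) ~= (d/n) * sum_i log(nu_k(i) / rho_k(i)) + log(m / (n - 1))
# where rho_k(i) is the distance from x_i to its k-th neighbor within P
# (self excluded) and nu_k(i) its k-th neighbor distance into Q. The
# matrix is symmetrized, (D(A||B) + D(B||A)) / 2, and clipped below at 0.

# One-directional k-NN KL estimate P -> Q.
knn_kl_divergence <- function(p, q, k = 6) {
  p <- as.matrix(p); q <- as.matrix(q)
  n <- nrow(p); m <- nrow(q); d <- ncol(p)
  stopifnot(ncol(q) == d)
  if (k >= n || k > m)
    .stopf("k = %d too large for sample sizes %d and %d", k, n, m)
  rho <- FNN::get.knn(p, k = k)$nn.dist[, k]
  nu <- FNN::get.knnx(q, p, k = k)$nn.dist[, k]
  eps <- .Machine$double.eps
  (d / n) * sum(log(pmax(nu, eps) / pmax(rho, eps))) + log(m / (n - 1))
}

#' Pairwise sample divergence matrix
#'
#' Symmetrized k-nearest-neighbor Kullback-Leibler divergence between the
#' cell-state distributions of all sample pairs. Samples with fewer than
#' \code{min_cells} cells are dropped before estimation.
#'
#' @param coords cells-by-dimensions latent coordinates (e.g. PCA
#'   scores).
#' @param sample_ids sample id per cell.
#' @param k neighbor order of the estimator.
#' @param min_cells minimum cells per retained sample (samples with
#'   fewer are excluded).
#' @return list with \code{divergence} (samples-by-samples symmetric
#'   non-negative matrix, zero diagonal), \code{n_cells} per retained
#'   sample, \code{k}, and \code{dropped} sample ids.
#' @export
sample_divergence_matrix <- function(coords, sample_ids, k = 6,
                                     min_cells = 500) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(sample_ids))
  sizes <- table(sample_ids)
  keep <- names(sizes)[sizes >= min_cells]
  dropped <- setdiff(names(sizes), keep)
  if (length(keep) < 2)
    .stopf("fewer than 2 samples with at least %d cells", min_cells)
  if (any(sizes[keep] <= k))
    .stopf("k = %d must be smaller than every retained sample size", k)
  blocks <- lapply(keep, function(s)
    coords[sample_ids == s, , drop = FALSE])
  names(blocks) <- keep
  S <- length(keep)
  D <- matrix(0, S, S, dimnames = list(keep, keep))
  for (a in seq_len(S - 1)) {
    for (b in (a + 1):S) {
      dab <- knn_kl_divergence(blocks[[a]], blocks[[b]], k = k)
      dba <- knn_kl_divergence(blocks[[b]], blocks[[a]], k = k)
      D[a, b] <- D[b, a] <- max(0, (dab + dba) / 2)
    }
  }
  list(divergence = D, n_cells = as.integer(sizes[keep]), k = k,
       dropped = dropped)
}

#' Latent coordinates from log-normalized expression
#'
#' Default pluggable reducer feeding
#' \code{\link{sample_divergence_matrix}}: PCA on the most variable
#' genes of a log-normalized matrix.
#'
#' @param lognorm cells-by-genes log-normalized matrix.
#' @param n_pcs number of principal components.
#' @param n_top_genes variable genes retained before PCA.
#' @return cells-by-\code{n_pcs} score matrix.
#' @export
pca_embed <- function(lognorm, n_pcs = 10, n_top_genes = 500) {
  v <- matrixStats::colVars(as.matrix(lognorm))
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, ncol(lognorm)))]
  x <- as.matrix(lognorm[, top, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x) - 1, nrow(x) - 1)
  stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
}
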