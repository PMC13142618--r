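# Spatially variable gene detection: Delaunay neighbor graphs, Moran's I
# with permutation p-values, domain restriction and cross-sample
# aggregation.

#' Delaunay neighbor graph
#'
#' Spatial connectivity from the Delaunay triangulation of the cell
#' coordinates. Edges longer than a configurable percentile can be
#' pruned; duplicate coordinates are an error unless jittering is
#' enabled.
#'
#' @param coords 2-column matrix/data.frame of x, y positions.
#' @param prune_quantile optional quantile in (0, 1); edges longer than
#'   this quantile of edge lengths are removed.
#' @param jitter if TRUE, duplicated points are jittered by at most
#'   0.01 before triangulation.
#' @param seed seed for the jitter draw.
#' @return A \code{neighbor_graph}: list with \code{n}, \code{edges}
#'   (2-column index matrix), and sparse symmetric binary adjacency
#'   \code{W}.
#' @export
delaunay_graph <- function(coords, prune_quantile = NULL, jitter = FALSE,
                           seed = 1L) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords)
  if (n < 3) .stopf("need at least 3 points")
  if (anyDuplicated(round(coords, 8))) {
    if (!jitter)
      .stopf(paste("duplicate coordinates; enable jitter = TRUE to",
                   "displace them by <= 0.01"))
    dup <- duplicated(round(coords, 8))
    coords[dup, ] <- coords[dup, ] + withr::with_seed(
      as.integer(seed),
      matrix(stats::runif(2 * sum(dup), -0.01, 0.01), ncol = 2))
  }
  tri <- deldir::deldir(coords[, 1], coords[, 2], suppressMsge = TRUE)
  e <- cbind(tri$delsgs$ind1, tri$delsgs$ind2)
  if (is.null(e) || nrow(e) == 0)
    .stopf("degenerate (collinear?) point set: no triangulation edges")
  if (!is.null(prune_quantile)) {
    len <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                           coords[e[, 2], , drop = FALSE])^2))
    e <- e[len <= stats::quantile(len, prune_quantile), , drop = FALSE]
  }
  W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  W <- methods::as(W, "CsparseMatrix")
  W@x[] <- 1  # collapse any duplicate edge entries to binary
  structure(list(n = n, edges = e, W = W), class = "neighbor_graph")
}

# Resolve a weight matrix from a neighbor_graph or bare matrix.
.graph_w <- function(graph, row_standardize) {
  W <- if (inherits(graph, "neighbor_graph")) graph$W else
    methods::as(methods::as(graph, "generalMatrix"), "CsparseMatrix")
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  W
}

#' Moran's I spatial autocorrelation
#'
#' \code{I = (n / S0) * (z' W z) / (z' z)} with centred values \code{z}
#' and \code{S0} the total weight. Weights are binary Delaunay adjacency,
#' row-standardized by default. The expectation under random labeling is
#' \code{-1/(n-1)}.
#'
#' @param values numeric vector over the graph nodes.
#' @param graph a \code{\link{delaunay_graph}} result or a weight
#'   matrix.
#' @param row_standardize row-standardize the weights first.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, graph, row_standardize = TRUE) {
  W <- .graph_w(graph, row_standardize)
  n <- length(values)
  stopifnot(nrow(W) == n)
  z <- values - mean(values)
  den <- sum(z^2)
  if (den == 0) .stopf("values have zero variance; Moran's I is undefined")
  s0 <- sum(W)
  as.numeric((n / s0) * sum(z * as.numeric(W %*% z)) / den)
}

#' Permutation test for Moran's I
#'
#' Seeded label shuffles; one-sided (greater) p-value with the +1
#' pseudo-count, \code{p = (1 + #{I_perm >= I_obs}) / (1 + n_perm)}, so
#' the minimum attainable p at 100 permutations is 1/101. A two-sided
#' alternative doubles the smaller tail.
#'
#' @param values numeric vector over the graph nodes.
#' @param graph a \code{\link{delaunay_graph}} result or weight matrix.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param row_standardize row-standardize the weights.
#' @param alternative "greater" (positive autocorrelation, default) or
#'   "two.sided".
#' @return list with \code{I}, \code{p}, \code{n_perm}, \code{perm_I}.
#' @export
morans_i_permutation <- function(values, graph, n_perm = 100, seed = 1L,
                                 row_standardize = TRUE,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  W <- .graph_w(graph, row_standardize)
  n <- length(values)
  stopifnot(nrow(W) == n)
  z <- values - mean(values)
  den <- sum(z^2)
  if (den == 0) .stopf("values have zero variance; Moran's I is undefined")
  s0 <- sum(W)
  i_of <- function(zz) as.numeric((n / s0) * sum(zz * as.numeric(W %*% zz)) / den)
  obs <- i_of(z)
  perm <- withr::with_seed(as.integer(seed), vapply(seq_len(n_perm),
    function(i) i_of(z[sample.int(n)]), 0))
  p <- switch(alternative,
    greater = (1 + sum(perm >= obs)) / (1 + n_perm),
    two.sided = min(1, 2 * min((1 + sum(perm >= obs)) / (1 + n_perm),
                               (1 + sum(perm <= obs)) / (1 + n_perm))))
  list(I = obs, p = p, n_perm = n_perm, perm_I = perm)
}

#' Per-sample spatially variable genes with cross-sample aggregation
#'
#' For each sample: restricts cells to the named tissue domain, skips
#' samples with fewer than \code{min_obs} retained cells, builds a
#' Delaunay graph, and computes Moran's I with a permutation p-value for
#' every panel gene on log-normalized counts. Results are aggregated per
#' condition as unweighted means over retained samples, with a top-k
#' list by mean I.
#'
#' @param samples list of \code{\link{spatial_sample}} objects (or
#'   compatible lists with \code{cells}, \code{panel_counts},
#'   \code{sample_id}, \code{condition}).
#' @param domain tissue domain retained (default gray matter).
#' @param min_obs minimum cells per retained sample.
#' @param n_perm permutations per gene.
#' @param seed integer seed; per-sample seeds are derived from it.
#' @param top_k size of the top gene list.
#' @param normalize log-normalize panel counts before scoring.
#' @return list with \code{per_sample} (gene, sample, condition, I, p,
#'   n_cells), \code{aggregate} (per gene and condition: mean_I, mean_p,
#'   n_samples), \code{top} (top_k genes by mean I per condition), and
#'   \code{skipped} sample ids.
#' @export
per_sample_svg <- function(samples, domain = "GM", min_obs = 50,
                           n_perm = 100, seed = 1L, top_k = 10,
                           normalize = TRUE) {
  if (!length(samples)) .stopf("no samples supplied")
  seeds <- derive_seeds(seed, length(samples))
  rows <- list()
  skipped <- character()
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    in_dom <- s$cells$domain == domain
    if (sum(in_dom) < min_obs) {
      skipped <- c(skipped, s$sample_id)
      next
    }
    coords <- as.matrix(s$cells[in_dom, c("x_um", "y_um")])
    counts <- s$panel_counts[in_dom, , drop = FALSE]
    vals <- if (normalize) lognormalize(counts) else counts
    g <- delaunay_graph(coords)
    gseeds <- derive_seeds(seeds[si], ncol(counts))
    for (j in seq_len(ncol(counts))) {
      v <- as.numeric(vals[, j])
      if (stats::var(v) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = colnames(counts)[j], sample = s$sample_id,
          condition = s$condition, I = NA_real_, p = NA_real_,
          n_cells = sum(in_dom), stringsAsFactors = FALSE)
        next
      }
      mr <- morans_i_permutation(v, g, n_perm = n_perm, seed = gseeds[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = colnames(counts)[j], sample = s$sample_id,
        condition = s$condition, I = mr$I, p = mr$p,
        n_cells = sum(in_dom), stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample))
    .stopf("no sample retained at least %d cells in domain '%s'",
           min_obs, domain)
  agg <- do.call(rbind, lapply(
    split(per_sample, per_sample[c("gene", "condition")], drop = TRUE),
    function(d) data.frame(gene = d$gene[1], condition = d$condition[1],
                           mean_I = mean(d$I, na.rm = TRUE),
                           mean_p = mean(d$p, na.rm = TRUE),
                           n_samples = sum(!is.na(d$I)),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  top <- do.call(rbind, lapply(split(agg, agg$condition), function(d) {
    d <- d[order(-d$mean_I), , drop = FALSE]
    utils::head(d, top_k)
  }))
  rownames(top) <- NULL
  list(per_sample = per_sample, aggregate = agg, top = top,
       skipped = skipped)
}
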