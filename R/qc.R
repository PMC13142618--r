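# Four-layer nucleus quality control:
#   1. fixed thresholds on UMIs, detected genes and mitochondrial fraction
#   2. second-degree polynomial genes-vs-log10(UMI) residual outliers
#   3. consensus doublet voting over repeated runs of a pluggable scorer
#   4. Gaussian-mixture thresholds on cell-class marker scores; nuclei
#      exceeding the threshold for more than one class are heterotypic
#      doublets.

#' Quality-control thresholds
#'
#' Defaults: keep nuclei with 500-250,000 UMIs, 1,200-15,000 detected
#' genes, at most 10\% mitochondrial content; drop nuclei whose detected
#' gene count deviates from a degree-2 polynomial fit on log10(UMI) by
#' more than 2,000; run the doublet scorer 100 times and drop nuclei
#' flagged in more than 10\% of runs; per cell class, threshold marker
#' scores at the lower Gaussian-mixture component's mean plus 4 SD.
#'
#' @param min_umi,max_umi,min_genes,max_genes inclusive count bounds.
#' @param max_mito_frac maximum mitochondrial fraction (inclusive).
#' @param poly_degree,poly_residual_max polynomial layer settings; the
#'   residual bound is in detected genes on the linear scale.
#' @param consensus_iters,consensus_flag_frac consensus voting settings;
#'   removal requires being flagged in strictly more than
#'   \code{consensus_flag_frac} of runs.
#' @param gmm_sd_mult multiplier on the lower component's SD.
#' @return A \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(min_umi = 500, max_umi = 250000,
                          min_genes = 1200, max_genes = 15000,
                          max_mito_frac = 0.10,
                          poly_degree = 2, poly_residual_max = 2000,
                          consensus_iters = 100, consensus_flag_frac = 0.10,
                          gmm_sd_mult = 4.0) {
  stopifnot(min_umi < max_umi, min_genes < max_genes,
            max_mito_frac > 0, max_mito_frac <= 1, poly_degree >= 1)
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 min_genes = min_genes, max_genes = max_genes,
                 max_mito_frac = max_mito_frac, poly_degree = poly_degree,
                 poly_residual_max = poly_residual_max,
                 consensus_iters = consensus_iters,
                 consensus_flag_frac = consensus_flag_frac,
                 gmm_sd_mult = gmm_sd_mult),
            class = "qc_thresholds")
}

#' Fixed-threshold nucleus filters
#'
#' Keeps a nucleus iff its UMI total, detected gene count and
#' mitochondrial fraction all lie within the configured bounds
#' (bounds inclusive).
#'
#' @param counts a \code{\link{count_matrix}} with mitochondrial gene
#'   flags, or a bare matrix plus \code{gene_flags}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param gene_flags logical mitochondrial indicator when \code{counts}
#'   is a bare matrix.
#' @return logical keep mask, one entry per cell.
#' @export
basic_filters <- function(counts, thresholds = qc_thresholds(),
                          gene_flags = NULL) {
  m <- cm_counts(counts)
  flags <- if (is.null(gene_flags)) cm_flags(counts) else gene_flags
  if (is.null(flags))
    .stopf("mitochondrial gene flags are required for basic_filters")
  if (nrow(m) == 0) return(logical(0))
  umi <- Matrix::rowSums(m)
  genes <- Matrix::rowSums(m > 0)
  mito_frac <- if (any(flags))
    Matrix::rowSums(m[, flags, drop = FALSE]) / pmax(umi, 1) else
    numeric(nrow(m))
  unname(umi >= thresholds$min_umi & umi <= thresholds$max_umi &
    genes >= thresholds$min_genes & genes <= thresholds$max_genes &
    mito_frac <= thresholds$max_mito_frac)
}

#' Polynomial-residual outlier filter
#'
#' Fits detected genes (linear scale) on log10(UMI) by least squares with
#' a degree-2 polynomial and removes nuclei whose observed gene count
#' deviates from the fitted curve by more than the configured residual
#' bound.
#'
#' @param umi_per_cell,genes_per_cell per-cell totals.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with \code{keep} (logical mask), \code{coefficients} of
#'   the fit, and \code{residuals}.
#' @export
polynomial_outlier_filter <- function(umi_per_cell, genes_per_cell,
                                      thresholds = qc_thresholds()) {
  n <- length(umi_per_cell)
  stopifnot(length(genes_per_cell) == n)
  if (n < thresholds$poly_degree + 2)
    .stopf("need at least %d cells to fit a degree-%d polynomial",
           thresholds$poly_degree + 2, thresholds$poly_degree)
  lu <- log10(pmax(umi_per_cell, 1))
  fit <- stats::lm(genes_per_cell ~ stats::poly(lu, thresholds$poly_degree,
                                                raw = TRUE))
  res <- stats::residuals(fit)
  list(keep = unname(abs(res) <= thresholds$poly_residual_max),
       coefficients = unname(stats::coef(fit)), residuals = unname(res))
}

#' Consensus doublet filter
#'
#' Runs a doublet scorer repeatedly with derived seeds and removes nuclei
#' flagged in strictly more than \code{consensus_flag_frac} of runs.
#'
#' @param counts a \code{\link{count_matrix}} or matrix for one sample.
#' @param scorer function \code{(counts, seed) -> logical flags}; see
#'   \code{\link{knn_doublet_scorer}} for the built-in reference scorer.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param seed integer seed from which per-iteration seeds are derived.
#' @return list with \code{keep}, per-cell \code{flag_frac}, and the
#'   number of iterations run.
#' @export
consensus_doublet_filter <- function(counts, scorer,
                                     thresholds = qc_thresholds(),
                                     seed = 1L) {
  m <- cm_counts(counts)
  n <- nrow(m)
  iters <- thresholds$consensus_iters
  seeds <- derive_seeds(seed, iters)
  votes <- numeric(n)
  for (i in seq_len(iters)) {
    fl <- scorer(m, seeds[i])
    if (!is.logical(fl) || length(fl) != n)
      .stopf("scorer must return a logical vector of length %d", n)
    votes <- votes + fl
  }
  frac <- votes / iters
  list(keep = frac <= thresholds$consensus_flag_frac, flag_frac = frac,
       iterations = iters)
}

#' Reference k-nearest-neighbor doublet scorer
#'
#' Minimal built-in scorer for \code{\link{consensus_doublet_filter}}:
#' simulates synthetic doublets as sums of random parent pairs, embeds
#' observed and simulated cells in log-normalized space restricted to the
#' most variable genes, and scores each observed cell by the fraction of
#' simulated doublets among its nearest neighbors. Cells above the
#' score quantile are flagged.
#'
#' @param sim_ratio simulated doublets per observed cell.
#' @param k neighbors used for the score.
#' @param n_top_genes variable genes retained for the distance space.
#' @param flag_quantile score quantile above which cells are flagged.
#' @return A scorer \code{function(counts, seed)} returning logical flags.
#' @export
knn_doublet_scorer <- function(sim_ratio = 0.5, k = 10, n_top_genes = 30,
                               flag_quantile = 0.95) {
  # The observed-cell embedding (variable-gene choice, normalized block)
  # depends only on the input matrix, so it is cached across the repeated
  # calls the consensus layer makes on the same sample.
  cache <- new.env(parent = emptyenv())
  function(counts, seed) {
    m <- cm_counts(counts)
    n <- nrow(m)
    key <- paste(n, ncol(m), sum(m@x))
    if (!identical(cache$key, key)) {
      ln <- lognormalize(m)
      mu <- Matrix::colMeans(ln)
      ln2 <- ln
      ln2@x <- ln2@x^2
      v <- Matrix::colMeans(ln2) - mu^2   # sparse column variances
      cache$top <- order(v, decreasing = TRUE)[
        seq_len(min(n_top_genes, ncol(m)))]
      cache$lib <- pmax(Matrix::rowSums(m), 1)
      cache$obs_emb <- as.matrix(ln[, cache$top, drop = FALSE])
      cache$key <- key
    }
    withr::with_seed(as.integer(seed), {
      n_sim <- max(1L, round(sim_ratio * n))
      p1 <- sample.int(n, n_sim, replace = TRUE)
      p2 <- sample.int(n, n_sim, replace = TRUE)
      sim_block <- m[p1, cache$top, drop = FALSE] +
        m[p2, cache$top, drop = FALSE]
      sim_lib <- cache$lib[p1] + cache$lib[p2]
      sim_emb <- log1p(as.matrix(sim_block) * (1e4 / sim_lib))
      emb <- rbind(cache$obs_emb, sim_emb)
      kk <- min(k, n + n_sim - 1)
      nn <- FNN::get.knn(emb, k = kk)$nn.index[seq_len(n), , drop = FALSE]
      score <- rowMeans(nn > n)
      score > stats::quantile(score, flag_quantile)
    })
  }
}

#' Per-class marker scores
#'
#' Scores every nucleus for each cell class as the mean log-normalized
#' expression of that class's marker genes.
#'
#' @param lognorm log-normalized cells-by-genes matrix
#'   (\code{\link{lognormalize}}).
#' @param marker_sets named list, class -> character vector of marker
#'   genes. Markers missing from the matrix are dropped with a warning;
#'   a class with no present markers is an error.
#' @return cells-by-classes numeric score matrix.
#' @export
marker_score <- function(lognorm, marker_sets) {
  stopifnot(is.list(marker_sets), length(marker_sets) >= 1)
  out <- matrix(0, nrow = nrow(lognorm), ncol = length(marker_sets),
                dimnames = list(rownames(lognorm), names(marker_sets)))
  for (cls in names(marker_sets)) {
    genes <- marker_sets[[cls]]
    present <- intersect(genes, colnames(lognorm))
    if (!length(present))
      .stopf("no marker genes for class '%s' present in the matrix", cls)
    if (length(present) < length(genes))
      .warnf("class '%s': %d of %d marker genes absent, dropped", cls,
             length(genes) - length(present), length(genes))
    out[, cls] <- Matrix::rowSums(lognorm[, present, drop = FALSE]) /
      length(present)
  }
  out
}

#' Gaussian-mixture heterotypic doublet filter
#'
#' Per cell class, fits a 2-component univariate Gaussian mixture to the
#' marker scores and sets a threshold at the lower component's mean plus
#' \code{gmm_sd_mult} standard deviations. A nucleus exceeding the
#' threshold for two or more classes is a heterotypic doublet and is
#' removed; exceeding a single class threshold is the expected behaviour
#' of a genuine member of that class.
#'
#' @param score_matrix cells-by-classes marker score matrix
#'   (\code{\link{marker_score}}).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param min_weight classes whose smaller mixture component has weight
#'   below this are skipped with a warning (degenerate fit).
#' @return list with \code{keep}, per-class \code{thresholds},
#'   \code{n_classes_exceeded} per cell, and the fitted mixture
#'   \code{parameters} per class.
#' @export
gmm_heterotypic_filter <- function(score_matrix,
                                   thresholds = qc_thresholds(),
                                   min_weight = 0.01) {
  stopifnot(ncol(score_matrix) >= 2)
  classes <- colnames(score_matrix)
  thr <- setNames(rep(NA_real_, length(classes)), classes)
  params <- list()
  exceeded <- matrix(FALSE, nrow = nrow(score_matrix),
                     ncol = length(classes),
                     dimnames = dimnames(score_matrix))
  for (cls in classes) {
    x <- score_matrix[, cls]
    fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit))
      .stopf("Gaussian mixture fit failed to converge for class '%s'", cls)
    mu <- fit$parameters$mean
    sdv <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sdv) == 1) sdv <- rep(sdv, 2)
    w <- fit$parameters$pro
    if (min(w) < min_weight) {
      .warnf("class '%s': degenerate mixture component (weight %.3f), skipped",
             cls, min(w))
      next
    }
    lo <- which.min(mu)
    thr[cls] <- mu[lo] + thresholds$gmm_sd_mult * sdv[lo]
    params[[cls]] <- list(means = unname(mu), sds = unname(sdv),
                          weights = unname(w))
    exceeded[, cls] <- x > thr[cls]
  }
  n_exc <- rowSums(exceeded)
  list(keep = unname(n_exc < 2), thresholds = thr,
       n_classes_exceeded = n_exc, parameters = params)
}

#' Blacklist expression filter
#'
#' Generic curation utility: drops cells expressing any gene from a user
#' blacklist above a count threshold (e.g. off-region neuronal markers).
#'
#' @param counts a \code{\link{count_matrix}} or matrix.
#' @param genes blacklisted gene ids; absent genes are ignored.
#' @param max_count maximum tolerated count (default 0: any expression
#'   removes the cell).
#' @return logical keep mask.
#' @export
blacklist_filter <- function(counts, genes, max_count = 0) {
  m <- cm_counts(counts)
  present <- intersect(genes, colnames(m))
  if (!length(present)) return(rep(TRUE, nrow(m)))
  unname(Matrix::rowSums(m[, present, drop = FALSE] > max_count) == 0)
}

#' Run the full quality-control cascade on one sample
#'
#' Applies, in order: consensus doublet voting, fixed thresholds, the
#' polynomial residual filter, and the Gaussian-mixture heterotypic
#' filter. Layer membership is computed on the original cells so layers
#' can also be intersected independently.
#'
#' @param counts a \code{\link{count_matrix}} with mitochondrial flags.
#' @param marker_sets class -> marker genes for the mixture layer.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param scorer doublet scorer; default \code{\link{knn_doublet_scorer}()}.
#' @param seed integer seed.
#' @return A \code{qc_report}: per-layer masks, per-layer removal counts,
#'   polynomial coefficients, mixture parameters/thresholds and the final
#'   kept cell ids.
#' @export
run_qc <- function(counts, marker_sets, thresholds = qc_thresholds(),
                   scorer = knn_doublet_scorer(), seed = 1L) {
  m <- cm_counts(counts)
  n <- nrow(m)
  cons <- consensus_doublet_filter(counts, scorer, thresholds, seed)
  basic <- basic_filters(counts, thresholds)
  umi <- Matrix::rowSums(m)
  genes <- Matrix::rowSums(m > 0)
  poly <- polynomial_outlier_filter(umi, genes, thresholds)
  scores <- marker_score(lognormalize(m), marker_sets)
  gmm <- gmm_heterotypic_filter(scores, thresholds)
  keep <- cons$keep & basic & poly$keep & gmm$keep
  masks <- list(consensus = cons$keep, basic = basic,
                polynomial = poly$keep, gmm = gmm$keep)
  structure(list(
    masks = masks, keep = keep,
    kept_cells = rownames(m)[keep],
    removed_per_layer = vapply(masks, function(k) sum(!k), 0L),
    n_input = n, n_kept = sum(keep),
    poly_coefficients = poly$coefficients,
    gmm_thresholds = gmm$thresholds, gmm_parameters = gmm$parameters,
    flag_frac = cons$flag_frac, seed = as.integer(seed)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d of %d nuclei kept\n", x$n_kept, x$n_input))
  for (nm in names(x$removed_per_layer))
    cat(sprintf("  %-11s removed %d\n", nm, x$removed_per_layer[[nm]]))
  invisible(x)
}
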