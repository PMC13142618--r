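# Gene-signature module scoring with expression-matched control baselines,
# one-vs-rest score enrichment, per-cell signature labeling and dot-plot
# style expression summaries.

#' Module score against expression-matched controls
#'
#' Per cell: mean log-normalized expression over the gene set minus the
#' mean over a control set sampled (seeded) from expression-matched bins.
#' Genes are binned by their dataset-wide mean expression into
#' \code{n_bins} equal-occupancy bins; from each bin containing set genes,
#' up to \code{n_ctrl_per_bin} non-set genes are drawn uniformly without
#' replacement.
#'
#' @param lognorm cells-by-genes log-normalized matrix.
#' @param gene_set character vector of gene ids; genes absent from the
#'   matrix are dropped (an empty intersection is an error listing them).
#' @param n_bins expression bins.
#' @param n_ctrl_per_bin control genes drawn per occupied bin.
#' @param seed integer seed for the control draw.
#' @return numeric per-cell score vector with attributes
#'   \code{control_genes}, \code{set_genes}, \code{n_bins},
#'   \code{n_ctrl_per_bin}, \code{seed}.
#' @export
module_score <- function(lognorm, gene_set, n_bins = 25,
                         n_ctrl_per_bin = 50, seed = 1L) {
  genes <- colnames(lognorm)
  present <- intersect(gene_set, genes)
  if (!length(present))
    .stopf("no gene of the set is present in the matrix; missing: %s",
           paste(utils::head(gene_set, 10), collapse = ", "))
  avg <- Matrix::colMeans(lognorm)
  n_bins_eff <- min(n_bins, length(avg))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins_eff,
              labels = FALSE)
  names(bins) <- genes
  ctrl <- withr::with_seed(as.integer(seed), {
    unlist(lapply(unique(bins[present]), function(b) {
      pool <- setdiff(genes[bins == b], present)
      # a bin fully occupied by set genes still contributes a matched
      # control drawn from the bin itself
      if (!length(pool)) pool <- genes[bins == b]
      sample(pool, min(n_ctrl_per_bin, length(pool)))
    }), use.names = FALSE)
  })
  set_mean <- Matrix::rowSums(lognorm[, present, drop = FALSE]) /
    length(present)
  ctrl_mean <- if (length(ctrl))
    Matrix::rowSums(lognorm[, ctrl, drop = FALSE]) / length(ctrl) else 0
  score <- as.numeric(set_mean - ctrl_mean)
  names(score) <- rownames(lognorm)
  attr(score, "set_genes") <- present
  attr(score, "control_genes") <- ctrl
  attr(score, "n_bins") <- n_bins
  attr(score, "n_ctrl_per_bin") <- n_ctrl_per_bin
  attr(score, "seed") <- as.integer(seed)
  score
}

#' One-versus-rest enrichment of scores
#'
#' Per group: two-sided Wilcoxon rank-sum of the group's scores against
#' all other cells, the group and rest means, and a log2 fold change of
#' the positivity-shifted means. Module scores can be negative, so both
#' means are shifted by the global minimum before the ratio; the shift
#' and epsilon are recorded as attributes. P-values are BH-adjusted
#' across groups.
#'
#' @param scores per-cell numeric scores.
#' @param group_labels group label per cell.
#' @param min_group_size groups smaller than this are skipped with a
#'   warning.
#' @param eps positivity guard added to both shifted means.
#' @return data.frame: group, n, mean_group, mean_rest, lfc, p, p_adj.
#' @export
one_vs_rest_enrichment <- function(scores, group_labels,
                                   min_group_size = 3, eps = 1e-9) {
  stopifnot(length(scores) == length(group_labels))
  groups <- sort(unique(as.character(group_labels)))
  if (length(groups) < 2) .stopf("need at least 2 groups")
  shift <- min(scores)
  rows <- lapply(groups, function(g) {
    ing <- group_labels == g
    if (sum(ing) < min_group_size) {
      .warnf("group '%s' has fewer than %d cells; skipped", g,
             min_group_size)
      return(NULL)
    }
    mw <- mann_whitney_u(scores[ing], scores[!ing])
    mg <- mean(scores[ing]); mr <- mean(scores[!ing])
    data.frame(group = g, n = sum(ing), mean_group = mg, mean_rest = mr,
               lfc = log2((mg - shift + eps) / (mr - shift + eps)),
               p = mw$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no group passed the size filter")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "shift") <- shift
  attr(out, "eps") <- eps
  out
}

#' Label cells by their best signature
#'
#' Scores are z-scaled per signature; a cell is labeled with the argmax
#' signature when its top z-score is positive and exceeds the runner-up
#' by more than \code{margin_z}, otherwise it is \code{"Unassigned"}.
#' Ties at the top never clear the margin and therefore fall to
#' Unassigned.
#'
#' @param score_matrix cells-by-signatures score matrix.
#' @param margin_z required lead of the top z-score over the runner-up.
#' @return character vector of labels, one per cell.
#' @export
label_cells_by_signature <- function(score_matrix, margin_z = 0.5) {
  stopifnot(ncol(score_matrix) >= 2)
  z <- apply(score_matrix, 2, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  top <- max.col(z, ties.method = "first")
  zs <- t(apply(z, 1, sort, decreasing = TRUE))
  best <- zs[, 1]; second <- zs[, 2]
  lab <- colnames(score_matrix)[top]
  lab[!(best > 0 & (best - second) > margin_z)] <- "Unassigned"
  names(lab) <- rownames(score_matrix)
  lab
}

#' Dot-plot expression summary
#'
#' Per gene and group: the fraction of cells with nonzero expression,
#' the mean log-normalized expression over all cells of the group, and
#' the mean over expressing cells only (both variants of the ambiguous
#' "mean expression" are emitted).
#'
#' @param lognorm cells-by-genes log-normalized matrix.
#' @param genes genes to summarize; missing genes are dropped with a
#'   warning.
#' @param group_labels group per cell.
#' @return data.frame: gene, group, frac_expressing, mean_all,
#'   mean_expressing.
#' @export
expression_dot_summary <- function(lognorm, genes, group_labels) {
  present <- intersect(genes, colnames(lognorm))
  if (length(present) < length(genes))
    .warnf("%d gene(s) absent from the matrix, dropped",
           length(genes) - length(present))
  if (!length(present)) .stopf("no requested gene present")
  out <- list()
  for (g in sort(unique(as.character(group_labels)))) {
    sub <- lognorm[group_labels == g, present, drop = FALSE]
    n <- nrow(sub)
    nexpr <- Matrix::colSums(sub > 0)
    tot <- Matrix::colSums(sub)
    out[[g]] <- data.frame(
      gene = present, group = g,
      frac_expressing = as.numeric(nexpr / max(n, 1)),
      mean_all = as.numeric(tot / max(n, 1)),
      mean_expressing = as.numeric(ifelse(nexpr > 0, tot / nexpr, 0)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
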