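# Wilcoxon differential expression with prevalence filtering, |LFC|
# magnitude tiers, pseudogene-prefix filtering, and the dual strict /
# relaxed threshold overlap logic used for three-way (program vs disease)
# Venn partitions and cross-cell-type intersections.

#' Tier thresholds and significance rule
#'
#' Significant DEGs require adjusted p < 0.05 and expression prevalence
#' pts > 0.1 in the test group; significant genes are partitioned by
#' |LFC| into Tier 1 (>= 2.0), Tier 2 ([1.0, 2.0)), Tier 3 ([0.5, 1.0)),
#' Tier 4 ([0.25, 0.5)).
#'
#' @param p_adj_max significance cutoff on the adjusted p-value.
#' @param min_pts prevalence cutoff (strict \code{>}).
#' @param tier_breaks ascending |LFC| boundaries of Tiers 4..1.
#' @return A \code{tier_thresholds} list.
#' @export
tier_thresholds <- function(p_adj_max = 0.05, min_pts = 0.1,
                            tier_breaks = c(0.25, 0.5, 1.0, 2.0)) {
  stopifnot(all(diff(tier_breaks) > 0), length(tier_breaks) == 4)
  structure(list(p_adj_max = p_adj_max, min_pts = min_pts,
                 tier_breaks = tier_breaks),
            class = "tier_thresholds")
}

#' Wilcoxon rank-sum differential expression
#'
#' Per gene: two-sided rank-sum test of the test group against the
#' reference (tie-corrected; exact permutation null for small combined
#' sizes), log2 fold change of the de-logged group means, expression
#' prevalence in both groups, and BH adjustment across genes.
#'
#' @param lognorm cells-by-genes log-normalized matrix.
#' @param labels two-level vector over cells.
#' @param test_group which level is the test group (default: first
#'   encountered level); LFC and pts refer to this group.
#' @param eps positivity guard in the fold-change ratio.
#' @param block_size genes processed per dense block.
#' @return A \code{deg_table} data.frame: gene, statistic (U for the
#'   test group), lfc, p, p_adj, pts, pts_rest, direction; group sizes
#'   in attributes.
#' @export
wilcoxon_de <- function(lognorm, labels, test_group = NULL, eps = 1e-9,
                        block_size = 500) {
  lv <- unique(as.character(labels))
  if (length(lv) != 2) .stopf("labels must have exactly two levels")
  if (is.null(test_group)) test_group <- lv[1]
  g1 <- which(labels == test_group)
  g2 <- which(labels != test_group)
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 3 || n2 < 3) .stopf("both groups need at least 3 cells")
  N <- n1 + n2
  genes <- colnames(lognorm)
  G <- length(genes)
  use_exact <- N <= 30
  U <- p <- lfc <- pts <- pts_rest <- numeric(G)
  for (start in seq(1, G, by = block_size)) {
    idx <- start:min(start + block_size - 1, G)
    X <- as.matrix(lognorm[, idx, drop = FALSE])
    for (j in seq_along(idx)) {
      v <- X[, j]
      r <- rank(v)
      Uj <- sum(r[g1]) - n1 * (n1 + 1) / 2
      U[idx[j]] <- Uj
      p[idx[j]] <- if (use_exact) mw_exact_p(r, n1, Uj) else
        mw_approx_p(r, n1, Uj)
      m1 <- mean(expm1(v[g1])); m2 <- mean(expm1(v[g2]))
      lfc[idx[j]] <- log2((m1 + eps) / (m2 + eps))
      pts[idx[j]] <- mean(v[g1] > 0)
      pts_rest[idx[j]] <- mean(v[g2] > 0)
    }
  }
  out <- data.frame(gene = genes, statistic = U, lfc = lfc, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    pts = pts, pts_rest = pts_rest,
                    direction = ifelse(lfc > 0, "up",
                                       ifelse(lfc < 0, "down", "flat")),
                    stringsAsFactors = FALSE)
  attr(out, "test_group") <- test_group
  attr(out, "n_test") <- n1
  attr(out, "n_ref") <- n2
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Significant DEGs with magnitude tiers
#'
#' Retains genes with adjusted p below the cutoff, prevalence above the
#' cutoff, and |LFC| at or above the Tier 4 floor; attaches the tier
#' label and up/down direction.
#'
#' @param table a \code{\link{wilcoxon_de}} result (or compatible
#'   data.frame with \code{lfc}, \code{p_adj}, \code{pts}).
#' @param thresholds a \code{\link{tier_thresholds}}.
#' @return the filtered table with a \code{tier} column ("Tier 1" ..
#'   "Tier 4").
#' @export
significant_degs <- function(table, thresholds = tier_thresholds()) {
  b <- thresholds$tier_breaks
  keep <- table$p_adj < thresholds$p_adj_max &
    table$pts > thresholds$min_pts & abs(table$lfc) >= b[1]
  out <- table[keep, , drop = FALSE]
  a <- abs(out$lfc)
  out$tier <- ifelse(a >= b[4], "Tier 1",
                     ifelse(a >= b[3], "Tier 2",
                            ifelse(a >= b[2], "Tier 3", "Tier 4")))
  rownames(out) <- NULL
  out
}

#' Filter clone-derived and long non-coding gene identifiers
#'
#' Removes ids that look like clone-based or lncRNA nomenclature:
#' \code{AC}, \code{AL}, \code{AP} or \code{AF} immediately followed by a
#' digit (e.g. AC012345.1), and any id starting with \code{LINC}.
#' Case-sensitive, so gene symbols such as ACTB or ALDH1L1 survive.
#'
#' @param gene_ids character vector.
#' @param prefixes digit-anchored prefixes to remove.
#' @return the kept gene ids.
#' @export
filter_noncoding <- function(gene_ids,
                             prefixes = c("AC", "AL", "AP", "AF")) {
  pat <- sprintf("^(%s)[0-9]", paste(prefixes, collapse = "|"))
  drop <- grepl(pat, gene_ids) | startsWith(gene_ids, "LINC")
  gene_ids[!drop]
}

#' Dual strict/relaxed overlap specification
#'
#' @param strict_lfc |LFC| bound defining the candidate universe.
#' @param relaxed_lfc |LFC| bound for presence in other comparisons
#'   (0.5 for three-way Venn partitions, 0.25 for cross-cell-type
#'   intersections).
#' @param p_adj_max adjusted-p cutoff applied at both tiers.
#' @param direction_consistent require the relaxed hit to share the sign
#'   of the strict occurrence.
#' @param min_intersection_display intersections with strictly more
#'   genes than this are flagged displayable.
#' @return An \code{overlap_spec} list.
#' @export
overlap_spec <- function(strict_lfc = 1.0, relaxed_lfc = 0.5,
                         p_adj_max = 0.05, direction_consistent = TRUE,
                         min_intersection_display = 10) {
  stopifnot(relaxed_lfc <= strict_lfc)
  structure(list(strict_lfc = strict_lfc, relaxed_lfc = relaxed_lfc,
                 p_adj_max = p_adj_max,
                 direction_consistent = direction_consistent,
                 min_intersection_display = min_intersection_display),
            class = "overlap_spec")
}

# Strict / relaxed significance masks for one DEG table, as named
# data.frame keyed by gene.
.overlap_hits <- function(tab, spec) {
  data.frame(gene = tab$gene,
             strict = tab$p_adj < spec$p_adj_max &
               abs(tab$lfc) >= spec$strict_lfc,
             relaxed = tab$p_adj < spec$p_adj_max &
               abs(tab$lfc) >= spec$relaxed_lfc,
             sign = sign(tab$lfc), stringsAsFactors = FALSE)
}

#' Three-way Venn membership under the dual-threshold rule
#'
#' The candidate universe is every (coding) gene strict-significant in at
#' least one comparison; a universe gene is "present" in a comparison if
#' it is relaxed-significant there with the same LFC sign as its strict
#' occurrence(s). Each universe gene lands in exactly one of the 7 Venn
#' regions. Genes whose strict occurrences disagree in sign are excluded
#' and reported.
#'
#' @param tables named list of exactly three \code{\link{wilcoxon_de}}
#'   tables (e.g. PD, UPR, Reactive).
#' @param spec an \code{\link{overlap_spec}} (relaxed default 0.5).
#' @param apply_noncoding_filter drop clone/lncRNA ids first.
#' @return list with \code{membership} (gene, region, presence flags per
#'   comparison, sign), \code{region_counts}, and
#'   \code{sign_conflicts} (excluded genes).
#' @export
dual_threshold_overlap <- function(tables, spec = overlap_spec(),
                                   apply_noncoding_filter = TRUE) {
  if (length(tables) != 3 || is.null(names(tables)))
    .stopf("exactly three named comparisons are required")
  cmp <- names(tables)
  hits <- lapply(tables, .overlap_hits, spec = spec)
  genes <- sort(unique(unlist(lapply(hits, function(h)
    h$gene[h$strict]))))
  if (apply_noncoding_filter) genes <- filter_noncoding(genes)
  membership <- conflicts <- list()
  for (g in genes) {
    strict_signs <- relaxed <- c()
    for (cc in cmp) {
      h <- hits[[cc]]
      i <- match(g, h$gene)
      if (!is.na(i) && h$strict[i]) strict_signs <- c(strict_signs, h$sign[i])
    }
    if (length(unique(strict_signs)) > 1) {
      conflicts[[g]] <- g
      next
    }
    sgn <- strict_signs[1]
    present <- vapply(cmp, function(cc) {
      h <- hits[[cc]]
      i <- match(g, h$gene)
      !is.na(i) && h$relaxed[i] &&
        (!spec$direction_consistent || h$sign[i] == sgn)
    }, TRUE)
    membership[[g]] <- cbind(
      data.frame(gene = g, region = paste(cmp[present], collapse = "&"),
                 stringsAsFactors = FALSE),
      as.data.frame(t(present)), sign = sgn)
  }
  mem <- do.call(rbind, membership)
  rownames(mem) <- NULL
  all_regions <- unlist(lapply(1:3, function(k)
    utils::combn(cmp, k, paste, collapse = "&")))
  counts <- setNames(integer(length(all_regions)), all_regions)
  if (!is.null(mem)) {
    tb <- table(mem$region)
    counts[names(tb)] <- as.integer(tb)
  }
  list(membership = mem, region_counts = counts,
       sign_conflicts = unlist(conflicts, use.names = FALSE))
}

#' Cross-cell-type DEG intersections for one comparison
#'
#' Same strict/relaxed logic across cell types: the universe is every
#' gene strict-significant in at least one cell type; presence elsewhere
#' uses the relaxed threshold with sign concordance. Emits the size of
#' every non-empty cell-type intersection, split into up- and
#' down-regulated genes, flagging those with more than
#' \code{min_intersection_display} genes as displayable.
#'
#' @param tables named list (cell type -> \code{\link{wilcoxon_de}}
#'   table) for one comparison.
#' @param spec an \code{\link{overlap_spec}}; the cross-cell-type
#'   convention is \code{relaxed_lfc = 0.25}.
#' @param apply_noncoding_filter drop clone/lncRNA ids first.
#' @return list with \code{counts} (data.frame: combo, direction, n,
#'   displayable) and \code{membership} (gene, direction, combo).
#' @export
cross_celltype_intersections <- function(tables,
                                         spec = overlap_spec(relaxed_lfc = 0.25),
                                         apply_noncoding_filter = TRUE) {
  if (length(tables) < 2 || is.null(names(tables)))
    .stopf("at least two named cell types are required")
  cts <- names(tables)
  hits <- lapply(tables, .overlap_hits, spec = spec)
  genes <- sort(unique(unlist(lapply(hits, function(h)
    h$gene[h$strict]))))
  if (apply_noncoding_filter) genes <- filter_noncoding(genes)
  rows <- list()
  for (g in genes) {
    strict_signs <- c()
    for (cc in cts) {
      h <- hits[[cc]]
      i <- match(g, h$gene)
      if (!is.na(i) && h$strict[i]) strict_signs <- c(strict_signs, h$sign[i])
    }
    if (length(unique(strict_signs)) > 1) next
    sgn <- strict_signs[1]
    present <- vapply(cts, function(cc) {
      h <- hits[[cc]]
      i <- match(g, h$gene)
      !is.na(i) && h$relaxed[i] &&
        (!spec$direction_consistent || h$sign[i] == sgn)
    }, TRUE)
    rows[[g]] <- data.frame(
      gene = g, direction = if (sgn >= 0) "up" else "down",
      combo = paste(cts[present], collapse = "&"),
      stringsAsFactors = FALSE)
  }
  mem <- do.call(rbind, rows)
  rownames(mem) <- NULL
  if (is.null(mem)) {
    return(list(counts = data.frame(combo = character(),
                                    direction = character(), n = integer(),
                                    displayable = logical()),
                membership = mem))
  }
  agg <- aggregate(gene ~ combo + direction, data = mem, FUN = length)
  names(agg)[3] <- "n"
  agg$displayable <- agg$n > spec$min_intersection_display
  list(counts = agg[order(-agg$n), ], membership = mem)
}
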