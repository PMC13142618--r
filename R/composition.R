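# Subject-level compositional analysis: per-sample subpopulation counts,
# centred log-ratio transformation, condition comparisons (Mann-Whitney),
# Braak-stage profiles, abundance correlation structure and correlations
# against Lewy body pathology.

#' Per-sample subpopulation composition table
#'
#' Counts cells per sample (donor x region by default) and category
#' (cell class or subpopulation), optionally restricted to the
#' subpopulations of one parent cell class so that fractions are taken
#' within that class.
#'
#' @param annotations cell annotation table (as produced by
#'   \code{\link{generate_cohort}}).
#' @param level \code{"subpopulation"} or \code{"cell_class"}.
#' @param within optional parent cell class; only its cells enter counts
#'   and denominators.
#' @param sample_cols columns defining a sample.
#' @return A \code{composition_table}: list with integer \code{counts}
#'   (samples x categories), \code{proportions}, and \code{meta}
#'   (per-sample metadata: first value of donor, region, condition,
#'   Braak stage, sex present in the sample).
#' @export
sample_compositions <- function(annotations,
                                level = c("subpopulation", "cell_class"),
                                within = NULL,
                                sample_cols = c("donor_id", "region")) {
  level <- match.arg(level)
  if (!level %in% names(annotations))
    .stopf("annotations lack a '%s' column", level)
  ann <- annotations
  all_samples <- unique(do.call(paste, c(ann[sample_cols], sep = "|")))
  if (!is.null(within)) ann <- ann[ann$cell_class %in% within, , drop = FALSE]
  key <- do.call(paste, c(ann[sample_cols], sep = "|"))
  cats <- sort(unique(ann[[level]]))
  tab <- table(factor(key, levels = sort(all_samples)),
               factor(ann[[level]], levels = cats))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  totals <- rowSums(counts)
  if (any(totals == 0))
    .warnf("%d sample(s) have zero cells at this level; zero rows retained",
           sum(totals == 0))
  props <- counts / pmax(totals, 1)
  meta_cols <- intersect(c(sample_cols, "condition", "braak_stage", "sex"),
                         names(annotations))
  akey <- do.call(paste, c(annotations[sample_cols], sep = "|"))
  meta <- annotations[match(rownames(counts), akey), meta_cols, drop = FALSE]
  rownames(meta) <- rownames(counts)
  structure(list(counts = counts, proportions = props, meta = meta,
                 level = level, within = within),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table: %d samples x %d %s categories%s\n",
              nrow(x$counts), ncol(x$counts), x$level,
              if (is.null(x$within)) "" else
                paste0(" (within ", x$within, ")")))
  invisible(x)
}

#' Centred log-ratio transform
#'
#' \code{clr_ij = ln((c_ij + pc) / g_i)} where \code{g_i} is the geometric
#' mean of the pseudocounted counts in row \code{i}. Every output row sums
#' to zero; the pseudocount (default 1) keeps zero counts finite.
#'
#' @param table a \code{\link{composition_table}} or a non-negative
#'   samples-by-categories matrix.
#' @param pseudocount added to every count before the log.
#' @return matrix of CLR values, same shape as the input counts.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  counts <- if (inherits(table, "composition_table")) table$counts else
    as.matrix(table)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  lg <- log(counts + pseudocount)
  sweep(lg, 1, rowMeans(lg))
}

#' Compare CLR abundances between two conditions
#'
#' Two-sided Mann-Whitney U test per subpopulation on CLR values, with
#' Benjamini-Hochberg adjustment across subpopulations. Raw p-values are
#' kept alongside the adjusted ones.
#'
#' @param clr samples-by-subpopulations CLR matrix
#'   (\code{\link{clr_transform}}).
#' @param group_labels two-level factor/character vector over samples.
#' @return data.frame: subpopulation, U statistic, raw and BH-adjusted p,
#'   direction (sign of the first group's mean CLR minus the second's),
#'   group means.
#' @export
compare_conditions <- function(clr, group_labels) {
  groups <- unique(as.character(group_labels))
  if (length(groups) != 2) .stopf("exactly two groups are required")
  g1 <- group_labels == groups[1]
  g2 <- group_labels == groups[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    .stopf("each group needs at least 2 samples")
  res <- lapply(colnames(clr), function(sp) {
    x <- clr[g1, sp]; y <- clr[g2, sp]
    mw <- mann_whitney_u(x, y)
    data.frame(subpopulation = sp, U = mw$statistic, p = mw$p.value,
               mean_1 = mean(x), mean_2 = mean(y),
               direction = sign(mean(x) - mean(y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  attr(out, "groups") <- groups
  out
}

#' Braak-stage composition profile
#'
#' Mean subject-level CLR per Braak Lewy body stage. Stage cells backed
#' by fewer than \code{min_subjects} subjects are set to missing;
#' optionally each subpopulation's profile is z-scored across its
#' non-missing stages.
#'
#' @param clr subjects-by-subpopulations CLR matrix (one row per subject
#'   per region).
#' @param stages Braak stage (0-6) per row of \code{clr}.
#' @param min_subjects minimum subjects backing a stage summary.
#' @param zscore standardize each subpopulation across stages.
#' @return subpopulations-by-stages matrix (stages "0".."6" present in
#'   the data), \code{NA} where insufficiently backed.
#' @export
braak_stage_profile <- function(clr, stages, min_subjects = 2,
                                zscore = FALSE) {
  stopifnot(nrow(clr) == length(stages))
  lv <- sort(unique(stages))
  prof <- sapply(lv, function(s) {
    rows <- which(stages == s)
    if (length(rows) < min_subjects) return(rep(NA_real_, ncol(clr)))
    colMeans(clr[rows, , drop = FALSE])
  })
  prof <- matrix(prof, nrow = ncol(clr),
                 dimnames = list(colnames(clr), as.character(lv)))
  if (zscore) {
    prof <- t(apply(prof, 1, function(v) {
      ok <- !is.na(v)
      if (sum(ok) < 2) return(v)
      v[ok] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
      v
    }))
  }
  prof
}

#' Pairwise subpopulation abundance correlation
#'
#' Pearson correlation of subpopulation abundances (CLR values or
#' proportions) across samples; pairwise-complete over missing entries.
#' Zero-variance columns yield missing correlations with a warning.
#'
#' @param values samples-by-subpopulations numeric matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
abundance_correlation <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) .stopf("need at least 3 samples")
  sds <- apply(values, 2, stats::sd, na.rm = TRUE)
  zv <- which(!is.na(sds) & sds == 0)
  if (length(zv))
    .warnf("zero-variance column(s): %s; correlations set to NA",
           paste(colnames(values)[zv], collapse = ", "))
  suppressWarnings(r <- stats::cor(values, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r[zv, ] <- NA; r[, zv] <- NA
  diag(r)[zv] <- 1
  r
}

#' Correlate subpopulation abundance with Lewy body density
#'
#' Per region: donors contributing fewer than \code{min_cells} nuclei are
#' excluded, remaining counts are converted to proportions and
#' CLR-transformed, and each subpopulation's CLR abundance is rank-
#' correlated (Spearman) with the donor's regional LB density.
#'
#' @param composition a \code{\link{composition_table}} whose samples are
#'   donor x region (the default of \code{\link{sample_compositions}}).
#' @param lb_density data.frame with columns \code{donor_id},
#'   \code{region}, \code{lb_density}.
#' @param min_cells minimum nuclei per donor and region.
#' @return data.frame: region, subpopulation, rho, p, n_donors.
#' @export
pathology_correlation <- function(composition, lb_density, min_cells = 50) {
  stopifnot(inherits(composition, "composition_table"))
  meta <- composition$meta
  counts <- composition$counts
  out <- list()
  for (reg in unique(meta$region)) {
    rows <- which(meta$region == reg & rowSums(counts) >= min_cells)
    dens <- lb_density$lb_density[match(
      paste(meta$donor_id[rows], reg),
      paste(lb_density$donor_id, lb_density$region))]
    ok <- !is.na(dens)
    rows <- rows[ok]; dens <- dens[ok]
    if (length(rows) < 3)
      .stopf("fewer than 3 donors remain in region '%s' after filtering", reg)
    clr <- clr_transform(counts[rows, , drop = FALSE])
    for (sp in colnames(clr)) {
      ct <- suppressWarnings(
        stats::cor.test(clr[, sp], dens, method = "spearman"))
      out[[length(out) + 1L]] <- data.frame(
        region = reg, subpopulation = sp,
        rho = unname(ct$estimate), p = ct$p.value, n_donors = length(rows),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
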