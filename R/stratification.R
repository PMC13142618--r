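# Donor classification into multicellular program groups.
#
# Two rules, both with strict ">" comparisons so boundary equality falls
# to the lower branch:
#   * 3-way hierarchical astrocyte rule: UPR if the UPR-related
#     subpopulation exceeds 10% of the astrocyte composition (after
#     excluding ventricle-specific SVZCs from the denominator), else
#     Reactive if the reactive subpopulation exceeds 10%, else
#     Homeostatic.
#   * 4-way quadrant rule on per-donor fractions of UPR-like and M1-like
#     cells: Reactive / UPR-high / Homeostatic / Mixed.

#' Stratification rule
#'
#' @param primary_subpop subpopulation checked first (UPR-related).
#' @param secondary_subpop subpopulation checked second (reactive).
#' @param threshold abundance threshold (strict \code{>}).
#' @param excluded_subpops subpopulations removed from the denominator
#'   before fractions are computed.
#' @param labels labels for primary / secondary / neither.
#' @return A \code{stratification_rule} list.
#' @export
stratification_rule <- function(primary_subpop = "AR1",
                                secondary_subpop = "AR2",
                                threshold = 0.10,
                                excluded_subpops = "SVZC",
                                labels = c(primary = "UPR",
                                           secondary = "Reactive",
                                           neither = "Homeostatic")) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(excluded_subpops %in% c(primary_subpop, secondary_subpop)))
    .stopf("excluded_subpops must be disjoint from the rule subpopulations")
  structure(list(primary_subpop = primary_subpop,
                 secondary_subpop = secondary_subpop,
                 threshold = threshold,
                 excluded_subpops = excluded_subpops, labels = labels),
            class = "stratification_rule")
}

#' Hierarchical 3-way astrocyte stratification
#'
#' Applies the hierarchical thresholding rule to per-sample astrocyte
#' subtype compositions. Excluded subpopulations are removed from the
#' denominator first; samples with zero remaining cells are left
#' unassigned with a warning.
#'
#' @param composition a \code{\link{composition_table}} over astrocyte
#'   subtypes (e.g. \code{sample_compositions(ann, within = "Astrocytes")})
#'   or a samples-by-subtypes count/proportion matrix.
#' @param rule a \code{\link{stratification_rule}}.
#' @return data.frame: sample, label, and the evidence fractions of the
#'   rule subpopulations.
#' @export
astro_stratify <- function(composition, rule = stratification_rule()) {
  counts <- if (inherits(composition, "composition_table"))
    composition$counts else as.matrix(composition)
  keep <- setdiff(colnames(counts), rule$excluded_subpops)
  counts <- counts[, keep, drop = FALSE]
  denom <- rowSums(counts)
  f_pri <- if (rule$primary_subpop %in% keep)
    counts[, rule$primary_subpop] / pmax(denom, 1) else numeric(nrow(counts))
  f_sec <- if (rule$secondary_subpop %in% keep)
    counts[, rule$secondary_subpop] / pmax(denom, 1) else numeric(nrow(counts))
  label <- ifelse(f_pri > rule$threshold, rule$labels[["primary"]],
                  ifelse(f_sec > rule$threshold, rule$labels[["secondary"]],
                         rule$labels[["neither"]]))
  if (any(denom == 0)) {
    .warnf("%d sample(s) have no cells after exclusions; left unassigned",
           sum(denom == 0))
    label[denom == 0] <- NA_character_
  }
  data.frame(sample = rownames(counts), label = label,
             frac_primary = unname(f_pri), frac_secondary = unname(f_sec),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Four-way quadrant stratification
#'
#' Classifies donors by their fractions of M1-like and UPR-like cells:
#' Reactive (M1 fraction > threshold only), UPR-high (UPR fraction >
#' threshold only), Mixed (both), Homeostatic (neither). Comparisons are
#' strict.
#'
#' @param m1_frac,upr_frac per-donor fractions in [0, 1] (named vectors
#'   share donor ids).
#' @param threshold classification threshold.
#' @return data.frame: donor, label, and both evidence fractions.
#' @export
fourway_stratify <- function(m1_frac, upr_frac, threshold = 0.10) {
  stopifnot(length(m1_frac) == length(upr_frac),
            all(m1_frac >= 0 & m1_frac <= 1, na.rm = TRUE),
            all(upr_frac >= 0 & upr_frac <= 1, na.rm = TRUE))
  hi_m1 <- m1_frac > threshold
  hi_upr <- upr_frac > threshold
  label <- ifelse(hi_m1 & hi_upr, "Mixed",
                  ifelse(hi_m1, "Reactive",
                         ifelse(hi_upr, "UPR-high", "Homeostatic")))
  ids <- names(m1_frac)
  if (is.null(ids)) ids <- as.character(seq_along(m1_frac))
  data.frame(donor_id = ids, label = unname(label),
             m1_frac = unname(m1_frac), upr_frac = unname(upr_frac),
             stringsAsFactors = FALSE)
}

#' Fraction of donors with a mixed phenotype
#'
#' @param assignments data.frame with a \code{label} column (e.g. from
#'   \code{\link{fourway_stratify}}).
#' @return list with \code{rate} (exact fraction), \code{n_mixed} and
#'   \code{n_total}.
#' @export
mixed_rate <- function(assignments) {
  if (NROW(assignments) == 0) .stopf("no assignments provided")
  lab <- assignments$label
  lab <- lab[!is.na(lab)]
  list(rate = sum(lab == "Mixed") / length(lab),
       n_mixed = sum(lab == "Mixed"), n_total = length(lab))
}

#' Cross-region consistency of donor labels
#'
#' For donors profiled in several regions, computes the modal label and
#' the fraction of that donor's regions agreeing with it. Modal ties are
#' broken toward non-Homeostatic labels, then lexicographically; the
#' tie-break applied is recorded.
#'
#' @param assignments data.frame with columns \code{donor_id},
#'   \code{region}, \code{label}.
#' @return list with \code{per_donor} (donor, modal label, agreement,
#'   n_regions, tie flag) and \code{mean_agreement} over donors.
#' @export
cross_region_consistency <- function(assignments) {
  stopifnot(all(c("donor_id", "region", "label") %in% names(assignments)))
  if (max(table(assignments$donor_id)) < 2)
    .stopf("at least one donor must be profiled in 2+ regions")
  per <- lapply(split(assignments, assignments$donor_id), function(d) {
    tab <- table(d$label)
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1
    if (tie) {
      nh <- setdiff(top, "Homeostatic")
      top <- if (length(nh)) sort(nh)[1] else sort(top)[1]
    }
    data.frame(donor_id = d$donor_id[1], modal_label = top[1],
               agreement = max(tab) / nrow(d), n_regions = nrow(d),
               tie_broken = tie, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(per_donor = per, mean_agreement = mean(per$agreement))
}
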