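# Synthetic cohort generator.
#
# Emulates the statistical structure of a two-region PD/control striatum
# snRNA-seq cohort: donors nested in condition and Braak stage, glial
# subpopulations organised into multicellular programs (homeostatic / UPR /
# reactive / neutral), donor-group-dependent compositions drawn from a
# Dirichlet centred on the group mean, marker-gene programs, shared-
# dispersion negative-binomial counts, ambient contamination, and optional
# doublets. Ground-truth labels ride along so every downstream stage can be
# scored against what was planted.

default_subpops <- function() {
  data.frame(
    name = c("A0", "AR1", "AR2", "SVZC",
             "MH", "MH-HSP", "M1",
             "MOL", "PDAO"),
    cell_class = c(rep("Astrocytes", 4), rep("Microglia", 3),
                   rep("Oligodendrocytes", 2)),
    program = c("homeostatic", "UPR", "reactive", "neutral",
                "homeostatic", "UPR", "reactive",
                "homeostatic", "UPR"),
    stringsAsFactors = FALSE
  )
}

default_composition_means <- function() {
  # The two disease programs are planted mutually exclusive: a donor
  # group's reciprocal-program subpopulations sit far below the 10%
  # classification threshold relative to the Dirichlet donor noise.
  m <- rbind(
    UPR         = c(A0 = .235, AR1 = .12, AR2 = .005, SVZC = .04,
                    MH = .185, `MH-HSP` = .10, M1 = .005,
                    MOL = .21, PDAO = .10),
    Reactive    = c(A0 = .255, AR1 = .005, AR2 = .10, SVZC = .04,
                    MH = .185, `MH-HSP` = .005, M1 = .10,
                    MOL = .28, PDAO = .03),
    Homeostatic = c(A0 = .32, AR1 = .01, AR2 = .01, SVZC = .05,
                    MH = .26, `MH-HSP` = .015, M1 = .015,
                    MOL = .31, PDAO = .01)
  )
  colnames(m) <- default_subpops()$name
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a 30-donor desk-scale cohort: 10 donors per
#' multicellular program group (UPR-high, Reactive, Homeostatic), two
#' striatal regions per donor, 500 nuclei per donor, 1000 genes.
#' Compositions are drawn per donor from a Dirichlet centred on the
#' group's mean composition; group means place the program-defining
#' subpopulation fractions well clear of the 10% classification
#' threshold, mirroring the clear separation between programs.
#'
#' @param n_donors_per_group named integer vector, donors per program group.
#' @param subpops data.frame with columns \code{name}, \code{cell_class},
#'   \code{program} describing the simulated subpopulations.
#' @param composition_means group-by-subpopulation matrix of mean
#'   proportions; each row must lie on the simplex.
#' @param composition_concentration Dirichlet concentration (larger =
#'   less donor-to-donor compositional variability).
#' @param n_cells_per_donor scalar cell count per donor, or length-2 range
#'   sampled uniformly per donor.
#' @param n_genes number of genes.
#' @param n_markers_per_subpop,marker_lfc number of subpopulation marker
#'   genes and their log2 enrichment in the home subpopulation.
#' @param n_markers_per_class,class_marker_lfc same for cell-class markers
#'   (canonical class markers are near-exclusive, hence the larger default).
#' @param nb_dispersion shared negative-binomial dispersion (\code{size}
#'   parameter is \code{1/nb_dispersion}).
#' @param ambient_fraction fraction of each cell's counts redistributed
#'   proportionally to the pooled gene profile (ambient contamination).
#' @param doublet_rate default doublet rate used by the pipeline when it
#'   calls \code{\link{inject_doublets}}.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial.
#' @param mito_expr_share share of baseline expression carried by the
#'   mitochondrial genes.
#' @param target_umi mean library size per cell.
#' @param lib_sdlog log-normal sd of the per-cell library-size factor.
#' @param braak_assignment per-group probability vectors over Braak Lewy
#'   body stages 0-6.
#' @param condition_by_group per-group condition: a single label or a
#'   named probability vector over \code{c("PD","Control")}.
#' @param upr_male_only if TRUE, donors in the UPR group are all male.
#' @param regions region labels; each donor contributes cells to every
#'   region.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return A validated \code{cohort_config} object.
#' @export
cohort_config <- function(n_donors_per_group = c(UPR = 10, Reactive = 10,
                                                 Homeostatic = 10),
                          subpops = default_subpops(),
                          composition_means = default_composition_means(),
                          composition_concentration = 200,
                          n_cells_per_donor = 500,
                          n_genes = 1000,
                          n_markers_per_subpop = 10,
                          marker_lfc = 3,
                          n_markers_per_class = 20,
                          class_marker_lfc = 5,
                          nb_dispersion = 0.5,
                          ambient_fraction = 0.05,
                          doublet_rate = 0.05,
                          mito_gene_fraction = 0.01,
                          mito_expr_share = 0.02,
                          target_umi = 2000,
                          lib_sdlog = 0.3,
                          braak_assignment = list(
                            UPR         = c(0, .05, .10, .15, .20, .25, .25),
                            Reactive    = c(0, .10, .15, .25, .25, .15, .10),
                            Homeostatic = c(.25, .25, .20, .15, .10, .05, 0)),
                          condition_by_group = list(
                            UPR = "PD", Reactive = "PD",
                            Homeostatic = c(PD = 0.4, Control = 0.6)),
                          upr_male_only = TRUE,
                          regions = c("Pu", "CN"),
                          seed = 1L) {
  cfg <- list(n_donors_per_group = n_donors_per_group, subpops = subpops,
              composition_means = composition_means,
              composition_concentration = composition_concentration,
              n_cells_per_donor = n_cells_per_donor, n_genes = n_genes,
              n_markers_per_subpop = n_markers_per_subpop,
              marker_lfc = marker_lfc,
              n_markers_per_class = n_markers_per_class,
              class_marker_lfc = class_marker_lfc,
              nb_dispersion = nb_dispersion,
              ambient_fraction = ambient_fraction,
              doublet_rate = doublet_rate,
              mito_gene_fraction = mito_gene_fraction,
              mito_expr_share = mito_expr_share,
              target_umi = target_umi, lib_sdlog = lib_sdlog,
              braak_assignment = braak_assignment,
              condition_by_group = condition_by_group,
              upr_male_only = upr_male_only, regions = regions,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  groups <- names(cfg$n_donors_per_group)
  if (is.null(groups) || any(!groups %in% rownames(cfg$composition_means)))
    .stopf("composition_means must have one row per donor group")
  if (!setequal(colnames(cfg$composition_means), cfg$subpops$name))
    .stopf("composition_means columns must match subpops$name")
  cfg$composition_means <-
    cfg$composition_means[, cfg$subpops$name, drop = FALSE]
  if (any(cfg$composition_means < 0))
    .stopf("composition means must be non-negative")
  rs <- rowSums(cfg$composition_means)
  if (any(abs(rs - 1) > 1e-9))
    .stopf("each composition_means row must sum to 1 (got %s)",
           paste(format(rs), collapse = ", "))
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 0.5)
    .stopf("doublet_rate must be in [0, 0.5)")
  if (cfg$ambient_fraction < 0 || cfg$ambient_fraction >= 1)
    .stopf("ambient_fraction must be in [0, 1)")
  if (length(cfg$n_cells_per_donor) > 2 || any(cfg$n_cells_per_donor < 1))
    .stopf("n_cells_per_donor must be a positive scalar or range")
  min_cells <- min(cfg$n_cells_per_donor)
  exp_counts <- cfg$composition_means[groups, , drop = FALSE] * min_cells
  if (any(exp_counts > 0 & exp_counts < 1))
    .stopf(paste("config gives expected subpopulation counts < 1 cell;",
                 "increase n_cells_per_donor or composition means"))
  for (g in groups) {
    p <- cfg$braak_assignment[[g]]
    if (is.null(p) || length(p) != 7 || abs(sum(p) - 1) > 1e-9)
      .stopf("braak_assignment[['%s']] must be 7 probabilities over stages 0-6", g)
  }
  cfg
}

#' Sparse count matrix with cell/gene bookkeeping
#'
#' Light container pairing a sparse cells-by-genes integer count matrix
#' with its id lists and a per-gene mitochondrial flag.
#'
#' @param counts cells-by-genes matrix of non-negative integers.
#' @param gene_flags logical per-gene mitochondrial indicator.
#' @return A \code{count_matrix} object.
#' @export
count_matrix <- function(counts, gene_flags = NULL) {
  m <- as_count_matrix(counts)
  if (is.null(rownames(m)) && nrow(m) > 0)
    rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (is.null(colnames(m)) && ncol(m) > 0)
    colnames(m) <- paste0("gene", seq_len(ncol(m)))
  if (!is.null(gene_flags)) {
    stopifnot(is.logical(gene_flags), length(gene_flags) == ncol(m))
  }
  structure(list(counts = m, cell_ids = rownames(m), gene_ids = colnames(m),
                 gene_flags = gene_flags),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$gene_flags)) 0L else sum(x$gene_flags)))
  invisible(x)
}

# Accept a count_matrix or bare matrix everywhere.
cm_counts <- function(x) if (inherits(x, "count_matrix")) x$counts else
  as_count_matrix(x)
cm_flags <- function(x) if (inherits(x, "count_matrix")) x$gene_flags else NULL

# Per-subpopulation expected gene profiles (rows sum to 1).
build_profiles <- function(cfg, rel, markers) {
  sp <- cfg$subpops
  prof <- matrix(rel, nrow = nrow(sp), ncol = cfg$n_genes, byrow = TRUE,
                 dimnames = list(sp$name, names(rel)))
  for (i in seq_len(nrow(sp))) {
    cls <- sp$cell_class[i]
    prof[i, markers$class[[cls]]] <-
      prof[i, markers$class[[cls]]] * 2^cfg$class_marker_lfc
    prof[i, markers$subpop[[sp$name[i]]]] <-
      prof[i, markers$subpop[[sp$name[i]]]] * 2^cfg$marker_lfc
  }
  prof / rowSums(prof)
}

#' Generate a synthetic cohort
#'
#' Draws donors, per-donor compositions, cell annotations and a sparse
#' negative-binomial count matrix under the configured study structure.
#' Deterministic under a fixed \code{config$seed}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with elements \code{counts} (a \code{\link{count_matrix}}),
#'   \code{annotations} (one row per cell), \code{donors} (per-donor truth:
#'   group, condition, sex, Braak stage, planted composition), and
#'   \code{markers} (planted marker gene lists per class and subpopulation).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  G <- cfg$n_genes
  n_mito <- round(cfg$mito_gene_fraction * G)
  gene_ids <- sprintf("G%04d", seq_len(G))
  if (n_mito > 0) gene_ids[seq_len(n_mito)] <- sprintf("MT-%02d", seq_len(n_mito))
  mito <- seq_len(G) <= n_mito

  # baseline relative expression; mitochondrial genes pinned to their share
  rel <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
  names(rel) <- gene_ids
  if (n_mito > 0) {
    s <- cfg$mito_expr_share
    rel[mito] <- rel[mito] * (s / (1 - s)) * sum(rel[!mito]) / sum(rel[mito])
  }

  # disjoint marker gene assignments drawn from non-mitochondrial genes
  sp <- cfg$subpops
  classes <- unique(sp$cell_class)
  pool <- sample(gene_ids[!mito])
  need <- length(classes) * cfg$n_markers_per_class +
    nrow(sp) * cfg$n_markers_per_subpop
  if (need > length(pool)) .stopf("n_genes too small for the marker layout")
  markers <- list(class = list(), subpop = list())
  off <- 0L
  for (cls in classes) {
    markers$class[[cls]] <- pool[off + seq_len(cfg$n_markers_per_class)]
    off <- off + cfg$n_markers_per_class
  }
  for (s in sp$name) {
    markers$subpop[[s]] <- pool[off + seq_len(cfg$n_markers_per_subpop)]
    off <- off + cfg$n_markers_per_subpop
  }
  prof <- build_profiles(cfg, rel, markers)

  # donors
  groups <- rep(names(cfg$n_donors_per_group), cfg$n_donors_per_group)
  n_donor <- length(groups)
  donor_ids <- sprintf("D%02d", seq_len(n_donor))
  sexes <- vapply(groups, function(g) {
    if (g == "UPR" && isTRUE(cfg$upr_male_only)) "M" else sample(c("M", "F"), 1)
  }, "")
  braak <- vapply(groups, function(g)
    sample(0:6, 1, prob = cfg$braak_assignment[[g]]), 0L)
  cond <- vapply(groups, function(g) {
    cg <- cfg$condition_by_group[[g]]
    if (length(cg) == 1 && is.character(cg)) cg else
      sample(names(cg), 1, prob = cg)
  }, "")
  sexes <- unname(sexes); braak <- unname(braak); cond <- unname(cond)
  K <- nrow(sp)
  props <- t(vapply(seq_len(n_donor), function(i) {
    a <- cfg$composition_concentration *
      cfg$composition_means[groups[i], sp$name]
    x <- stats::rgamma(K, shape = a)
    x / sum(x)
  }, numeric(K)))
  colnames(props) <- sp$name

  # cells
  ncell_d <- if (length(cfg$n_cells_per_donor) == 2)
    sample(cfg$n_cells_per_donor[1]:cfg$n_cells_per_donor[2], n_donor,
           replace = TRUE) else rep(cfg$n_cells_per_donor, n_donor)
  ann <- do.call(rbind, lapply(seq_len(n_donor), function(i) {
    n <- ncell_d[i]
    subp <- sample(sp$name, n, replace = TRUE, prob = props[i, ])
    region <- rep(cfg$regions, length.out = n)
    data.frame(donor_id = donor_ids[i], region = region,
               condition = cond[i], braak_stage = braak[i], sex = sexes[i],
               cell_class = sp$cell_class[match(subp, sp$name)],
               subpopulation = subp, stringsAsFactors = FALSE)
  }))
  n <- nrow(ann)
  ann <- cbind(cell_id = sprintf("C%06d", seq_len(n)), ann,
               is_doublet_truth = FALSE,
               doublet_partner_class = NA_character_)
  libfac <- stats::rlnorm(n, meanlog = -cfg$lib_sdlog^2 / 2,
                          sdlog = cfg$lib_sdlog)

  # negative-binomial counts, drawn per subpopulation block
  size <- 1 / cfg$nb_dispersion
  ii <- jj <- xx <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(ann$subpopulation == sp$name[k])
    if (!length(idx)) next
    mu <- outer(libfac[idx] * cfg$target_umi, prof[k, ])
    cnt <- matrix(stats::rnbinom(length(mu), size = size, mu = as.vector(mu)),
                  nrow = length(idx))
    nz <- which(cnt > 0, arr.ind = TRUE)
    ii[[k]] <- idx[nz[, 1]]; jj[[k]] <- nz[, 2]; xx[[k]] <- cnt[nz]
  }
  counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                 x = unlist(xx), dims = c(n, G),
                                 dimnames = list(ann$cell_id, gene_ids))

  # ambient contamination: thin each cell, put removed mass back following
  # the pooled profile
  if (cfg$ambient_fraction > 0) {
    tot_before <- Matrix::rowSums(counts)
    counts@x <- as.double(stats::rbinom(length(counts@x), counts@x,
                                        1 - cfg$ambient_fraction))
    counts <- Matrix::drop0(counts)
    n_amb <- tot_before - Matrix::rowSums(counts)
    pooled <- rel / sum(rel)
    amb_gene <- sample.int(G, sum(n_amb), replace = TRUE, prob = pooled)
    amb_cell <- rep(seq_len(n), n_amb)
    counts <- counts + Matrix::sparseMatrix(i = amb_cell, j = amb_gene,
                                            x = 1, dims = c(n, G))
    dimnames(counts) <- list(ann$cell_id, gene_ids)
  }

  donors <- data.frame(donor_id = donor_ids, group = groups,
                       condition = cond, sex = sexes, braak_stage = braak,
                       n_cells = ncell_d, stringsAsFactors = FALSE)
  donors <- cbind(donors, as.data.frame(props))
  rownames(donors) <- NULL

  list(counts = count_matrix(counts, gene_flags = mito),
       annotations = ann, donors = donors, markers = markers)
}

#' Append synthetic doublets to a count matrix
#'
#' Forms \code{round(rate * n)} synthetic cells by summing the counts of
#' two sampled parent cells. A doublet is heterotypic when its parents
#' belong to different cell classes; truth columns are populated so the
#' quality-control layers can be scored.
#'
#' @param counts a \code{\link{count_matrix}} (or matrix).
#' @param annotations cell annotation table aligned with \code{counts}.
#' @param rate doublet rate in [0, 0.5).
#' @param seed integer seed.
#' @param heterotypic_only if TRUE, parents are forced to come from
#'   different cell classes.
#' @return list with the augmented \code{counts} and \code{annotations}.
#' @export
inject_doublets <- function(counts, annotations, rate, seed = 1L,
                            heterotypic_only = FALSE) {
  if (rate < 0 || rate >= 0.5) .stopf("doublet rate must be in [0, 0.5)")
  m <- cm_counts(counts)
  flags <- cm_flags(counts)
  n <- nrow(m)
  stopifnot(nrow(annotations) == n)
  n_doub <- round(rate * n)
  if (n_doub == 0)
    return(list(counts = count_matrix(m, flags), annotations = annotations))
  withr::with_seed(as.integer(seed), {
    p1 <- sample.int(n, n_doub, replace = TRUE)
    p2 <- sample.int(n, n_doub, replace = TRUE)
    for (i in seq_len(n_doub)) {
      while (p2[i] == p1[i] ||
             (heterotypic_only &&
              annotations$cell_class[p1[i]] == annotations$cell_class[p2[i]]))
        p2[i] <- sample.int(n, 1)
    }
  })
  dbl <- m[p1, , drop = FALSE] + m[p2, , drop = FALSE]
  rownames(dbl) <- sprintf("DBL%05d", seq_len(n_doub))
  add <- annotations[p1, , drop = FALSE]
  add$cell_id <- rownames(dbl)
  add$is_doublet_truth <- TRUE
  add$doublet_partner_class <- annotations$cell_class[p2]
  rownames(add) <- NULL
  ann_out <- rbind(annotations, add)
  attr(ann_out, "doublet_parents") <-
    data.frame(doublet = rownames(dbl),
               parent1 = annotations$cell_id[p1],
               parent2 = annotations$cell_id[p2],
               stringsAsFactors = FALSE)
  list(counts = count_matrix(rbind(m, dbl), flags),
       annotations = ann_out)
}
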