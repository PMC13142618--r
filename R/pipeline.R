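# End-to-end pipeline driver: simulate -> qc -> composition -> score ->
# deg -> stratify -> spatial, with per-stage outputs written as CSV files
# carrying a metadata comment header, and a JSON manifest.

#' Pipeline configuration
#'
#' Defaults run the full pipeline on the default synthetic cohort.
#' Quality-control count thresholds are scaled to the simulated
#' sequencing depth (the synthetic cohort has ~1000 genes and ~2000
#' UMIs per cell, so the deep-data gene floor would be meaningless
#' here); all other stage parameters are the package defaults.
#'
#' @param out_dir output directory.
#' @param seed global seed; every stage derives its own seeds from it.
#' @param stages named logical vector toggling stages.
#' @param cohort a \code{\link{cohort_config}}.
#' @param qc a \code{\link{qc_thresholds}}.
#' @param tiers a \code{\link{tier_thresholds}}.
#' @param overlap an \code{\link{overlap_spec}} for the three-way Venn.
#' @param rule a \code{\link{stratification_rule}}.
#' @param fourway_margin_z z-score margin for the per-cell microglial
#'   signature labels feeding the four-way donor rule. Stricter than the
#'   labeling default: donor fractions sit near the 10\% rule threshold,
#'   so bulk homeostatic cells must essentially never be mislabeled.
#' @param divergence_min_cells per-sample cell floor for the divergence
#'   matrix (scaled to the per-donor cell counts of the cohort).
#' @param n_spatial_samples spatial samples simulated per condition.
#' @param spatial_n_cells cells per spatial sample.
#' @param n_perm Moran permutations.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir = tempfile("glioprog_run_"),
                            seed = 1L,
                            stages = c(simulate = TRUE, qc = TRUE,
                                       composition = TRUE, score = TRUE,
                                       deg = TRUE, stratify = TRUE,
                                       spatial = TRUE),
                            cohort = cohort_config(),
                            qc = qc_thresholds(min_genes = 150,
                                               poly_residual_max = 200),
                            tiers = tier_thresholds(),
                            overlap = overlap_spec(),
                            rule = stratification_rule(),
                            fourway_margin_z = 1.5,
                            divergence_min_cells = 200,
                            n_spatial_samples = 2,
                            spatial_n_cells = 2000,
                            n_perm = 100) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, cohort = cohort, qc = qc, tiers = tiers,
                 overlap = overlap, rule = rule,
                 fourway_margin_z = fourway_margin_z,
                 divergence_min_cells = divergence_min_cells,
                 n_spatial_samples = n_spatial_samples,
                 spatial_n_cells = spatial_n_cells, n_perm = n_perm),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort and writes
#' every tabular output as CSV with a metadata header (package version,
#' seed, parameter hash), plus a JSON manifest listing outputs and stage
#' runtimes. Two runs with the same config produce byte-identical CSV
#' bodies.
#'
#' @param config a \code{\link{pipeline_config}}, or a path to a YAML
#'   file of arguments for it.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("reading YAML configs requires the yaml package")
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$outputs <- character()
  state$runtimes <- list()
  meta <- list(package = "glioprog",
               version = as.character(utils::packageVersion("glioprog")),
               seed = config$seed, params_hash = object_hash(config[
                 setdiff(names(config), "out_dir")]))
  emit <- function(df, name) {
    write_csv_meta(df, file.path(config$out_dir, name), meta)
    state$outputs <- c(state$outputs, name)
  }
  seeds <- derive_seeds(config$seed, 8)
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    state$runtimes[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  run_stage("simulate", function() {
    cc <- config$cohort
    cc$seed <- seeds[1]
    sim <- generate_cohort(cc)
    state$sim <- sim
    write_mtx_bundle(sim$counts, file.path(config$out_dir, "counts"))
    state$outputs <- c(state$outputs, "counts/matrix.mtx",
                       "counts/barcodes.tsv", "counts/features.tsv")
    emit(sim$annotations, "cells.csv")
    emit(sim$donors, "donors.csv")
    # donor-level pathology: LB density rises with Braak stage
    path <- withr::with_seed(seeds[1], do.call(rbind, lapply(
      seq_len(nrow(sim$donors)), function(i) data.frame(
        donor_id = sim$donors$donor_id[i], region = cc$regions,
        lb_density = round(exp(0.5 * sim$donors$braak_stage[i] +
                                 stats::rnorm(length(cc$regions), 0, 0.3)),
                           4)))))
    state$pathology <- path
    emit(path, "pathology.csv")
    jsonlite::write_json(
      list(markers = sim$markers,
           donor_groups = setNames(as.list(sim$donors$group),
                                   sim$donors$donor_id)),
      file.path(config$out_dir, "truth.json"), auto_unbox = TRUE)
    state$outputs <- c(state$outputs, "truth.json")
  })

  run_stage("qc", function() {
    sim <- state$sim
    m <- sim$counts$counts
    keep <- logical(nrow(m))
    qseeds <- derive_seeds(seeds[2], nrow(sim$donors))
    layer_tot <- c(consensus = 0L, basic = 0L, polynomial = 0L, gmm = 0L)
    for (i in seq_len(nrow(sim$donors))) {
      idx <- which(sim$annotations$donor_id == sim$donors$donor_id[i])
      rep_i <- run_qc(count_matrix(m[idx, , drop = FALSE],
                                   sim$counts$gene_flags),
                      marker_sets = sim$markers$class,
                      thresholds = config$qc, seed = qseeds[i])
      keep[idx] <- rep_i$keep
      layer_tot <- layer_tot + rep_i$removed_per_layer
    }
    state$keep <- keep
    emit(data.frame(layer = names(layer_tot),
                    removed = as.integer(layer_tot)), "qc_summary.csv")
    emit(data.frame(cell_id = sim$annotations$cell_id, keep = keep),
         "qc_keep.csv")
    state$lognorm <- lognormalize(m[keep, , drop = FALSE])
    state$ann <- sim$annotations[keep, , drop = FALSE]
  })

  run_stage("composition", function() {
    ann <- state$ann
    comp <- sample_compositions(ann, level = "subpopulation")
    state$comp <- comp
    emit(data.frame(sample = rownames(comp$counts), comp$counts,
                    check.names = FALSE), "composition.csv")
    clr <- clr_transform(comp)
    emit(data.frame(sample = rownames(clr), clr, check.names = FALSE),
         "clr.csv")
    tests <- do.call(rbind, lapply(unique(comp$meta$region), function(r) {
      rows <- comp$meta$region == r
      cond <- comp$meta$condition[rows]
      # a region needs both conditions with 2+ samples to be testable
      if (length(unique(cond)) != 2 || min(table(cond)) < 2) return(NULL)
      tt <- compare_conditions(clr[rows, , drop = FALSE], cond)
      cbind(region = r, tt)
    }))
    if (is.null(tests))
      tests <- data.frame(region = character(), subpopulation = character(),
                          U = numeric(), p = numeric(), p_adj = numeric())
    emit(tests, "composition_tests.csv")
    prof <- braak_stage_profile(clr, comp$meta$braak_stage)
    emit(data.frame(subpopulation = rownames(prof), prof,
                    check.names = FALSE), "braak_profile.csv")
    corr <- abundance_correlation(clr)
    emit(data.frame(subpopulation = rownames(corr), corr,
                    check.names = FALSE), "abundance_correlation.csv")
    pc <- pathology_correlation(comp, state$pathology, min_cells = 50)
    emit(pc, "pathology_correlation.csv")
  })

  run_stage("score", function() {
    sim <- state$sim
    ln <- state$lognorm
    ann <- state$ann
    sp <- config$cohort$subpops
    prog_sets <- lapply(split(sp$name, sp$program), function(nms)
      unique(unlist(sim$markers$subpop[nms])))
    disease_set <- unique(c(prog_sets$UPR, prog_sets$reactive))
    score <- module_score(ln, disease_set, seed = seeds[4])
    enr <- one_vs_rest_enrichment(score, ann$subpopulation)
    emit(enr, "enrichment.csv")
    sig <- cbind(UPR = module_score(ln, prog_sets$UPR, seed = seeds[4]),
                 Reactive = module_score(ln, prog_sets$reactive,
                                         seed = seeds[4] + 1))
    labels <- label_cells_by_signature(sig)
    state$sig_labels <- labels
    # class-restricted microglial signatures feed the four-way donor rule:
    # scores and z-scales are computed over microglia only, against the
    # UPR-microglia and M1 marker programs
    micro <- ann$cell_class == "Microglia"
    lnm <- ln[micro, , drop = FALSE]
    msig <- cbind(
      UPR = module_score(lnm, sim$markers$subpop[["MH-HSP"]],
                         seed = seeds[4] + 2),
      Reactive = module_score(lnm, sim$markers$subpop[["M1"]],
                              seed = seeds[4] + 3))
    state$micro_labels <- label_cells_by_signature(
      msig, margin_z = config$fourway_margin_z)
    state$micro_idx <- which(micro)
    emit(data.frame(cell_id = ann$cell_id, disease_score = round(score, 6),
                    upr_score = round(sig[, 1], 6),
                    reactive_score = round(sig[, 2], 6),
                    signature_label = labels), "scores.csv")
    dot <- expression_dot_summary(
      ln, utils::head(prog_sets$UPR, 12), ann$subpopulation)
    emit(dot, "dot_summary.csv")
  })

  run_stage("deg", function() {
    ln <- state$lognorm
    ann <- state$ann
    sim <- state$sim
    grp <- sim$donors$group[match(ann$donor_id, sim$donors$donor_id)]
    venn_rows <- list(); upset_rows <- list()
    for (cls in unique(ann$cell_class)) {
      tabs <- list()
      incls <- ann$cell_class == cls
      # PD vs Control (needs 3+ cells on both sides)
      sub <- incls & ann$condition %in% c("PD", "Control")
      if (min(table(factor(ann$condition[sub],
                           c("PD", "Control")))) >= 3)
        tabs$PD <- wilcoxon_de(ln[sub, , drop = FALSE], ann$condition[sub],
                               test_group = "PD")
      # donor-group contrasts exclude the reciprocal PD-associated group
      for (g in c("UPR", "Reactive")) {
        sub <- incls & grp %in% c(g, "Homeostatic")
        lab <- ifelse(grp[sub] == g, g, "Homeostatic")
        if (min(table(factor(lab, c(g, "Homeostatic")))) >= 3)
          tabs[[g]] <- wilcoxon_de(ln[sub, , drop = FALSE], lab,
                                   test_group = g)
      }
      for (nm in names(tabs)) {
        sig <- significant_degs(tabs[[nm]], config$tiers)
        emit(sig, sprintf("deg_%s_%s.csv", gsub("[^A-Za-z0-9]", "", cls),
                          nm))
      }
      if (length(tabs) == 3) {
        ov <- dual_threshold_overlap(tabs, config$overlap)
        if (!is.null(ov$membership))
          venn_rows[[cls]] <- cbind(cell_class = cls,
                                    ov$membership[c("gene", "region",
                                                    "sign")])
      }
      state$deg_tabs[[cls]] <- tabs
    }
    emit(if (length(venn_rows)) do.call(rbind, venn_rows) else
      data.frame(cell_class = character(), gene = character(),
                 region = character(), sign = numeric()),
      "venn_membership.csv")
    for (nm in c("PD", "UPR", "Reactive")) {
      per_ct <- Filter(Negate(is.null), lapply(state$deg_tabs, `[[`, nm))
      if (length(per_ct) < 2) next
      cx <- cross_celltype_intersections(per_ct)
      upset_rows[[nm]] <- if (nrow(cx$counts)) cbind(comparison = nm,
                                                     cx$counts) else NULL
    }
    emit(if (length(upset_rows)) do.call(rbind, upset_rows) else
      data.frame(), "upset_counts.csv")
  })

  run_stage("stratify", function() {
    ann <- state$ann
    sim <- state$sim
    astro <- sample_compositions(ann, level = "subpopulation",
                                 within = "Astrocytes")
    asg <- astro_stratify(astro, config$rule)
    asg$donor_id <- astro$meta$donor_id
    asg$region <- astro$meta$region
    emit(asg, "assignments_astro.csv")
    cons <- cross_region_consistency(asg)
    emit(cons$per_donor, "consistency.csv")
    # four-way rule on per-donor signature fractions of microglia
    lab <- state$micro_labels
    don <- ann$donor_id[state$micro_idx]
    frac <- function(l) vapply(split(lab, don),
                               function(v) mean(v == l), 0)
    fw <- fourway_stratify(frac("Reactive"), frac("UPR"))
    emit(fw, "assignments_fourway.csv")
    mr <- mixed_rate(fw)
    emit(data.frame(n_mixed = mr$n_mixed, n_total = mr$n_total,
                    rate = mr$rate), "mixed_rate.csv")
    emb <- pca_embed(state$lognorm)
    dv <- sample_divergence_matrix(emb, ann$donor_id,
                                   min_cells = config$divergence_min_cells)
    emit(data.frame(sample = rownames(dv$divergence),
                    round(dv$divergence, 6), check.names = FALSE),
         "divergence.csv")
  })

  run_stage("spatial", function() {
    sseeds <- derive_seeds(seeds[7], 2 * config$n_spatial_samples)
    samples <- list()
    for (i in seq_len(2 * config$n_spatial_samples)) {
      cond <- if (i <= config$n_spatial_samples) "PD" else "Control"
      samples[[i]] <- generate_spatial_sample(
        spatial_config(sample_id = sprintf("X%02d", i),
                       n_cells = config$spatial_n_cells,
                       condition = cond),
        seed = sseeds[i])
    }
    sc <- do.call(rbind, lapply(samples, function(s)
      cbind(sample_id = s$sample_id, s$cells,
            as.data.frame(s$panel_counts))))
    emit(sc, "spatial_cells.csv")
    svg <- per_sample_svg(samples, n_perm = config$n_perm,
                          seed = seeds[8])
    emit(svg$per_sample, "moran_per_sample.csv")
    emit(svg$aggregate, "moran_aggregate.csv")
    emit(svg$top, "moran_top.csv")
  })

  manifest <- list(package = meta$package, version = meta$version,
                   seed = config$seed, params_hash = meta$params_hash,
                   outputs = state$outputs, runtimes = state$runtimes)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
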