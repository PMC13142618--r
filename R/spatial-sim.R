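# Synthetic imaging spatial transcriptomics sample: a uniform point field
# over a rectangular section, partitioned into gray matter with white-matter
# bands, scattered vascular structures and an optional ventricle strip at
# one edge; a small targeted gene panel in which designated genes are
# expressed in spatially contiguous patches and the rest are
# position-independent.

#' Configuration for the spatial sample simulator
#'
#' Domain area targets default to the observed tissue makeup of striatal
#' sections (GM-dominant with interspersed WM bundles, sparse vasculature,
#' a ventricle strip at one edge).
#'
#' @param sample_id sample identifier.
#' @param n_cells number of cells.
#' @param width_um,height_um section extent in micrometres.
#' @param domain_props named area targets for \code{GM}, \code{WM},
#'   \code{Vascular}, \code{Ventricle}; normalized to sum to 1.
#' @param n_wm_bands number of vertical white-matter bands.
#' @param n_vascular_discs number of circular vascular structures.
#' @param n_panel_genes targeted panel size.
#' @param n_spatial_genes how many panel genes carry planted spatial
#'   structure (patches).
#' @param n_patches patches per spatial gene.
#' @param patch_radius_um patch radius.
#' @param rate_in,rate_out Poisson rate for a spatial gene inside /
#'   outside its patches.
#' @param base_rate Poisson rate for non-spatial panel genes.
#' @param condition condition label attached to the sample.
#' @return A \code{spatial_config} list.
#' @export
spatial_config <- function(sample_id = "S1", n_cells = 3000,
                           width_um = 2000, height_um = 2000,
                           domain_props = c(GM = 0.721, WM = 0.190,
                                            Vascular = 0.051,
                                            Ventricle = 0.028),
                           n_wm_bands = 3, n_vascular_discs = 15,
                           n_panel_genes = 30, n_spatial_genes = 5,
                           n_patches = 4, patch_radius_um = 300,
                           rate_in = 12, rate_out = 0.2, base_rate = 1,
                           condition = "PD") {
  domain_props <- domain_props / sum(domain_props)
  cfg <- list(sample_id = sample_id, n_cells = n_cells,
              width_um = width_um, height_um = height_um,
              domain_props = domain_props, n_wm_bands = n_wm_bands,
              n_vascular_discs = n_vascular_discs,
              n_panel_genes = n_panel_genes,
              n_spatial_genes = n_spatial_genes, n_patches = n_patches,
              patch_radius_um = patch_radius_um, rate_in = rate_in,
              rate_out = rate_out, base_rate = base_rate,
              condition = condition)
  if (cfg$n_spatial_genes > cfg$n_panel_genes)
    .stopf("n_spatial_genes cannot exceed n_panel_genes")
  if (cfg$n_cells < 3) .stopf("need at least 3 cells")
  class(cfg) <- "spatial_config"
  cfg
}

#' Generate a synthetic spatial sample
#'
#' @param config a \code{\link{spatial_config}}.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A \code{spatial_sample}: list with \code{sample_id},
#'   \code{condition}, \code{cells} (cell_id, x_um, y_um, domain),
#'   \code{panel_counts} (cells x panel genes) and
#'   \code{truth_spatial_genes}.
#' @export
generate_spatial_sample <- function(config, seed = 1L) {
  stopifnot(inherits(config, "spatial_config"))
  withr::with_seed(as.integer(seed), generate_spatial_sample_impl(config))
}

generate_spatial_sample_impl <- function(cfg) {
  W <- cfg$width_um; H <- cfg$height_um
  n <- cfg$n_cells
  x <- stats::runif(n, 0, W)
  y <- stats::runif(n, 0, H)

  # ventricle: strip at the left edge
  p <- cfg$domain_props
  vent_w <- p[["Ventricle"]] * W
  domain <- rep("GM", n)

  # white-matter bands: vertical stripes in the non-ventricle area
  band_total <- p[["WM"]] / (1 - p[["Ventricle"]]) * (W - vent_w)
  band_w <- band_total / cfg$n_wm_bands
  centers <- vent_w + (seq_len(cfg$n_wm_bands) - 0.5) *
    (W - vent_w) / cfg$n_wm_bands
  in_wm <- rep(FALSE, n)
  for (cx in centers)
    in_wm <- in_wm | (abs(x - cx) <= band_w / 2)
  domain[in_wm] <- "WM"

  # vascular structures: discs scattered over the non-ventricle area
  disc_r <- sqrt(p[["Vascular"]] * W * H / (cfg$n_vascular_discs * pi))
  vx <- stats::runif(cfg$n_vascular_discs, vent_w + disc_r, W - disc_r)
  vy <- stats::runif(cfg$n_vascular_discs, disc_r, H - disc_r)
  in_vasc <- rep(FALSE, n)
  for (d in seq_len(cfg$n_vascular_discs))
    in_vasc <- in_vasc | ((x - vx[d])^2 + (y - vy[d])^2 <= disc_r^2)
  domain[in_vasc] <- "Vascular"
  domain[x <= vent_w] <- "Ventricle"

  # panel counts
  Gp <- cfg$n_panel_genes
  gene_ids <- sprintf("PG%03d", seq_len(Gp))
  n_sp <- cfg$n_spatial_genes
  if (n_sp > 0) gene_ids[seq_len(n_sp)] <- sprintf("SPAT%02d", seq_len(n_sp))
  counts <- matrix(0L, nrow = n, ncol = Gp,
                   dimnames = list(sprintf("%s_c%05d", cfg$sample_id,
                                           seq_len(n)), gene_ids))
  for (g in seq_len(Gp)) {
    if (g <= n_sp) {
      px <- stats::runif(cfg$n_patches, 0, W)
      py <- stats::runif(cfg$n_patches, 0, H)
      inside <- rep(FALSE, n)
      for (q in seq_len(cfg$n_patches))
        inside <- inside |
          ((x - px[q])^2 + (y - py[q])^2 <= cfg$patch_radius_um^2)
      lam <- ifelse(inside, cfg$rate_in, cfg$rate_out)
    } else {
      lam <- rep(cfg$base_rate, n)
    }
    counts[, g] <- stats::rpois(n, lam)
  }

  structure(list(
    sample_id = cfg$sample_id, condition = cfg$condition,
    cells = data.frame(cell_id = rownames(counts), x_um = x, y_um = y,
                       domain = domain, stringsAsFactors = FALSE),
    panel_counts = counts,
    truth_spatial_genes = if (n_sp > 0) gene_ids[seq_len(n_sp)] else character()
  ), class = "spatial_sample")
}

#' @export
print.spatial_sample <- function(x, ...) {
  tab <- table(x$cells$domain)
  cat(sprintf("spatial_sample %s (%s): %d cells, %d panel genes\n",
              x$sample_id, x$condition, nrow(x$cells), ncol(x$panel_counts)))
  cat("  domains:", paste(sprintf("%s %.1f%%", names(tab),
                                  100 * tab / sum(tab)), collapse = ", "), "\n")
  invisible(x)
}
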