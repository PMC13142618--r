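make_lognorm <- function(m) lognormalize(m)

test_that("identical groups give flat fold changes and p = 1", {
  withr::with_seed(1, block <- matrix(rpois(5 * 40, 3), 5, 40))
  m <- rbind(block, block)
  colnames(m) <- paste0("g", 1:40)
  ln <- lognormalize(m)
  res <- wilcoxon_de(ln, rep(c("PD", "Control"), each = 5),
                     test_group = "PD")
  expect_true(all(res$p == 1))
  expect_true(all(res$lfc == 0))
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("the 4-vs-4 fully separated gene yields the exact 2/70 p-value", {
  m <- matrix(1, 8, 2, dimnames = list(NULL, c("sep", "noise")))
  m[, "sep"] <- c(5, 6, 7, 8, 1, 2, 3, 4)
  withr::with_seed(2, m[, "noise"] <- rpois(8, 4))
  # skip normalization: feed values directly as expression
  res <- wilcoxon_de(Matrix::Matrix(m, sparse = TRUE),
                     rep(c("A", "B"), each = 4), test_group = "A")
  expect_equal(res$p[res$gene == "sep"], 2 / 70)
  expect_error(wilcoxon_de(Matrix::Matrix(m, sparse = TRUE),
                           c("A", "A", rep("B", 6))), "at least 3")
})

test_that("rank p-values are invariant to monotone per-gene transforms", {
  withr::with_seed(3, m <- matrix(rpois(60 * 30, 2), 60, 30,
                                  dimnames = list(NULL, paste0("g", 1:30))))
  lab <- rep(c("A", "B"), 30)
  a <- wilcoxon_de(Matrix::Matrix(m, sparse = TRUE), lab, test_group = "A")
  b <- wilcoxon_de(Matrix::Matrix(sqrt(m), sparse = TRUE), lab,
                   test_group = "A")
  expect_equal(a$p, b$p)
  expect_false(isTRUE(all.equal(a$lfc, b$lfc)))
})

test_that("significance rule and tier boundaries follow the definitions", {
  tab <- data.frame(
    gene = paste0("g", 1:6),
    lfc = c(2.0, 0.9, 0.2, -1.5, 0.3, 3.0),
    p = 0.001, p_adj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2),
    pts = c(0.5, 0.5, 0.5, 0.5, 0.05, 0.5))
  res <- significant_degs(tab)
  expect_equal(res$gene, c("g1", "g2", "g4"))
  expect_equal(res$tier, c("Tier 1", "Tier 3", "Tier 2"))
})

test_that("tiers partition significant genes", {
  withr::with_seed(4, tab <- data.frame(
    gene = paste0("g", 1:500),
    lfc = rnorm(500, 0, 1.5),
    p = runif(500), p_adj = runif(500), pts = runif(500)))
  res <- significant_degs(tab)
  expect_true(all(res$p_adj < 0.05 & res$pts > 0.1 & abs(res$lfc) >= 0.25))
  expect_false(any(is.na(res$tier)))
  expect_equal(sum(table(res$tier)), nrow(res))
  # no significant gene below the Tier 4 floor
  expect_equal(nrow(res[abs(res$lfc) < 0.25, ]), 0)
})

test_that("clone-based and lncRNA identifiers are filtered, symbols kept", {
  ids <- c("AC012345.1", "ACTB", "LINC00507", "ALDH1L1", "AL627309.1",
           "AP006222.2", "AF127936.3", "APOE", "AFM", "ACE2", "LINCMD1")
  kept <- filter_noncoding(ids)
  expect_equal(kept, c("ACTB", "ALDH1L1", "APOE", "AFM", "ACE2"))
})

venn_fixture <- function() {
  # 30-gene toy across three comparisons with known strict/relaxed hits
  genes <- paste0("g", sprintf("%02d", 1:30))
  mk <- function(lfc, p_adj) data.frame(gene = genes, statistic = 0,
                                        lfc = lfc, p = p_adj,
                                        p_adj = p_adj, pts = 0.5,
                                        pts_rest = 0.5, direction = "up")
  withr::with_seed(9, {
    lfc_a <- round(rnorm(30, 0, 1.2), 2)
    lfc_b <- round(rnorm(30, 0, 1.2), 2)
    lfc_c <- round(rnorm(30, 0, 1.2), 2)
    p_a <- round(runif(30, 0, 0.1), 3)
    p_b <- round(runif(30, 0, 0.1), 3)
    p_c <- round(runif(30, 0, 0.1), 3)
  })
  list(PD = mk(lfc_a, p_a), UPR = mk(lfc_b, p_b), Reactive = mk(lfc_c, p_c))
}

# Independent set-arithmetic oracle for the dual-threshold Venn logic.
venn_oracle <- function(tabs, strict = 1, relaxed = 0.5, pmax = 0.05) {
  genes <- tabs[[1]]$gene
  strict_in <- sapply(tabs, function(t) abs(t$lfc) >= strict &
                        t$p_adj < pmax)
  relaxed_in <- sapply(tabs, function(t) abs(t$lfc) >= relaxed &
                         t$p_adj < pmax)
  signs <- sapply(tabs, function(t) sign(t$lfc))
  out <- list()
  for (i in seq_along(genes)) {
    sidx <- which(strict_in[i, ])
    if (!length(sidx)) next
    ss <- unique(signs[i, sidx])
    if (length(ss) > 1) next
    pres <- relaxed_in[i, ] & signs[i, ] == ss
    out[[genes[i]]] <- paste(names(tabs)[pres], collapse = "&")
  }
  unlist(out)
}

test_that("three-way Venn membership matches the exhaustive oracle", {
  tabs <- venn_fixture()
  res <- dual_threshold_overlap(tabs, apply_noncoding_filter = FALSE)
  oracle <- venn_oracle(tabs)
  expect_equal(nrow(res$membership), length(oracle))
  expect_equal(setNames(res$membership$region, res$membership$gene),
               oracle[res$membership$gene])
  # regions partition the universe
  expect_equal(sum(res$region_counts), nrow(res$membership))
  expect_false(any(duplicated(res$membership$gene)))
})

test_that("forced Venn cases behave per the dual-threshold rule", {
  mk <- function(lfc, p_adj = 0.01) data.frame(
    gene = "gX", statistic = 0, lfc = lfc, p = p_adj, p_adj = p_adj,
    pts = 0.5, pts_rest = 0.5, direction = "up")
  # strict in UPR, relaxed same-sign in PD -> UPR&PD region
  tabs <- list(PD = mk(0.6), UPR = mk(1.2), Reactive = mk(0.1))
  res <- dual_threshold_overlap(tabs, apply_noncoding_filter = FALSE)
  expect_equal(res$membership$region, "PD&UPR")
  # opposite sign in PD -> UPR-only
  tabs2 <- list(PD = mk(-0.8), UPR = mk(1.2), Reactive = mk(0.1))
  res2 <- dual_threshold_overlap(tabs2, apply_noncoding_filter = FALSE)
  expect_equal(res2$membership$region, "UPR")
  # sign conflict between two strict occurrences -> excluded, reported
  tabs3 <- list(PD = mk(-1.4), UPR = mk(1.2), Reactive = mk(0.1))
  res3 <- dual_threshold_overlap(tabs3, apply_noncoding_filter = FALSE)
  expect_null(res3$membership)
  expect_equal(res3$sign_conflicts, "gX")
})

test_that("cross-cell-type intersections match brute-force set arithmetic", {
  tabs <- venn_fixture()
  names(tabs) <- c("Astro", "Micro", "Oligo")
  spec <- overlap_spec(relaxed_lfc = 0.25)
  res <- cross_celltype_intersections(tabs, spec,
                                      apply_noncoding_filter = FALSE)
  oracle <- venn_oracle(tabs, strict = 1, relaxed = 0.25)
  expect_equal(nrow(res$membership), length(oracle))
  got <- setNames(res$membership$combo, res$membership$gene)
  expect_equal(got[names(oracle)], oracle)
  expect_equal(sum(res$counts$n), length(oracle))
  expect_equal(res$counts$displayable, res$counts$n > 10)
  # identical tables intersect fully
  same <- list(A = tabs[[1]], B = tabs[[1]])
  res2 <- cross_celltype_intersections(same, spec,
                                       apply_noncoding_filter = FALSE)
  expect_true(all(res2$membership$combo == "A&B"))
})
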