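# Fixed thresholds, polynomial residuals, consensus voting, GMM doublets.

make_cells <- function(umis, n_genes = 2000, mito_frac = 0) {
  # one row per requested UMI total, spread over many genes so the gene
  # floor is controlled separately via thresholds
  m <- t(vapply(seq_along(umis), function(i) {
    v <- rep(0, n_genes)
    mito_umi <- round(umis[i] * mito_frac[min(i, length(mito_frac))])
    body <- umis[i] - mito_umi
    k <- min(n_genes - 1, body)
    v[1 + seq_len(k)] <- diff(round(seq(0, body, length.out = k + 1)))
    v[1] <- mito_umi
    v
  }, numeric(n_genes)))
  count_matrix(m, gene_flags = c(TRUE, rep(FALSE, n_genes - 1)))
}

test_that("UMI bounds are inclusive: 499 fails, 500 passes", {
  cm <- make_cells(c(499, 500, 250000, 250001))
  thr <- qc_thresholds(min_genes = 1)
  expect_equal(basic_filters(cm, thr), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("mitochondrial fraction over 10% removes the nucleus", {
  cm <- make_cells(c(1000, 1000), mito_frac = c(0.11, 0.09))
  thr <- qc_thresholds(min_genes = 1)
  expect_equal(basic_filters(cm, thr), c(FALSE, TRUE))
})

test_that("basic filters handle an empty matrix and require mito flags", {
  empty <- count_matrix(matrix(0L, 0, 3), gene_flags = rep(FALSE, 3))
  expect_length(basic_filters(empty), 0)
  m <- matrix(1:6, 2, 3)
  expect_error(basic_filters(m, qc_thresholds()), "mitochondrial")
})

test_that("polynomial filter keeps exact-quadratic points and nails outliers", {
  withr::with_seed(1, u <- 10^runif(200, 2.8, 4.5))
  g <- 100 + 400 * log10(u) + 30 * log10(u)^2
  res <- polynomial_outlier_filter(u, g)
  expect_true(all(res$keep))
  expect_lt(max(abs(res$residuals)), 1e-6)
  g2 <- g
  g2[17] <- g2[17] + 3000
  res2 <- polynomial_outlier_filter(u, g2)
  expect_false(res2$keep[17])
  expect_equal(sum(!res2$keep), 1)
  # zero tolerance keeps only zero-residual points
  res3 <- polynomial_outlier_filter(u, g,
                                    qc_thresholds(poly_residual_max = 1e-6))
  expect_true(all(res3$keep))
  expect_error(polynomial_outlier_filter(u[1:3], g[1:3]), "at least")
})

test_that("consensus voting removes only persistently flagged cells", {
  cm <- toy_counts(20, 30)
  always_3 <- function(counts, seed) seq_len(nrow(counts)) == 3
  res <- consensus_doublet_filter(cm, always_3, seed = 1)
  expect_false(res$keep[3])
  expect_true(all(res$keep[-3]))
  expect_equal(res$flag_frac[3], 1)
  never <- function(counts, seed) rep(FALSE, nrow(counts))
  expect_true(all(consensus_doublet_filter(cm, never, seed = 1)$keep))
  bad <- function(counts, seed) TRUE
  expect_error(consensus_doublet_filter(cm, bad, seed = 1), "length")
})

test_that("a deterministic scorer yields the same mask for any seed", {
  cm <- toy_counts(15, 20)
  det <- function(counts, seed) Matrix::rowSums(counts) >
    median(Matrix::rowSums(counts))
  a <- consensus_doublet_filter(cm, det, seed = 1)
  b <- consensus_doublet_filter(cm, det, seed = 999)
  expect_identical(a$keep, b$keep)
})

test_that("random p=0.05 scorer removal matches the exact binomial tail", {
  n <- 2000
  cm <- count_matrix(matrix(1L, n, 4), gene_flags = rep(FALSE, 4))
  rs <- function(counts, seed)
    withr::with_seed(seed, runif(nrow(counts)) < 0.05)
  res <- consensus_doublet_filter(cm, rs, seed = 5)
  expected <- pbinom(10, 100, 0.05, lower.tail = FALSE)  # ~0.0115
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(!res$keep) - expected), 4 * mc_se)
})

test_that("marker scores reduce to means of the marker genes", {
  m <- Matrix::Matrix(0, 4, 3, sparse = TRUE,
                      dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(marker_score(m, list(A = c("a", "b")))[, 1]),
               rep(0, 4))
  m2 <- Matrix::Matrix(matrix(c(1, 2, 3, 4, 0, 0, 0, 0, 5, 5, 5, 5), 4, 3),
                       sparse = TRUE, dimnames = list(NULL, c("a", "b", "c")))
  sc <- marker_score(m2, list(A = "a", B = c("b", "c")))
  expect_equal(unname(sc[, "A"]), c(1, 2, 3, 4))
  expect_equal(unname(sc[, "B"]), rep(2.5, 4))
  expect_warning(marker_score(m2, list(A = c("a", "zz"))), "absent")
  expect_error(marker_score(m2, list(A = "zz")), "no marker genes")
})

test_that("GMM threshold recovers mu_low + 4 sd_low on a known mixture", {
  withr::with_seed(11, {
    x1 <- c(rnorm(1800, 0, 1), rnorm(200, 10, 1))
    x2 <- c(rnorm(1800, 0, 1), rnorm(200, 10, 1))
  })
  res <- gmm_heterotypic_filter(cbind(A = x1, B = x2))
  expect_true(all(res$thresholds > 3.5 & res$thresholds < 4.5))
})

test_that("exceeding one class threshold does not remove a nucleus", {
  withr::with_seed(12, {
    a <- c(rnorm(800, 0, 1), rnorm(100, 10, 1), rnorm(100, 0, 1))
    b <- c(rnorm(800, 0, 1), rnorm(100, 0, 1), rnorm(100, 10, 1))
  })
  sc <- cbind(A = a, B = b)
  res <- gmm_heterotypic_filter(sc)
  one_class <- res$n_classes_exceeded == 1
  expect_gt(sum(one_class), 0)
  expect_true(all(res$keep[one_class]))
  expect_true(all(!res$keep[res$n_classes_exceeded >= 2]))
})

test_that("planted heterotypic doublets are flagged; clean cells survive", {
  sim <- small_cohort(seed = 21, n_cells = 500, n_genes = 400)
  dbl <- inject_doublets(sim$counts, sim$annotations, rate = 0.05,
                         seed = 2, heterotypic_only = TRUE)
  sc <- marker_score(lognormalize(dbl$counts$counts), sim$markers$class)
  res <- gmm_heterotypic_filter(sc)
  truth <- dbl$annotations$is_doublet_truth
  expect_gte(mean(!res$keep[truth]), 0.9)
  expect_lte(mean(!res$keep[!truth]), 0.02)
})

test_that("blacklist filter drops cells expressing banned genes", {
  m <- matrix(c(0, 2, 0, 5, 5, 5), 3, 2,
              dimnames = list(NULL, c("NEUROD2", "ok")))
  expect_equal(blacklist_filter(m, "NEUROD2"), c(TRUE, FALSE, TRUE))
  expect_equal(blacklist_filter(m, "absent"), rep(TRUE, 3))
})
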