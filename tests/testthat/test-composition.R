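test_that("sample compositions count and normalize per sample", {
  ann <- data.frame(
    cell_id = paste0("c", 1:6),
    donor_id = c("D1", "D1", "D1", "D1", "D2", "D2"),
    region = "Pu",
    condition = "PD", braak_stage = 3, sex = "M",
    cell_class = c(rep("Astrocytes", 5), "Microglia"),
    subpopulation = c("A0", "A0", "A0", "AR1", "A0", "MH"))
  comp <- sample_compositions(ann)
  expect_equal(comp$counts["D1|Pu", c("A0", "AR1")], c(A0 = 3L, AR1 = 1L))
  expect_equal(comp$proportions["D1|Pu", c("A0", "AR1")],
               c(A0 = 0.75, AR1 = 0.25))
  # restriction to one parent class drops other classes from denominators
  within <- sample_compositions(ann, within = "Astrocytes")
  expect_false("MH" %in% colnames(within$counts))
  expect_equal(sum(within$counts["D2|Pu", ]), 1L)
  # a sample emptied by the restriction is retained as a zero row
  ann2 <- ann
  ann2$cell_class[5:6] <- "Microglia"
  ann2$subpopulation[5] <- "MH"
  expect_warning(w <- sample_compositions(ann2, within = "Astrocytes"),
                 "zero cells")
  expect_equal(sum(w$counts["D2|Pu", ]), 0L)
  expect_error(sample_compositions(ann, level = "nope"))
})

test_that("CLR matches the worked example and is zero-sum", {
  expect_equal(as.numeric(clr_transform(matrix(c(7, 1), 1, 2))),
               c(log(2), -log(2)))
  expect_equal(as.numeric(clr_transform(matrix(0, 1, 3))), rep(0, 3))
  withr::with_seed(1, m <- matrix(rpois(60, 8), 10, 6))
  clr <- clr_transform(m)
  expect_lt(max(abs(rowSums(clr))), 1e-9)
  expect_true(all(is.finite(clr)))
  # scale invariance holds without the pseudocount on positive rows
  clr0 <- clr_transform(m + 1, pseudocount = 0)
  clr0s <- clr_transform((m + 1) * 7, pseudocount = 0)
  expect_equal(clr0, clr0s, tolerance = 1e-12)
})

test_that("condition comparison reproduces exact rank-test cases", {
  clr <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                dimnames = list(NULL, "AR1"))
  res <- compare_conditions(clr, c("A", "A", "A", "B", "B", "B"))
  expect_equal(res$p, 0.1)
  expect_equal(res$U, 0)
  same <- matrix(rep(c(1, 2, 2, 3), 2), ncol = 1,
                 dimnames = list(NULL, "X"))
  res2 <- compare_conditions(same, rep(c("A", "B"), each = 4))
  expect_equal(res2$p, 1)
  expect_error(compare_conditions(clr, c("A", "B", "B", "B", "B", "B")),
               "at least 2")
})

test_that("a planted +1 CLR shift is detected with high power", {
  # baseline where AR1 is well populated (the UPR group mean, 12%); a
  # rare subpopulation's CLR carries irreducible log-count noise that no
  # sequencing depth removes
  hits <- 0
  reps <- 100
  mu <- default_composition_means()["UPR", ]
  for (r in seq_len(reps)) {
    counts <- withr::with_seed(r, t(vapply(1:30, function(i) {
      p <- rgamma(length(mu), 200 * mu)
      rmultinom(1, 500, p / sum(p))[, 1]
    }, numeric(length(mu)))))
    colnames(counts) <- names(mu)
    clr <- clr_transform(counts)
    clr[1:15, "AR1"] <- clr[1:15, "AR1"] + 1
    res <- compare_conditions(clr, rep(c("PD", "Control"), each = 15))
    if (res$p_adj[res$subpopulation == "AR1"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("condition comparison holds its size under the null", {
  rejections <- 0; tests <- 0
  mu <- default_composition_means()["Homeostatic", ]
  for (r in 1:200) {
    counts <- withr::with_seed(1000 + r, t(vapply(1:20, function(i) {
      p <- rgamma(length(mu), 200 * mu)
      rmultinom(1, 400, p / sum(p))[, 1]
    }, numeric(length(mu)))))
    colnames(counts) <- names(mu)
    res <- compare_conditions(clr_transform(counts),
                              rep(c("A", "B"), each = 10))
    rejections <- rejections + sum(res$p < 0.05)
    tests <- tests + nrow(res)
  }
  expect_lte(rejections / tests, 0.07)
})

test_that("Braak profiles honour the minimum-subject rule and z-scoring", {
  clr <- matrix(c(1, 2, 3, 4, 5,
                  5, 4, 3, 2, 1), ncol = 2,
                dimnames = list(NULL, c("A0", "AR1")))
  stages <- c(0, 0, 1, 1, 2)      # stage 2 has a single subject
  prof <- braak_stage_profile(clr, stages)
  expect_true(all(is.na(prof[, "2"])))
  expect_equal(prof["A0", "0"], 1.5)
  zp <- braak_stage_profile(clr, stages, zscore = TRUE)
  expect_equal(mean(zp["A0", c("0", "1")]), 0)
  expect_equal(sd(zp["A0", c("0", "1")]), 1)
  # a planted monotone decline survives stage averaging
  stages2 <- rep(0:4, each = 3)
  clr2 <- matrix(rep(seq(2, -2, length.out = 5), each = 3) +
                   withr::with_seed(4, rnorm(15, 0, 0.05)),
                 ncol = 1, dimnames = list(NULL, "A0"))
  prof2 <- braak_stage_profile(clr2, stages2)
  expect_true(all(diff(prof2["A0", ]) < 0))
})

test_that("abundance correlations are symmetric with unit diagonal", {
  withr::with_seed(2, v <- matrix(rnorm(40), 10, 4,
                                  dimnames = list(NULL, letters[1:4])))
  v <- cbind(v, dup = v[, 1])
  r <- abundance_correlation(v)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r["a", "dup"], 1)
  v2 <- cbind(v, flat = 1)
  expect_warning(r2 <- abundance_correlation(v2), "zero-variance")
  expect_true(all(is.na(r2["flat", colnames(v)])))
  expect_error(abundance_correlation(v[1:2, ]), "at least 3")
})

test_that("planted program covariance shows the expected sign structure", {
  sim <- generate_cohort(cohort_config(n_genes = 200,
                                       n_cells_per_donor = 400, seed = 31))
  comp <- sample_compositions(sim$annotations, sample_cols = "donor_id")
  clr <- clr_transform(comp)
  r <- abundance_correlation(clr)
  upr_block <- c("AR1", "MH-HSP", "PDAO")
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(r[upr_block[i], upr_block[j]], 0.5)
  expect_lt(r["AR1", "AR2"], 0)
  expect_lt(r["MH-HSP", "M1"], 0)
})

test_that("pathology correlations exclude thin donors and find monotone links", {
  ann <- do.call(rbind, lapply(1:6, function(i) data.frame(
    cell_id = paste0("c", i, "_", 1:80), donor_id = paste0("D", i),
    region = "Pu", condition = "PD", braak_stage = i, sex = "M",
    cell_class = "Astrocytes",
    subpopulation = rep(c("A0", "AR1"), c(80 - 8 * i, 8 * i)))))
  thin <- data.frame(cell_id = paste0("t", 1:30), donor_id = "D7",
                     region = "Pu", condition = "PD", braak_stage = 1,
                     sex = "M", cell_class = "Astrocytes",
                     subpopulation = "A0")
  comp <- sample_compositions(rbind(ann, thin), sample_cols = c("donor_id",
                                                                "region"))
  lb <- data.frame(donor_id = paste0("D", 1:7), region = "Pu",
                   lb_density = c(1:6, 100))
  res <- pathology_correlation(comp, lb, min_cells = 50)
  expect_false("D7" %in% ann$donor_id[res$n_donors])  # thin donor dropped
  expect_equal(unique(res$n_donors), 6)
  expect_equal(res$rho[res$subpopulation == "AR1"], 1)
  expect_error(pathology_correlation(comp, lb[1:2, ], min_cells = 50),
               "fewer than 3")
})
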