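test_that("hierarchical astrocyte rule follows order, strictness, exclusion", {
  counts <- rbind(
    s1 = c(A0 = 58, AR1 = 12, AR2 = 30, SVZC = 0),
    s2 = c(A0 = 81, AR1 = 10, AR2 = 9, SVZC = 0),    # exactly 10%: strict >
    s3 = c(A0 = 80, AR1 = 0, AR2 = 15, SVZC = 20))   # SVZC out: 15/95
  res <- astro_stratify(counts)
  expect_equal(res$label, c("UPR", "Homeostatic", "Reactive"))
  expect_equal(res$frac_secondary[3], 15 / 95)
  # unassigned empty sample
  counts2 <- rbind(counts, s4 = c(A0 = 0, AR1 = 0, AR2 = 0, SVZC = 5))
  expect_warning(res2 <- astro_stratify(counts2), "unassigned")
  expect_true(is.na(res2$label[4]))
  # invariance to column order
  res3 <- astro_stratify(counts[, c("SVZC", "AR2", "A0", "AR1")])
  expect_equal(res3$label, res$label)
})

test_that("four-way quadrant rule uses strict thresholds", {
  res <- fourway_stratify(m1_frac = c(0.25, 0.12, 0.10, 0.05),
                          upr_frac = c(0.05, 0.14, 0.10, 0.30))
  expect_equal(res$label, c("Reactive", "Mixed", "Homeostatic", "UPR-high"))
})

test_that("mixed rate is an exact fraction", {
  asg <- data.frame(label = c(rep("Reactive", 49), rep("UPR-high", 49),
                              rep("Mixed", 2)))
  mr <- mixed_rate(asg)
  expect_equal(mr$rate, 0.02)
  expect_equal(mr$n_mixed, 2L)
  expect_equal(mixed_rate(data.frame(label = rep("Homeostatic", 5)))$rate, 0)
  expect_error(mixed_rate(data.frame(label = character())), "no assignments")
})

test_that("cross-region consistency reports modal labels and agreement", {
  asg <- data.frame(
    donor_id = c(rep("D1", 5), rep("D2", 5)),
    region = paste0("R", c(1:5, 1:5)),
    label = c(rep("UPR", 5), c("UPR", "UPR", "UPR", "Homeostatic",
                               "Homeostatic")))
  res <- cross_region_consistency(asg)
  expect_equal(res$per_donor$agreement[res$per_donor$donor_id == "D1"], 1)
  d2 <- res$per_donor[res$per_donor$donor_id == "D2", ]
  expect_equal(d2$modal_label, "UPR")
  expect_equal(d2$agreement, 0.6)
  # ties break toward the non-homeostatic label
  tie <- data.frame(donor_id = "D3", region = c("R1", "R2"),
                    label = c("Homeostatic", "Reactive"))
  res2 <- cross_region_consistency(tie)
  expect_equal(res2$per_donor$modal_label, "Reactive")
  expect_true(res2$per_donor$tie_broken)
})

test_that("planted brain-wide programs give high cross-region agreement", {
  sim <- generate_cohort(cohort_config(n_genes = 200,
                                       n_cells_per_donor = 600, seed = 13))
  comp <- sample_compositions(sim$annotations, within = "Astrocytes")
  asg <- astro_stratify(comp)
  asg$donor_id <- comp$meta$donor_id
  asg$region <- comp$meta$region
  res <- cross_region_consistency(asg)
  expect_gte(res$mean_agreement, 0.9)
})

test_that("divergence matrix drops thin samples and is a pseudometric", {
  withr::with_seed(5, {
    coords <- rbind(matrix(rnorm(600 * 3), ncol = 3),
                    matrix(rnorm(600 * 3) + 2, ncol = 3),
                    matrix(rnorm(400 * 3), ncol = 3))
  })
  ids <- rep(c("A", "B", "thin"), c(600, 600, 400))
  res <- sample_divergence_matrix(coords, ids, k = 6, min_cells = 500)
  expect_equal(res$dropped, "thin")
  expect_equal(rownames(res$divergence), c("A", "B"))
  expect_equal(unname(diag(res$divergence)), c(0, 0))
  expect_equal(res$divergence, t(res$divergence))
  expect_true(all(res$divergence >= 0))
  expect_error(sample_divergence_matrix(coords, ids, k = 600,
                                        min_cells = 500), "k = 600")
})

test_that("divergence vanishes for same-distribution samples", {
  vals <- vapply(1:5, function(r) {
    withr::with_seed(100 + r, {
      p <- matrix(rnorm(1000 * 5), ncol = 5)
      q <- matrix(rnorm(1000 * 5), ncol = 5)
    })
    res <- sample_divergence_matrix(rbind(p, q),
                                    rep(c("a", "b"), each = 1000),
                                    k = 6, min_cells = 500)
    res$divergence["a", "b"]
  }, 0)
  expect_lt(max(abs(vals)), 0.2)
})

test_that("divergence grows monotonically with a Gaussian mean shift", {
  est <- vapply(c(0.5, 1, 2), function(mu) {
    withr::with_seed(7, {
      p <- matrix(rnorm(1000 * 5), ncol = 5)
      q <- matrix(rnorm(1000 * 5), ncol = 5)
    })
    q[, 1] <- q[, 1] + mu
    res <- sample_divergence_matrix(rbind(p, q),
                                    rep(c("a", "b"), each = 1000),
                                    k = 6, min_cells = 500)
    res$divergence["a", "b"]
  }, 0)
  expect_true(all(diff(est) > 0))
  # order of magnitude against the closed form mu^2/2
  expect_lt(abs(est[3] - 2), 1)
})

test_that("divergence separates planted donor groups in latent space", {
  sim <- generate_cohort(cohort_config(n_genes = 200,
                                       n_cells_per_donor = 600, seed = 17))
  ln <- lognormalize(sim$counts$counts)
  emb <- pca_embed(ln)
  res <- sample_divergence_matrix(emb, sim$annotations$donor_id, k = 6,
                                  min_cells = 300)
  grp <- sim$donors$group[match(rownames(res$divergence),
                                sim$donors$donor_id)]
  same <- outer(grp, grp, "==") & upper.tri(res$divergence)
  diff_ <- (!outer(grp, grp, "==")) & upper.tri(res$divergence)
  expect_lt(mean(res$divergence[same]), mean(res$divergence[diff_]))
})
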