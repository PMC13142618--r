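# Shared fixtures, all generated in code.

# A compact cohort: 2 donors per program group, 200 cells, 200 genes.
small_cohort <- function(seed = 1, n_cells = 200, n_genes = 200, ...) {
  generate_cohort(cohort_config(
    n_donors_per_group = c(UPR = 2, Reactive = 2, Homeostatic = 2),
    n_cells_per_donor = n_cells, n_genes = n_genes, seed = seed, ...))
}

# Deterministic dense toy count matrix with one mitochondrial gene.
toy_counts <- function(n_cells = 6, n_genes = 5, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes,
                dimnames = list(paste0("c", seq_len(n_cells)),
                                c("MT-01", paste0("g", seq_len(n_genes - 1)))))
    count_matrix(m, gene_flags = c(TRUE, rep(FALSE, n_genes - 1)))
  })
}

# Brute-force O(n^2) Moran's I, the independent oracle.
morans_i_bruteforce <- function(values, W, row_standardize = TRUE) {
  W <- as.matrix(W)
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Exhaustive two-sided Mann-Whitney p by enumeration of all group splits.
mw_bruteforce_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  ctr <- n1 * (N - n1) / 2
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(N, n1)
  U_all <- apply(splits, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  mean(abs(U_all - ctr) >= abs(U_obs - ctr) - 1e-9)
}
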