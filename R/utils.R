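#' @importFrom mclust Mclust mclustBIC
#' @importFrom Matrix rowSums colSums t sparseMatrix Diagonal drop0
#' @importFrom stats rnbinom rbinom rmultinom rlnorm runif rnorm rpois
#'   p.adjust quantile sd var cor cor.test prcomp lm coef predict
#'   complete.cases setNames aggregate rgamma
#' @importFrom utils head modifyList write.csv read.csv packageVersion
NULL

# Derive a stream of child seeds from one user seed without consuming the
# global RNG state. Keeps every derived seed inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce any matrix-like counts input to dgCMatrix, checking integrality.
as_count_matrix <- function(counts) {
  m <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (any(m@x < 0)) .stopf("counts must be non-negative")
  if (any(abs(m@x - round(m@x)) > 1e-8)) .stopf("counts must be integers")
  m
}

#' Library-size normalize and log-transform a count matrix
#'
#' Counts are scaled per cell to a common library size (counts-per-10k by
#' default) and transformed with \code{log1p}, the standard normalization
#' applied ahead of marker scoring, module scoring and rank-based
#' differential expression.
#'
#' @param counts sparse or dense cells-by-genes count matrix.
#' @param scale_factor target library size per cell (default 1e4).
#' @return A sparse cells-by-genes matrix of log-normalized expression.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  m <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  libs <- Matrix::rowSums(m)
  libs[libs == 0] <- 1
  out <- Matrix::Diagonal(x = scale_factor / libs) %*% m
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

# Stable hash of an R object (used to stamp parameter hashes into output
# metadata); md5 over the serialized deparse, via base tools.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
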