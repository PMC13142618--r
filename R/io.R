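# File formats: 10x-style MatrixMarket bundles (matrix.mtx + barcodes.tsv
# + features.tsv, optionally gzipped), GMT gene-set collections, and CSV
# outputs carrying a metadata comment header.

#' Read a 10x-style MatrixMarket bundle
#'
#' Expects \code{matrix.mtx}, \code{barcodes.tsv}, \code{features.tsv}
#' (each optionally \code{.gz}) in one directory. On-disk orientation is
#' normalized to cells x genes using the id-list lengths; a genuinely
#' ambiguous square matrix is taken as genes x cells (the 10x
#' convention). Non-integer entries or dimension mismatches are errors.
#'
#' @param dir bundle directory.
#' @return A \code{\link{count_matrix}}; mitochondrial genes are flagged
#'   by the conventional \code{MT-} prefix. Gene ids use the feature
#'   name column when present, else the id column.
#' @export
read_mtx_bundle <- function(dir) {
  find1 <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    .stopf("missing %s(.gz) in %s", base, dir)
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  barcodes <- readLines(find1("barcodes.tsv"))
  feats <- utils::read.delim(find1("features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  gene_ids <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  nb <- length(barcodes); ng <- length(gene_ids)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)                     # genes x cells on disk (10x)
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    .stopf("matrix is %d x %d but there are %d barcodes and %d features",
           nrow(m), ncol(m), nb, ng)
  }
  m <- methods::as(m, "CsparseMatrix")
  if (any(abs(m@x - round(m@x)) > 1e-8))
    .stopf("matrix contains non-integer entries")
  dimnames(m) <- list(barcodes, gene_ids)
  count_matrix(m, gene_flags = startsWith(gene_ids, "MT-"))
}

#' Write a 10x-style MatrixMarket bundle
#'
#' Writes \code{matrix.mtx} in genes x cells orientation with
#' \code{barcodes.tsv} and a 3-column \code{features.tsv} (id, name,
#' feature type).
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_mtx_bundle <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(counts$counts), file.path(dir, "matrix.mtx"))
  writeLines(counts$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(counts$gene_ids, counts$gene_ids, "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one set per line, tab-separated
#'   \code{name<TAB>description<TAB>gene...}.
#' @return named list of character gene vectors; descriptions kept in
#'   the \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, "", 2)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character gene vectors.
#' @param path output file.
#' @param descriptions optional per-set description column.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

# CSV writer with a machine-parsable metadata comment block before the
# single header row.
write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written with a metadata comment block
#'
#' @param path CSV file whose leading \code{#} lines carry metadata.
#' @return data.frame; metadata in the \code{"meta"} attribute.
#' @export
read_csv_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1L else length(lines)
  df <- utils::read.csv(text = paste(lines[(n_meta + 1):length(lines)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  meta <- list()
  for (l in lines[seq_len(n_meta)]) {
    kv <- sub("^# *", "", l)
    i <- regexpr(": ", kv, fixed = TRUE)
    if (i > 0) meta[[substr(kv, 1, i - 1)]] <- substr(kv, i + 2, nchar(kv))
  }
  attr(df, "meta") <- meta
  df
}
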