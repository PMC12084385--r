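#' Write a simulated bundle to disk
#'
#' Counts go out as Matrix Market MTX (genes x cells, 1-based indices) with
#' `genes.tsv` and `cells.tsv`, cell metadata as `meta.tsv`, and the ground
#' truth as `truth.json` plus a per-gene `gene_programs.tsv`.
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_mtx(bundle$counts, dir)
  utils::write.table(bundle$meta, file.path(dir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- bundle$truth
  utils::write.table(
    data.frame(gene = names(tr$gene_program), program = unname(tr$gene_program)),
    file.path(dir, "gene_programs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(t_true = as.list(tr$t_true), branch = as.list(tr$branch),
         cycling = as.list(tr$cycling), stage = as.list(tr$stage),
         regulons = tr$regulons,
         s_genes = tr$s_genes, g2m_genes = tr$g2m_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a genes x cells count matrix as MTX + TSV sidecars
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a genes x cells count matrix written by [write_counts_mtx()]
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return dense genes x cells matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "cells.tsv")))
  m
}

#' Read a signature gene list (one gene per line; blank lines and `#` comments
#' skipped)
#' @param path file path.
#' @return character vector of gene names.
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read regulon definitions
#'
#' Accepts either a two-column TSV (`tf`, `target`; header optional) or a JSON
#' object mapping TF names to target arrays. By convention a regulon's target
#' set includes the TF itself; the TF is added if absent.
#'
#' @param path `.tsv` or `.json` file.
#' @return named list: TF -> character vector of targets.
#' @export
read_regulons <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    regs <- jsonlite::read_json(path, simplifyVector = TRUE)
    regs <- lapply(regs, as.character)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, col.names = c("tf", "target"))
    if (identical(tolower(df$tf[1]), "tf")) df <- df[-1, , drop = FALSE]
    regs <- split(df$target, df$tf)
  }
  mapply(function(tf, tg) unique(c(tf, tg)), names(regs), regs,
         SIMPLIFY = FALSE)
}
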