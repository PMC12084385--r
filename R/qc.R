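# Row-wise sample variance without forming intermediate copies per gene.
.row_vars <- function(m, means = rowMeans(m)) {
  n <- ncol(m)
  (rowSums(m^2) - n * means^2) / (n - 1)
}

#' Quality-control thresholds
#'
#' All comparisons downstream are strict, following the conventions
#' `<10%` mitochondrial reads, `>1400` features, `>100,000` counts,
#' features in `>2` cells, cells with `>200` features. Contaminant rules flag
#' stromal (`Epcam < 2` counts) and salivary (`Dcpp1 > 1` counts) cells.
#'
#' @param min_cells_per_gene keep genes detected in more than this many cells.
#' @param min_features_basic keep cells with more than this many detected genes
#'   at the basic-filter stage.
#' @param max_mito_fraction remove cells at or above this mitochondrial
#'   fraction.
#' @param min_features remove cells at or below this many detected genes.
#' @param min_total_counts remove cells at or below this total count.
#' @param contaminant_rules list of `list(gene, comparator, threshold)` with
#'   comparator `"<"` or `">"`; a cell matching any rule is removed.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_cells_per_gene = 2L,
                          min_features_basic = 200L,
                          max_mito_fraction = 0.10,
                          min_features = 1400L,
                          min_total_counts = 1e5,
                          contaminant_rules = list(
                            list(gene = "Epcam", comparator = "<", threshold = 2),
                            list(gene = "Dcpp1", comparator = ">", threshold = 1)
                          )) {
  thr <- list(min_cells_per_gene = min_cells_per_gene,
              min_features_basic = min_features_basic,
              max_mito_fraction = max_mito_fraction,
              min_features = min_features,
              min_total_counts = min_total_counts,
              contaminant_rules = contaminant_rules)
  stopifnot(min_cells_per_gene >= 0, min_features_basic >= 0,
            max_mito_fraction >= 0, min_features >= 0, min_total_counts >= 0)
  for (r in thr$contaminant_rules) {
    if (!r$comparator %in% c("<", ">")) {
      stop("contaminant rule comparator must be '<' or '>'")
    }
  }
  structure(thr, class = "qc_thresholds")
}

#' Basic gene/cell detection filter
#'
#' Retains genes detected (count > 0) in strictly more than
#' `min_cells_per_gene` cells, then cells with strictly more than
#' `min_features_basic` detected genes among the retained genes. Row/column
#' order is preserved.
#'
#' @param raw genes x cells integer count matrix.
#' @param thresholds a [qc_thresholds()] object.
#' @return filtered count matrix, with attribute `removed` listing counts of
#'   dropped genes and cells.
#' @export
basic_gene_cell_filter <- function(raw, thresholds = qc_thresholds()) {
  stopifnot(all(raw >= 0))
  keep_genes <- rowSums(raw > 0) > thresholds$min_cells_per_gene
  m <- raw[keep_genes, , drop = FALSE]
  keep_cells <- colSums(m > 0) > thresholds$min_features_basic
  out <- m[, keep_cells, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L) {
    stop("basic filter removed everything (", sum(!keep_genes), " genes, ",
         sum(!keep_cells), " cells dropped)")
  }
  attr(out, "removed") <- c(genes = sum(!keep_genes), cells = sum(!keep_cells))
  out
}

#' Cell-level quality filter on mitochondrial fraction, features and depth
#'
#' Removes cells unless mitochondrial fraction < `max_mito_fraction`, detected
#' genes > `min_features` and total counts > `min_total_counts` (all strict).
#' Mitochondrial genes are found by the case-insensitive `mt-` name prefix
#' unless a gene list is supplied.
#'
#' @param m genes x cells count matrix.
#' @param mito_genes optional character vector of mitochondrial gene names.
#' @param thresholds a [qc_thresholds()] object.
#' @return filtered matrix with attribute `qc_report`: a per-cell data.frame of
#'   mito fraction, feature count, total count and pass flags.
#' @export
qc_cell_filter <- function(m, mito_genes = NULL, thresholds = qc_thresholds()) {
  if (is.null(mito_genes)) {
    mito_genes <- rownames(m)[grepl("^mt-", rownames(m), ignore.case = TRUE)]
  } else {
    mito_genes <- intersect(mito_genes, rownames(m))
  }
  total <- colSums(m)
  if (length(mito_genes) == 0L) {
    warning("no mitochondrial genes found; mito criterion treated as pass")
    mito_frac <- rep(0, ncol(m))
  } else {
    mito_frac <- colSums(m[mito_genes, , drop = FALSE]) / total
  }
  n_feat <- colSums(m > 0)
  report <- data.frame(
    cell = colnames(m), mito_fraction = mito_frac, n_features = n_feat,
    total_counts = total,
    pass_mito = mito_frac < thresholds$max_mito_fraction,
    pass_features = n_feat > thresholds$min_features,
    pass_counts = total > thresholds$min_total_counts,
    row.names = NULL, stringsAsFactors = FALSE
  )
  report$pass <- report$pass_mito & report$pass_features & report$pass_counts
  out <- m[, report$pass, drop = FALSE]
  if (ncol(out) == 0L) stop("QC filter removed all cells")
  attr(out, "qc_report") <- report
  out
}

#' Remove contaminant cell types by per-gene count rules
#'
#' A cell matching any rule (e.g. stromal `Epcam < 2`, salivary `Dcpp1 > 1`,
#' strict comparisons on raw counts) is removed. Rules whose gene is absent
#' are skipped with a warning.
#'
#' @param m genes x cells count matrix.
#' @param rules list of `list(gene, comparator, threshold)`.
#' @return filtered matrix with attribute `removed` (number of cells dropped).
#' @export
contaminant_filter <- function(m, rules = qc_thresholds()$contaminant_rules) {
  flagged <- rep(FALSE, ncol(m))
  for (r in rules) {
    if (!r$gene %in% rownames(m)) {
      warning("contaminant rule gene not found, skipping: ", r$gene)
      next
    }
    x <- m[r$gene, ]
    flagged <- flagged | if (r$comparator == "<") x < r$threshold else x > r$threshold
  }
  out <- m[, !flagged, drop = FALSE]
  attr(out, "removed") <- sum(flagged)
  out
}

#' Log-normalize counts
#'
#' `value = ln(1 + count / cell_total * scale_factor)`, the standard
#' log-normalization for full-length single-cell data.
#'
#' @param m genes x cells count matrix; all per-cell totals must be positive.
#' @param scale_factor target per-cell total after scaling (default 1e4).
#' @return genes x cells matrix of normalized values with attribute
#'   `scale_factor`; zeros map exactly to zeros.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  total <- colSums(m)
  if (any(total == 0)) {
    stop("zero-total cell(s): ",
         paste(colnames(m)[total == 0], collapse = ", "))
  }
  out <- log1p(sweep(m, 2, total, "/") * scale_factor)
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Select highly variable genes by trend-standardized variance
#'
#' The "vst" convention: per-gene variance of raw counts is standardized
#' against a loess trend of log10(variance) on log10(mean); standardized
#' values are clipped at sqrt(n_cells) before recomputing the variance, and
#' genes are ranked by that clipped standardized variance.
#'
#' @param counts genes x cells raw count matrix.
#' @param n number of genes to return.
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of the top `n` gene names in decreasing rank order.
#' @export
select_hvg <- function(counts, n = 2000L, loess_span = 0.3) {
  if (n > nrow(counts)) {
    stop("requested ", n, " variable genes but only ", nrow(counts), " available")
  }
  mu <- rowMeans(counts)
  v <- .row_vars(counts, mu)
  fit_on <- which(v > 0 & mu > 0)
  std_var <- stats::setNames(rep(0, nrow(counts)), rownames(counts))
  if (length(fit_on) >= 2L) {
    fit <- tryCatch(
      stats::loess(log10(v[fit_on]) ~ log10(mu[fit_on]), span = loess_span),
      error = function(e)
        stats::loess(log10(v[fit_on]) ~ log10(mu[fit_on]), span = 1))
    exp_sd <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(ncol(counts))
    for (idx in seq_along(fit_on)) {
      g <- fit_on[idx]
      z <- pmin((counts[g, ] - mu[g]) / exp_sd[idx], clip)
      std_var[g] <- stats::var(z)
    }
  }
  names(sort(std_var, decreasing = TRUE))[seq_len(n)]
}

#' Center and unit-scale genes, clipping extreme positive values
#'
#' Per-gene z-scores across cells (mean 0, sd 1), with values clipped at
#' `clip_max` to bound the influence of outlier cells. Zero-variance genes are
#' set to all zeros with a warning.
#'
#' @param norm genes x cells normalized matrix.
#' @param genes genes to scale (default all).
#' @param clip_max upper clip value (default 10).
#' @return genes x cells scaled matrix over `genes`.
#' @export
scale_features <- function(norm, genes = rownames(norm), clip_max = 10) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) stop("genes not in matrix: ", paste(missing, collapse = ", "))
  m <- norm[genes, , drop = FALSE]
  mu <- rowMeans(m)
  sd_g <- sqrt(.row_vars(m, mu))
  zero <- sd_g == 0 | is.na(sd_g)
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) scaled to all zeros")
    sd_g[zero] <- 1
  }
  out <- (m - mu) / sd_g
  out[zero, ] <- 0
  pmin(out, clip_max)
}
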