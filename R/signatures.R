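#' Marker discovery by single-gene classifier AUC
#'
#' For each gene, the AUC of the single-gene classifier separating the target
#' cluster from the rest, computed from the rank-sum statistic
#' `AUC = U / (n_in * n_out)`; together with the log2 fold change
#' (`log2(mean(expm1(x)) + 1)` difference, the convention for log-normalized
#' data) and the fractions of expressing cells inside and outside the target.
#' With `only_pos`, genes must be expressed in at least `min_pct` of target
#' cells and have positive fold change. Rows are ordered by decreasing log2
#' fold change, the ordering used to report top markers.
#'
#' @param norm genes x cells normalized matrix.
#' @param labels per-cell cluster labels.
#' @param target_cluster cluster to contrast against all others, or `NULL` to
#'   run every cluster (a `cluster` column distinguishes them).
#' @param min_pct minimum expressing fraction in the target (default 0.40).
#' @param only_pos keep positive markers only (default TRUE).
#' @return data.frame with columns `gene`, `cluster`, `auc`,
#'   `log2_fold_change`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(norm, labels, target_cluster = NULL,
                         min_pct = 0.40, only_pos = TRUE) {
  labels <- as.factor(labels)
  targets <- if (is.null(target_cluster)) levels(droplevels(labels)) else target_cluster
  out <- lapply(targets, function(cl) {
    inb <- labels == cl
    n_in <- sum(inb)
    n_out <- sum(!inb)
    if (n_in < 2L || n_out < 2L) {
      stop("need at least 2 cells inside and outside cluster ", cl)
    }
    auc <- apply(norm, 1, function(x) {
      r <- rank(x)
      (sum(r[inb]) - n_in * (n_in + 1) / 2) / (n_in * n_out)
    })
    mean_in <- rowMeans(expm1(norm[, inb, drop = FALSE]))
    mean_out <- rowMeans(expm1(norm[, !inb, drop = FALSE]))
    df <- data.frame(
      gene = rownames(norm), cluster = cl, auc = auc,
      log2_fold_change = log2(mean_in + 1) - log2(mean_out + 1),
      pct_in = rowMeans(norm[, inb, drop = FALSE] > 0),
      pct_out = rowMeans(norm[, !inb, drop = FALSE] > 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
    if (only_pos) {
      df <- df[df$pct_in >= min_pct & df$log2_fold_change > 0, , drop = FALSE]
    }
    df[order(df$log2_fold_change, decreasing = TRUE), , drop = FALSE]
  })
  do.call(rbind, out)
}

#' Gene-set module score with expression-matched controls
#'
#' Mean expression of the gene set minus the mean expression of control genes
#' drawn, for each set gene, from the same average-expression bin (`n_bins`
#' equal-frequency bins over all genes; `n_ctrl` controls per set gene,
#' sampled with a fixed seed). A positive score means the set is expressed
#' above expectation for genes of comparable abundance.
#'
#' @param norm genes x cells normalized matrix.
#' @param gene_set character vector; genes absent from `norm` are dropped with
#'   a warning.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return named per-cell numeric vector.
#' @export
module_score <- function(norm, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 42L) {
  present <- intersect(gene_set, rownames(norm))
  if (length(present) == 0L) stop("no genes of the set are present in the matrix")
  if (length(present) < length(gene_set)) {
    warning(length(gene_set) - length(present), " gene(s) of the set missing, dropped")
  }
  avg <- rowMeans(norm)
  if (n_bins > nrow(norm)) {
    warning("more bins than genes; reducing to ", nrow(norm))
    n_bins <- nrow(norm)
  }
  # Equal-frequency binning on the rank of average expression; ranks make the
  # bins well-defined under ties.
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(norm) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  names(bin) <- rownames(norm)
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
  }))
  score <- colMeans(norm[present, , drop = FALSE]) -
    colMeans(norm[ctrl, , drop = FALSE])
  stats::setNames(score, colnames(norm))
}

#' Combined luminal score from ER-positive and ER-negative signatures
#'
#' The two luminal signatures are combined by set union before a single
#' module score is computed.
#'
#' @inheritParams module_score
#' @param lum_er_pos_set,lum_er_neg_set the two luminal signatures.
#' @return named per-cell numeric vector.
#' @export
combined_luminal_score <- function(norm, lum_er_pos_set, lum_er_neg_set, ...) {
  a <- intersect(lum_er_pos_set, rownames(norm))
  b <- intersect(lum_er_neg_set, rownames(norm))
  if (length(a) == 0L && length(b) == 0L) {
    stop("both luminal signatures are empty after intersection with the matrix")
  }
  if (length(a) == 0L || length(b) == 0L) {
    warning("one luminal signature is empty after filtering; ",
            "score equals the other signature's module score")
  }
  module_score(norm, union(lum_er_pos_set, lum_er_neg_set), ...)
}

#' Huber robust simple linear regression by IRLS
#'
#' M-estimation of `y ~ x` with the Huber psi, tuning constant
#' `c = 1.345 x robust scale`, where the scale is re-estimated each iteration
#' as `MAD(residuals) = median(|r|) / 0.6745`. Iteratively reweighted least
#' squares runs until the largest coefficient change is below `tol` or
#' `max_iter` is reached.
#'
#' @param x,y numeric vectors; `x` must not be constant.
#' @param tol convergence tolerance on coefficients (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 50).
#' @return a `robust_fit` list: `slope`, `intercept`, `residuals`, `weights`,
#'   `n_iterations`, `converged`, `scale`.
#' @export
robust_linear_fit <- function(x, y, tol = 1e-8, max_iter = 50L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is constant; robust fit undefined")
  c_tune <- 1.345
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  w <- rep(1, length(x))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - X %*% beta
    s <- stats::median(abs(r)) / 0.6745
    if (s < .Machine$double.eps^0.5) {
      w <- rep(1, length(x))
      converged <- TRUE
      break
    }
    w <- pmin(1, c_tune * s / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    fit <- stats::lm.wfit(X, y, as.vector(w))
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("IRLS did not converge in ", max_iter, " iterations")
  r <- as.vector(y - X %*% beta)
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 residuals = r, weights = as.vector(w),
                 n_iterations = iter, converged = converged,
                 scale = stats::median(abs(r)) / 0.6745),
            class = "robust_fit")
}

#' Adjusted marker-proportion score
#'
#' The hybrid-state score: for each marker gene the threshold is its median
#' normalized expression across all cells; a cell's raw score is the fraction
#' of markers it expresses strictly above their thresholds. Because this
#' proportion is confounded by transcriptome complexity, the raw score is
#' residualized against the per-cell detected-gene count by Huber robust
#' regression and re-centered at the raw-score mean, so the adjusted score
#' stays on the interpretable \[~0, 1\] proportion scale.
#'
#' @param norm genes x cells normalized matrix.
#' @param marker_set marker genes (typically a cluster's top 50 AUC markers);
#'   missing genes are dropped with a warning and shrink the denominator.
#' @param complexity per-cell detected-gene counts; computed from `norm > 0`
#'   when `NULL`.
#' @param pooled_threshold if TRUE, a single pooled median over all marker
#'   expression values is used instead of per-gene medians.
#' @return data.frame with per-cell `raw`, `adjusted`, `complexity`, plus the
#'   `robust_fit` as attribute `fit`.
#' @export
adjusted_proportion_score <- function(norm, marker_set, complexity = NULL,
                                      pooled_threshold = FALSE) {
  present <- intersect(marker_set, rownames(norm))
  if (length(present) == 0L) stop("no marker genes present in the matrix")
  if (length(present) < length(marker_set)) {
    warning(length(marker_set) - length(present), " marker(s) missing, dropped")
  }
  m <- norm[present, , drop = FALSE]
  if (pooled_threshold) {
    thr <- rep(stats::median(m), length(present))
  } else {
    thr <- apply(m, 1, stats::median)
  }
  raw <- colMeans(m > thr)
  if (is.null(complexity)) complexity <- colSums(norm > 0)
  fit <- robust_linear_fit(complexity, raw)
  adjusted <- fit$residuals + mean(raw)
  out <- data.frame(cell = colnames(norm), raw = unname(raw),
                    adjusted = unname(adjusted),
                    complexity = unname(complexity),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "n_markers") <- length(present)
  out
}

#' Cell-cycle scores and phase call
#'
#' S and G2M module scores ([module_score()]); a cell is called `G1` when both
#' scores are negative, otherwise the phase with the larger score.
#'
#' @param norm genes x cells normalized matrix.
#' @param s_genes,g2m_genes phase signatures.
#' @param seed RNG seed for control sampling.
#' @param ... passed to [module_score()].
#' @return data.frame with per-cell `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_scores <- function(norm, s_genes, g2m_genes, seed = 42L, ...) {
  s <- module_score(norm, s_genes, seed = seed, ...)
  g2m <- module_score(norm, g2m_genes, seed = seed + 1L, ...)
  phase <- ifelse(s < 0 & g2m < 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(cell = colnames(norm), s_score = unname(s),
             g2m_score = unname(g2m), phase = unname(phase),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select cells inside a rectangle of the embedding
#'
#' The programmatic equivalent of drawing a rectangle on the UMAP to pick a
#' region (e.g. the high-cell-cycle proliferative subgroup); membership uses
#' the closed rectangle. Downstream enrichment is [find_markers()] of the
#' subset against the rest.
#'
#' @param coords cells x 2 embedding coordinates.
#' @param rectangle numeric `c(xmin, xmax, ymin, ymax)`, finite.
#' @return character vector of selected cell names (or indices when unnamed).
#' @export
select_embedding_region <- function(coords, rectangle) {
  stopifnot(length(rectangle) == 4L, all(is.finite(rectangle)))
  inside <- coords[, 1] >= rectangle[1] & coords[, 1] <= rectangle[2] &
            coords[, 2] >= rectangle[3] & coords[, 2] <= rectangle[4]
  if (!any(inside)) stop("empty selection: no cells inside the rectangle")
  if (!is.null(rownames(coords))) rownames(coords)[inside] else which(inside)
}
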