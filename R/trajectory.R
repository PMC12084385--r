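#' Infer lineages from an origin cluster via a centroid spanning tree
#'
#' Builds the minimum spanning tree over cluster centroids (Euclidean
#' distance in PCA space) and reports every root-to-leaf path starting at the
#' origin cluster, in stable leaf-label-sorted order. With a forked topology
#' this yields one lineage per terminal fate.
#'
#' @param embedding cells x k scores or `embedding_set`.
#' @param labels per-cell cluster labels.
#' @param origin label of the origin (root) cluster.
#' @return a `trajectory_lineages` list: `lineages` (list of ordered label
#'   vectors), `centroids`, `mst` (edge data.frame).
#' @export
infer_lineages <- function(embedding, labels, origin) {
  s <- .scores(embedding)
  labels <- droplevels(as.factor(labels))
  if (!origin %in% levels(labels)) stop("origin cluster not found: ", origin)
  if (nlevels(labels) < 2L) stop("need at least 2 clusters")
  cent <- t(vapply(levels(labels),
                   function(cl) colMeans(s[labels == cl, , drop = FALSE]),
                   numeric(ncol(s))))
  d <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  deg <- igraph::degree(mst)
  leaves <- setdiff(names(deg)[deg == 1L], origin)
  leaves <- sort(leaves)
  lineages <- lapply(leaves, function(leaf) {
    p <- igraph::shortest_paths(mst, from = origin, to = leaf)$vpath[[1]]
    igraph::V(mst)$name[p]
  })
  names(lineages) <- leaves
  edges <- igraph::as_data_frame(mst, what = "edges")
  structure(list(lineages = lineages, centroids = cent, mst = edges),
            class = "trajectory_lineages")
}

# Project points onto a piecewise-linear path; returns arc-length position and
# orthogonal distance of the projection foot.
.project_polyline <- function(points, path) {
  n_seg <- nrow(path) - 1L
  seg_len <- sqrt(rowSums((path[-1, , drop = FALSE] -
                           path[-nrow(path), , drop = FALSE])^2))
  cum_len <- c(0, cumsum(seg_len))
  best_pt <- rep(Inf, nrow(points))
  best_d <- rep(Inf, nrow(points))
  for (si in seq_len(n_seg)) {
    a <- path[si, ]
    v <- path[si + 1L, ] - a
    vv <- sum(v^2)
    diff <- sweep(points, 2, a)
    tt <- if (vv == 0) rep(0, nrow(points)) else
      pmin(pmax((diff %*% v) / vv, 0), 1)
    foot <- outer(as.vector(tt), v) + rep(a, each = nrow(points))
    d <- sqrt(rowSums((points - foot)^2))
    better <- d < best_d
    best_d[better] <- d[better]
    best_pt[better] <- cum_len[si] + tt[better] * seg_len[si]
  }
  list(pseudotime = best_pt, dist = best_d)
}

#' Per-cell pseudotime along a lineage
#'
#' Cells of the lineage's clusters are projected orthogonally onto the
#' piecewise-linear path through the cluster centroids; pseudotime is the arc
#' length of the projection foot from the origin end. Optional principal-curve
#' refinement alternates local-averaging smoothing of the curve (running means
#' of cell coordinates in pseudotime order) with re-projection, until the mean
#' pseudotime shift drops below 1e-4 or `refine_iterations` is reached. Cells
#' of clusters off the lineage get weight 0 and `NA` pseudotime.
#'
#' @param embedding cells x k scores or `embedding_set`.
#' @param lineage ordered cluster labels (one element of
#'   [infer_lineages()]`$lineages`).
#' @param labels per-cell cluster labels.
#' @param refine_iterations principal-curve refinement iterations (default 0:
#'   centroid-path projection only).
#' @return list with named `pseudotime` (NA off-lineage), `weights` (0/1) and
#'   the final `curve` control points.
#' @export
compute_pseudotime <- function(embedding, lineage, labels,
                               refine_iterations = 0L) {
  s <- .scores(embedding)
  labels <- as.character(labels)
  on_lin <- labels %in% lineage
  cent <- t(vapply(lineage, function(cl)
    colMeans(s[labels == cl, , drop = FALSE]), numeric(ncol(s))))
  pts <- s[on_lin, , drop = FALSE]
  proj <- .project_polyline(pts, cent)
  pt <- proj$pseudotime
  curve <- cent
  iter <- 0L
  while (iter < refine_iterations) {
    iter <- iter + 1L
    ord <- order(pt)
    win <- max(10L, ceiling(nrow(pts) / 10))
    sm <- apply(pts[ord, , drop = FALSE], 2, function(col)
      as.vector(zoo::rollmean(zoo::zoo(col), k = min(win, length(col)),
                              align = "center")))
    if (is.null(dim(sm))) sm <- matrix(sm, nrow = 1)
    idx <- unique(round(seq(1, nrow(sm), length.out = min(100L, nrow(sm)))))
    curve <- sm[idx, , drop = FALSE]
    proj <- .project_polyline(pts, curve)
    shift <- mean(abs(proj$pseudotime - pt))
    pt <- proj$pseudotime
    if (shift < 1e-4) break
  }
  out_pt <- rep(NA_real_, nrow(s))
  out_pt[on_lin] <- pt
  names(out_pt) <- rownames(s)
  list(pseudotime = out_pt, weights = stats::setNames(as.numeric(on_lin),
                                                      rownames(s)),
       curve = curve)
}

#' Test genes for association with pseudotime
#'
#' Each gene's normalized expression is regressed on a cubic B-spline basis of
#' pseudotime with `n_knots` knots placed at pseudotime quantiles. The
#' statistic is a Wald test that all consecutive differences of the fitted
#' values anchored at the knots are zero (the consecutive-contrast form), with
#' p-values from the F reference distribution and Benjamini-Hochberg
#' adjustment across genes.
#'
#' @param norm genes x cells normalized matrix.
#' @param pseudotime named per-cell pseudotime; `NA` cells are excluded.
#' @param genes genes to test (default all rows).
#' @param n_knots number of spline knots (default 8).
#' @return data.frame with `gene`, `statistic`, `p_value`, `adjusted_p`,
#'   ordered by decreasing statistic; fitted knot values in attribute
#'   `knot_fits` and knot locations in `knots`.
#' @export
association_test <- function(norm, pseudotime, genes = rownames(norm),
                             n_knots = 8L) {
  if (n_knots < 3L) stop("n_knots must be >= 3")
  pt <- pseudotime[colnames(norm)]
  use <- !is.na(pt)
  if (sum(use) < 30L) stop("pseudotime defined for fewer than 30 cells")
  x <- pt[use]
  if (stats::sd(x) == 0) stop("degenerate pseudotime: design is singular")
  knots <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_knots),
                                  names = FALSE))
  if (length(knots) < 3L) stop("degenerate pseudotime: too few distinct knots")
  interior <- knots[-c(1, length(knots))]
  X <- splines::bs(x, knots = interior, degree = 3, intercept = TRUE,
                   Boundary.knots = range(x))
  B <- splines::bs(knots, knots = interior, degree = 3, intercept = TRUE,
                   Boundary.knots = range(x))
  L <- diff(diag(length(knots)))   # consecutive differences
  C <- L %*% B
  qrX <- qr(X)
  XtX_inv <- chol2inv(qr.R(qrX))
  n <- nrow(X)
  p <- ncol(X)
  CVC <- C %*% XtX_inv %*% t(C)
  sv <- svd(CVC)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  CVC_inv <- sv$v[, seq_len(r), drop = FALSE] %*%
    diag(1 / sv$d[seq_len(r)], r) %*% t(sv$u[, seq_len(r), drop = FALSE])
  genes <- intersect(genes, rownames(norm))
  Y <- t(norm[genes, use, drop = FALSE])
  beta <- qr.coef(qrX, Y)
  beta[is.na(beta)] <- 0
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  D <- C %*% beta                  # consecutive knot differences per gene
  # genes with (numerically) zero residual variance are flat fits: no signal
  ms <- colMeans(Y^2)
  wald <- vapply(seq_along(genes), function(j) {
    if (sigma2[j] <= 1e-12 * (ms[j] + 1e-300)) return(0)
    as.numeric(t(D[, j]) %*% CVC_inv %*% D[, j]) / sigma2[j]
  }, numeric(1))
  p_val <- stats::pf(wald / r, r, n - p, lower.tail = FALSE)
  out <- data.frame(gene = genes, statistic = wald, p_value = p_val,
                    adjusted_p = stats::p.adjust(p_val, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$statistic, decreasing = TRUE), , drop = FALSE]
  attr(out, "knot_fits") <- t(B %*% beta)
  attr(out, "knots") <- knots
  out
}

#' Keep genes passing a low-expression filter for trajectory plotting
#'
#' @param counts genes x cells raw count matrix (the analyzed cells).
#' @param min_count minimum count (default 1).
#' @param min_cells minimum number of cells reaching `min_count` (default 20;
#'   inclusive bounds).
#' @return character vector of surviving gene names.
#' @export
filter_trajectory_genes <- function(counts, min_count = 1, min_cells = 20) {
  rownames(counts)[rowSums(counts >= min_count) >= min_cells]
}

#' Rolling-window smoothing along pseudotime with per-bin cluster annotation
#'
#' Cells are ordered by pseudotime (ties broken by cell name); each gene is
#' smoothed by a rolling mean over `window` consecutive cells advancing by
#' `step`, and each bin is annotated with its modal cluster label (ties
#' resolved to the label of the earliest cell in the bin).
#'
#' @param expr genes x cells expression matrix (normalized values).
#' @param pseudotime named per-cell pseudotime; `NA` cells are dropped.
#' @param labels per-cell cluster labels aligned with `expr` columns.
#' @param window bin width in cells (default `ceiling(n/20)`).
#' @param step bin advance (default 1).
#' @return list with `smoothed` (genes x bins), `bin_annotation`,
#'   `bin_pseudotime`, `cell_order`, `window`, `step`.
#' @export
smooth_and_annotate <- function(expr, pseudotime, labels, window = NULL,
                                step = 1L) {
  pt <- pseudotime[colnames(expr)]
  keep <- !is.na(pt)
  expr <- expr[, keep, drop = FALSE]
  labels <- as.character(labels)[keep]
  pt <- pt[keep]
  n <- ncol(expr)
  ord <- order(pt, colnames(expr))
  expr <- expr[, ord, drop = FALSE]
  labels <- labels[ord]
  pt <- pt[ord]
  if (is.null(window)) window <- ceiling(n / 20)
  if (window < 2L) stop("window must be >= 2")
  if (window > n) stop("window (", window, ") exceeds number of cells (", n, ")")
  starts <- seq(1L, n - window + 1L, by = step)
  smoothed <- vapply(starts, function(s0)
    rowMeans(expr[, s0:(s0 + window - 1L), drop = FALSE]),
    numeric(nrow(expr)))
  if (is.null(dim(smoothed))) smoothed <- matrix(smoothed, nrow = nrow(expr))
  rownames(smoothed) <- rownames(expr)
  colnames(smoothed) <- paste0("bin", seq_along(starts))
  ann <- vapply(starts, function(s0) {
    lab <- labels[s0:(s0 + window - 1L)]
    tab <- table(lab)
    winners <- names(tab)[tab == max(tab)]
    lab[lab %in% winners][1]
  }, character(1))
  bin_pt <- vapply(starts, function(s0) mean(pt[s0:(s0 + window - 1L)]),
                   numeric(1))
  list(smoothed = smoothed, bin_annotation = ann, bin_pseudotime = bin_pt,
       cell_order = colnames(expr), window = window, step = step)
}

#' Classify temporal expression patterns by hierarchical clustering
#'
#' Per-gene smoothed profiles are z-scored and clustered by average-linkage
#' agglomeration on Euclidean distance; the tree is cut into `k` groups.
#' Groups are named by trend and timing: decreasing profiles are basal-like
#' (`bas`), increasing profiles luminal-like (`lum`), transient profiles
#' intermediate (`int`); within a class, groups are suffixed `_early`/`_late`
#' (or `_1`, `_2`, ... beyond two) by the pseudotime position of their
#' characteristic transition.
#'
#' @param smoothed genes x bins matrix from [smooth_and_annotate()].
#' @param k number of pattern groups (3 for coarse, 6 for the full early/late
#'   split).
#' @return list with `groups` (named gene -> group-name vector), `cut`
#'   (integer assignments), `hclust`, `z` (the z-scored profiles), and
#'   `group_profiles` (group mean profiles).
#' @export
pattern_groups <- function(smoothed, k = 6L) {
  if (k > nrow(smoothed)) stop("k exceeds number of genes")
  mu <- rowMeans(smoothed)
  sd_g <- sqrt(pmax(.row_vars(smoothed, mu), 0))
  z <- (smoothed - mu) / ifelse(sd_g == 0, 1, sd_g)
  hc <- stats::hclust(stats::dist(z), method = "average")
  cut <- stats::cutree(hc, k = k)
  prof <- t(vapply(seq_len(k), function(g)
    colMeans(z[cut == g, , drop = FALSE]), numeric(ncol(z))))
  idx <- seq_len(ncol(z))
  trend <- apply(prof, 1, function(p) stats::cor(p, idx, method = "spearman"))
  klass <- ifelse(trend <= -0.3, "bas", ifelse(trend >= 0.3, "lum", "int"))
  timing <- vapply(seq_len(k), function(g) {
    p <- prof[g, ]
    switch(klass[g],
      bas = {w <- which(p < 0); if (length(w)) w[1] else ncol(z)},
      lum = {w <- which(p > 0); if (length(w)) w[1] else ncol(z)},
      int = which.max(p))
  }, numeric(1))
  group_names <- character(k)
  for (cl in unique(klass)) {
    members <- which(klass == cl)
    ord <- members[order(timing[members])]
    suffix <- if (length(ord) == 1L) "" else if (length(ord) == 2L)
      c("_early", "_late") else paste0("_", seq_along(ord))
    group_names[ord] <- paste0(cl, suffix)
  }
  groups <- stats::setNames(group_names[cut], rownames(smoothed))
  rownames(prof) <- group_names
  list(groups = groups, cut = cut, hclust = hc, z = z, group_profiles = prof)
}
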