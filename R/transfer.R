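#' Transfer cluster labels from a reference to a query dataset
#'
#' The reference is embedded by PCA on its highly variable genes; query cells
#' are projected with the reference loadings after matching the reference's
#' per-gene centering and scaling. Each query cell then takes a
#' Gaussian-kernel-weighted k-nearest-neighbor vote over reference labels; the
#' per-label score vector sums to 1 and the predicted ID is its argmax (ties
#' broken alphabetically and flagged).
#'
#' @param reference list with `norm` (genes x cells normalized matrix) and
#'   `labels` (per-cell labels).
#' @param query genes x cells normalized matrix.
#' @param n_pcs number of principal components (default 30).
#' @param k neighbors in the vote (default 30).
#' @param n_hvg highly variable genes selected on the reference.
#' @return a `transfer_result` list: `predicted_id`, `prediction_score`
#'   (max score), `scores` (query cells x reference labels), `tied` flags.
#' @export
transfer_labels <- function(reference, query, n_pcs = 30L, k = 30L,
                            n_hvg = 2000L) {
  ref <- reference$norm
  labels <- as.factor(reference$labels)
  shared <- intersect(rownames(ref), rownames(query))
  if (length(shared) < 100L) {
    stop("need at least 100 shared genes; found ", length(shared))
  }
  ref <- ref[shared, , drop = FALSE]
  qry <- query[shared, , drop = FALSE]
  # HVG by normalized-value variance on the shared reference genes.
  v <- .row_vars(ref)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, length(v)))]
  hvg <- hvg[v[hvg] > 0]
  ref <- ref[hvg, , drop = FALSE]
  qry <- qry[hvg, , drop = FALSE]
  mu <- rowMeans(ref)
  sd_g <- sqrt(.row_vars(ref, mu))
  sd_g[sd_g == 0] <- 1
  ref_sc <- pmin((ref - mu) / sd_g, 10)
  qry_sc <- pmin((qry - mu) / sd_g, 10)
  n_pcs <- min(n_pcs, min(dim(ref_sc)) - 1L)
  emb <- run_pca(ref_sc, n_components = n_pcs)
  ref_pc <- emb$scores
  qry_pc <- t(qry_sc - emb$center) %*% emb$loadings
  d <- .cross_dist(qry_pc, ref_pc)
  k <- min(k, ncol(ref))
  lev <- levels(labels)
  scores <- matrix(0, nrow(qry_pc), length(lev),
                   dimnames = list(colnames(query), lev))
  tied <- logical(nrow(qry_pc))
  for (i in seq_len(nrow(qry_pc))) {
    nn <- order(d[i, ])[seq_len(k)]
    dn <- d[i, nn]
    sigma <- max(dn[k] / 3, 1e-8)
    w <- exp(-dn^2 / (2 * sigma^2))
    for (j in seq_len(k)) {
      scores[i, as.integer(labels[nn[j]])] <-
        scores[i, as.integer(labels[nn[j]])] + w[j]
    }
    scores[i, ] <- scores[i, ] / sum(scores[i, ])
    best <- which(scores[i, ] == max(scores[i, ]))
    tied[i] <- length(best) > 1L
  }
  predicted <- lev[apply(scores, 1, which.max)]
  structure(list(
    predicted_id = stats::setNames(predicted, colnames(query)),
    prediction_score = stats::setNames(apply(scores, 1, max), colnames(query)),
    scores = scores, tied = tied
  ), class = "transfer_result")
}

#' Contingency flow table of query clusters vs predicted IDs
#'
#' Counts per (query cluster, predicted ID) pair, in long format for alluvial
#' plotting; marginals are preserved exactly.
#'
#' @param query_labels per-cell query cluster labels.
#' @param predicted_ids per-cell predicted reference labels.
#' @return data.frame with `query_cluster`, `predicted_id`, `n`.
#' @export
flow_table <- function(query_labels, predicted_ids) {
  if (length(query_labels) != length(predicted_ids)) {
    stop("label vectors must align to the same cells")
  }
  tab <- table(query_cluster = as.character(query_labels),
               predicted_id = as.character(predicted_ids))
  df <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  df[df$n > 0, , drop = FALSE]
}
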