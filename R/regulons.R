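#' Per-cell regulon activity by ranking AUC
#'
#' For each cell, genes are ranked by decreasing expression (ties broken by a
#' fixed lexicographic gene order for determinism). The activity is the area
#' under the recovery curve — cumulative regulon hits against rank — over the
#' top `ceiling(top_fraction * n_genes)` ranks, normalized by the maximum
#' attainable area, so values lie in \[0, 1\].
#'
#' @param norm genes x cells normalized (or any within-cell monotone) matrix.
#' @param regulon character vector of target genes (by convention including
#'   the TF itself).
#' @param top_fraction fraction of the ranking that defines the recovery
#'   window (default 0.05).
#' @return named per-cell numeric vector in \[0, 1\].
#' @export
aucell_score <- function(norm, regulon, top_fraction = 0.05) {
  hits_set <- intersect(regulon, rownames(norm))
  n_genes <- nrow(norm)
  window <- ceiling(top_fraction * n_genes)
  if (length(hits_set) == 0L) {
    warning("regulon has no genes in the matrix; returning zeros")
    return(stats::setNames(rep(0, ncol(norm)), colnames(norm)))
  }
  lex <- order(rownames(norm))
  tie_rank <- numeric(n_genes)
  tie_rank[lex] <- seq_len(n_genes)
  is_hit <- rownames(norm) %in% hits_set
  m_eff <- length(hits_set)
  max_area <- sum(pmin(seq_len(window), m_eff))
  score <- vapply(seq_len(ncol(norm)), function(i) {
    ord <- order(-norm[, i], tie_rank)[seq_len(window)]
    sum(cumsum(is_hit[ord])) / max_area
  }, numeric(1))
  stats::setNames(score, colnames(norm))
}

#' Activity matrix for a list of regulons
#'
#' @param norm genes x cells normalized matrix.
#' @param regulons named list: TF -> target gene set.
#' @param top_fraction recovery-window fraction, see [aucell_score()].
#' @return cells x regulons matrix of activities in \[0, 1\].
#' @export
regulon_activity <- function(norm, regulons, top_fraction = 0.05) {
  stopifnot(length(regulons) > 0, !is.null(names(regulons)))
  out <- vapply(regulons, function(r) aucell_score(norm, r, top_fraction),
                numeric(ncol(norm)))
  rownames(out) <- colnames(norm)
  out
}

.jsd_base2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity scores
#'
#' For regulon r and cluster c: the regulon's activity column normalized to
#' sum 1 over cells is compared with the cluster's normalized indicator
#' distribution via the Jensen-Shannon divergence in base-2 logs (so JSD lies
#' in \[0, 1\]), and `RSS = 1 - sqrt(JSD)`. RSS is 1 exactly when activity is
#' uniform on the cluster's cells and zero elsewhere.
#'
#' @param activity cells x regulons activity matrix.
#' @param labels per-cell cluster labels.
#' @return regulons x clusters matrix of RSS values; regulons with all-zero
#'   activity get `NA` with a warning.
#' @export
regulon_specificity_score <- function(activity, labels) {
  labels <- as.factor(labels)
  stopifnot(nrow(activity) == length(labels))
  cl <- levels(droplevels(labels))
  rss <- matrix(NA_real_, ncol(activity), length(cl),
                dimnames = list(colnames(activity), cl))
  for (r in seq_len(ncol(activity))) {
    a <- activity[, r]
    tot <- sum(a)
    if (tot == 0) {
      warning("all-zero activity for regulon ", colnames(activity)[r],
              "; RSS undefined")
      next
    }
    p <- a / tot
    for (c_i in seq_along(cl)) {
      q <- as.numeric(labels == cl[c_i])
      q <- q / sum(q)
      rss[r, c_i] <- 1 - sqrt(max(.jsd_base2(p, q), 0))
    }
  }
  rss
}

#' Top regulons per cluster with overlap reporting
#'
#' Per cluster, the `n` regulons with the highest RSS (ties broken by regulon
#' name); pairwise overlap counts and cluster-exclusive regulons support
#' Venn-style summaries of shared regulatory programs.
#'
#' @param rss regulons x clusters RSS matrix.
#' @param n list size per cluster (default 50; all regulons with a warning if
#'   fewer are available).
#' @return list with `top` (named list of ordered regulon vectors),
#'   `overlap` (clusters x clusters matrix of shared-regulon counts) and
#'   `exclusive` (regulons present in exactly one cluster's list).
#' @export
top_regulons_per_cluster <- function(rss, n = 50L) {
  if (nrow(rss) < n) {
    warning("only ", nrow(rss), " regulons scored; returning all")
    n <- nrow(rss)
  }
  top <- lapply(colnames(rss), function(cl) {
    v <- rss[, cl]
    ord <- order(-v, rownames(rss), na.last = TRUE)
    rownames(rss)[ord][seq_len(n)]
  })
  names(top) <- colnames(rss)
  k <- length(top)
  overlap <- matrix(0L, k, k, dimnames = list(names(top), names(top)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    overlap[i, j] <- length(intersect(top[[i]], top[[j]]))
  }
  counts <- table(unlist(top))
  exclusive <- lapply(top, function(t) t[counts[t] == 1L])
  list(top = top, overlap = overlap, exclusive = exclusive)
}
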