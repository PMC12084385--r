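#' Principal component analysis with deterministic sign convention
#'
#' PCA of cells over the supplied (typically scaled highly-variable) genes.
#' Components are ordered by decreasing explained variance and each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive, making results reproducible across platforms.
#'
#' @param scaled genes x cells matrix (e.g. from [scale_features()]).
#' @param n_components number of components to keep (default 30).
#' @return an `embedding_set` list: `scores` (cells x k), `loadings`
#'   (genes x k), `sdev`, `var_explained`, `center`.
#' @export
run_pca <- function(scaled, n_components = 30L) {
  x <- t(scaled)
  max_rank <- min(dim(x))
  if (n_components > max_rank) {
    stop("n_components exceeds min(cells, genes) = ", max_rank)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pos <- which(pc$sdev > 1e-10)
  k <- min(n_components, length(pos))
  if (k < n_components) {
    warning("input rank ", length(pos), " < requested ", n_components,
            " components; returning ", k)
  }
  flip <- vapply(seq_len(k), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  structure(list(
    scores = scores, loadings = loadings,
    sdev = pc$sdev[seq_len(k)],
    var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
    center = pc$center
  ), class = "embedding_set")
}

.scores <- function(x) if (inherits(x, "embedding_set")) x$scores else as.matrix(x)

#' Integrate batches by smoothed mutual-nearest-neighbor correction
#'
#' All batches are jointly scaled and embedded by PCA; each non-reference
#' batch is then shifted toward the reference batch by locally smoothed
#' mutual-nearest-neighbor (MNN) correction vectors. Per cell, the correction
#' is a Gaussian-kernel weighted average of the MNN pair vectors anchored
#' nearest to it, so within-batch geometry is preserved up to a smooth shift.
#'
#' @param norm_list named list of genes x cells normalized matrices, one per
#'   batch.
#' @param reference_batch name of the reference batch (chosen, as in practice,
#'   as the batch with balanced cell-type representation).
#' @param hvg optional gene subset to integrate on.
#' @param n_pcs number of principal components.
#' @param k_mnn neighbors per direction when calling mutual pairs.
#' @return an `embedding_set` with corrected `scores` (cells in the
#'   concatenated order of `norm_list`) plus `batch` and `uncorrected` fields.
#' @export
integrate_batches <- function(norm_list, reference_batch, hvg = NULL,
                              n_pcs = 30L, k_mnn = 20L) {
  stopifnot(length(norm_list) >= 1, reference_batch %in% names(norm_list))
  shared <- Reduce(intersect, lapply(norm_list, rownames))
  if (!is.null(hvg)) shared <- intersect(hvg, shared)
  joint <- do.call(cbind, lapply(norm_list, function(m) m[shared, , drop = FALSE]))
  batch <- rep(names(norm_list), vapply(norm_list, ncol, integer(1)))
  scaled <- suppressWarnings(scale_features(joint))
  emb <- run_pca(scaled, n_components = min(n_pcs, min(dim(joint)) - 1L))
  scores <- emb$scores
  if (length(norm_list) == 1L) {
    emb$batch <- batch
    emb$uncorrected <- scores
    return(emb)
  }
  ref_idx <- which(batch == reference_batch)
  corrected <- scores
  for (b in setdiff(names(norm_list), reference_batch)) {
    bi <- which(batch == b)
    d <- .cross_dist(scores[bi, , drop = FALSE], scores[ref_idx, , drop = FALSE])
    k1 <- min(k_mnn, length(ref_idx))
    k2 <- min(k_mnn, length(bi))
    nn_b2r <- t(apply(d, 1, function(r) rank(r, ties.method = "first") <= k1))
    nn_r2b <- t(apply(d, 2, function(r) rank(r, ties.method = "first") <= k2))
    mutual <- which(nn_b2r & t(nn_r2b), arr.ind = TRUE)
    if (nrow(mutual) == 0L) {
      warning("no MNN pairs for batch ", b, "; left uncorrected")
      next
    }
    vec <- scores[ref_idx[mutual[, 2]], , drop = FALSE] -
           scores[bi[mutual[, 1]], , drop = FALSE]
    # one correction estimate per anchored batch cell: the average over all
    # of its mutual pairs (per-anchor averaging keeps the estimate unbiased)
    grp <- factor(mutual[, 1])
    vec <- rowsum(vec, grp) / as.vector(table(grp))
    anchor_cells <- as.integer(levels(grp))
    anchor <- scores[bi[anchor_cells], , drop = FALSE]
    da <- .cross_dist(scores[bi, , drop = FALSE], anchor)
    sigma <- stats::median(apply(da, 1, min)) + 1e-8
    # anchor-proximity kernel; the row minimum is subtracted before
    # exponentiating so weights never underflow to an all-zero row
    w <- exp(-(da^2 - apply(da, 1, min)^2) / (2 * sigma^2))
    w <- w / rowSums(w)
    corrected[bi, ] <- scores[bi, , drop = FALSE] + w %*% vec
  }
  emb$uncorrected <- scores
  emb$scores <- corrected
  emb$batch <- batch
  emb
}

.cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Shared-nearest-neighbor graph
#'
#' k-nearest-neighbor sets (self included) in the embedding, with edges
#' weighted by the Jaccard similarity of neighbor sets; weights below
#' `prune` are dropped.
#'
#' @param embedding cells x k score matrix or an `embedding_set`.
#' @param k_neighbors neighborhood size (default 20, self included).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return an undirected weighted [igraph::graph] with one vertex per cell.
#' @export
snn_graph <- function(embedding, k_neighbors = 20L, prune = 1 / 15) {
  s <- .scores(embedding)
  n <- nrow(s)
  if (k_neighbors >= n) stop("k_neighbors must be < number of cells")
  d <- as.matrix(stats::dist(s))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  inter <- as.matrix(Matrix::tcrossprod(adj))
  jac <- inter / (2 * k_neighbors - inter)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(s) %||% as.character(seq_len(n))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Leiden community detection with the modularity objective at the given
#' resolution, seeded for determinism. Cluster labels are integers as
#' characters, sorted by decreasing cluster size.
#'
#' @param embedding cells x k scores or `embedding_set`.
#' @param resolution modularity resolution (default 0.5).
#' @param k_neighbors SNN neighborhood size (default 20).
#' @param seed RNG seed.
#' @return factor of per-cell labels with attribute `resolution`.
#' @export
cluster_cells <- function(embedding, resolution = 0.5, k_neighbors = 20L,
                          seed = 42L) {
  g <- snn_graph(embedding, k_neighbors = k_neighbors)
  if (igraph::count_components(g) > 1L) {
    warning("SNN graph is disconnected (", igraph::count_components(g),
            " components)")
  }
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(g)$weight,
                                 n_iterations = 10L)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(as.character(seq_along(sizes)), names(sizes))
  lab <- factor(relabel[as.character(memb)], levels = as.character(seq_along(sizes)))
  names(lab) <- igraph::V(g)$name
  attr(lab, "resolution") <- resolution
  lab
}

#' Re-cluster the cells of one cluster
#'
#' Rebuilds an SNN graph on the target subset alone and clusters it at
#' `resolution`; other cells keep their labels, the target's cells get
#' suffixed labels (e.g. `"1.1"`, `"1.2"`).
#'
#' @param embedding cells x k scores or `embedding_set` (all cells).
#' @param labels factor of current per-cell labels.
#' @param target_label label to split.
#' @param resolution subclustering resolution (default 0.6).
#' @param k_neighbors SNN neighborhood size.
#' @param seed RNG seed.
#' @return factor of updated labels with provenance attributes.
#' @export
subcluster <- function(embedding, labels, target_label, resolution = 0.6,
                       k_neighbors = 20L, seed = 42L) {
  s <- .scores(embedding)
  if (!target_label %in% labels) stop("target label not found: ", target_label)
  idx <- which(labels == target_label)
  if (length(idx) < k_neighbors + 1L) {
    stop("subset too small to subcluster (", length(idx), " cells)")
  }
  sub <- cluster_cells(s[idx, , drop = FALSE], resolution = resolution,
                       k_neighbors = k_neighbors, seed = seed)
  new_lab <- as.character(labels)
  new_lab[idx] <- paste0(target_label, ".", as.character(sub))
  out <- factor(new_lab)
  names(out) <- names(labels) %||% rownames(s)
  attr(out, "parent") <- target_label
  attr(out, "subcluster_resolution") <- resolution
  out
}

#' UMAP embedding of the PCA scores
#'
#' @param embedding cells x k scores or `embedding_set`.
#' @param spread UMAP spread (default 0.4).
#' @param min_dist UMAP minimum distance (default 0.3).
#' @param n_neighbors UMAP neighborhood size.
#' @param n_epochs optimization epochs; the default is generous because the
#'   embeddings here are small and tighter convergence keeps near-duplicate
#'   cells together.
#' @param seed RNG seed; fixed seeds reproduce the layout exactly.
#' @return cells x 2 matrix with columns `UMAP1`, `UMAP2`.
#' @export
run_umap <- function(embedding, spread = 0.4, min_dist = 0.3,
                     n_neighbors = 30L, n_epochs = 1000L, seed = 42L) {
  s <- .scores(embedding)
  if (nrow(s) < 10L) stop("need at least 10 cells for UMAP")
  set.seed(seed)
  um <- uwot::umap(s, spread = spread, min_dist = min(min_dist, spread),
                   n_neighbors = min(n_neighbors, nrow(s) - 1L),
                   n_epochs = n_epochs, init = "spca",
                   n_threads = 1, n_sgd_threads = 0)
  dimnames(um) <- list(rownames(s), c("UMAP1", "UMAP2"))
  um
}

#' Name clusters by canonical marker expression and FACS gates
#'
#' Assigns the study vocabulary {BAS, INT1, INT2, HRneg, HRpos} to raw cluster
#' labels: the hormone-receptor-positive cluster by Esr1/Pgr score, the basal
#' anchor by Krt5/Krt14/Acta2, the mature luminal (HRneg) cluster by
#' Krt8/Krt19/Krt18, and remaining clusters as INT1, INT2, ... ordered from
#' most to least basal. When FACS gates are supplied, a cluster whose majority
#' gate agrees with a candidate identity receives a small score bonus.
#'
#' @param norm genes x cells normalized matrix.
#' @param labels factor of raw cluster labels.
#' @param gates optional per-cell FACS gate labels
#'   (`basal`/`intermediate`/`luminal`).
#' @param markers named list of canonical marker sets (`basal`, `luminal`,
#'   `hr`); the luminal set uses HRneg luminal-progenitor markers
#'   (Elf5/Kit/Cd14) because pan-luminal keratins stop discriminating once
#'   the shared luminal program is installed in the intermediates.
#' @return factor of per-cell names with attribute `mapping` (raw -> name).
#' @export
name_clusters <- function(norm, labels, gates = NULL,
                          markers = list(
                            basal = c("Krt5", "Krt14", "Acta2"),
                            luminal = c("Elf5", "Kit", "Cd14"),
                            hr = c("Esr1", "Pgr"))) {
  labels <- droplevels(as.factor(labels))
  score_set <- function(set) {
    set <- intersect(set, rownames(norm))
    if (!length(set)) return(stats::setNames(rep(0, nlevels(labels)), levels(labels)))
    m <- norm[set, , drop = FALSE]
    mu <- rowMeans(m)
    sd_g <- sqrt(pmax(.row_vars(m, mu), 1e-12))
    z <- (m - mu) / sd_g
    vapply(levels(labels), function(cl) mean(z[, labels == cl, drop = FALSE]),
           numeric(1))
  }
  sc <- cbind(basal = score_set(markers$basal),
              luminal = score_set(markers$luminal),
              hr = score_set(markers$hr))
  if (!is.null(gates)) {
    maj <- vapply(levels(labels), function(cl) {
      names(which.max(table(gates[labels == cl])))
    }, character(1))
    sc[, "basal"] <- sc[, "basal"] + 0.25 * (maj == "basal")
    sc[, "luminal"] <- sc[, "luminal"] + 0.25 * (maj == "luminal")
  }
  mapping <- stats::setNames(rep(NA_character_, nlevels(labels)), levels(labels))
  remaining <- levels(labels)
  pick <- function(col, pool) pool[which.max(sc[pool, col])]
  if (length(remaining) >= 1L) {
    hrpos <- pick("hr", remaining)
    mapping[hrpos] <- "HRpos"
    remaining <- setdiff(remaining, hrpos)
  }
  if (length(remaining) >= 1L) {
    bas <- pick("basal", remaining)
    mapping[bas] <- "BAS"
    remaining <- setdiff(remaining, bas)
  }
  if (length(remaining) >= 1L) {
    hrneg <- pick("luminal", remaining)
    mapping[hrneg] <- "HRneg"
    remaining <- setdiff(remaining, hrneg)
  }
  if (length(remaining)) {
    # Remaining clusters are intermediates: INT1 if closer to the basal than
    # the luminal anchor on the basal-minus-luminal axis, INT2 otherwise.
    axis <- sc[, "basal"] - sc[, "luminal"]
    anchors <- c(names(mapping)[which(mapping == "BAS")],
                 names(mapping)[which(mapping == "HRneg")])
    midpoint <- mean(axis[anchors])
    ord <- remaining[order(axis[remaining], decreasing = TRUE)]
    if (length(ord) == 2L) {
      mapping[ord] <- c("INT1", "INT2")
    } else {
      mapping[ord] <- ifelse(axis[ord] > midpoint, "INT1", "INT2")
      if (all(mapping[ord] == "INT2")) mapping[ord[1]] <- "INT1"
      if (all(mapping[ord] == "INT1")) mapping[ord[length(ord)]] <- "INT2"
    }
  }
  out <- factor(mapping[as.character(labels)],
                levels = intersect(c("BAS", "INT1", "INT2", "HRneg", "HRpos"),
                                   mapping))
  names(out) <- names(labels)
  attr(out, "mapping") <- mapping
  out
}
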