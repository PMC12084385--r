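#' Default pipeline configuration
#'
#' Assembles the full run configuration with defaults matching the study
#' settings: clustering resolution 0.5 with targeted subclustering at 0.6,
#' 30 principal components, UMAP spread 0.4, 2000 variable genes for PCA and
#' 4000 for trajectory association, marker min.pct 0.40, top 50 markers,
#' 8 spline knots, top 40 genes at k = 3 and all trajectory genes at k = 6
#' pattern groups. Unknown keys are rejected.
#'
#' @param ... named overrides; nested sections can be given as lists, e.g.
#'   `cluster = list(resolution = 0.4)`.
#' @param yaml_file optional YAML file of overrides applied before `...`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., yaml_file = NULL) {
  defaults <- list(
    seed = 7L,
    out_dir = NULL,
    input_dir = NULL,
    stages = list(simulate = TRUE, qc = TRUE, cluster = TRUE, score = TRUE,
                  regulons = TRUE, trajectory = TRUE, transfer = FALSE),
    simulate = list(),                      # sim_config() overrides
    qc = list(exclude_plates = character(), thresholds = list()),
    cluster = list(n_hvg = 2000L, n_pcs = 30L, resolution = 0.5,
                   subcluster_resolution = 0.6, k_neighbors = 20L,
                   spread = 0.4, min_dist = 0.3, reference_batch = "1"),
    score = list(n_markers = 50L, min_pct = 0.40, rectangle = NULL),
    regulons = list(top_fraction = 0.05, n_top = 50L, regulon_file = NULL),
    trajectory = list(origin = "BAS", n_knots = 8L, n_hvg = 4000L,
                      top_genes = 40L, k_coarse = 3L, k_fine = 6L,
                      min_count = 1, min_cells = 20, refine_iterations = 2L,
                      sig_alpha = 1e-4, window = NULL, test_lineage = "HRneg"),
    transfer = list(k = 30L, n_pcs = 30L, reference_dir = NULL)
  )
  merge_into <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) {
        stop("unknown configuration key: ", paste0(path, nm))
      }
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          nm != "simulate" && nm != "thresholds") {
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]], paste0(path, nm, "$"))
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  cfg <- defaults
  if (!is.null(yaml_file)) cfg <- merge_into(cfg, yaml::read_yaml(yaml_file))
  cfg <- merge_into(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate (or load), QC,
#' integration/clustering/naming/UMAP, signature scoring, regulon activity and
#' specificity, trajectory and pattern analysis, optional label transfer —
#' and returns a run report plus all intermediate objects. With `out_dir`
#' set, artifacts (matrices, metadata, scores, report JSON) are written out.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `report` (plain summary, serializable to
#'   JSON) and `objects` (bundle, matrices, labels, scores, trajectory and
#'   transfer results).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  report <- list(seed = cfg$seed)
  obj <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- simulate / load --------------------------------------------------
  if (isTRUE(cfg$stages$simulate) && is.null(cfg$input_dir)) {
    run_stage("simulate", function() {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      obj$bundle <<- simulate_dataset(do.call(sim_config, sim_args))
    })
  } else {
    run_stage("load", function() {
      counts <- read_counts_mtx(cfg$input_dir)
      meta <- utils::read.table(file.path(cfg$input_dir, "meta.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      obj$bundle <<- list(counts = counts, meta = meta, truth = NULL)
    })
  }
  counts <- obj$bundle$counts
  meta <- obj$bundle$meta
  report$n_cells_input <- ncol(counts)
  report$n_genes_input <- nrow(counts)

  ## ---- QC ----------------------------------------------------------------
  if (isTRUE(cfg$stages$qc)) {
    run_stage("qc", function() {
      thr <- do.call(qc_thresholds, cfg$qc$thresholds)
      if (length(cfg$qc$exclude_plates)) {
        keep <- !meta$plate %in% cfg$qc$exclude_plates
        counts <<- counts[, keep, drop = FALSE]
        report$n_excluded_plate_cells <<- sum(!keep)
      }
      m1 <- basic_gene_cell_filter(counts, thr)
      m2 <- qc_cell_filter(m1, thresholds = thr)
      m3 <- contaminant_filter(m2, thr$contaminant_rules)
      report$qc <<- list(
        after_basic = dim(m1)[2], genes_after_basic = dim(m1)[1],
        after_cell_qc = dim(m2)[2],
        after_contaminant = dim(m3)[2]
      )
      counts <<- m3
    })
  }
  meta <- meta[match(colnames(counts), meta$cell), , drop = FALSE]
  norm <- log_normalize(counts)
  obj$counts <- counts
  obj$norm <- norm

  ## ---- clustering --------------------------------------------------------
  if (isTRUE(cfg$stages$cluster)) {
    run_stage("cluster", function() {
      cc <- cfg$cluster
      hvg <- select_hvg(counts, n = min(cc$n_hvg, nrow(counts)))
      batches <- split(colnames(counts), meta$batch)
      ref <- as.character(cc$reference_batch)
      if (!ref %in% names(batches)) ref <- names(batches)[1]
      emb <- integrate_batches(
        lapply(batches, function(cl) norm[, cl, drop = FALSE]),
        reference_batch = ref, hvg = hvg, n_pcs = cc$n_pcs)
      # restore original cell order
      ord <- match(colnames(counts), rownames(emb$scores))
      emb$scores <- emb$scores[ord, , drop = FALSE]
      labels <- cluster_cells(emb$scores, resolution = cc$resolution,
                              k_neighbors = cc$k_neighbors, seed = cfg$seed)
      # If fewer than five clusters, split the mixed basal/intermediate one,
      # mirroring the targeted subclustering of the study design.
      tries <- 0L
      while (nlevels(droplevels(labels)) < 5L && tries < 2L) {
        tries <- tries + 1L
        mix <- vapply(levels(droplevels(labels)), function(l) {
          g <- meta$gate[labels == l]
          min(mean(g == "basal"), mean(g == "intermediate"))
        }, numeric(1))
        target <- names(which.max(mix))
        labels <- subcluster(emb$scores, labels, target,
                             resolution = cc$subcluster_resolution,
                             k_neighbors = min(cc$k_neighbors,
                                               sum(labels == target) - 1L),
                             seed = cfg$seed)
      }
      named <- name_clusters(norm, labels, gates = meta$gate)
      um <- run_umap(emb$scores, spread = cc$spread, min_dist = cc$min_dist,
                     seed = cfg$seed)
      obj$embedding <<- emb
      obj$raw_labels <<- labels
      obj$labels <<- named
      obj$umap <<- um
      obj$hvg <<- hvg
      report$cluster <<- list(
        n_raw_clusters = nlevels(droplevels(labels)),
        sizes = as.list(table(named))
      )
    })
  }

  ## ---- signature scoring ---------------------------------------------------
  if (isTRUE(cfg$stages$score) && !is.null(obj$labels)) {
    run_stage("score", function() {
      sc <- cfg$score
      mk_bas <- find_markers(norm, obj$labels, "BAS", min_pct = sc$min_pct)
      mk_lum <- find_markers(norm, obj$labels, "HRneg", min_pct = sc$min_pct)
      top_by_auc <- function(mk, n) mk$gene[order(mk$auc,
                                                  decreasing = TRUE)][seq_len(min(n, nrow(mk)))]
      bas_sig <- top_by_auc(mk_bas, sc$n_markers)
      lum_sig <- top_by_auc(mk_lum, sc$n_markers)
      complexity <- colSums(counts > 0)
      aps_bas <- adjusted_proportion_score(norm, bas_sig, complexity)
      aps_lum <- adjusted_proportion_score(norm, lum_sig, complexity)
      scores <- data.frame(
        cell = colnames(norm),
        module_bas = unname(module_score(norm, bas_sig, seed = cfg$seed)),
        module_lum = unname(module_score(norm, lum_sig, seed = cfg$seed)),
        raw_prop_bas = aps_bas$raw, adj_prop_bas = aps_bas$adjusted,
        raw_prop_lum = aps_lum$raw, adj_prop_lum = aps_lum$adjusted,
        stringsAsFactors = FALSE
      )
      truth <- obj$bundle$truth
      if (!is.null(truth)) {
        ccs <- cell_cycle_scores(norm, truth$s_genes, truth$g2m_genes,
                                 seed = cfg$seed)
        scores$s_score <- ccs$s_score
        scores$g2m_score <- ccs$g2m_score
        scores$phase <- ccs$phase
      }
      obj$markers <<- list(BAS = mk_bas, HRneg = mk_lum)
      obj$signatures <<- list(bas = bas_sig, lum = lum_sig)
      obj$scores <<- scores
      report$score <<- list(n_bas_markers = length(bas_sig),
                            n_lum_markers = length(lum_sig))
      if (!is.null(sc$rectangle) && !is.null(obj$umap)) {
        sel <- select_embedding_region(obj$umap, sc$rectangle)
        report$score$n_selected_region <<- length(sel)
        obj$region_cells <<- sel
      }
    })
  }

  ## ---- regulons ------------------------------------------------------------
  if (isTRUE(cfg$stages$regulons) && !is.null(obj$labels)) {
    run_stage("regulons", function() {
      regs <- if (!is.null(cfg$regulons$regulon_file)) {
        read_regulons(cfg$regulons$regulon_file)
      } else if (!is.null(obj$bundle$truth)) {
        obj$bundle$truth$regulons
      } else {
        NULL
      }
      if (is.null(regs)) return(invisible(NULL))
      act <- regulon_activity(norm, regs,
                              top_fraction = cfg$regulons$top_fraction)
      rss <- regulon_specificity_score(act, obj$labels)
      top <- suppressWarnings(
        top_regulons_per_cluster(rss, n = min(cfg$regulons$n_top, nrow(rss))))
      obj$regulon_activity <<- act
      obj$rss <<- rss
      obj$top_regulons <<- top
      report$regulons <<- list(
        n_regulons = nrow(rss),
        top_per_cluster = lapply(top$top, utils::head, 5L)
      )
    })
  }

  ## ---- trajectory ------------------------------------------------------------
  if (isTRUE(cfg$stages$trajectory) && !is.null(obj$labels)) {
    run_stage("trajectory", function() {
      tj <- cfg$trajectory
      lin <- infer_lineages(obj$embedding$scores, obj$labels, tj$origin)
      target <- if (tj$test_lineage %in% names(lin$lineages))
        tj$test_lineage else names(lin$lineages)[1]
      ptime <- compute_pseudotime(obj$embedding$scores,
                                  lin$lineages[[target]], obj$labels,
                                  refine_iterations = tj$refine_iterations)
      hvg4k <- select_hvg(counts, n = min(tj$n_hvg, nrow(counts)))
      assoc <- association_test(norm, ptime$pseudotime, genes = hvg4k,
                                n_knots = tj$n_knots)
      on_traj <- names(ptime$pseudotime)[!is.na(ptime$pseudotime)]
      lowexp_pass <- filter_trajectory_genes(
        counts[, on_traj, drop = FALSE], tj$min_count, tj$min_cells)
      sig <- assoc$gene[assoc$adjusted_p < tj$sig_alpha]
      sig <- intersect(sig, lowexp_pass)
      sm <- smooth_and_annotate(norm[sig, , drop = FALSE], ptime$pseudotime,
                                obj$labels[match(colnames(norm),
                                                 names(obj$labels))],
                                window = tj$window)
      pg6 <- pattern_groups(sm$smoothed, k = min(tj$k_fine, length(sig)))
      top40 <- utils::head(assoc$gene, tj$top_genes)
      sm40 <- smooth_and_annotate(norm[intersect(top40, rownames(norm)), ,
                                       drop = FALSE],
                                  ptime$pseudotime,
                                  obj$labels[match(colnames(norm),
                                                   names(obj$labels))],
                                  window = tj$window)
      pg3 <- pattern_groups(sm40$smoothed,
                            k = min(tj$k_coarse, nrow(sm40$smoothed)))
      obj$lineages <<- lin
      obj$pseudotime <<- ptime
      obj$association <<- assoc
      obj$smoothed <<- sm
      obj$patterns6 <<- pg6
      obj$patterns3 <<- pg3
      report$trajectory <<- list(
        n_lineages = length(lin$lineages),
        lineages = lapply(lin$lineages, paste, collapse = " -> "),
        tested_lineage = target,
        n_tested_genes = nrow(assoc),
        n_significant = length(sig),
        pattern_sizes_k6 = as.list(table(pg6$groups))
      )
    })
  }

  ## ---- transfer ------------------------------------------------------------
  if (isTRUE(cfg$stages$transfer) && !is.null(cfg$transfer$reference_dir)) {
    run_stage("transfer", function() {
      ref_counts <- read_counts_mtx(cfg$transfer$reference_dir)
      ref_labels <- readLines(file.path(cfg$transfer$reference_dir,
                                        "labels.txt"))
      tr <- transfer_labels(
        list(norm = log_normalize(ref_counts), labels = ref_labels),
        norm, n_pcs = cfg$transfer$n_pcs, k = cfg$transfer$k)
      obj$transfer <<- tr
      report$transfer <<- list(
        flow = flow_table(obj$labels, tr$predicted_id))
    })
  }

  ## ---- artifacts -----------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts_mtx(counts, cfg$out_dir)
    out_meta <- meta
    if (!is.null(obj$labels)) out_meta$cluster <- as.character(obj$labels)
    if (!is.null(obj$scores)) {
      out_meta <- cbind(out_meta, obj$scores[, setdiff(names(obj$scores),
                                                       "cell"), drop = FALSE])
    }
    utils::write.table(out_meta, file.path(cfg$out_dir, "cell_meta.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    if (!is.null(obj$umap)) {
      utils::write.table(data.frame(cell = rownames(obj$umap), obj$umap),
                         file.path(cfg$out_dir, "umap.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(obj$association)) {
      utils::write.table(obj$association,
                         file.path(cfg$out_dir, "association.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(report = report, objects = obj))
}
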