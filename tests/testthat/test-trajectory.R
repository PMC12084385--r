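test_that("lineage inference reproduces the exhaustive spanning-tree oracle", {
  # 2 clusters: a single lineage
  s2 <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
              matrix(rnorm(20, 5, 0.1), 10, 2))
  rownames(s2) <- paste0("c", 1:20)
  lab2 <- rep(c("o", "x"), each = 10)
  lin2 <- infer_lineages(s2, lab2, "o")
  expect_identical(lin2$lineages, list(x = c("o", "x")))

  # 3 collinear clusters with the origin at one end: one path
  s3 <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2),
              matrix(rnorm(10, 3, 0.05), 5, 2),
              matrix(rnorm(10, 6, 0.05), 5, 2))
  rownames(s3) <- paste0("c", 1:15)
  lab3 <- rep(c("a", "b", "c"), each = 5)
  lin3 <- infer_lineages(s3, lab3, "a")
  expect_identical(lin3$lineages, list(c = c("a", "b", "c")))

  # Y-shaped 5-centroid toy: MST compared against all labelled spanning
  # trees via Pruefer sequences (5^3 = 125 trees)
  cent <- rbind(a = c(0, 0), b = c(1, 0), c = c(2, 0),
                d = c(3, 1), e = c(3, -1))
  set.seed(4)
  pts <- cent[rep(1:5, each = 6), ] + matrix(rnorm(60, sd = 0.01), 30, 2)
  rownames(pts) <- paste0("c", 1:30)
  labs <- rep(rownames(cent), each = 6)
  lin <- infer_lineages(pts, labs, "a")
  expect_identical(names(lin$lineages), c("d", "e"))
  expect_identical(lin$lineages$d, c("a", "b", "c", "d"))
  expect_identical(lin$lineages$e, c("a", "b", "c", "e"))

  # oracle: best spanning tree weight over all Pruefer sequences
  emp_cent <- t(vapply(rownames(cent), function(cl)
    colMeans(pts[labs == cl, ]), numeric(2)))
  dmat <- as.matrix(dist(emp_cent))
  from_pruefer <- function(p) {
    n <- length(p) + 2
    degree <- rep(1L, n)
    for (i in p) degree[i] <- degree[i] + 1L
    edges <- matrix(0L, n - 1, 2)
    k <- 1L
    p2 <- p
    for (i in seq_along(p2)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, p2[i]); k <- k + 1L
      degree[leaf] <- 0L
      degree[p2[i]] <- degree[p2[i]] - 1L
    }
    edges[k, ] <- which(degree == 1L)
    edges
  }
  best <- Inf
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    e <- from_pruefer(c(i, j, k))
    best <- min(best, sum(dmat[e]))
  }
  got <- sum(dmat[as.matrix(lin$mst[, c("from", "to")])])
  expect_equal(got, best, tolerance = 1e-9)

  expect_error(infer_lineages(pts, labs, "zz"), "origin")
})

test_that("pseudotime is the arc length of orthogonal projections", {
  # three collinear clusters on a line; off-path probes are placed in
  # mirror-symmetric, x-balanced pairs so each cluster centroid stays exact
  cent <- rbind(a = c(0, 0), b = c(4, 0), c = c(10, 0))
  pts <- rbind(cent[rep(1:3, each = 4), ],
               pb1 = c(2, 1), pb2 = c(2, -1), pb3 = c(6, 1), pb4 = c(6, -1),
               pc1 = c(7, 2), pc2 = c(7, -2), pc3 = c(13, 2), pc4 = c(13, -2))
  rownames(pts)[1:12] <- sprintf("c%02d", 1:12)
  labs <- c(rep(c("a", "b", "c"), each = 4), rep("b", 4), rep("c", 4))
  res <- compute_pseudotime(pts, c("a", "b", "c"), labs)
  expect_equal(unname(res$pseudotime["c01"]), 0)
  expect_equal(unname(res$pseudotime["c09"]), 10)  # total path length
  # orthogonal projection: pseudotime equals the x coordinate on the path
  expect_equal(unname(res$pseudotime["pb1"]), 2)
  expect_equal(unname(res$pseudotime["pc1"]), 7)
  # beyond the terminal centroid the projection clamps to the endpoint
  expect_equal(unname(res$pseudotime["pc3"]), 10)

  # off-lineage cells get zero weight and NA pseudotime
  labs2 <- c(rep(c("a", "b", "z"), each = 4), rep("b", 4), rep("z", 4))
  res2 <- compute_pseudotime(pts, c("a", "b"), labs2)
  expect_true(all(is.na(res2$pseudotime[labs2 == "z"])))
  expect_true(all(res2$weights[labs2 == "z"] == 0))

  # refinement keeps the ordering of a clean linear arrangement
  res3 <- compute_pseudotime(pts, c("a", "b", "c"), labs,
                             refine_iterations = 3)
  expect_equal(order(res3$pseudotime[1:12]), order(res$pseudotime[1:12]))
})

test_that("association test has power, honest nulls and calibrated size", {
  set.seed(11)
  n <- 300
  pt <- setNames(runif(n), paste0("c", 1:n))
  # constant gene: statistic ~ 0, p ~ 1
  cm <- matrix(5, 1, n, dimnames = list("flat", names(pt)))
  a0 <- association_test(cm, pt)
  expect_lt(a0$statistic, 1e-8)
  expect_gt(a0$p_value, 0.99)

  # strongly linear gene: overwhelming significance
  lin <- matrix(10 * pt + rnorm(n, sd = 0.1), 1, n,
                dimnames = list("lin", names(pt)))
  expect_lt(association_test(lin, pt)$p_value, 1e-6)

  # size: 500 pure-noise genes against the pseudotime
  Y <- matrix(rnorm(500 * n), 500, n,
              dimnames = list(paste0("g", 1:500), names(pt)))
  a <- association_test(Y, pt, n_knots = 8)
  rate <- mean(a$p_value < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  expect_true(all(a$adjusted_p >= a$p_value - 1e-12))

  expect_error(association_test(Y[, 1:10], pt[1:10]), "fewer than 30")
  expect_error(association_test(Y, setNames(rep(1, n), names(pt))),
               "degenerate")
})

test_that("low-expression trajectory filter uses inclusive bounds", {
  m <- matrix(0L, 3, 25, dimnames = list(c("in20", "in19", "rich"),
                                         paste0("c", 1:25)))
  m["in20", 1:20] <- 1L
  m["in19", 1:19] <- 5L
  m["rich", ] <- 2L
  expect_identical(filter_trajectory_genes(m, min_count = 1, min_cells = 20),
                   c("in20", "rich"))
})

test_that("rolling windows smooth expression and annotate bins modally", {
  pt <- setNames(c(5, 1, 3, 2, 4, 6, 8, 7, 9, 10) / 10, paste0("c", 1:10))
  expr <- matrix(seq_len(20), 2, 10,
                 dimnames = list(c("g1", "g2"), names(pt)))
  labs <- setNames(c("A", "A", "A", "B", "B", "B", "C", "C", "C", "C"),
                   names(pt))
  sm <- smooth_and_annotate(expr, pt, labs[colnames(expr)], window = 3)
  ord <- names(sort(pt))
  expected_first <- mean(expr["g1", ord[1:3]])
  expect_equal(sm$smoothed["g1", 1], expected_first)
  expect_identical(ncol(sm$smoothed), 8L)
  # hand-computed rolling means for every bin
  for (i in 1:8) {
    expect_equal(sm$smoothed["g2", i], mean(expr["g2", ord[i:(i + 2)]]))
  }
  # modal annotation with earliest-cell tie-break
  expect_identical(sm$bin_annotation[1], "A")
  # bin of cells ranked 3:5 holds labels A,B,B -> B wins
  expect_identical(sm$bin_annotation[3],
                   names(which.max(table(labs[ord[3:5]]))))

  # full-width window: one bin equal to global means
  sm2 <- smooth_and_annotate(expr, pt, labs, window = 10)
  expect_identical(ncol(sm2$smoothed), 1L)
  expect_equal(sm2$smoothed[, 1], rowMeans(expr))
  cm <- matrix(4, 1, 10, dimnames = list("k", names(pt)))
  smc <- smooth_and_annotate(cm, pt, labs, window = 4)
  expect_true(all(smc$smoothed == 4))
  expect_error(smooth_and_annotate(expr, pt, labs, window = 11), "exceeds")
  expect_error(smooth_and_annotate(expr, pt, labs, window = 1), ">= 2")
})

test_that("average-linkage grouping matches a naive O(n^3) oracle", {
  set.seed(26)
  prof <- rbind(matrix(rep(c(2, 2, 0, 0), 3), 3, 4, byrow = TRUE),
                matrix(rep(c(0, 0, 2, 2), 3), 3, 4, byrow = TRUE),
                matrix(rnorm(24), 6, 4))
  prof <- prof + matrix(rnorm(48, sd = 0.05), 12, 4)
  rownames(prof) <- sprintf("p%02d", 1:12)
  colnames(prof) <- paste0("b", 1:4)

  pg <- pattern_groups(prof, k = 4)
  # antiphase step profiles split apart
  expect_identical(length(unique(pg$groups[1:3])), 1L)
  expect_identical(length(unique(pg$groups[4:6])), 1L)
  expect_false(pg$groups[1] == pg$groups[4])

  # duplicated rows always co-assigned
  prof2 <- rbind(prof, p13 = prof["p01", ])
  pg2 <- pattern_groups(prof2, k = 5)
  expect_identical(unname(pg2$groups["p13"]), unname(pg2$groups["p01"]))

  # naive average-linkage agglomeration oracle on the z-scored profiles
  z <- t(scale(t(prof)))
  naive_heights <- local({
    clusters <- as.list(seq_len(nrow(z)))
    d <- as.matrix(dist(z))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < best[1]) best <- c(dd, j, i)
      }
      heights <- c(heights, best[1])
      clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
      clusters[[best[3]]] <- NULL
    }
    heights
  })
  expect_equal(sort(pg$hclust$height), sort(naive_heights), tolerance = 1e-9)
  expect_error(pattern_groups(prof, k = 20), "exceeds")
})

test_that("the synthetic conversion is recovered end to end", {
  run <- default_run()
  o <- run$objects
  r <- run$report
  tr <- o$bundle$truth

  # forked topology: two lineages through the intermediates, split after INT2
  expect_identical(length(o$lineages$lineages), 2L)
  expect_identical(o$lineages$lineages$HRneg, c("BAS", "INT1", "INT2", "HRneg"))
  expect_identical(o$lineages$lineages$HRpos, c("BAS", "INT1", "INT2", "HRpos"))

  # pseudotime tracks the true conversion time
  pt <- o$pseudotime$pseudotime
  ok <- !is.na(pt)
  rho <- cor(pt[ok], tr$t_true[names(pt)[ok]], method = "spearman")
  expect_gte(rho, 0.9)

  # housekeeping genes rank at the bottom of the association ordering
  asc <- o$association
  hk <- names(tr$gene_program)[tr$gene_program == "housekeeping"]
  hk_ranks <- which(asc$gene %in% hk)
  expect_gte(median(hk_ranks) / nrow(asc), 0.5)
  bottom_decile <- asc$gene[asc$statistic <=
                              quantile(asc$statistic, 0.10)]
  expect_gte(mean(bottom_decile %in% hk), 0.95)
})
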