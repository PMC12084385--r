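test_that("marker AUC equals brute-force concordant-pair counting", {
  # 8-cell toy, 4 in / 4 out
  norm <- rbind(
    sep   = c(5, 6, 7, 8, 1, 2, 3, 4),   # perfect separation
    same  = rep(2, 8),                    # identical values
    mix   = c(3, 1, 4, 2, 2, 4, 1, 3)
  )
  colnames(norm) <- paste0("c", 1:8)
  labels <- rep(c("in", "out"), each = 4)
  mk <- find_markers(norm, labels, "in", min_pct = 0, only_pos = FALSE)
  brute_auc <- function(x_in, x_out) {
    mean(outer(x_in, x_out, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  for (g in rownames(norm)) {
    expect_equal(mk$auc[mk$gene == g],
                 brute_auc(norm[g, 1:4], norm[g, 5:8]), tolerance = 1e-12)
  }
  expect_equal(mk$auc[mk$gene == "sep"], 1)
  expect_equal(mk$auc[mk$gene == "same"], 0.5)

  # AUC is invariant to strictly monotone transforms
  mk2 <- find_markers(exp(norm), labels, "in", min_pct = 0, only_pos = FALSE)
  expect_equal(mk$auc[order(mk$gene)], mk2$auc[order(mk2$gene)])

  # only_pos + min.pct filtering and log2FC ordering
  norm2 <- rbind(hi = c(3, 3, 3, 0, 0, 0), sparse = c(2, 0, 0, 0, 0, 0),
                 dn = c(0, 0, 0, 3, 3, 3))
  colnames(norm2) <- paste0("c", 1:6)
  mk3 <- find_markers(norm2, rep(c("a", "b"), each = 3), "a", min_pct = 0.4)
  expect_identical(mk3$gene, "hi")   # "sparse" fails min.pct, "dn" not positive
  expect_error(find_markers(norm2, c("a", rep("b", 5)), "a"), "at least 2")
})

test_that("module scores match a straight-line reimplementation", {
  set.seed(14)
  norm <- matrix(rexp(50 * 12), 50, 12,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:12)))
  gene_set <- c("g03", "g17", "g41")
  got <- module_score(norm, gene_set, n_bins = 2, n_ctrl = 5, seed = 7)

  # oracle: recompute bins, control draws and the score from the definition
  avg <- rowMeans(norm)
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(norm) / 2))
  bin <- pmin(pmax(bin, 1L), 2L)
  names(bin) <- rownames(norm)
  set.seed(7)
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    if (length(pool) <= 5) pool else sample(pool, 5)
  }))
  want <- colMeans(norm[gene_set, ]) - colMeans(norm[ctrl, ])
  expect_equal(unname(got), unname(want), tolerance = 1e-12)

  # all genes as the set: controls come from the same pool, score ~ 0
  s_all <- module_score(norm, rownames(norm), n_bins = 5, n_ctrl = 20, seed = 1)
  expect_lt(max(abs(s_all)), 0.35)
  # constant matrix: exactly zero
  cm <- matrix(3, 20, 4, dimnames = list(paste0("g", 1:20), paste0("c", 1:4)))
  expect_true(all(module_score(cm, paste0("g", 1:5), n_bins = 4, seed = 2) == 0))
  expect_warning(module_score(norm, c("g01", "nope"), seed = 2), "missing")
  expect_error(module_score(norm, "absent"), "no genes")
})

test_that("random gene sets score near zero on average", {
  set.seed(30)
  norm <- matrix(rexp(200 * 20), 200, 20,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:20)))
  means <- vapply(1:50, function(s) {
    set.seed(s)
    mean(module_score(norm, sample(rownames(norm), 10), seed = s))
  }, numeric(1))
  ci <- mean(means) + c(-1, 1) * 3 * sd(means) / sqrt(50)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("combined luminal score is the union-set module score", {
  set.seed(15)
  norm <- matrix(rexp(40 * 10), 40, 10,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:10)))
  a <- c("g01", "g05", "g09")
  b <- c("g20", "g31")
  expect_equal(combined_luminal_score(norm, a, b, seed = 3),
               module_score(norm, union(a, b), seed = 3))
  w <- testthat::capture_warnings(
    s <- combined_luminal_score(norm, a, c("zz"), seed = 3))
  expect_true(any(grepl("empty", w)))
  expect_equal(s, module_score(norm, a, seed = 3))
  expect_error(combined_luminal_score(norm, "zz", "yy"), "both")
})

test_that("Huber IRLS matches an independent oracle and downweights outliers", {
  # exact line: perfect fit, all weights one
  x <- 1:10
  fit <- robust_linear_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_true(all(fit$weights == 1))
  expect_true(fit$converged)

  set.seed(18)
  x2 <- seq(0, 5, length.out = 20)
  y2 <- 1.5 * x2 - 2 + rnorm(20, sd = 0.2)
  y2[7] <- y2[7] + 25
  fit2 <- robust_linear_fit(x2, y2)
  expect_lt(fit2$weights[7], min(fit2$weights[-7]))

  # independent IRLS oracle iterated to 1e-12
  oracle <- function(x, y) {
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    repeat {
      r <- y - X %*% beta
      s <- median(abs(r)) / 0.6745
      w <- pmin(1, 1.345 * s / abs(r))
      w[abs(r) < 1e-300] <- 1
      W <- diag(as.vector(w))
      beta_new <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
      if (max(abs(beta_new - beta)) < 1e-12) return(beta_new)
      beta <- beta_new
    }
  }
  ref <- oracle(x2, y2)
  expect_equal(fit2$intercept, ref[1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit2$slope, ref[2], tolerance = 1e-8, ignore_attr = TRUE)

  # cross-check against the classical M-estimation implementation
  skip_if_not_installed("MASS")
  rf <- MASS::rlm(y2 ~ x2, k = 1.345, maxit = 100, acc = 1e-10)
  expect_equal(fit2$slope, unname(coef(rf)[2]), tolerance = 1e-3)

  expect_error(robust_linear_fit(rep(1, 5), rnorm(5)), "constant")
  expect_error(robust_linear_fit(1:2, 1:2), "at least 3")
})

test_that("adjusted proportion scores match the end-to-end oracle", {
  # 30-cell toy with a constructed complexity confound
  set.seed(19)
  n_cells <- 30
  complexity <- round(seq(200, 2000, length.out = n_cells))
  markers <- sprintf("m%02d", 1:8)
  norm <- matrix(0, 20, n_cells,
                 dimnames = list(c(markers, sprintf("f%02d", 1:12)),
                                 sprintf("c%02d", 1:n_cells)))
  for (g in seq_len(20)) {
    norm[g, ] <- rexp(n_cells) + 0.002 * complexity * runif(1)
  }
  norm[3, 5] <- 40  # gross outlier cell

  res <- adjusted_proportion_score(norm, markers, complexity)

  # oracle: independent medians, strict counting, IRLS residual recentring
  thr <- apply(norm[markers, ], 1, median)
  raw <- sapply(seq_len(n_cells), function(i) mean(norm[markers, i] > thr))
  X <- cbind(1, complexity)
  beta <- solve(t(X) %*% X, t(X) %*% raw)
  repeat {
    r <- raw - X %*% beta
    s <- median(abs(r)) / 0.6745
    w <- if (s < 1e-12) rep(1, n_cells) else pmin(1, 1.345 * s / abs(r))
    w[abs(r) < 1e-300] <- 1
    W <- diag(as.vector(w))
    beta_new <- solve(t(X) %*% W %*% X, t(X) %*% W %*% raw)
    if (max(abs(beta_new - beta)) < 1e-13) break
    beta <- beta_new
  }
  adj_oracle <- as.vector(raw - X %*% beta_new) + mean(raw)
  expect_equal(res$raw, raw, tolerance = 1e-12)
  expect_equal(res$adjusted, adj_oracle, tolerance = 1e-8)

  # Huber-weighted residual mean is zero against the fitted line
  fit <- attr(res, "fit")
  expect_lt(abs(sum(fit$weights * fit$residuals)), 1e-8)

  # boundary semantics: all above -> 1; exactly at threshold -> 0
  m2 <- matrix(c(5, 5, 1, 1, 3, 3), 2, 3,
               dimnames = list(c("a", "b"), c("hi", "lo", "at")))
  r2 <- suppressWarnings(adjusted_proportion_score(m2, c("a", "b"),
                                                   complexity = c(10, 20, 30)))
  expect_equal(r2$raw[1], 1)
  expect_equal(r2$raw[3], 0)   # ties at the median count as not expressed
  expect_error(adjusted_proportion_score(m2, "zz", 1:3), "no marker")
})

test_that("cell cycle phases follow the score rules and track truth", {
  run <- default_run()
  o <- run$objects
  truth <- o$bundle$truth
  ccs <- cell_cycle_scores(o$norm, truth$s_genes, truth$g2m_genes, seed = 7)
  expect_true(all(ccs$phase %in% c("G1", "S", "G2M")))
  neg <- ccs$s_score < 0 & ccs$g2m_score < 0
  expect_true(all(ccs$phase[neg] == "G1"))
  pos <- !neg
  expect_true(all(ccs$phase[pos] ==
                    ifelse(ccs$s_score[pos] >= ccs$g2m_score[pos], "S", "G2M")))
  cyc <- truth$cycling[ccs$cell]
  rate_cyc <- mean(ccs$phase[cyc] != "G1")
  rate_not <- mean(ccs$phase[!cyc] != "G1")
  expect_gte(rate_cyc, 2 * rate_not)
})

test_that("embedding-region selection is exact pointwise containment", {
  coords <- cbind(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3))
  rownames(coords) <- paste0("c", 1:4)
  expect_identical(select_embedding_region(coords, c(-1, 4, -1, 4)),
                   rownames(coords))
  expect_identical(select_embedding_region(coords, c(0.5, 2.5, 0.5, 2.5)),
                   c("c2", "c3"))
  expect_identical(select_embedding_region(coords, c(1, 1, 1, 1)), "c2")
  expect_error(select_embedding_region(coords, c(9, 10, 9, 10)), "empty")
  expect_error(select_embedding_region(coords, c(Inf, 1, 0, 1)))
})
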