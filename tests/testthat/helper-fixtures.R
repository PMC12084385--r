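# Shared fixtures: toy matrices built in code, plus one memoised default
# pipeline run reused by the truth-recovery tests.

.cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- suppressWarnings(run_pipeline(pipeline_config(seed = 7L)))
  }
  .cache$run
}

default_bundle <- function() default_run()$objects$bundle

# deterministic genes x cells toy count matrix
toy_counts <- function(n_genes = 10L, n_cells = 6L, seed = 1L,
                       lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# two well-separated Gaussian blobs in d dimensions (cells x d scores)
toy_blobs <- function(n_per = 40L, d = 5L, sep = 20, seed = 3L) {
  set.seed(seed)
  s <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep / sqrt(d)), n_per, d))
  rownames(s) <- sprintf("cell%03d", seq_len(2 * n_per))
  list(scores = s, label = rep(c("A", "B"), each = n_per))
}

# simple mean silhouette of a binary grouping on a score matrix
mean_silhouette <- function(scores, groups) {
  d <- as.matrix(dist(scores))
  sil <- vapply(seq_len(nrow(scores)), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

six_programs <- c("bas_early", "bas_late", "int_early", "int_late",
                  "lum_early", "lum_late")
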