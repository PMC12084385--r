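#' Simulation configuration for the lineage-conversion generator
#'
#' Builds a validated configuration for [simulate_dataset()]. Defaults encode
#' a desk-scale Smart-seq2-like experiment: ~500 index-sorted cells in three
#' batches undergoing a basal-to-luminal conversion along a latent time
#' `t in [0,1]`, with heterogeneous per-gene switch times, a proliferative
#' mid-conversion subpopulation, and a minority hormone-receptor-positive
#' (HRpos) terminal branch that forks the trajectory.
#'
#' Gene programs: `basal` genes switch off along t (decreasing sigmoid),
#' `luminal` genes switch on (increasing sigmoid), `intermediate` genes are
#' transiently induced (Gaussian bump), `hr_pos` genes switch on late and only
#' on the HRpos branch, `cell_cycle` genes are constant-low with a bonus in
#' cycling cells, and `housekeeping` genes are constant. Each switching
#' program is split into an "early" and a "late" half by drawing the per-gene
#' switch time tau from program-specific windows, giving the six temporal
#' patterns (bas/int/lum x early/late) recovered downstream.
#'
#' @param n_cells number of cells.
#' @param n_batches number of batches (batch 1 is the clean reference).
#' @param n_basal,n_intermediate,n_luminal,n_hr_pos,n_cell_cycle,n_housekeeping
#'   gene-program sizes; `n_housekeeping` includes 10 mitochondrial (`mt-`)
#'   genes and the `Dcpp1` salivary contaminant gene.
#' @param switch_sharpness logistic slope k of the on/off switches.
#' @param tau_windows named list of length-2 numeric ranges in \[0,1\], one per
#'   switching program, from which per-gene switch times are drawn.
#' @param off_fraction ratio mu_low / mu_high for switching genes.
#' @param nb_dispersion negative-binomial size (shape) parameter; larger values
#'   approach Poisson noise.
#' @param library_size_meanlog,library_size_sdlog log-normal library size.
#' @param mito_share expected fraction of counts from mitochondrial genes.
#' @param cycling_fraction_at_mid_t peak probability that a mid-conversion cell
#'   is cycling; the probability decays as a Gaussian in t around the late-
#'   intermediate stage (t = 0.625), where proliferation peaks.
#' @param batch_effect_sd sd of per-gene log-normal multiplicative batch
#'   factors (batch 1 unperturbed).
#' @param hr_branch_fraction probability a cell belongs to the HRpos branch.
#' @param gfp_pos_fraction fraction of cells that are GFP-positive (induced);
#'   GFP-negative cells sit at the trajectory endpoints only.
#' @param gate_quantiles length-2 quantiles (low, high) of the surrogate
#'   surface markers used to draw the rectangular FACS gates.
#' @param discrete_timepoints if TRUE, t is drawn from four discrete chase
#'   timepoints instead of a continuum (off by default).
#' @param seed integer RNG seed; identical seeds give identical bundles.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 500L,
                       n_batches = 3L,
                       n_basal = 60L,
                       n_intermediate = 40L,
                       n_luminal = 60L,
                       n_hr_pos = 60L,
                       n_cell_cycle = 40L,
                       n_housekeeping = 1770L,
                       switch_sharpness = 30,
                       tau_windows = list(
                         bas_early = c(0.18, 0.32),
                         bas_late  = c(0.43, 0.57),
                         int_early = c(0.33, 0.42),
                         int_late  = c(0.58, 0.67),
                         lum_early = c(0.18, 0.32),
                         lum_late  = c(0.68, 0.82),
                         hr_pos    = c(0.65, 0.80)
                       ),
                       off_fraction = 0.05,
                       nb_dispersion = 2,
                       library_size_meanlog = log(5e5),
                       library_size_sdlog = 0.25,
                       mito_share = 0.05,
                       cycling_fraction_at_mid_t = 0.5,
                       batch_effect_sd = 0.15,
                       hr_branch_fraction = 0.2,
                       gfp_pos_fraction = 0.75,
                       gate_quantiles = c(0.35, 0.65),
                       discrete_timepoints = FALSE,
                       seed = 7L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_batches = as.integer(n_batches),
    n_basal = as.integer(n_basal), n_intermediate = as.integer(n_intermediate),
    n_luminal = as.integer(n_luminal), n_hr_pos = as.integer(n_hr_pos),
    n_cell_cycle = as.integer(n_cell_cycle),
    n_housekeeping = as.integer(n_housekeeping),
    switch_sharpness = switch_sharpness, tau_windows = tau_windows,
    off_fraction = off_fraction, nb_dispersion = nb_dispersion,
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    mito_share = mito_share,
    cycling_fraction_at_mid_t = cycling_fraction_at_mid_t,
    batch_effect_sd = batch_effect_sd,
    hr_branch_fraction = hr_branch_fraction,
    gfp_pos_fraction = gfp_pos_fraction,
    gate_quantiles = gate_quantiles,
    discrete_timepoints = isTRUE(discrete_timepoints),
    seed = as.integer(seed)
  )
  counts <- c("n_cells", "n_batches", "n_basal", "n_intermediate", "n_luminal",
              "n_hr_pos", "n_cell_cycle", "n_housekeeping")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("configuration error: `", f, "` must be >= 1")
  }
  props <- c("off_fraction", "mito_share", "cycling_fraction_at_mid_t",
             "hr_branch_fraction", "gfp_pos_fraction")
  for (f in props) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("configuration error: `", f, "` must lie in [0, 1]")
    }
  }
  if (cfg$nb_dispersion <= 0) stop("configuration error: nb_dispersion must be > 0")
  if (cfg$switch_sharpness <= 0) stop("configuration error: switch_sharpness must be > 0")
  if (cfg$batch_effect_sd < 0) stop("configuration error: batch_effect_sd must be >= 0")
  if (cfg$n_housekeeping < 12L) {
    stop("configuration error: n_housekeeping must be >= 12 ",
         "(10 mt- genes, Dcpp1 and at least one generic housekeeping gene)")
  }
  for (w in names(cfg$tau_windows)) {
    tw <- cfg$tau_windows[[w]]
    if (length(tw) != 2L || any(tw < 0) || any(tw > 1) || tw[1] > tw[2]) {
      stop("configuration error: tau window `", w, "` must be an ordered range in [0,1]")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Expected expression of a gene at a given conversion time
#'
#' The per-gene mean model before library-size scaling. Basal genes follow a
#' decreasing logistic in t centered at the gene's switch time tau (value
#' `(mu_low + mu_high)/2` at `t = tau`), luminal and hr_pos genes an increasing
#' logistic, intermediate genes a transient Gaussian bump of width
#' `bump_width`, housekeeping genes are exactly constant at `mu_high`, and
#' cell-cycle genes sit at `mu_low` unless the cell is cycling.
#'
#' @param gene_params list with `program` (one of `bas_early`, `bas_late`,
#'   `int_early`, `int_late`, `lum_early`, `lum_late`, `hr_pos`, `cc`,
#'   `housekeeping`), `tau`, `mu_low`, `mu_high`, `k`.
#' @param t conversion time(s) in \[0, 1\].
#' @param cycling logical, only consulted for `cc` genes.
#' @param bump_width sd of the transient bump for intermediate genes.
#' @return non-negative mean expression, vectorized over `t`.
#' @export
program_mean <- function(gene_params, t, cycling = FALSE, bump_width = 0.12) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  p <- gene_params
  if (p$mu_low > p$mu_high) stop("mu_low must be <= mu_high")
  span <- p$mu_high - p$mu_low
  switch(p$program,
    housekeeping = rep(p$mu_high, length(t)),
    bas_early = ,
    bas_late = p$mu_low + span * (1 - stats::plogis(p$k * (t - p$tau))),
    lum_early = ,
    lum_late = ,
    hr_pos = p$mu_low + span * stats::plogis(p$k * (t - p$tau)),
    int_early = ,
    int_late = p$mu_low + span * exp(-(t - p$tau)^2 / (2 * bump_width^2)),
    cc = rep(if (isTRUE(cycling)) p$mu_high else p$mu_low, length(t)),
    stop("unknown gene program: ", p$program)
  )
}

# Canonical marker names seeded at the head of each program so downstream
# cluster naming and FACS surrogates refer to real genes.
.program_gene_names <- function(cfg) {
  pad <- function(prefix, n, canon = character()) {
    n_extra <- n - length(canon)
    if (n_extra < 0) canon <- canon[seq_len(n)]
    c(canon[seq_len(min(n, length(canon)))],
      if (n_extra > 0) sprintf("%s%03d", prefix, seq_len(n_extra)))
  }
  list(
    basal = pad("Basg", cfg$n_basal,
                c("Krt5", "Krt14", "Acta2", "Myh11", "Trp63", "Itga6", "Oxtr", "Mylk")),
    intermediate = pad("Intg", cfg$n_intermediate, c("Aldh1a3", "Sox10")),
    luminal = {
      # pan-luminal canon seeds the early (shared) half, the secretory
      # HRneg-specific canon the late half
      n_e <- ceiling(cfg$n_luminal / 2)
      c(pad("Lumg", n_e, c("Krt8", "Krt18", "Krt19", "Epcam")),
        pad("Lumn", cfg$n_luminal - n_e, c("Elf5", "Kit", "Cd14", "Foxc1")))
    },
    hr_pos = pad("Hrg", cfg$n_hr_pos, c("Esr1", "Pgr", "Prlr", "Cited1")),
    cell_cycle = pad("Ccg", cfg$n_cell_cycle,
                     c("Mki67", "Top2a", "Ccnb1", "Cdk1", "Mcm2", "Pcna", "Birc5", "Bub1")),
    housekeeping = c(sprintf("mt-Gene%02d", 1:10), "Dcpp1",
                     pad("Hkg", cfg$n_housekeeping - 11L, c("Actb", "Gapdh")))
  )
}

#' Simulate a lineage-conversion Smart-seq2-like dataset
#'
#' Draws negative-binomial counts for `n_cells` cells along a latent
#' basal-to-luminal conversion time, with library-size variation, per-gene
#' multiplicative batch effects (batch 1 left unperturbed as the reference),
#' a transiently cycling mid-conversion subpopulation, and an HRpos terminal
#' branch. GFP-positive (induced) cells span the whole time range; GFP-negative
#' (wild-type) cells occupy only the basal (t ~ 0) and luminal (t ~ 1)
#' endpoints. FACS gates are derived from the cells' normalized expression of
#' the surrogate surface markers Epcam (EpCAM) and Itga6 (CD49f).
#'
#' @param config a [sim_config()] object.
#' @return a `sim_bundle` list with elements
#'   \describe{
#'     \item{counts}{genes x cells integer matrix.}
#'     \item{meta}{per-cell data.frame: `cell`, `batch`, `plate`, `gate`,
#'       `gfp`, `timepoint`.}
#'     \item{truth}{ground truth: `t_true`, `branch`, `cycling`, `stage`
#'       (BAS/INT1/INT2/HRneg/HRpos from t and branch), `gene_program`,
#'       `gene_params`, `regulons`, `regulon_activity`, `s_genes`,
#'       `g2m_genes`, `facs_thresholds`.}
#'   }
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed)

  nm <- .program_gene_names(cfg)
  genes <- unlist(nm, use.names = FALSE)
  n_genes <- length(genes)
  n <- cfg$n_cells

  ## --- cell-level latent state ------------------------------------------
  gfp <- stats::runif(n) < cfg$gfp_pos_fraction
  t_true <- numeric(n)
  # Converting cells dwell at semi-stable transcriptional states (basal, two
  # intermediates, luminal) rather than spreading uniformly: draw t from a
  # mixture of four attractor bumps plus a uniform in-transit component.
  n_pos <- sum(gfp)
  from_bump <- stats::runif(n_pos) < 0.85
  centers <- c(0.125, 0.375, 0.625, 0.875)
  t_pos <- ifelse(from_bump,
                  centers[sample.int(4L, n_pos, replace = TRUE)] +
                    stats::rnorm(n_pos, 0, 0.085),
                  stats::runif(n_pos))
  t_true[gfp] <- pmin(pmax(t_pos, 0), 1)
  n_neg <- sum(!gfp)
  at_basal_end <- stats::runif(n_neg) < 0.5
  t_neg <- ifelse(at_basal_end, stats::runif(n_neg, 0, 0.05),
                  stats::runif(n_neg, 0.95, 1))
  t_true[!gfp] <- t_neg
  if (cfg$discrete_timepoints) {
    weeks <- c(1, 3, 4, 6)
    idx <- findInterval(t_true, c(-Inf, 0.25, 0.5, 0.75))
    t_true <- (weeks[idx] + stats::runif(n, -0.4, 0.4) - 1) / 5.4
    t_true <- pmin(pmax(t_true, 0), 1)
  }
  branch <- ifelse(stats::runif(n) < cfg$hr_branch_fraction, "HRpos", "HRneg")
  p_cyc <- cfg$cycling_fraction_at_mid_t * exp(-(t_true - 0.625)^2 / (2 * 0.12^2))
  cycling <- stats::runif(n) < p_cyc
  batch <- sample(rep_len(seq_len(cfg$n_batches), n))
  plate <- paste0("b", batch, "_p", 1L + (seq_len(n) %% 2L))
  cells <- sprintf("cell%04d", seq_len(n))

  stage <- ifelse(t_true < 0.25, "BAS",
           ifelse(t_true < 0.50, "INT1",
           ifelse(t_true < 0.75, "INT2",
           ifelse(branch == "HRpos", "HRpos", "HRneg"))))

  ## --- gene-level parameters --------------------------------------------
  half_split <- function(n, early, late) {
    n_early <- ceiling(n / 2)
    c(rep(early, n_early), rep(late, n - n_early))
  }
  program <- c(
    half_split(cfg$n_basal, "bas_early", "bas_late"),
    half_split(cfg$n_intermediate, "int_early", "int_late"),
    half_split(cfg$n_luminal, "lum_early", "lum_late"),
    rep("hr_pos", cfg$n_hr_pos),
    rep("cc", cfg$n_cell_cycle),
    rep("housekeeping", cfg$n_housekeeping)
  )
  names(program) <- genes
  # Surrogate surface markers must rise/fall across the whole conversion for
  # gating: pin Epcam to an early-rising and Itga6 to a late-falling switch.
  # (Tiny configs may not carry the named genes; fall back to program heads.)
  if ("Epcam" %in% names(program)) program[["Epcam"]] <- "lum_early"
  if ("Itga6" %in% names(program)) program[["Itga6"]] <- "bas_late"
  epcam_gene <- if ("Epcam" %in% names(program)) "Epcam" else
    names(program)[program == "lum_early"][1]
  itga6_gene <- if ("Itga6" %in% names(program)) "Itga6" else
    names(program)[match(TRUE, program %in% c("bas_late", "bas_early"))]

  mu_high <- stats::rlnorm(n_genes, meanlog = log(10), sdlog = 0.6)
  names(mu_high) <- genes
  # Keep the expected mitochondrial share near `mito_share`.
  mito <- grepl("^mt-", genes)
  exp_total <- sum(mu_high[!mito])
  mu_high[mito] <- cfg$mito_share * exp_total / ((1 - cfg$mito_share) * sum(mito))
  mu_high[["Dcpp1"]] <- 0.002
  mu_high[[epcam_gene]] <- stats::median(mu_high) * 4
  mu_high[[itga6_gene]] <- stats::median(mu_high) * 4

  tau <- numeric(n_genes)
  for (pr in names(cfg$tau_windows)) {
    i <- which(program == pr)
    tau[i] <- stats::runif(length(i), cfg$tau_windows[[pr]][1], cfg$tau_windows[[pr]][2])
  }
  k_gene <- cfg$switch_sharpness * stats::runif(n_genes, 0.8, 1.2)
  mu_low <- cfg$off_fraction * mu_high
  # Cycling roughly triples cell-cycle transcript abundance; keeping the
  # contrast moderate leaves proliferation a secondary axis inside the
  # intermediate clusters instead of a cluster of its own.
  mu_low[program == "cc"] <- 0.3 * mu_high[program == "cc"]

  gene_params <- data.frame(
    gene = genes, program = unname(program), tau = tau,
    mu_low = unname(mu_low), mu_high = unname(mu_high), k = k_gene,
    stringsAsFactors = FALSE
  )

  # Early luminal genes are the pan-luminal identity shared by both terminal
  # fates; the late luminal program is the terminal secretory (HRneg) one and
  # is suppressed on the HRpos branch as the hormone-sensing identity is
  # installed. This branch-exclusive late program is what makes the two
  # terminal fates diverge after the intermediate stage.
  hrneg_specific <- program == "lum_late"
  gene_params$hrneg_specific <- hrneg_specific
  late_suppress <- 1 - stats::plogis(cfg$switch_sharpness * (t_true - 0.70))

  ## --- expected expression ----------------------------------------------
  M <- matrix(0, n_genes, n, dimnames = list(genes, cells))
  for (g in seq_len(n_genes)) {
    pars <- list(program = program[[g]], tau = tau[g], mu_low = mu_low[[g]],
                 mu_high = mu_high[[g]], k = k_gene[g])
    M[g, ] <- switch(program[[g]],
      cc = ifelse(cycling, mu_high[[g]], mu_low[[g]]),
      hr_pos = ifelse(branch == "HRpos",
                      program_mean(pars, t_true), mu_low[[g]]),
      program_mean(pars, t_true))
    if (hrneg_specific[g]) {
      on_hrpos <- branch == "HRpos"
      M[g, on_hrpos] <- pmax(M[g, on_hrpos] * late_suppress[on_hrpos],
                             mu_low[[g]])
    }
  }

  batch_fac <- matrix(1, n_genes, cfg$n_batches)
  if (cfg$n_batches > 1L && cfg$batch_effect_sd > 0) {
    batch_fac[, -1L] <- exp(matrix(
      stats::rnorm(n_genes * (cfg$n_batches - 1L), 0, cfg$batch_effect_sd),
      n_genes))
  }

  lib <- stats::rlnorm(n, cfg$library_size_meanlog, cfg$library_size_sdlog)
  counts <- matrix(0L, n_genes, n, dimnames = list(genes, cells))
  for (i in seq_len(n)) {
    rel <- M[, i] * batch_fac[, batch[i]]
    mu_i <- lib[i] * rel / sum(rel)
    counts[, i] <- stats::rnbinom(n_genes, size = cfg$nb_dispersion, mu = mu_i)
  }

  ## --- FACS gating from surrogate markers -------------------------------
  lognorm <- log1p(sweep(counts[c(epcam_gene, itga6_gene), , drop = FALSE], 2,
                         colSums(counts), "/") * 1e4)
  thr <- list(
    epcam = stats::quantile(lognorm[epcam_gene, ], cfg$gate_quantiles,
                            names = FALSE),
    itga6 = stats::quantile(lognorm[itga6_gene, ], cfg$gate_quantiles,
                            names = FALSE)
  )
  gate <- assign_facs_gate(lognorm[epcam_gene, ], lognorm[itga6_gene, ], thr)

  ## --- ground-truth regulons --------------------------------------------
  reg_programs <- c("bas_early", "bas_late", "lum_early", "lum_late", "hr_pos", "cc")
  regulons <- list()
  activity <- matrix(0, n, length(reg_programs),
                     dimnames = list(cells, character(length(reg_programs))))
  for (j in seq_along(reg_programs)) {
    pr <- reg_programs[j]
    gset <- genes[program == pr]
    tf <- gset[1]
    regulons[[tf]] <- gset
    mid <- mean(cfg$tau_windows[[if (pr == "cc") "int_early" else pr]])
    act <- switch(pr,
      bas_early = ,
      bas_late = 1 - stats::plogis(cfg$switch_sharpness * (t_true - mid)),
      lum_early = ,
      lum_late = stats::plogis(cfg$switch_sharpness * (t_true - mid)),
      hr_pos = ifelse(branch == "HRpos",
                      stats::plogis(cfg$switch_sharpness * (t_true - mid)), 0),
      cc = as.numeric(cycling))
    activity[, j] <- act
    colnames(activity)[j] <- tf
  }

  cc_genes <- genes[program == "cc"]
  meta <- data.frame(
    cell = cells, batch = batch, plate = plate, gate = gate,
    gfp = ifelse(gfp, "GFPpos", "GFPneg"),
    timepoint = if (cfg$discrete_timepoints)
      c(1, 3, 4, 6)[findInterval(t_true, c(-Inf, 0.25, 0.5, 0.75))] else NA_real_,
    stringsAsFactors = FALSE
  )
  truth <- list(
    t_true = stats::setNames(t_true, cells),
    branch = stats::setNames(branch, cells),
    cycling = stats::setNames(cycling, cells),
    stage = stats::setNames(stage, cells),
    gene_program = program,
    gene_params = gene_params,
    regulons = regulons,
    regulon_activity = activity,
    s_genes = cc_genes[seq_len(floor(length(cc_genes) / 2))],
    g2m_genes = cc_genes[(floor(length(cc_genes) / 2) + 1):length(cc_genes)],
    facs_thresholds = thr
  )
  structure(list(counts = counts, meta = meta, truth = truth, config = cfg),
            class = "sim_bundle")
}

#' Assign rectangular FACS gates from two surrogate surface markers
#'
#' Mirrors index sorting on EpCAM/CD49f: luminal cells are
#' EpCAM-high/CD49f-low, basal cells EpCAM-low/CD49f-high, and everything else
#' falls in the intermediate gate. The thresholds partition the plane, so
#' every cell receives exactly one label.
#'
#' @param epcam,itga6 numeric vectors of normalized surrogate-marker levels.
#' @param thresholds list with numeric length-2 elements `epcam` and `itga6`
#'   giving the (low, high) gate boundaries for each marker.
#' @return character vector in `{basal, intermediate, luminal}`.
#' @export
assign_facs_gate <- function(epcam, itga6, thresholds) {
  stopifnot(length(epcam) == length(itga6))
  ep <- thresholds$epcam
  it <- thresholds$itga6
  ifelse(epcam >= ep[2] & itga6 <= it[1], "luminal",
  ifelse(epcam <= ep[1] & itga6 >= it[2], "basal", "intermediate"))
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(unique(x$meta$batch)), "batches\n")
  cat("  stages:", paste(names(table(x$truth$stage)),
                         table(x$truth$stage), collapse = ", "), "\n")
  invisible(x)
}
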