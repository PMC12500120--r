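# Two-stage calibration of the whole-brain model against a target
# functional-connectivity matrix and mean Kuramoto synchrony: first a
# homogeneous grid search over the global coupling G, then a heterogeneous
# grid search over (bias, scale) given a heterogeneity vector beta.

#' Goodness-of-fit score
#'
#' `score = r_FC * (1 - |KOP_sim - KOP_ref|)`, where `r_FC` is the Pearson
#' correlation between the off-diagonal upper triangles of simulated and
#' reference FC. Both a well-matched FC pattern and a matched synchrony level
#' are required for a high score; the product is clipped below at -1.
#'
#' @param fc_sim,kop_sim simulated FC matrix and mean KOP.
#' @param target list with `fc_ref` (N x N) and `kop_ref` (scalar in
#'   \[0, 1\]).
#' @return list with `score`, `fc_similarity`, `kop_gap`.
#' @export
fit_score <- function(fc_sim, kop_sim, target) {
  r <- cor(upper_tri_vec(fc_sim), upper_tri_vec(target$fc_ref))
  gap <- abs(kop_sim - target$kop_ref)
  list(score = max(-1, r * (1 - gap)), fc_similarity = r, kop_gap = gap)
}

score_cell <- function(connectomes, cfg_base, seed, cell_id, target,
                       reps_per_cell) {
  fcs <- list()
  kops <- numeric(0)
  ok <- 0L
  for (k in seq_along(connectomes)) {
    for (r in seq_len(reps_per_cell)) {
      cfg <- cfg_base
      cfg$seed <- derive_seed(seed, cell_id * 10000L + k * 100L + r)
      sim <- tryCatch(run_hopf(connectomes[[k]], cfg), error = function(e) NULL)
      if (is.null(sim)) next
      ok <- ok + 1L
      fcs[[ok]] <- sim$fc
      kops <- c(kops, sim$kop_mean)
    }
  }
  if (ok == 0L) return(NULL)
  fc_avg <- Reduce(`+`, fcs) / ok
  sc <- fit_score(fc_avg, mean(kops), target)
  sc
}

#' Stage 1: homogeneous global-coupling fit
#'
#' Grid search over G with a homogeneous bifurcation parameter
#' (`a_i = bias0` for all regions). For each G every connectome is simulated
#' (`reps_per_cell` times), FC matrices and KOP are averaged across runs, and
#' the cell is scored with [fit_score()]. Ties pick the smallest G; cells
#' where every simulation diverged are excluded with a warning.
#'
#' @param target list with `fc_ref`, `kop_ref`.
#' @param connectomes list of connectomes.
#' @param G_grid numeric grid of couplings.
#' @param bias0 homogeneous bifurcation parameter (default -0.02).
#' @param reps_per_cell simulations per connectome per cell.
#' @param seed master seed.
#' @param config_base `hopf_config` carrying the protocol (its `G`, `bias`,
#'   `scale`, `beta` are overridden).
#' @return list of class `fit_result`: `grid`, `score_surface`,
#'   `fc_similarity`, `kop_gap`, `best_params`.
#' @export
fit_global_coupling <- function(target, connectomes, G_grid = seq(0, 0.3, 0.02),
                                bias0 = -0.02, reps_per_cell = 1L, seed = 1L,
                                config_base = hopf_config()) {
  stopifnot(length(G_grid) >= 1, reps_per_cell >= 1)
  surface <- rep(NA_real_, length(G_grid))
  fc_sim <- rep(NA_real_, length(G_grid))
  kop_gap <- rep(NA_real_, length(G_grid))
  for (gi in seq_along(G_grid)) {
    cfg <- config_base
    cfg$G <- G_grid[gi]
    cfg$bias <- bias0
    cfg$scale <- 0
    cfg$beta <- NULL
    cfg$alpha <- 0
    cfg$target <- NULL
    sc <- score_cell(connectomes, cfg, seed, gi, target, reps_per_cell)
    if (is.null(sc)) {
      warning(sprintf("all simulations diverged at G = %g; cell excluded", G_grid[gi]))
      next
    }
    surface[gi] <- sc$score
    fc_sim[gi] <- sc$fc_similarity
    kop_gap[gi] <- sc$kop_gap
  }
  if (all(is.na(surface))) stop("fit_global_coupling: no finite cells")
  best <- which(surface == max(surface, na.rm = TRUE))[1]  # ties: smallest G
  structure(list(
    grid = list(G = G_grid), score_surface = surface,
    fc_similarity = fc_sim, kop_gap = kop_gap,
    best_params = list(G = G_grid[best])
  ), class = "fit_result")
}

#' Stage 2: heterogeneous bias/scale fit
#'
#' Grid search over (bias, scale) with `a_i = bias + scale * beta_i` at fixed
#' global coupling G. Scoring as in [fit_global_coupling()]; ties pick the
#' smallest |bias|, then the smallest scale. A constant beta makes bias and
#' scale unidentifiable (the score depends only on `bias + scale * beta`);
#' this ridge is detected and flagged with a warning.
#'
#' @param target list with `fc_ref`, `kop_ref`.
#' @param connectomes list of connectomes.
#' @param G fixed global coupling (typically stage-1 output).
#' @param beta length-N heterogeneity vector in \[0, 1\].
#' @param bias_grid,scale_grid numeric grids.
#' @param reps_per_cell simulations per connectome per cell.
#' @param seed master seed.
#' @param config_base `hopf_config` carrying the protocol.
#' @return `fit_result` with a `length(bias_grid) x length(scale_grid)` score
#'   surface.
#' @export
fit_bias_scale <- function(target, connectomes, G, beta,
                           bias_grid = seq(-0.3, 0.1, 0.01),
                           scale_grid = seq(0, 0.4, 0.01),
                           reps_per_cell = 1L, seed = 1L,
                           config_base = hopf_config()) {
  if (diff(range(beta)) < 1e-12) {
    warning("fit_bias_scale: constant beta; bias and scale are unidentifiable (score ridge)")
  }
  nb <- length(bias_grid)
  ns <- length(scale_grid)
  surface <- matrix(NA_real_, nb, ns)
  fc_sim <- matrix(NA_real_, nb, ns)
  kop_gap <- matrix(NA_real_, nb, ns)
  for (bi in seq_len(nb)) {
    for (si in seq_len(ns)) {
      cfg <- config_base
      cfg$G <- G
      cfg$bias <- bias_grid[bi]
      cfg$scale <- scale_grid[si]
      cfg$beta <- beta
      cfg$alpha <- 0
      cfg$target <- NULL
      sc <- score_cell(connectomes, cfg, seed, (bi - 1L) * ns + si, target,
                       reps_per_cell)
      if (is.null(sc)) {
        warning(sprintf("all simulations diverged at (bias, scale) = (%g, %g)",
                        bias_grid[bi], scale_grid[si]))
        next
      }
      surface[bi, si] <- sc$score
      fc_sim[bi, si] <- sc$fc_similarity
      kop_gap[bi, si] <- sc$kop_gap
    }
  }
  if (all(is.na(surface))) stop("fit_bias_scale: no finite cells")
  mx <- max(surface, na.rm = TRUE)
  cand <- which(surface == mx, arr.ind = TRUE)
  # deterministic tie-break: smallest |bias|, then smallest scale
  ord <- order(abs(bias_grid[cand[, 1]]), scale_grid[cand[, 2]])
  pick <- cand[ord[1], ]
  structure(list(
    grid = list(bias = bias_grid, scale = scale_grid),
    score_surface = surface, fc_similarity = fc_sim, kop_gap = kop_gap,
    best_params = list(bias = bias_grid[pick[1]], scale = scale_grid[pick[2]],
                       G = G)
  ), class = "fit_result")
}

#' Build a fit target from a simulated (or empirical) cohort
#'
#' Averages FC matrices and mean-KOP values across subjects.
#'
#' @param cohort a `bold_cohort` (with `fc` and `kop_mean` entries).
#' @return list with `fc_ref`, `kop_ref`.
#' @export
fit_target_from_cohort <- function(cohort) {
  list(
    fc_ref = Reduce(`+`, cohort$fc) / length(cohort$fc),
    kop_ref = mean(cohort$kop_mean)
  )
}
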