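# Standard end-to-end experiments on synthetic ground truth. These drive the
# package's own methods at fixed, documented problem sizes; the same
# functions back the test suite and the reproduction script.

# Thresholded small backbones occasionally disconnect; experiments retry on
# successive derived seeds (deterministically) rather than abort.
connected_cohort <- function(tab, n_subjects, density, seed, max_tries = 20L) {
  for (k in seq_len(max_tries)) {
    s <- if (k == 1L) seed else derive_seed(seed, 9000L + k)
    out <- tryCatch(
      make_connectome_cohort(tab, n_subjects = n_subjects, density = density,
                             seed = s),
      error = function(e) NULL
    )
    if (!is.null(out)) return(out)
  }
  stop("connected_cohort: no connected backbone in ", max_tries, " tries")
}

#' Two-stage parameter-recovery experiment
#'
#' Generates fit targets from known simulator parameters on a synthetic
#' connectome cohort and measures how often each calibration stage recovers
#' the truth within one grid step. Stage 1 targets are generated by the
#' homogeneous model at `G_true` and fitted over `G_grid`; stage 2 targets by
#' the heterogeneous model at (`bias_true`, `scale_true`) with `G_true` held
#' fixed, fitted over `bias_grid` x `scale_grid`. Generator and fitting model
#' are matched within each stage: fitting a homogeneous proxy to a
#' heterogeneous generator confounds G with the mean bifurcation parameter.
#'
#' @param n_reps repetitions (target regeneration + refit) per stage.
#' @param n_regions,n_subjects,density cohort geometry.
#' @param G_true,bias_true,scale_true generating parameters.
#' @param G_grid,bias_grid,scale_grid search grids.
#' @param band analysis band, Hz (carrier-inclusive by default; see the
#'   methods vignette).
#' @param seed master seed.
#' @return list with `G_hits`, `bias_scale_hits` (counts in `n_reps`),
#'   `G_estimates`, `bias_estimates`, `scale_estimates`, and the grids.
#' @export
recovery_experiment <- function(n_reps = 10, n_regions = 16, n_subjects = 8,
                                density = 0.5, G_true = 0.16,
                                bias_true = -0.17, scale_true = 0.24,
                                G_grid = seq(0.08, 0.24, 0.04),
                                bias_grid = seq(-0.25, -0.09, 0.04),
                                scale_grid = seq(0.16, 0.32, 0.04),
                                band = c(0.01, 0.1), seed = 1L) {
  tab <- make_region_table(n_regions, seed = derive_seed(seed, 1L))
  cons <- connected_cohort(tab, n_subjects, density, derive_seed(seed, 2L))
  beta <- model_vector(comm_model_set(cons)$distance, "node_summary")
  cfg_h <- hopf_config(G = G_true, bias = -0.02, scale = 0, band = band)
  cfg_b <- hopf_config(G = G_true, bias = bias_true, scale = scale_true,
                       beta = beta, band = band)
  step_G <- if (length(G_grid) > 1) min(diff(sort(G_grid))) else Inf
  step_b <- if (length(bias_grid) > 1) min(diff(sort(bias_grid))) else Inf
  step_s <- if (length(scale_grid) > 1) min(diff(sort(scale_grid))) else Inf
  G_est <- bias_est <- scale_est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    targ_h <- fit_target_from_cohort(
      simulate_cohort(cons, cfg_h, seed = derive_seed(seed, 100L + r))
    )
    f1 <- fit_global_coupling(targ_h, cons, G_grid = G_grid,
                              seed = derive_seed(seed, 200L + r),
                              config_base = cfg_h)
    G_est[r] <- f1$best_params$G
    targ_b <- fit_target_from_cohort(
      simulate_cohort(cons, cfg_b, seed = derive_seed(seed, 300L + r))
    )
    f2 <- fit_bias_scale(targ_b, cons, G = G_true, beta = beta,
                         bias_grid = bias_grid, scale_grid = scale_grid,
                         seed = derive_seed(seed, 400L + r),
                         config_base = cfg_b)
    bias_est[r] <- f2$best_params$bias
    scale_est[r] <- f2$best_params$scale
  }
  list(
    G_hits = sum(abs(G_est - G_true) <= step_G + 1e-9),
    bias_scale_hits = sum(abs(bias_est - bias_true) <= step_b + 1e-9 &
                            abs(scale_est - scale_true) <= step_s + 1e-9),
    n_reps = n_reps,
    G_estimates = G_est, bias_estimates = bias_est,
    scale_estimates = scale_est,
    grids = list(G = G_grid, bias = bias_grid, scale = scale_grid)
  )
}

#' Local-to-global transition experiment
#'
#' Simulates control and stimulated cohorts at three stimulation-intensity
#' zones (strongly negative, zero, strongly positive), computes per-subject
#' HOI maps, and counts significant regions in the regionwise permutation
#' contrast on both the rank and absolute scales. Quenching the target
#' (negative alpha) is a relative, localized effect best seen in ranks;
#' strong excitation (large positive alpha) shifts redundancy globally and
#' shows on the absolute scale while cancelling in ranks.
#'
#' @param n_regions,n_subjects,density cohort geometry.
#' @param alphas length-3 numeric: negative, null and positive zone
#'   intensities (the alpha scale is model-specific; several units of
#'   `scale` are needed to push one region across the bifurcation against
#'   the coupling).
#' @param fit_params list with `G`, `bias`, `scale`.
#' @param measure HOI measure to contrast.
#' @param n_perm permutations per region.
#' @param band band for the stored series; `NULL` (default) keeps the
#'   broadband series, on which amplitude changes at a quenched region
#'   translate into correlation changes (see the methods vignette).
#' @param seed master seed.
#' @return list with `alphas`, `sig_rank`, `sig_abs` (length-3 counts),
#'   `target`, `target_sig` (was the target significant on either scale,
#'   per zone), `target_t_rank` (t-values at the target, rank scale),
#'   `kop_mean` per zone, `n_regions`.
#' @export
regime_experiment <- function(n_regions = 84, n_subjects = 8, density = 0.35,
                              alphas = c(-4, 0, 4),
                              fit_params = list(G = 0.16, bias = -0.17,
                                                scale = 0.24),
                              measure = "redundancy", n_perm = 1000L,
                              band = NULL, seed = 1L) {
  stopifnot(length(alphas) == 3)
  tab <- make_region_table(n_regions, seed = derive_seed(seed, 1L))
  cons <- connected_cohort(tab, n_subjects, density, derive_seed(seed, 2L))
  beta <- model_vector(comm_model_set(cons)$distance, "node_summary")
  target <- which.min(abs(beta - median(beta)))
  cfg <- hopf_config(G = fit_params$G, bias = fit_params$bias,
                     scale = fit_params$scale, beta = beta, band = band)
  ctrl <- simulate_cohort(cons, cfg, alpha = 0, seed = derive_seed(seed, 3L))
  hoi_ctrl <- lapply(ctrl$series, hoi_matrices)
  sig_rank <- sig_abs <- integer(3)
  tgt_sig <- logical(3)
  t_rank <- kops <- numeric(3)
  for (z in 1:3) {
    tus <- simulate_cohort(cons, cfg, alpha = alphas[z], target = target,
                           seed = derive_seed(seed, 10L + z),
                           seed_offset = 100000L, condition = "tus")
    hoi_tus <- lapply(tus$series, hoi_matrices)
    cr <- regionwise_contrast(hoi_tus, hoi_ctrl, measure = measure,
                              scale = "rank", n_perm = n_perm,
                              seed = derive_seed(seed, 20L + z))
    ca <- regionwise_contrast(hoi_tus, hoi_ctrl, measure = measure,
                              scale = "absolute", n_perm = n_perm,
                              seed = derive_seed(seed, 30L + z))
    sig_rank[z] <- sum(cr$significant)
    sig_abs[z] <- sum(ca$significant)
    tgt_sig[z] <- cr$significant[target] || ca$significant[target]
    t_rank[z] <- cr$t_values[target]
    kops[z] <- mean(tus$kop_mean)
  }
  list(alphas = alphas, sig_rank = sig_rank, sig_abs = sig_abs,
       target = target, target_sig = tgt_sig, target_t_rank = t_rank,
       kop_mean = kops, kop_control = mean(ctrl$kop_mean),
       n_regions = n_regions)
}

#' Type-I error calibration of the permutation t-test
#'
#' Repeated null simulations (both groups standard normal, unbalanced 11 vs
#' 22 as in the emulated design) and the rejection rate at the 0.05 level.
#'
#' @param n_sims number of null simulations.
#' @param n_a,n_b group sizes.
#' @param n_perm permutations per test.
#' @param seed master seed.
#' @return list with `rate`, `n_sims`, and the binomial 95% interval
#'   `ci_low`, `ci_high` around the nominal 0.05.
#' @export
ttest_calibration <- function(n_sims = 500, n_a = 11, n_b = 22,
                              n_perm = 500L, seed = 1L) {
  rej <- 0L
  for (i in seq_len(n_sims)) {
    sim <- with_seed(derive_seed(seed, i), {
      list(a = rnorm(n_a), b = rnorm(n_b))
    })
    p <- perm_ttest(sim$a, sim$b, n_perm = n_perm,
                    seed = derive_seed(seed, 100000L + i))["p"]
    rej <- rej + (p < 0.05)
  }
  list(rate = rej / n_sims, n_sims = n_sims,
       ci_low = qbinom(0.025, n_sims, 0.05) / n_sims,
       ci_high = qbinom(0.975, n_sims, 0.05) / n_sims)
}
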