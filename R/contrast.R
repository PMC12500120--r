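# Permutation group statistics: regionwise stimulated-vs-control contrasts
# of high-order-interaction strengths, model-HOI associations with
# Bonferroni correction, and the stimulation-intensity sweep.

#' Permutation two-sample t-test
#'
#' Welch (unequal-variance) t-statistic for `a` minus `b`; the two-sided
#' p-value counts label permutations whose |t| reaches the observed one,
#' with the add-one correction `p = (1 + #exceed) / (n_perm + 1)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @return named numeric: `t`, `p`.
#' @export
perm_ttest <- function(a, b, n_perm = 1000L, seed = 1L) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("perm_ttest: each group needs >= 2 values")
  if (n_perm < 100) stop("perm_ttest: n_perm must be >= 100")
  pooled <- c(a, b)
  if (var(pooled) == 0) stop("perm_ttest: degenerate data (zero pooled variance)")
  n <- na + nb
  welch_t <- function(mask) {
    # mask: n_perm x n logical, TRUE = group a
    sA <- mask %*% pooled
    sA2 <- mask %*% pooled^2
    mA <- sA / na
    vA <- pmax(0, (sA2 - na * mA^2) / (na - 1))
    sB <- sum(pooled) - sA
    sB2 <- sum(pooled^2) - sA2
    mB <- sB / nb
    vB <- pmax(0, (sB2 - nb * mB^2) / (nb - 1))
    den <- sqrt(vA / na + vB / nb)
    ifelse(den == 0, 0, (mA - mB) / den)
  }
  t_obs <- as.numeric(welch_t(matrix(c(rep(TRUE, na), rep(FALSE, nb)), 1)))
  with_seed(seed, {
    mask <- matrix(FALSE, n_perm, n)
    for (i in seq_len(n_perm)) mask[i, sample.int(n, na)] <- TRUE
    t_perm <- as.numeric(welch_t(mask))
    p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (n_perm + 1)
    c(t = t_obs, p = p)
  })
}

#' Regionwise permutation contrast of HOI strengths
#'
#' For every region, compares the per-subject strength (median persistent
#' redundancy or synergy, on the absolute or rank scale) between a
#' stimulated and a control cohort with [perm_ttest()] (stimulated minus
#' control). Significance is assessed per region at the two-sided 0.05 level
#' on the permutation p-value; no additional across-region correction is
#' applied by default, matching the per-region permutation correction of the
#' analysis. An optional max-statistic correction (`across = "maxT"`) is
#' available.
#'
#' @param hoi_tus,hoi_ctrl lists of per-subject `hoi_maps`.
#' @param measure `"redundancy"` or `"synergy"`.
#' @param scale `"absolute"` (median strength) or `"rank"`.
#' @param n_perm permutations per region.
#' @param seed master seed; per-region streams are derived from it.
#' @param alpha_level significance level (default 0.05).
#' @param across `"none"` (default) or `"maxT"` for a max-statistic
#'   across-region correction.
#' @return list of class `region_stat_map`: `t_values`, `p_values`,
#'   `significant`, `n_perm`, `seed`, `measure`, `scale`.
#' @export
regionwise_contrast <- function(hoi_tus, hoi_ctrl,
                                measure = c("redundancy", "synergy"),
                                scale = c("absolute", "rank"),
                                n_perm = 1000L, seed = 1L,
                                alpha_level = 0.05,
                                across = c("none", "maxT")) {
  measure <- match.arg(measure)
  scale <- match.arg(scale)
  across <- match.arg(across)
  if (length(hoi_tus) < 2 || length(hoi_ctrl) < 2) {
    stop("regionwise_contrast: each group needs >= 2 subjects")
  }
  field <- if (scale == "absolute") paste0("median_", measure) else paste0("rank_", measure)
  mat_tus <- t(vapply(hoi_tus, `[[`, numeric(length(hoi_tus[[1]][[field]])), field))
  mat_ctrl <- t(vapply(hoi_ctrl, `[[`, numeric(ncol(mat_tus)), field))
  N <- ncol(mat_tus)
  t_values <- numeric(N)
  p_values <- numeric(N)
  for (r in seq_len(N)) {
    res <- perm_ttest(mat_tus[, r], mat_ctrl[, r], n_perm = n_perm,
                      seed = derive_seed(seed, r))
    t_values[r] <- res["t"]
    p_values[r] <- res["p"]
  }
  if (across == "maxT") {
    # max-statistic correction: shared permutation stream across regions
    pooled <- rbind(mat_tus, mat_ctrl)
    na <- nrow(mat_tus); n <- nrow(pooled)
    maxt <- with_seed(derive_seed(seed, 0L), {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, na)
        tt <- vapply(seq_len(N), function(r) {
          x <- pooled[idx, r]; y <- pooled[-idx, r]
          den <- sqrt(var(x) / length(x) + var(y) / length(y))
          if (den == 0) 0 else (mean(x) - mean(y)) / den
        }, numeric(1))
        max(abs(tt))
      }, numeric(1))
    })
    p_values <- vapply(t_values, function(t0) {
      (1 + sum(maxt >= abs(t0))) / (n_perm + 1)
    }, numeric(1))
  }
  structure(list(
    t_values = t_values, p_values = p_values,
    significant = p_values < alpha_level,
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    measure = measure, scale = scale
  ), class = "region_stat_map")
}

#' Association between a communication-model vector and an HOI change vector
#'
#' Rank (Spearman, default) or Pearson correlation with asymptotic p-value
#' and Bonferroni correction over the test family (default 8: four models
#' times two measures per target). Pairs where either entry is non-finite
#' (e.g. unreachable-pair `Inf` in search information) are removed.
#'
#' @param model_vec,delta_vec equal-length numeric vectors.
#' @param method `"spearman"` or `"pearson"`.
#' @param n_tests Bonferroni family size.
#' @return list of class `association_result`: `rho`, `p_raw`, `p_corrected`,
#'   `n_tests`, `n_used`, `method`.
#' @export
model_association <- function(model_vec, delta_vec,
                              method = c("spearman", "pearson"),
                              n_tests = 8L) {
  method <- match.arg(method)
  stopifnot(length(model_vec) == length(delta_vec))
  keep <- is.finite(model_vec) & is.finite(delta_vec)
  ct <- suppressWarnings(
    cor.test(model_vec[keep], delta_vec[keep], method = method, exact = FALSE)
  )
  structure(list(
    rho = unname(ct$estimate), p_raw = ct$p.value,
    p_corrected = min(1, ct$p.value * n_tests),
    n_tests = as.integer(n_tests), n_used = sum(keep), method = method
  ), class = "association_result")
}

#' Per-region HOI change vector between two cohorts
#'
#' The representative change used for model associations: HOI maps are
#' computed per subject, the pairwise matrices are averaged within cohort,
#' and the per-region median strength difference (stimulated minus control)
#' is returned.
#'
#' @param hoi_tus,hoi_ctrl lists of per-subject `hoi_maps`.
#' @param measure `"redundancy"` or `"synergy"`.
#' @return length-N numeric vector.
#' @export
hoi_change_vector <- function(hoi_tus, hoi_ctrl,
                              measure = c("redundancy", "synergy")) {
  measure <- match.arg(measure)
  avg <- function(hs) Reduce(`+`, lapply(hs, `[[`, measure)) / length(hs)
  offdiag_row_median(avg(hoi_tus)) - offdiag_row_median(avg(hoi_ctrl))
}

#' Stimulation-intensity sweep
#'
#' For each intensity alpha on the grid, simulates a stimulated cohort (one
#' run per connectome), computes per-subject HOI maps and the regionwise
#' permutation contrast against a control cohort, and records (i) the
#' Spearman correlation between the supplied reference t-vector and the
#' simulated t-vector and (ii) the number of significant regions. The
#' control cohort (alpha = 0) is simulated once and shared across the grid.
#'
#' @param emp_stat a `region_stat_map` (reference t-values, e.g. from
#'   ground-truth or empirical data).
#' @param connectomes list of connectomes.
#' @param fit_params list with `G`, `bias`, `scale` (calibrated parameters).
#' @param beta length-N heterogeneity vector.
#' @param target 1-based stimulated region.
#' @param alpha_grid intensity grid (default `seq(-1, 1, 0.1)`).
#' @param measure HOI measure to contrast.
#' @param scale contrast scale (`"absolute"` or `"rank"`).
#' @param n_perm permutations per region.
#' @param seed master seed.
#' @param config_base `hopf_config` carrying the protocol.
#' @param tau lag for the HOI maps.
#' @return list of class `sweep_curve`: `alphas`, `similarity`, `sig_count`,
#'   `t_matrix` (length(grid) x N).
#' @export
alpha_sweep <- function(emp_stat, connectomes, fit_params, beta, target,
                        alpha_grid = seq(-1, 1, 0.1),
                        measure = "redundancy", scale = "absolute",
                        n_perm = 1000L, seed = 1L,
                        config_base = hopf_config(), tau = 1L) {
  cfg <- config_base
  cfg$G <- fit_params$G
  cfg$bias <- fit_params$bias
  cfg$scale <- fit_params$scale
  cfg$beta <- beta
  hoi_of_cohort <- function(cohort) lapply(cohort$series, hoi_matrices, tau = tau)
  ctrl <- simulate_cohort(connectomes, cfg, alpha = 0, target = NULL,
                          seed = derive_seed(seed, 0L))
  hoi_ctrl <- hoi_of_cohort(ctrl)
  N <- ncol(ctrl$series[[1]])
  similarity <- numeric(length(alpha_grid))
  sig_count <- integer(length(alpha_grid))
  t_matrix <- matrix(NA_real_, length(alpha_grid), N)
  for (ai in seq_along(alpha_grid)) {
    al <- alpha_grid[ai]
    tus <- simulate_cohort(connectomes, cfg, alpha = al, target = target,
                           seed = derive_seed(seed, ai),
                           seed_offset = 100000L, condition = "tus")
    hoi_tus <- hoi_of_cohort(tus)
    cst <- regionwise_contrast(hoi_tus, hoi_ctrl, measure = measure,
                               scale = scale, n_perm = n_perm,
                               seed = derive_seed(seed, 1000L + ai))
    t_matrix[ai, ] <- cst$t_values
    sig_count[ai] <- sum(cst$significant)
    similarity[ai] <- suppressWarnings(
      cor(emp_stat$t_values, cst$t_values, method = "spearman")
    )
  }
  structure(list(
    alphas = alpha_grid, similarity = similarity, sig_count = sig_count,
    t_matrix = t_matrix
  ), class = "sweep_curve")
}
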