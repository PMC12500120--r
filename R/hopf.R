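# Heterogeneous Stuart-Landau (Hopf) whole-brain simulator.
#
# Each region is a Stuart-Landau oscillator at its Hopf bifurcation
# parameter a_i: a_i < 0 gives a noise-dominated stable focus, a_i > 0 a
# limit cycle of radius sqrt(a_i); regions are diffusively coupled through
# the structural weights. Regional heterogeneity enters through
# a_i = bias + scale * (beta_i + alpha * [i == target]), where beta is a
# communication-model summary in [0, 1] and alpha the stimulation intensity
# applied at the target region.

#' Hopf simulator configuration
#'
#' Collects every simulator parameter with the defaults of the simulation
#' protocol: 0.05 Hz intrinsic frequency, noise sd 0.02, global coupling
#' 0.16, 0.1 s Euler-Maruyama step, 1100 s runs trimmed by 100 s at each end
#' (so 15 min are retained), band-pass 0.001-0.01 Hz for the BOLD-like
#' output and 0.01-0.1 Hz for phase/synchrony estimation.
#'
#' @param freq intrinsic oscillation frequency, Hz (omega = 2*pi*freq).
#' @param gamma_noise additive noise standard deviation.
#' @param G global coupling.
#' @param bias,scale map from heterogeneity beta to bifurcation parameter.
#' @param beta length-N heterogeneity vector in \[0, 1\], or `NULL` for a
#'   homogeneous model (`a = bias`).
#' @param alpha stimulation intensity (0 = control).
#' @param target 1-based stimulated region index, or `NULL`.
#' @param dt integration step, s.
#' @param duration total simulated time, s.
#' @param trim seconds discarded at each end after filtering.
#' @param band band-pass edges for the BOLD-like signal, Hz.
#' @param kop_band band-pass edges for phase estimation, Hz.
#' @param seed RNG seed.
#' @param printed_bracket use the (x^2 - y^2) amplitude bracket instead of
#'   the supercritical normal form (x^2 + y^2); for auditing only.
#' @return list of class `hopf_config`.
#' @export
hopf_config <- function(freq = 0.05, gamma_noise = 0.02, G = 0.16,
                        bias = -0.02, scale = 0, beta = NULL, alpha = 0,
                        target = NULL, dt = 0.1, duration = 1100, trim = 100,
                        band = c(0.001, 0.01), kop_band = c(0.01, 0.1),
                        seed = 1L, printed_bracket = FALSE) {
  stopifnot(dt > 0, duration > 2 * trim,
            is.null(band) || band[1] < band[2],
            kop_band[1] < kop_band[2])
  structure(list(
    freq = freq, omega = 2 * pi * freq, gamma_noise = gamma_noise, G = G,
    bias = bias, scale = scale, beta = beta, alpha = alpha, target = target,
    dt = dt, duration = duration, trim = trim, band = band,
    kop_band = kop_band, seed = as.integer(seed),
    printed_bracket = isTRUE(printed_bracket)
  ), class = "hopf_config")
}

#' Regional bifurcation-parameter vector
#'
#' `a_i = bias + scale * (beta_i + alpha * [i == target])`; with `alpha = 0`
#' or no target this is the control heterogeneity `bias + scale * beta`.
#'
#' @param bias,scale scalars.
#' @param beta length-N heterogeneity vector.
#' @param alpha stimulation intensity.
#' @param target 1-based stimulated region, or `NULL`.
#' @return length-N numeric vector.
#' @export
bifurcation_vector <- function(bias, scale, beta, alpha = 0, target = NULL) {
  a <- bias + scale * beta
  if (!is.null(target) && alpha != 0) {
    stopifnot(target >= 1, target <= length(beta))
    a[target] <- a[target] + scale * alpha
  }
  a
}

#' Simulate the coupled Stuart-Landau system
#'
#' Euler-Maruyama integration on the structural weights, diffusive coupling
#' on both components, independent Gaussian noise increments
#' `gamma_noise * sqrt(dt) * N(0,1)` per node and component. Initial state is
#' uniform(-0.1, 0.1), seeded. Returns the raw (unfiltered, untrimmed)
#' series.
#'
#' @param connectome a connectome (list with `weights`), or a bare weight
#'   matrix.
#' @param config a `hopf_config`.
#' @return list of class `hopf_sim`: `x`, `y` (T x N raw series),
#'   `dt_sample`, `a_used`, `config`.
#' @export
simulate_hopf <- function(connectome, config) {
  M <- if (is.list(connectome)) connectome$weights else connectome
  stopifnot(is_symmetric_num(M, tol = 1e-6))
  # couple through max-normalized weights so the global coupling G lives on
  # the same scale regardless of streamline-count units
  if (max(M) > 0) M <- M / max(M)
  N <- ncol(M)
  beta <- config$beta
  a <- if (is.null(beta)) {
    rep(config$bias, N)
  } else {
    stopifnot(length(beta) == N)
    bifurcation_vector(config$bias, config$scale, beta, config$alpha, config$target)
  }
  nsteps <- round(config$duration / config$dt)
  out <- with_seed(config$seed, {
    x0 <- runif(N, -0.1, 0.1)
    y0 <- runif(N, -0.1, 0.1)
    hopf_integrate_cpp(M, a, config$omega, config$G, config$gamma_noise,
                       config$dt, nsteps, x0, y0, config$printed_bracket)
  })
  if (isTRUE(out$diverged)) {
    stop(sprintf("simulate_hopf: numerical blow-up at step %d", out$step))
  }
  structure(list(x = out$x, y = out$y, dt_sample = config$dt, a_used = a,
                 config = config), class = "hopf_sim")
}

butter_bandpass <- function(band, fs) {
  ny <- fs / 2
  if (band[2] >= ny) stop("band edge at or above Nyquist frequency")
  signal::butter(2, band / ny, type = "pass")
}

#' Band-pass and trim a simulated series
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass in
#' `config$band`, then removal of `config$trim` seconds at each end. With the
#' default protocol 1100 s minus 2 x 100 s leaves 900 s (15 min) of signal.
#' A `NULL` band skips the filter and only trims, leaving the broadband
#' series (the convention for the high-order-interaction stage, whose
#' empirical filtering is an open hook).
#'
#' @param raw a `hopf_sim` object or T x N matrix.
#' @param config a `hopf_config`.
#' @return T' x N numeric matrix.
#' @export
preprocess_sim <- function(raw, config) {
  x <- if (inherits(raw, "hopf_sim")) raw$x else as.matrix(raw)
  fs <- 1 / config$dt
  n_trim <- round(config$trim / config$dt)
  if (nrow(x) <= 2 * n_trim) stop("preprocess_sim: series shorter than 2*trim")
  if (!is.null(config$band)) {
    bf <- butter_bandpass(config$band, fs)
    x <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  x[(n_trim + 1):(nrow(x) - n_trim), , drop = FALSE]
}

#' Functional connectivity matrix
#'
#' Pearson correlation across time for every region pair; unit diagonal.
#'
#' @param series T x N matrix.
#' @return N x N correlation matrix.
#' @export
fc_matrix <- function(series) {
  fc <- cor(series)
  diag(fc) <- 1
  dimnames(fc) <- NULL
  fc
}

#' Kuramoto order parameter of a multivariate series
#'
#' Band-passes each region in `kop_band`, extracts instantaneous phases from
#' the analytic signal, computes `R(t) = |mean_j exp(i theta_j(t))|`,
#' discards 10% of samples at each edge (filter/Hilbert warm-up) and returns
#' the time-mean and time-sd of R.
#'
#' @param series T x N matrix (N >= 2).
#' @param kop_band band-pass edges, Hz.
#' @param dt_sample sampling interval, s.
#' @return named numeric: `mean`, `sd`.
#' @export
kop <- function(series, kop_band = c(0.01, 0.1), dt_sample = 0.1) {
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("kop: need at least 2 regions")
  if (nrow(series) < 50) stop("kop: series too short for filter warm-up")
  bf <- butter_bandpass(kop_band, 1 / dt_sample)
  phases <- apply(series, 2, function(col) {
    Arg(analytic_signal(signal::filtfilt(bf, col)))
  })
  R <- Mod(rowMeans(exp(1i * phases)))
  edge <- max(1L, floor(0.1 * length(R)))
  Rk <- R[(edge + 1):(length(R) - edge)]
  c(mean = mean(Rk), sd = sd(Rk))
}

#' Simulate, preprocess and summarize in one call
#'
#' Runs [simulate_hopf()], [preprocess_sim()], [fc_matrix()] and [kop()].
#'
#' @param connectome connectome or weight matrix.
#' @param config a `hopf_config`.
#' @return list of class `sim_output`: `series` (preprocessed T' x N),
#'   `dt_sample`, `a_used`, `fc`, `kop_mean`, `kop_sd`, `config`.
#' @export
run_hopf <- function(connectome, config) {
  raw <- simulate_hopf(connectome, config)
  series <- preprocess_sim(raw, config)
  k <- kop(raw$x, config$kop_band, config$dt)
  structure(list(
    series = series, dt_sample = config$dt, a_used = raw$a_used,
    fc = fc_matrix(series), kop_mean = unname(k["mean"]),
    kop_sd = unname(k["sd"]), config = config
  ), class = "sim_output")
}

#' Simulate ground-truth control and stimulated cohorts
#'
#' One simulation per connectome and condition with distinct derived seeds:
#' the control cohort runs at `alpha = 0`, the stimulated cohort at the
#' supplied intensity and target. Everything else (coupling, heterogeneity,
#' protocol) is shared, so condition differences are attributable to the
#' stimulation term alone.
#'
#' @param connectomes list of connectomes.
#' @param control_params a `hopf_config` describing the control condition
#'   (its `alpha`/`target` are ignored).
#' @param alpha stimulation intensity for the stimulated cohort.
#' @param target 1-based stimulated region index.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return list with `control` and `tus`, each a list of class `bold_cohort`:
#'   `condition`, `target`, `series` (list of T' x N matrices), `fc` and
#'   `kop_mean` lists, `dt_sample`, `seed`.
#' @export
make_ground_truth_cohorts <- function(connectomes, control_params, alpha,
                                      target, seed = 1L) {
  list(
    control = simulate_cohort(connectomes, control_params, alpha = 0,
                              target = NULL, seed = seed, seed_offset = 0L,
                              condition = "control"),
    tus = simulate_cohort(connectomes, control_params, alpha = alpha,
                          target = target, seed = seed,
                          seed_offset = 100000L, condition = "tus")
  )
}

#' Simulate one cohort (one run per connectome)
#'
#' @param connectomes list of connectomes.
#' @param config a `hopf_config` (its `alpha`, `target`, `seed` are
#'   overridden).
#' @param alpha stimulation intensity.
#' @param target 1-based stimulated region or `NULL`.
#' @param seed master seed.
#' @param seed_offset offset added to the per-subject seed index, so several
#'   cohorts drawn from one master seed stay independent.
#' @param condition label stored on the cohort.
#' @return a `bold_cohort` (see [make_ground_truth_cohorts()]).
#' @export
simulate_cohort <- function(connectomes, config, alpha = 0, target = NULL,
                            seed = 1L, seed_offset = 0L,
                            condition = if (alpha == 0) "control" else "tus") {
  runs <- lapply(seq_along(connectomes), function(k) {
    cfg <- config
    cfg$alpha <- alpha
    cfg$target <- if (alpha == 0) NULL else target
    cfg$seed <- derive_seed(seed, seed_offset + k)
    run_hopf(connectomes[[k]], cfg)
  })
  structure(list(
    condition = condition, target = target,
    series = lapply(runs, `[[`, "series"),
    fc = lapply(runs, `[[`, "fc"),
    kop_mean = vapply(runs, `[[`, numeric(1), "kop_mean"),
    dt_sample = config$dt, seed = seed
  ), class = "bold_cohort")
}
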