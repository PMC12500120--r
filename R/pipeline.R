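# Configuration-driven orchestration of the full analysis: synthetic cohort
# -> communication models -> (optional) calibration -> ground-truth cohorts
# -> HOI maps -> regionwise contrast -> model associations -> intensity
# sweep. Every stage writes plain-text artifacts plus a JSON manifest, and
# all randomness derives from a single master seed, so a config reruns to
# byte-identical outputs.

default_run_config <- function() {
  list(
    out_dir = "tusplast_run",
    master_seed = 1L,
    stages = list(synth = TRUE, commodels = TRUE, fit = FALSE,
                  cohorts = TRUE, phiid = TRUE, contrast = TRUE,
                  associate = TRUE, sweep = FALSE),
    synth = list(n_regions = 84L, n_subjects = 20L, edr_lambda = 30,
                 density = 0.35, subject_jitter = 0.2),
    commodels = list(normalization = "as_printed", beta_model = "distance"),
    hopf = list(freq = 0.05, gamma_noise = 0.02, G = 0.16, bias = -0.17,
                scale = 0.24, dt = 0.1, duration = 1100, trim = 100,
                band = c(0.001, 0.01), kop_band = c(0.01, 0.1)),
    fit = list(G_grid = seq(0.08, 0.24, 0.04),
               bias_grid = seq(-0.25, -0.09, 0.04),
               scale_grid = seq(0.12, 0.36, 0.04), reps_per_cell = 1L),
    cohorts = list(alpha = -1, target = 1L),
    phiid = list(tau = 1L),
    contrast = list(measure = "redundancy", scale = "absolute",
                    n_perm = 1000L),
    associate = list(method = "spearman", n_tests = 8L),
    sweep = list(alpha_grid = seq(-1, 1, 0.5), n_perm = 1000L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over the package defaults; fields absent
#' from the file keep their default values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg$master_seed <- as.integer(cfg$master_seed)
  cfg
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order and writes all artifacts
#' under `config$out_dir`: region table (CSV), connectomes and model
#' matrices (TSV), per-subject HOI maps, contrast tables, association
#' results and sweep curves (TSV/JSON), plus `manifest.json` recording the
#' configuration, seeds and stage outputs. Disabled upstream stages that a
#' requested stage depends on raise an error naming the stage to enable.
#'
#' @param config configuration list from [load_run_config()], or a YAML path.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  st <- config$stages
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- config$master_seed
  manifest <- list(package = "tusplast",
                   version = as.character(utils::packageVersion("tusplast")),
                   master_seed = seed, config = config, artifacts = list())
  need <- function(dep, stage) {
    stop(sprintf("run_pipeline: stage '%s' requires stage '%s'; enable it in config$stages",
                 stage, dep))
  }

  table <- NULL; connectomes <- NULL; models <- NULL; beta <- NULL
  cohorts <- NULL; hoi <- NULL; cst <- NULL

  if (isTRUE(st$synth)) {
    table <- make_region_table(config$synth$n_regions, seed = derive_seed(seed, 1L))
    connectomes <- make_connectome_cohort(
      table, config$synth$n_subjects, config$synth$edr_lambda,
      config$synth$density, config$synth$subject_jitter,
      seed = derive_seed(seed, 2L)
    )
    write_region_table(table, file.path(out, "regions.csv"))
    write_connectome_cohort(connectomes, file.path(out, "connectomes"))
    manifest$artifacts$regions <- "regions.csv"
    manifest$artifacts$connectomes <- "connectomes/"
  }

  if (isTRUE(st$commodels)) {
    if (is.null(connectomes)) need("synth", "commodels")
    models <- comm_model_set(connectomes, config$commodels$normalization)
    for (nm in c("distance", "weights", "SPE", "SI", "CMY")) {
      write_matrix_tsv(models[[nm]], file.path(out, paste0("model_", nm, ".tsv")))
    }
    jsonlite::write_json(
      list(normalization = config$commodels$normalization,
           unreachable_pairs = models$unreachable_pairs),
      file.path(out, "model_meta.json"), auto_unbox = TRUE
    )
    beta_mat <- if (config$commodels$beta_model == "distance") models$distance else models$CMY
    beta <- model_vector(beta_mat, "node_summary")
    manifest$artifacts$models <- "model_*.tsv"
  }

  hopf_cfg <- hopf_config(
    freq = config$hopf$freq, gamma_noise = config$hopf$gamma_noise,
    G = config$hopf$G, bias = config$hopf$bias, scale = config$hopf$scale,
    beta = beta, dt = config$hopf$dt, duration = config$hopf$duration,
    trim = config$hopf$trim, band = config$hopf$band,
    kop_band = config$hopf$kop_band
  )

  fit_params <- list(G = config$hopf$G, bias = config$hopf$bias,
                     scale = config$hopf$scale)
  if (isTRUE(st$fit)) {
    if (is.null(connectomes)) need("synth", "fit")
    if (is.null(beta)) need("commodels", "fit")
    target_cohort <- simulate_cohort(connectomes, hopf_cfg,
                                     seed = derive_seed(seed, 3L))
    target <- fit_target_from_cohort(target_cohort)
    fit1 <- fit_global_coupling(target, connectomes, config$fit$G_grid,
                                reps_per_cell = config$fit$reps_per_cell,
                                seed = derive_seed(seed, 4L),
                                config_base = hopf_cfg)
    fit2 <- fit_bias_scale(target, connectomes, fit1$best_params$G, beta,
                           config$fit$bias_grid, config$fit$scale_grid,
                           reps_per_cell = config$fit$reps_per_cell,
                           seed = derive_seed(seed, 5L),
                           config_base = hopf_cfg)
    fit_params <- fit2$best_params
    jsonlite::write_json(
      list(G = fit_params$G, bias = fit_params$bias, scale = fit_params$scale),
      file.path(out, "fit_params.json"), auto_unbox = TRUE, digits = NA
    )
    write_matrix_tsv(fit2$score_surface, file.path(out, "fit_surface_bias_scale.tsv"))
    manifest$artifacts$fit <- "fit_params.json"
  }

  if (isTRUE(st$cohorts)) {
    if (is.null(connectomes)) need("synth", "cohorts")
    if (is.null(beta)) need("commodels", "cohorts")
    cfg <- hopf_cfg
    cfg$G <- fit_params$G; cfg$bias <- fit_params$bias; cfg$scale <- fit_params$scale
    cohorts <- make_ground_truth_cohorts(connectomes, cfg,
                                         alpha = config$cohorts$alpha,
                                         target = config$cohorts$target,
                                         seed = derive_seed(seed, 6L))
    for (cond in names(cohorts)) {
      cdir <- file.path(out, paste0("cohort_", cond))
      if (!dir.exists(cdir)) dir.create(cdir)
      for (k in seq_along(cohorts[[cond]]$series)) {
        write_matrix_tsv(cohorts[[cond]]$series[[k]],
                         file.path(cdir, sprintf("sub-%03d_series.tsv", k)))
      }
      jsonlite::write_json(
        list(condition = cond, target = cohorts[[cond]]$target,
             dt = cohorts[[cond]]$dt_sample, seed = cohorts[[cond]]$seed),
        file.path(cdir, "manifest.json"), auto_unbox = TRUE
      )
    }
    manifest$artifacts$cohorts <- "cohort_*/"
  }

  if (isTRUE(st$phiid)) {
    if (is.null(cohorts)) need("cohorts", "phiid")
    hoi <- lapply(cohorts, function(ch) {
      lapply(ch$series, hoi_matrices, tau = config$phiid$tau)
    })
    hdir <- file.path(out, "hoi")
    for (cond in names(hoi)) {
      for (k in seq_along(hoi[[cond]])) {
        write_hoi_maps(hoi[[cond]][[k]], hdir,
                       prefix = sprintf("%s_sub-%03d", cond, k))
      }
    }
    manifest$artifacts$hoi <- "hoi/"
  }

  if (isTRUE(st$contrast)) {
    if (is.null(hoi)) need("phiid", "contrast")
    cst <- regionwise_contrast(hoi$tus, hoi$control,
                               measure = config$contrast$measure,
                               scale = config$contrast$scale,
                               n_perm = config$contrast$n_perm,
                               seed = derive_seed(seed, 7L))
    write.table(
      data.frame(t = cst$t_values, p = cst$p_values, sig = cst$significant),
      file.path(out, "contrast.tsv"), sep = "\t", row.names = FALSE, quote = FALSE
    )
    manifest$artifacts$contrast <- "contrast.tsv"
  }

  if (isTRUE(st$associate)) {
    if (is.null(hoi)) need("phiid", "associate")
    if (is.null(models)) need("commodels", "associate")
    tgt <- config$cohorts$target
    assoc <- lapply(c(distance = "distance", SPE = "SPE", SI = "SI", CMY = "CMY"),
                    function(nm) {
      mv <- model_vector(models[[nm]], "seed_row", target = tgt)
      res <- lapply(c(redundancy = "redundancy", synergy = "synergy"),
                    function(ms) {
        a <- model_association(mv, hoi_change_vector(hoi$tus, hoi$control, ms),
                               method = config$associate$method,
                               n_tests = config$associate$n_tests)
        list(rho = a$rho, p_raw = a$p_raw, p_corrected = a$p_corrected)
      })
      res
    })
    jsonlite::write_json(assoc, file.path(out, "associations.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$artifacts$associations <- "associations.json"
  }

  if (isTRUE(st$sweep)) {
    if (is.null(cst)) need("contrast", "sweep")
    sw <- alpha_sweep(cst, connectomes, fit_params, beta,
                      target = config$cohorts$target,
                      alpha_grid = config$sweep$alpha_grid,
                      measure = config$contrast$measure,
                      scale = config$contrast$scale,
                      n_perm = config$sweep$n_perm,
                      seed = derive_seed(seed, 8L),
                      config_base = hopf_cfg, tau = config$phiid$tau)
    write.table(
      data.frame(alpha = sw$alphas, similarity = sw$similarity,
                 sig_count = sw$sig_count),
      file.path(out, "sweep.tsv"), sep = "\t", row.names = FALSE, quote = FALSE
    )
    manifest$artifacts$sweep <- "sweep.tsv"
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
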