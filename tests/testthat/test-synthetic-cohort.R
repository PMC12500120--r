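test_that("region table has mirrored hemispheres and the expected structure", {
  tab <- make_region_table(84, seed = 1)
  expect_equal(nrow(tab), 84)
  expect_equal(tab$region_index, 0:83)
  expect_equal(sum(tab$hemisphere == "left"), 42)
  expect_equal(sum(tab$hemisphere == "right"), 42)
  expect_false(any(duplicated(tab$name)))
  for (s in c("thalamus", "caudate", "putamen", "pallidum", "accumbens")) {
    expect_true(paste0("lh_", s) %in% tab$name)
    expect_true(paste0("rh_", s) %in% tab$name)
    expect_true(all(tab$is_subcortical[tab$name %in% paste0(c("lh_", "rh_"), s)]))
  }
  # mirrored coordinates
  expect_equal(tab$x[tab$hemisphere == "left"], -tab$x[tab$hemisphere == "right"])
  expect_equal(tab$y[tab$hemisphere == "left"], tab$y[tab$hemisphere == "right"])

  small <- make_region_table(4, seed = 2)
  expect_equal(sum(small$hemisphere == "left"), 2)

  expect_identical(make_region_table(84, seed = 5), make_region_table(84, seed = 5))
  expect_error(make_region_table(5), "even")
  expect_error(make_region_table(2), "even|>= 4")
})

test_that("region table round-trips through CSV", {
  tab <- make_region_table(8, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_table(tab, path)
  back <- read_region_table(path)
  expect_equal(back$name, tab$name)
  expect_equal(back$x, tab$x, tolerance = 1e-12)
  expect_identical(back$is_subcortical, tab$is_subcortical)
})

test_that("connectome cohort satisfies structural invariants on many draws", {
  tab <- make_region_table(16, seed = 7)
  for (s in 1:25) {
    cohort <- make_connectome_cohort(tab, n_subjects = 4, density = 0.5, seed = s)
    for (cn in cohort) {
      expect_true(isSymmetric(cn$weights))
      expect_true(isSymmetric(cn$lengths))
      expect_equal(diag(cn$weights), rep(0, 16))
      expect_equal(diag(cn$lengths), rep(0, 16))
      expect_true(all(cn$weights >= 0))
      expect_true(all(cn$lengths[cn$weights > 0] > 0))
    }
  }
})

test_that("zero jitter collapses the cohort onto the shared backbone", {
  tab <- make_region_table(16, seed = 7)
  cohort <- make_connectome_cohort(tab, n_subjects = 3, density = 0.5,
                                   subject_jitter = 0, seed = 1)
  expect_identical(cohort[[1]]$weights, cohort[[2]]$weights)
  expect_identical(cohort[[2]]$lengths, cohort[[3]]$lengths)
  # jitter-free lengths are Euclidean distances: triangle inequality holds
  D <- cohort[[1]]$lengths
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (k in 1:5) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("subjects stay strongly correlated with the group backbone", {
  tab <- make_region_table(84, seed = 9)
  cohort <- make_connectome_cohort(tab, n_subjects = 20, seed = 10)
  backbone <- make_connectome_cohort(tab, n_subjects = 1, subject_jitter = 0,
                                     seed = 10)[[1]]$weights
  ut <- upper.tri(backbone)
  cors <- vapply(cohort, function(cn) cor(cn$weights[ut], backbone[ut]),
                 numeric(1))
  expect_gt(mean(cors), 0.8)
})

test_that("generator is reproducible and rejects bad arguments", {
  tab <- make_region_table(16, seed = 7)
  a <- make_connectome_cohort(tab, n_subjects = 2, density = 0.5, seed = 42)
  b <- make_connectome_cohort(tab, n_subjects = 2, density = 0.5, seed = 42)
  expect_identical(a, b)
  expect_error(make_connectome_cohort(tab, n_subjects = 0), "n_subjects")
  expect_error(make_connectome_cohort(tab, density = 0), "density")
  # very sparse backbones disconnect and must say so
  expect_error(make_connectome_cohort(tab, density = 0.05, seed = 1),
               "disconnected")
})

test_that("connectome cohort round-trips through TSV files", {
  cohort <- fixture_cohort(n_regions = 8, n_subjects = 2, density = 0.7)
  dir <- withr::local_tempdir()
  write_connectome_cohort(cohort, dir)
  back <- read_connectome_cohort(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$weights, cohort[[1]]$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back[[2]]$lengths, cohort[[2]]$lengths, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ground-truth cohorts have one run per connectome and respond to stimulation", {
  cohort <- fixture_cohort(n_regions = 8, n_subjects = 3, density = 0.7)
  cfg <- hopf_config(duration = 300, trim = 25, beta = rep(0.5, 8),
                     bias = -0.17, scale = 0.24, band = c(0.01, 0.1))
  gt <- make_ground_truth_cohorts(cohort, cfg, alpha = -1, target = 2, seed = 5)
  expect_equal(length(gt$control$series), 3)
  expect_equal(length(gt$tus$series), 3)
  expect_equal(gt$control$condition, "control")
  expect_equal(gt$tus$target, 2)
  # strongly negative alpha quenches the target's variance across seeds
  v_ctrl <- v_tus <- numeric(0)
  for (s in 1:4) {
    gts <- make_ground_truth_cohorts(cohort, cfg, alpha = -1, target = 2,
                                     seed = s)
    v_ctrl <- c(v_ctrl, vapply(gts$control$series, function(x) var(x[, 2]),
                               numeric(1)))
    v_tus <- c(v_tus, vapply(gts$tus$series, function(x) var(x[, 2]),
                             numeric(1)))
  }
  expect_lt(median(v_tus), median(v_ctrl))
})
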