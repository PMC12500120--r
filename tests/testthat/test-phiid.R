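test_that("zscore standardizes and rejects degenerate input", {
  x <- rnorm(100, mean = 5, sd = 3)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(var(z), 1, tolerance = 1e-12)
  z0 <- zscore(scale(rnorm(50))[, 1])
  expect_equal(sd(z0), 1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 50)), "degenerate")
})

test_that("lagged covariance matches AR(1) autocovariance and handles degeneracy", {
  set.seed(42)
  phi <- 0.7
  T <- 50000
  x <- as.numeric(arima.sim(list(ar = phi), T))
  y <- rnorm(T)
  for (tau in c(1L, 2L, 3L)) {
    lc <- lagged_cov(zscore(x), zscore(y), tau = tau)
    expect_s3_class(lc, "lagged_cov")
    expect_equal(lc$n_samples, T - tau)
    # autocovariance of a z-scored AR(1) at lag tau is phi^tau
    expect_equal(lc$cov[1, 3], phi^tau, tolerance = 4 / sqrt(T))
    # independent y: cross terms vanish
    expect_lt(abs(lc$cov[1, 2]), 3 / sqrt(T))
    expect_lt(abs(lc$cov[1, 4]), 3 / sqrt(T))
  }
  expect_error(lagged_cov(x[1:100], y[1:100], tau = 100), "tau")
  expect_error(lagged_cov(x[1:31], y[1:31], tau = 2), "30")
  # duplicated signal: rank-deficient, must warn and ridge
  expect_warning(lc2 <- lagged_cov(zscore(x[1:500]), zscore(x[1:500])),
                 "positive definite")
  ev <- eigen(lc2$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("gaussian MI has its closed form and is symmetric and nonnegative", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(gaussian_mi(S, 1, 2), -0.5 * log(1 - 0.25), tolerance = 1e-12)
  expect_equal(gaussian_mi(diag(4), c(1, 2), c(3, 4)), 0)
  for (s in 1:20) {
    R <- random_corr(4, seed = s)
    expect_equal(gaussian_mi(R, c(1, 2), c(3, 4)),
                 gaussian_mi(R, c(3, 4), c(1, 2)), tolerance = 1e-12)
    expect_gte(gaussian_mi(R, 1, 3), -1e-12)
  }
  expect_error(gaussian_mi(S, 1, 1), "disjoint")
  expect_error(gaussian_mi(S, integer(0), 2), "nonempty|disjoint")
})

test_that("product lattice has 16 nodes with the product partial order", {
  lat <- build_product_lattice()
  expect_length(lat$nodes, 16)
  expect_length(unique(lat$nodes), 16)
  bottom <- "{1}{2}->{1}{2}"
  top <- "{12}->{12}"
  expect_length(lat$down[[bottom]], 0)
  expect_length(lat$down[[top]], 15)
  # partial order axioms on the leq matrix
  expect_true(all(diag(lat$leq)))
  leq <- lat$leq
  for (i in 1:16) for (j in 1:16) {
    if (i != j && leq[i, j] && leq[j, i]) fail("antisymmetry violated")
  }
  # linear extension: everything below a node precedes it
  pos <- stats::setNames(seq_along(lat$nodes), lat$nodes)
  for (nd in lat$nodes) {
    for (lower in lat$down[[nd]]) expect_lt(pos[[lower]], pos[[nd]])
  }
})

test_that("atoms conserve TDMI and match the direct linear-solve oracle", {
  lat <- build_product_lattice()
  for (s in 1:60) {
    S <- random_corr(4, seed = 1000 + s)
    at <- phiid_mmi_atoms(S)
    tdmi <- gaussian_mi(S, c(1, 2), c(3, 4))
    expect_equal(sum(at$atoms), tdmi, tolerance = 1e-8)
    oracle <- phiid_oracle_atoms(S, lat)
    expect_equal(unname(at$atoms), oracle, tolerance = 1e-10)
    expect_gte(at$rtr, 0)
    expect_equal(at$tdmi, tdmi, tolerance = 1e-12)
  }
  at0 <- phiid_mmi_atoms(diag(4))
  expect_equal(unname(at0$atoms), rep(0, 16))
})

test_that("static MMI PID redundancy equals the minimum source-target MI", {
  for (s in 1:20) {
    S <- random_corr(3, seed = 2000 + s)
    p <- pid_mmi(S)
    expect_identical(unname(p["redundancy"]),
                     min(gaussian_mi(S, 1, 3), gaussian_mi(S, 2, 3)))
    expect_gte(p["unique_1"], -1e-12)
    expect_gte(p["unique_2"], -1e-12)
    expect_equal(unname(p["redundancy"] + p["unique_1"] + p["unique_2"] +
                          p["synergy"]), unname(p["joint_mi"]),
                 tolerance = 1e-12)
  }
})

test_that("hoi maps: independence limit, equivariance, ranks, degenerate input", {
  set.seed(99)
  X <- matrix(rnorm(10000 * 4), ncol = 4)
  maps <- hoi_matrices(X)
  expect_true(all(abs(maps$median_redundancy) < 1e-2))
  expect_true(all(is.na(diag(maps$redundancy))))
  expect_true(isSymmetric(unname(ifelse(is.na(maps$synergy), 0, maps$synergy))))

  # permutation equivariance
  set.seed(100)
  Y <- matrix(as.numeric(arima.sim(list(ar = 0.5), 600 * 5)), ncol = 5)
  m1 <- hoi_matrices(Y)
  perm <- c(3, 1, 5, 2, 4)
  m2 <- hoi_matrices(Y[, perm])
  expect_equal(m2$redundancy, m1$redundancy[perm, perm], tolerance = 1e-10)
  expect_equal(m2$median_synergy, m1$median_synergy[perm], tolerance = 1e-10)

  expect_equal(rank(c(0.1, 0.3, 0.2)), c(1, 3, 2))
  Xbad <- X
  Xbad[, 2] <- 1
  expect_error(hoi_matrices(Xbad), "2")
})

test_that("stationary-series atoms stabilize as T grows", {
  gen <- function(T, seed) {
    set.seed(seed)
    matrix(as.numeric(arima.sim(list(ar = 0.6), T * 3)), ncol = 3)
  }
  m_small <- hoi_matrices(gen(2000, 7))
  m_big <- hoi_matrices(gen(8000, 8))
  ut <- upper.tri(m_small$redundancy)
  # O(1/sqrt(T)) drift: generous band, checks stability not equality
  expect_lt(max(abs(m_small$redundancy[ut] - m_big$redundancy[ut])), 0.1)
})

test_that("hoi maps serialize to TSV + JSON sidecar", {
  set.seed(1)
  maps <- hoi_matrices(matrix(rnorm(400 * 3), ncol = 3))
  dir <- withr::local_tempdir()
  write_hoi_maps(maps, dir, prefix = "t")
  expect_true(file.exists(file.path(dir, "t_redundancy.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "t_meta.json"))
  expect_equal(meta$tau, 1)
  expect_equal(meta$units, "nats")
  back <- read_matrix_tsv(file.path(dir, "t_synergy.tsv"))
  expect_equal(back[2, 3], maps$synergy[2, 3], tolerance = 1e-12)
})
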