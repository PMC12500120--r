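test_that("representative matrices are means normalized by their maximum", {
  cohort <- fixture_cohort(n_regions = 8, n_subjects = 3, density = 0.7)
  dbar <- representative_distance(cohort)
  mbar <- representative_weights(cohort)
  expect_equal(max(dbar), 1)
  expect_equal(max(mbar), 1)
  expect_true(all(dbar >= 0 & dbar <= 1))
  expect_true(all(mbar >= 0 & mbar <= 1))
  expect_true(isSymmetric(dbar))
  expect_equal(diag(mbar), rep(0, 8))
  # single subject: equals its own normalized matrix
  one <- representative_distance(cohort[1])
  expect_equal(one, cohort[[1]]$lengths / max(cohort[[1]]$lengths))
  # two identical subjects: same as either alone
  expect_equal(representative_weights(cohort[c(1, 1)]),
               cohort[[1]]$weights / max(cohort[[1]]$weights))
})

test_that("cost matrix inverts weights with Inf for absent edges", {
  w <- matrix(c(0, 0.5, 0, 0.5, 0, 1, 0, 1, 0), 3)
  L <- cost_matrix(w)
  expect_equal(L[1, 2], 2)
  expect_equal(L[2, 3], 1)
  expect_identical(L[1, 3], Inf)
  expect_equal(diag(L), rep(0, 3))
})

test_that("shortest paths match brute-force enumeration with lexicographic ties", {
  # 3-node chain with unit costs
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  sp <- shortest_paths_cost(cost_matrix(w))
  expect_equal(sp$lambda[1, 3], 2)
  expect_equal(diag(sp$lambda), rep(0, 3))
  expect_equal(reconstruct_route(sp, 1, 3), c(1, 2, 3))

  for (s in 1:25) {
    n <- sample(5:8, 1)
    w <- random_toy_graph(n, p_edge = 0.5, seed = 300 + s)
    L <- cost_matrix(w / max(w))
    sp <- shortest_paths_cost(L)
    for (pair in list(c(1, n), c(2, n - 1), c(1, 2))) {
      bf <- brute_shortest(L, pair[1], pair[2])
      expect_equal(sp$lambda[pair[1], pair[2]], bf$cost, tolerance = 1e-10)
      if (is.finite(bf$cost)) {
        expect_equal(reconstruct_route(sp, pair[1], pair[2]), bf$path)
      }
    }
    # triangle inequality of minimal costs
    lam <- sp$lambda
    for (k in 1:n) {
      expect_true(all(lam <= outer(lam[, k], lam[k, ], `+`) + 1e-9))
    }
  }
})

test_that("SPE inverts costs and flags unreachable pairs with zero", {
  lam <- matrix(c(0, 2, Inf, 2, 0, 4, Inf, 4, 0), 3)
  e <- spe(lam)
  expect_equal(e[1, 2], 0.5)
  expect_equal(e[2, 3], 0.25)
  expect_equal(e[1, 3], 0)
  expect_true(all(is.na(diag(e))))
})

test_that("search information reproduces hand-enumerated chains and brute force", {
  # 3-node chain, uniform weights: end-to-end walks must pick the middle's
  # 1-of-2 branch; one bit of information
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  sp <- shortest_paths_cost(cost_matrix(w))
  SI <- search_information(w, sp)
  expect_equal(SI[1, 3], 1)
  # single-neighbor start, one hop: probability 1, zero bits
  expect_equal(SI[1, 2], 0)
  # asymmetry: from the middle, the first step already costs a bit
  expect_equal(SI[2, 1], 1)

  for (s in 1:15) {
    w <- random_toy_graph(6, p_edge = 0.6, seed = 400 + s)
    L <- cost_matrix(w / max(w))
    sp <- shortest_paths_cost(L)
    SI <- search_information(w / max(w), sp)
    Tr <- (w / max(w)) / rowSums(w / max(w))
    i <- 1; j <- 6
    bf <- brute_shortest(L, i, j)
    if (is.finite(bf$cost)) {
      steps <- cbind(bf$path[-length(bf$path)], bf$path[-1])
      expect_equal(SI[i, j], -sum(log2(Tr[steps])), tolerance = 1e-10)
    }
  }
})

test_that("communicability equals its truncated series and keeps symmetry", {
  w0 <- matrix(0, 4, 4)
  expect_error(communicability(w0), "zero-strength")
  for (s in 1:15) {
    w <- random_toy_graph(6, p_edge = 0.7, seed = 500 + s)
    for (norm in c("as_printed", "symmetric_sqrt")) {
      cmy <- communicability(w, norm)
      strength <- rowSums(w)
      denom <- if (norm == "as_printed") outer(strength, strength) else
        sqrt(outer(strength, strength))
      Wp <- w / denom
      series <- diag(6)
      term <- diag(6)
      for (k in 1:40) {
        term <- term %*% Wp / k
        series <- series + term
      }
      expect_equal(cmy, series, tolerance = 1e-10, ignore_attr = TRUE)
      expect_true(isSymmetric(cmy, tol = 1e-10))
      # all walk counts are nonnegative additions over the identity
      expect_true(all(diag(cmy) >= 1 - 1e-12))
      expect_true(all(cmy >= -1e-12))
    }
  }
})

test_that("model vectors extract seed rows and scaled node summaries", {
  m <- matrix(runif(25), 5)
  m <- (m + t(m)) / 2
  expect_equal(model_vector(m, "seed_row", target = 3), m[3, ])
  expect_equal(model_vector(m, "seed_row", target = 3), m[, 3])
  v <- model_vector(m, "node_summary")
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)
  expect_error(model_vector(m, "seed_row", target = 9), "range")
  cm <- matrix(1, 4, 4)
  expect_warning(vc <- model_vector(cm, "node_summary"), "constant")
  expect_equal(vc, rep(0, 4))
})

test_that("full model set is assembled consistently", {
  cohort <- fixture_cohort(n_regions = 12, n_subjects = 3, density = 0.7)
  ms <- comm_model_set(cohort)
  expect_s3_class(ms, "comm_model_set")
  expect_equal(dim(ms$CMY), c(12, 12))
  expect_equal(ms$unreachable_pairs, 0)
  expect_equal(ms$SPE[2, 5], 1 / ms$lambda[2, 5])
  # SI asymmetric in general, SPE symmetric
  expect_true(isSymmetric(ms$SPE[2:12, 2:12] * 1))
})
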