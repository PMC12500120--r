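# Shared fixtures, all generated in code at test time.

# random correlation-like positive-definite matrix with unit diagonal
random_corr <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  cov2cor(crossprod(A) + diag(0.5, d))
}

# small synthetic cohort reused across comm-model and simulator tests
fixture_cohort <- function(n_regions = 16, n_subjects = 4, density = 0.5,
                           seed = 11) {
  tab <- make_region_table(n_regions, seed = seed)
  make_connectome_cohort(tab, n_subjects = n_subjects, density = density,
                         seed = seed + 1)
}

# zeta matrix of the product lattice: f = Z %*% atoms
lattice_zeta <- function(lat = build_product_lattice()) {
  t(1 * lat$leq)
}

# independent oracle: cumulative MMI values solved directly (16x16 system)
phiid_oracle_atoms <- function(S, lat = build_product_lattice()) {
  colls <- list("{1}{2}" = list(1L, 2L), "{1}" = list(1L), "{2}" = list(2L),
                "{12}" = list(c(1L, 2L)))
  f <- vapply(seq_along(lat$nodes), function(i) {
    min(unlist(lapply(colls[[lat$a[i]]], function(a) {
      lapply(colls[[lat$b[i]]], function(b) gaussian_mi(S, a, b + 2L))
    })))
  }, numeric(1))
  as.numeric(solve(lattice_zeta(lat), f))
}

# brute-force shortest path by enumeration over all simple paths (small n)
brute_shortest <- function(L, i, j) {
  n <- nrow(L)
  best <- Inf
  best_path <- NULL
  recurse <- function(path, cost) {
    last <- path[length(path)]
    if (last == j) {
      if (cost < best - 1e-12 ||
          (abs(cost - best) <= 1e-12 &&
           paste(path, collapse = ",") < paste(best_path, collapse = ","))) {
        best <<- cost
        best_path <<- path
      }
      return()
    }
    for (k in setdiff(which(is.finite(L[last, ]) & L[last, ] > 0), path)) {
      if (cost + L[last, k] <= best + 1e-12) recurse(c(path, k), cost + L[last, k])
    }
  }
  recurse(i, 0)
  list(cost = best, path = best_path)
}

random_toy_graph <- function(n, p_edge = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    vals <- ifelse(runif(sum(ut)) < p_edge, runif(sum(ut), 0.1, 1), 0)
    w[ut] <- vals
    w <- w + t(w)
    if (all(rowSums(w) > 0)) return(w)
  }
}
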