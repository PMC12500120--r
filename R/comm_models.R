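# Structural communication models on a representative connectome: streamline
# distance, shortest-path efficiency (SPE), search information (SI) and
# network communicability (CMY).

#' Representative (group) structural matrices
#'
#' Elementwise mean across subjects, normalized by the maximum so entries lie
#' in \[0, 1\].
#'
#' @param cohort list of connectomes (see [make_connectome_cohort()]).
#' @return N x N matrix.
#' @export
representative_distance <- function(cohort) {
  stopifnot(length(cohort) >= 1)
  m <- Reduce(`+`, lapply(cohort, `[[`, "lengths")) / length(cohort)
  mx <- max(m)
  if (mx <= 0) stop("representative_distance: all lengths are zero")
  m / mx
}

#' @rdname representative_distance
#' @export
representative_weights <- function(cohort) {
  stopifnot(length(cohort) >= 1)
  m <- Reduce(`+`, lapply(cohort, `[[`, "weights")) / length(cohort)
  mx <- max(m)
  if (mx <= 0) stop("representative_weights: all weights are zero")
  m / mx
}

#' Communication cost matrix
#'
#' `L_ij = 1 / w_ij` where an edge exists, `Inf` otherwise; zero diagonal.
#'
#' @param weights normalized weight matrix in \[0, 1\].
#' @return N x N cost matrix.
#' @export
cost_matrix <- function(weights) {
  L <- ifelse(weights > 0, 1 / weights, Inf)
  diag(L) <- 0
  L
}

#' All-pairs shortest transmission costs and routes
#'
#' Minimal path costs on the cost matrix (Dijkstra via igraph), plus a
#' next-hop structure that reconstructs, for every pair, the
#' lexicographically smallest cost-minimal node sequence — a deterministic
#' tie-break so downstream search information is reproducible.
#'
#' @param L cost matrix from [cost_matrix()] (`Inf` = absent edge).
#' @return list with `lambda` (N x N minimal costs, `Inf` unreachable) and
#'   `next_hop` (N x N integer; `next_hop[i, j]` is the first step of the
#'   stored i-to-j route, `NA` if unreachable or `i == j`).
#' @export
shortest_paths_cost <- function(L) {
  n <- nrow(L)
  A <- L
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  lambda <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(lambda) <- NULL
  next_hop <- matrix(NA_integer_, n, n)
  tol <- 1e-10
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !is.finite(lambda[i, j])) next
      # smallest first step k on a cost-minimal route yields the
      # lexicographically smallest node sequence when applied recursively
      cand <- which(is.finite(L[i, ]) & L[i, ] > 0)
      ok <- cand[abs(L[i, cand] + lambda[cand, j] - lambda[i, j]) <=
                   tol * max(1, lambda[i, j])]
      next_hop[i, j] <- min(ok)
    }
  }
  list(lambda = lambda, next_hop = next_hop)
}

#' Reconstruct the stored shortest route between two nodes
#'
#' @param sp output of [shortest_paths_cost()].
#' @param i,j 1-based node indices.
#' @return integer vector of node indices from `i` to `j`, or `NULL` if
#'   unreachable.
#' @export
reconstruct_route <- function(sp, i, j) {
  if (i == j) return(i)
  if (is.na(sp$next_hop[i, j])) return(NULL)
  path <- i
  cur <- i
  while (cur != j) {
    cur <- sp$next_hop[cur, j]
    path <- c(path, cur)
    if (length(path) > nrow(sp$lambda)) stop("route reconstruction cycled")
  }
  path
}

#' Shortest-path efficiency
#'
#' Inverse of the minimal transmission cost; 0 for unreachable pairs, `NA`
#' diagonal.
#'
#' @param lambda minimal-cost matrix from [shortest_paths_cost()].
#' @return N x N matrix.
#' @export
spe <- function(lambda) {
  out <- ifelse(is.finite(lambda) & lambda > 0, 1 / lambda, 0)
  diag(out) <- NA_real_
  out
}

#' Search information along stored shortest routes
#'
#' Bits needed to bias a random walk onto the stored shortest path: the walk
#' transition matrix is the row-normalized weight matrix, the route
#' probability is the product of transition probabilities along the stored
#' route, and `SI = -log2` of that probability. Asymmetric by construction.
#'
#' @param weights normalized weight matrix.
#' @param sp output of [shortest_paths_cost()] computed on
#'   `cost_matrix(weights)`.
#' @return N x N matrix in bits; `Inf` for unreachable pairs, `NA` diagonal.
#' @export
search_information <- function(weights, sp) {
  n <- nrow(weights)
  strength <- rowSums(weights)
  if (any(strength == 0)) {
    stop("search_information: isolated node(s): ",
         paste(which(strength == 0), collapse = ", "))
  }
  Tr <- weights / strength
  SI <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      route <- reconstruct_route(sp, i, j)
      if (is.null(route)) next
      steps <- cbind(route[-length(route)], route[-1])
      SI[i, j] <- -sum(log2(Tr[steps]))
    }
  }
  diag(SI) <- NA_real_
  SI
}

#' Network communicability
#'
#' Matrix exponential of the strength-normalized weight matrix: walks of
#' length n are discounted by 1/n!. Two normalizations of `W' = f(W, s)` are
#' supported: `as_printed` divides by the product of endpoint strengths
#' (`W_ij / (s_i s_j)`), `symmetric_sqrt` by its square root
#' (`W_ij / sqrt(s_i s_j)`), the convention of the communicability
#' literature for weighted graphs.
#'
#' @param weights symmetric nonnegative weight matrix.
#' @param normalization `"as_printed"` (default) or `"symmetric_sqrt"`.
#' @return N x N communicability matrix.
#' @export
communicability <- function(weights, normalization = c("as_printed", "symmetric_sqrt")) {
  normalization <- match.arg(normalization)
  if (!is_symmetric_num(weights)) stop("communicability: weights must be symmetric")
  s <- rowSums(weights)
  if (any(s == 0)) {
    stop("communicability: zero-strength node(s): ",
         paste(which(s == 0), collapse = ", "))
  }
  denom <- if (normalization == "as_printed") outer(s, s) else sqrt(outer(s, s))
  Wp <- weights / denom
  as.matrix(Matrix::expm(Matrix::Matrix(Wp)))
}

#' Reduce a pairwise communication model to a regional vector
#'
#' `seed_row` extracts the model's row at a stimulation target (for
#' target-anchored associations); `node_summary` takes the per-region row
#' median (diagonal and non-finite entries excluded) and min-max scales it to
#' \[0, 1\] (the heterogeneity vector fed to the whole-brain model).
#'
#' @param model N x N model matrix.
#' @param mode `"seed_row"` or `"node_summary"`.
#' @param target 1-based region index (required for `seed_row`).
#' @return length-N numeric vector.
#' @export
model_vector <- function(model, mode = c("seed_row", "node_summary"), target = NULL) {
  mode <- match.arg(mode)
  n <- nrow(model)
  if (mode == "seed_row") {
    if (is.null(target) || target < 1 || target > n) {
      stop("model_vector: target index out of range")
    }
    return(model[target, ])
  }
  m <- model
  m[!is.finite(m)] <- NA_real_
  diag(m) <- NA_real_
  v <- apply(m, 1, median, na.rm = TRUE)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("model_vector: constant summary; returning zeros")
    return(rep(0, n))
  }
  (v - rng[1]) / diff(rng)
}

#' Build the full communication model set
#'
#' Convenience wrapper producing the representative distance and weight
#' matrices and all four communication models from a connectome cohort.
#'
#' @param cohort list of connectomes.
#' @param normalization communicability normalization (see
#'   [communicability()]).
#' @return list of class `comm_model_set` with elements `distance`,
#'   `weights`, `cost`, `lambda`, `next_hop`, `SPE`, `SI`, `CMY`, `strength`,
#'   `unreachable_pairs`.
#' @export
comm_model_set <- function(cohort, normalization = "as_printed") {
  dbar <- representative_distance(cohort)
  mbar <- representative_weights(cohort)
  L <- cost_matrix(mbar)
  sp <- shortest_paths_cost(L)
  structure(list(
    distance = dbar,
    weights = mbar,
    cost = L,
    lambda = sp$lambda,
    next_hop = sp$next_hop,
    SPE = spe(sp$lambda),
    SI = search_information(mbar, sp),
    CMY = communicability(mbar, normalization),
    strength = rowSums(mbar),
    unreachable_pairs = sum(!is.finite(sp$lambda[upper.tri(sp$lambda)]))
  ), class = "comm_model_set")
}
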