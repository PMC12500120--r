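# Gaussian integrated information decomposition (MMI redundancy function).
#
# For a pair of z-scored regional signals we form the 4-variate system
# (X_i(t-tau), X_j(t-tau), X_i(t), X_j(t)) and decompose the time-delayed
# mutual information I(past; present) over the 16-node product of two copies
# of the redundancy lattice {{1}{2}, {1}, {2}, {12}}. Cumulative values use
# the minimum-mutual-information redundancy: f(alpha -> beta) is the minimum
# Gaussian MI between any source collection in alpha (past) and any target
# collection in beta (present). Atoms follow by Moebius inversion.

#' Lagged covariance of a signal pair
#'
#' Sample covariance of the design `(x_{t-tau}, y_{t-tau}, x_t, y_t)`.
#' Inputs are expected z-scored (see [zscore()]); the result then has a unit
#' diagonal up to the O(tau/T) loss from trimming. If the matrix is not
#' positive definite (e.g. `y` duplicates `x`) the diagonal is ridged by
#' 1e-9 with a warning.
#'
#' @param x,y numeric vectors of equal length T.
#' @param tau positive integer lag, samples.
#' @return an object of class `lagged_cov`: list with `cov` (4 x 4), `tau`,
#'   `n_samples` (= T - tau).
#' @export
lagged_cov <- function(x, y, tau = 1L) {
  if (tau < 1) stop("lagged_cov: tau must be >= 1")
  T <- length(x)
  if (length(y) != T) stop("lagged_cov: x and y must have equal length")
  if (tau >= T) stop("lagged_cov: tau must be smaller than the series length")
  if (T - tau < 30) stop("lagged_cov: need at least 30 usable samples")
  idx_past <- seq_len(T - tau)
  idx_pres <- idx_past + tau
  design <- cbind(x[idx_past], y[idx_past], x[idx_pres], y[idx_pres])
  S <- cov(design)
  S <- regularize_pd(S)
  structure(list(cov = S, tau = as.integer(tau), n_samples = T - tau),
            class = "lagged_cov")
}

regularize_pd <- function(S, eps = 1e-9) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= eps) {
    warning("covariance not positive definite; ridging diagonal by 1e-9")
    S <- S + diag(eps, nrow(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance persistently non-positive-definite")
  }
  S
}

#' Gaussian mutual information between two index subsets
#'
#' `I(A; B) = (log det S_AA + log det S_BB - log det S_AB) / 2` in nats,
#' for a jointly Gaussian vector with covariance `cov`.
#'
#' @param cov covariance matrix, or a `lagged_cov` object.
#' @param set_a,set_b disjoint nonempty 1-based index subsets.
#' @return mutual information in nats (nonnegative up to roundoff).
#' @export
#' @examples
#' S <- matrix(c(1, 0.5, 0.5, 1), 2)
#' gaussian_mi(S, 1, 2)  # -log(1 - 0.25) / 2
gaussian_mi <- function(cov, set_a, set_b) {
  if (inherits(cov, "lagged_cov")) cov <- cov$cov
  if (length(set_a) == 0 || length(set_b) == 0 ||
      length(intersect(set_a, set_b)) > 0) {
    stop("gaussian_mi: index sets must be disjoint and nonempty")
  }
  ld <- function(idx) {
    d <- determinant(cov[idx, idx, drop = FALSE], logarithm = TRUE)
    if (d$sign <= 0) stop("gaussian_mi: singular submatrix")
    as.numeric(d$modulus)
  }
  0.5 * (ld(set_a) + ld(set_b) - ld(c(set_a, set_b)))
}

# ---- lattice ---------------------------------------------------------------

# PID redundancy lattice over two sources. Each node is a collection of
# source subsets; the order is: alpha <= beta iff every collection in beta
# contains some collection of alpha. With two sources this is the chain/
# diamond {1}{2} < {1}, {2} < {12} ({1} and {2} incomparable).
.pid_nodes <- c("{1}{2}", "{1}", "{2}", "{12}")
.pid_leq <- {
  m <- matrix(FALSE, 4, 4, dimnames = list(.pid_nodes, .pid_nodes))
  m["{1}{2}", ] <- TRUE
  m["{1}", c("{1}", "{12}")] <- TRUE
  m["{2}", c("{2}", "{12}")] <- TRUE
  m["{12}", "{12}"] <- TRUE
  m
}
# collections of source indices represented by each node
.pid_collections <- list(
  "{1}{2}" = list(1L, 2L),
  "{1}"    = list(1L),
  "{2}"    = list(2L),
  "{12}"   = list(c(1L, 2L))
)

#' Product lattice of the integrated information decomposition
#'
#' The 16 nodes are pairs `alpha -> beta` of redundancy-lattice nodes
#' (`alpha` describes the past/source side, `beta` the present/target side);
#' the partial order is the product order. Nodes are returned in a linear
#' extension (any node appears after everything strictly below it), so
#' Moebius inversion can run in one pass.
#'
#' @return list with `nodes` (character vector of 16 labels like
#'   `"{1}{2}->{12}"`), `leq` (16 x 16 logical matrix, `leq[a, b]` true iff
#'   node a is below-or-equal node b) and `down` (named list of strict
#'   down-sets).
#' @export
build_product_lattice <- function() {
  grid <- expand.grid(a = .pid_nodes, b = .pid_nodes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nodes <- paste0(grid$a, "->", grid$b)
  leq <- matrix(FALSE, 16, 16, dimnames = list(nodes, nodes))
  for (p in 1:16) {
    for (q in 1:16) {
      leq[p, q] <- .pid_leq[grid$a[p], grid$a[q]] && .pid_leq[grid$b[p], grid$b[q]]
    }
  }
  # linear extension: sort by down-set size
  ord <- order(colSums(leq))
  nodes <- nodes[ord]
  grid <- grid[ord, ]
  leq <- leq[ord, ord]
  down <- lapply(seq_along(nodes), function(i) {
    setdiff(nodes[leq[, i]], nodes[i])
  })
  names(down) <- nodes
  list(nodes = nodes, a = grid$a, b = grid$b, leq = leq, down = down)
}

.lattice_cache <- new.env(parent = emptyenv())
phiid_lattice <- function() {
  if (is.null(.lattice_cache$lat)) .lattice_cache$lat <- build_product_lattice()
  .lattice_cache$lat
}

#' ΦID atoms under the MMI redundancy function
#'
#' Computes the 16 atoms of the integrated information decomposition for a
#' Gaussian pair, given the lagged covariance of
#' `(x_{t-tau}, y_{t-tau}, x_t, y_t)`. Cumulative values are
#' `f(alpha -> beta) = min I(a_past; b_present)` over collections `a` of
#' `alpha` and `b` of `beta`; atoms are recovered by Moebius inversion, so
#' they sum exactly to the time-delayed mutual information
#' `I(x_{t-tau}, y_{t-tau}; x_t, y_t)`.
#'
#' @param cov a `lagged_cov` object or a bare 4 x 4 positive-definite matrix.
#' @return list with `atoms` (named numeric of length 16, nats), `rtr`
#'   (persistent redundancy, the `{1}{2}->{1}{2}` atom), `sts` (persistent
#'   synergy, `{12}->{12}`), and `tdmi`.
#' @export
phiid_mmi_atoms <- function(cov) {
  if (inherits(cov, "lagged_cov")) cov <- cov$cov
  stopifnot(is.matrix(cov), all(dim(cov) == 4))
  lat <- phiid_lattice()
  # base MIs between single collections: past subsets x present subsets
  subsets <- list("1" = 1L, "2" = 2L, "12" = c(1L, 2L))
  base <- matrix(NA_real_, 3, 3, dimnames = list(names(subsets), names(subsets)))
  for (a in names(subsets)) {
    for (b in names(subsets)) {
      base[a, b] <- gaussian_mi(cov, subsets[[a]], subsets[[b]] + 2L)
    }
  }
  coll_key <- function(v) paste(v, collapse = "")
  f <- numeric(16)
  names(f) <- lat$nodes
  for (i in seq_along(lat$nodes)) {
    cas <- .pid_collections[[lat$a[i]]]
    cbs <- .pid_collections[[lat$b[i]]]
    vals <- outer(seq_along(cas), seq_along(cbs),
                  Vectorize(function(p, q) base[coll_key(cas[[p]]), coll_key(cbs[[q]])]))
    f[i] <- min(vals)
  }
  atoms <- numeric(16)
  names(atoms) <- lat$nodes
  for (i in seq_along(lat$nodes)) {
    below <- lat$down[[lat$nodes[i]]]
    atoms[i] <- f[i] - sum(atoms[below])
  }
  list(
    atoms = atoms,
    rtr = unname(atoms["{1}{2}->{1}{2}"]),
    sts = unname(atoms["{12}->{12}"]),
    tdmi = unname(f["{12}->{12}"])
  )
}

#' Static Gaussian PID with the MMI redundancy
#'
#' Single-target partial information decomposition of `I(X1, X2; Y)` for a
#' jointly Gaussian triple: redundancy is the smaller of the two
#' source-target informations, unique terms are the excesses, synergy the
#' remainder of the joint information.
#'
#' @param cov 3 x 3 covariance over (X1, X2, Y).
#' @return named numeric: `redundancy`, `unique_1`, `unique_2`, `synergy`,
#'   `joint_mi` (nats).
#' @export
pid_mmi <- function(cov) {
  stopifnot(is.matrix(cov), all(dim(cov) == 3))
  i1 <- gaussian_mi(cov, 1L, 3L)
  i2 <- gaussian_mi(cov, 2L, 3L)
  i12 <- gaussian_mi(cov, c(1L, 2L), 3L)
  red <- min(i1, i2)
  c(
    redundancy = red,
    unique_1 = i1 - red,
    unique_2 = i2 - red,
    synergy = i12 - i1 - i2 + red,
    joint_mi = i12
  )
}

# ---- whole-matrix maps -----------------------------------------------------

#' Pairwise persistent redundancy / synergy maps for one subject
#'
#' Z-scores each region, forms the lagged covariance of every unordered
#' region pair, runs [phiid_mmi_atoms()], and assembles the two symmetric
#' N x N matrices of persistent redundancy and persistent synergy together
#' with per-region medians (diagonal excluded) and their rank vectors
#' (ascending, ties averaged).
#'
#' @param series T x N numeric matrix of regional time series.
#' @param tau lag in samples (default 1).
#' @return list of class `hoi_maps`: `redundancy`, `synergy` (N x N, `NA`
#'   diagonal, nats), `median_redundancy`, `median_synergy`,
#'   `rank_redundancy`, `rank_synergy` (length-N), `tau`, `n_samples`.
#' @export
hoi_matrices <- function(series, tau = 1L) {
  series <- as.matrix(series)
  N <- ncol(series)
  if (N < 2) stop("hoi_matrices: need at least 2 regions")
  sds <- apply(series, 2, sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad) > 0) {
    stop("hoi_matrices: degenerate (constant) series in regions: ",
         paste(bad, collapse = ", "))
  }
  Z <- scale(series)
  T <- nrow(Z)
  idx_past <- seq_len(T - tau)
  big <- cov(cbind(Z[idx_past, , drop = FALSE], Z[idx_past + tau, , drop = FALSE]))
  red <- matrix(NA_real_, N, N)
  syn <- matrix(NA_real_, N, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      sub <- big[c(i, j, N + i, N + j), c(i, j, N + i, N + j)]
      sub <- regularize_pd(sub)
      at <- phiid_mmi_atoms(sub)
      red[i, j] <- red[j, i] <- at$rtr
      syn[i, j] <- syn[j, i] <- at$sts
    }
  }
  med_r <- offdiag_row_median(red)
  med_s <- offdiag_row_median(syn)
  structure(list(
    redundancy = red, synergy = syn,
    median_redundancy = med_r, median_synergy = med_s,
    rank_redundancy = rank(med_r), rank_synergy = rank(med_s),
    tau = as.integer(tau), n_samples = T - tau
  ), class = "hoi_maps")
}

#' Serialize HOI maps
#'
#' Writes the pairwise matrices as TSV, the per-region median/rank vectors as
#' a TSV table, and a JSON sidecar recording lag, sample count and units.
#'
#' @param maps `hoi_maps` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_hoi_maps <- function(maps, dir, prefix = "hoi") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(maps$redundancy, file.path(dir, paste0(prefix, "_redundancy.tsv")))
  write_matrix_tsv(maps$synergy, file.path(dir, paste0(prefix, "_synergy.tsv")))
  vecs <- data.frame(
    median_redundancy = maps$median_redundancy,
    median_synergy = maps$median_synergy,
    rank_redundancy = maps$rank_redundancy,
    rank_synergy = maps$rank_synergy
  )
  write.table(vecs, file.path(dir, paste0(prefix, "_vectors.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(tau = maps$tau, n_samples = maps$n_samples, units = "nats"),
    file.path(dir, paste0(prefix, "_meta.json")),
    auto_unbox = TRUE
  )
  invisible(dir)
}
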