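# Synthetic structural connectomes: an exponential-distance-rule backbone
# shared by the cohort, with per-subject multiplicative lognormal jitter on
# both streamline-count-like weights and streamline lengths.

#' Generate a cohort of synthetic connectomes
#'
#' Builds a group backbone whose edge weights decay exponentially with
#' Euclidean distance between region centroids (`w_ij` proportional to
#' `exp(-d_ij / edr_lambda)`), keeps the strongest edges up to the requested
#' density, and then draws each subject by multiplying backbone weights and
#' lengths by lognormal jitter with mean 1 and the requested coefficient of
#' variation. Matrices are kept symmetric with a zero diagonal, and lengths
#' are positive wherever a weight is present.
#'
#' @param table region table from [make_region_table()].
#' @param n_subjects number of subjects in the cohort.
#' @param edr_lambda exponential distance-rule length constant, mm.
#' @param density fraction of off-diagonal pairs kept in the backbone.
#' @param subject_jitter coefficient of variation of the per-subject
#'   multiplicative lognormal jitter; `0` makes all subjects identical to the
#'   backbone.
#' @param seed RNG seed.
#' @return a list of connectomes; each element has `subject_id`, `weights`
#'   (N x N, arbitrary streamline-count-like units) and `lengths` (N x N, mm).
#' @export
#' @examples
#' tab <- make_region_table(20, seed = 1)
#' cs <- make_connectome_cohort(tab, n_subjects = 3, seed = 2)
#' isSymmetric(cs[[1]]$weights)
make_connectome_cohort <- function(table, n_subjects = 20L, edr_lambda = 30,
                                   density = 0.35, subject_jitter = 0.2,
                                   seed = 1L) {
  if (n_subjects < 1) stop("make_connectome_cohort: n_subjects must be >= 1")
  if (density <= 0 || density > 1) {
    stop("make_connectome_cohort: density must be in (0, 1]")
  }
  xyz <- as.matrix(table[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  dimnames(d) <- NULL
  w <- exp(-d / edr_lambda) * 200  # count-like scale, arbitrary units
  diag(w) <- 0
  # threshold to density: keep the strongest off-diagonal pairs
  ut <- upper.tri(w)
  n_keep <- max(1L, round(density * sum(ut)))
  thr <- sort(w[ut], decreasing = TRUE)[n_keep]
  w[w < thr] <- 0
  diag(w) <- 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  )
  if (comp$no > 1) {
    stop(sprintf(
      "make_connectome_cohort: backbone disconnected at density %.3f (largest component %d of %d regions)",
      density, max(comp$csize), n
    ))
  }
  sdlog <- if (subject_jitter > 0) sqrt(log(1 + subject_jitter^2)) else 0
  meanlog <- -sdlog^2 / 2  # mean-1 lognormal
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      jit_w <- matrix(1, n, n)
      jit_d <- matrix(1, n, n)
      if (sdlog > 0) {
        npair <- sum(ut)
        jw <- rlnorm(npair, meanlog, sdlog)
        jd <- rlnorm(npair, meanlog, sdlog)
        jit_w[ut] <- jw; jit_w <- t(jit_w); jit_w[ut] <- jw
        jit_d[ut] <- jd; jit_d <- t(jit_d); jit_d[ut] <- jd
      }
      M <- w * jit_w
      D <- d * jit_d
      diag(M) <- 0
      diag(D) <- 0
      list(subject_id = sprintf("sub-%03d", s), weights = M, lengths = D)
    })
  })
}

#' Write / read a connectome cohort as per-subject TSV matrices
#'
#' Files are named `<subject>_weights.tsv` and `<subject>_lengths.tsv`,
#' headerless, row/column order following the region table.
#'
#' @param cohort list of connectomes from [make_connectome_cohort()].
#' @param dir output directory (created if missing).
#' @return `write_connectome_cohort` returns `dir` invisibly;
#'   `read_connectome_cohort` returns the cohort list.
#' @export
write_connectome_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cn in cohort) {
    write_matrix_tsv(cn$weights, file.path(dir, paste0(cn$subject_id, "_weights.tsv")))
    write_matrix_tsv(cn$lengths, file.path(dir, paste0(cn$subject_id, "_lengths.tsv")))
  }
  invisible(dir)
}

#' @rdname write_connectome_cohort
#' @export
read_connectome_cohort <- function(dir) {
  wfiles <- sort(list.files(dir, pattern = "_weights\\.tsv$", full.names = TRUE))
  lapply(wfiles, function(f) {
    sid <- sub("_weights\\.tsv$", "", basename(f))
    list(
      subject_id = sid,
      weights = read_matrix_tsv(f),
      lengths = read_matrix_tsv(file.path(dir, paste0(sid, "_lengths.tsv")))
    )
  })
}
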