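# Synthetic parcellation tables. The default emulates an 84-region
# cortical + subcortical scheme (34 cortical and 8 subcortical structures per
# hemisphere), which fixes the row/column order of every matrix downstream.

.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.subcortical <- c(
  "thalamus", "caudate", "putamen", "pallidum", "accumbens",
  "hippocampus", "amygdala", "ventraldc"
)

#' Build a synthetic region table
#'
#' Generates a parcellation table with mirrored hemispheres and synthetic
#' 3-D coordinates (millimetres). Each hemisphere is an ellipsoid of
#' realistic brain dimensions; subcortical regions are placed medially so
#' that inter-regional distances show the gradients (short medial hops, long
#' fronto-occipital spans) that distance-ruled connectome generators rely on.
#' With the default `n_regions = 84` the names follow the standard
#' 34-cortical + 8-subcortical per-hemisphere scheme, so the thalamus,
#' caudate, putamen, pallidum and accumbens exist in both hemispheres.
#'
#' @param n_regions total number of regions; must be even and >= 4.
#' @param seed RNG seed for the coordinates.
#' @return a `data.frame` with columns `region_index` (0-based), `name`,
#'   `hemisphere` (`"left"`/`"right"`), `is_subcortical` (logical) and
#'   coordinates `x`, `y`, `z` in mm.
#' @export
#' @examples
#' tab <- make_region_table(84, seed = 1)
#' table(tab$hemisphere)
make_region_table <- function(n_regions = 84L, seed = 1L) {
  if (length(n_regions) != 1 || n_regions < 4 || n_regions %% 2 != 0) {
    stop("make_region_table: n_regions must be even and >= 4")
  }
  nh <- n_regions / 2
  if (n_regions == 84) {
    base_names <- c(.dk_cortical, .subcortical)
    subcort <- c(rep(FALSE, 34), rep(TRUE, 8))
  } else {
    n_sub <- min(length(.subcortical), floor(nh / 5))
    base_names <- c(sprintf("ctx_%03d", seq_len(nh - n_sub)),
                    .subcortical[seq_len(n_sub)])
    subcort <- c(rep(FALSE, nh - n_sub), rep(TRUE, n_sub))
  }
  with_seed(seed, {
    # rejection-sample points inside a unit ball, stretch to ellipsoid axes
    axes <- c(30, 60, 45)  # half-axes mm: lateral, anterior-posterior, dorsal
    pts <- matrix(NA_real_, nh, 3)
    filled <- 0
    while (filled < nh) {
      cand <- matrix(runif(3 * nh, -1, 1), ncol = 3)
      keep <- rowSums(cand^2) <= 1
      take <- min(sum(keep), nh - filled)
      if (take > 0) {
        pts[filled + seq_len(take), ] <- cand[which(keep)[seq_len(take)], ]
        filled <- filled + take
      }
    }
    pts <- sweep(pts, 2, axes, `*`)
    # hemisphere offset along x; subcortical structures pulled to the midline
    pts[, 1] <- abs(pts[, 1]) + 8
    pts[subcort, 1] <- pts[subcort, 1] * 0.25 + 2
    pts[subcort, 2] <- pts[subcort, 2] * 0.4
    pts[subcort, 3] <- pts[subcort, 3] * 0.4 - 10
    left <- data.frame(
      name = paste0("lh_", base_names),
      hemisphere = "left",
      is_subcortical = subcort,
      x = -pts[, 1], y = pts[, 2], z = pts[, 3],
      stringsAsFactors = FALSE
    )
    right <- left
    right$name <- paste0("rh_", base_names)
    right$hemisphere <- "right"
    right$x <- -right$x
    tab <- rbind(left, right)
    tab <- cbind(region_index = seq_len(nrow(tab)) - 1L, tab)
    rownames(tab) <- NULL
    tab
  })
}

#' Write / read a region table as CSV
#'
#' @param table region table from [make_region_table()].
#' @param path file path.
#' @return `read_region_table` returns the table; `write_region_table` the
#'   path, invisibly.
#' @export
write_region_table <- function(table, path) {
  write.table(table, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(identical(tab$region_index, seq_len(nrow(tab)) - 1L) ||
              all(tab$region_index == seq_len(nrow(tab)) - 1))
  tab$is_subcortical <- as.logical(tab$is_subcortical)
  tab
}
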