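# Matrix dialect used throughout: headerless TSV, full matrices (not
# triangles), row/column order fixed by the region table.

#' Read / write a headerless TSV matrix
#'
#' @param mat numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}
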