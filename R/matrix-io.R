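#' Read a labeled numeric matrix
#'
#' Two on-disk dialects are supported:
#' * delimited text (TSV or CSV) with a header row of column labels and a
#'   first column of row labels;
#' * MatrixMarket sparse triplets (`.mtx`), with sidecar label files
#'   `<stem>.rows.txt` and `<stem>.cols.txt` (one label per line).
#'
#' @param path path to the matrix file.
#' @param orientation either `"features_by_samples"` or `"cells_by_features"`;
#'   recorded as an attribute, the file is returned as stored.
#' @return a numeric matrix (dense) or `Matrix::dgCMatrix` (MatrixMarket
#'   input) with dimnames attached; all values finite.
#' @export
read_matrix <- function(path,
                        orientation = c("features_by_samples",
                                        "cells_by_features")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.mtx$", path)) {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    stem <- sub("\\.mtx$", "", path)
    rows <- readLines(paste0(stem, ".rows.txt"))
    cols <- readLines(paste0(stem, ".cols.txt"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop("label count mismatch: matrix is ", nrow(m), "x", ncol(m),
           " but sidecar files give ", length(rows), " row and ",
           length(cols), " column labels", call. = FALSE)
    }
    dimnames(m) <- list(rows, cols)
    if (any(!is.finite(m@x))) {
      stop("non-finite entries in matrix ", path, call. = FALSE)
    }
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (any(!is.finite(m))) {
      stop("non-finite entries (NA/NaN/Inf) in matrix ", path, call. = FALSE)
    }
  }
  attr(m, "orientation") <- orientation
  m
}

#' Write a labeled numeric matrix
#'
#' Inverse of [read_matrix()]: dense matrices go to TSV/CSV with row labels in
#' the first column; sparse matrices to MatrixMarket plus sidecar label files.
#'
#' @param m matrix with dimnames.
#' @param path output path; a `.mtx` suffix selects MatrixMarket.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
                    path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(m), paste0(stem, ".rows.txt"))
    writeLines(colnames(m), paste0(stem, ".cols.txt"))
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- data.frame(id = rownames(m), as.data.frame(as.matrix(m),
                                                     check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
  }
  invisible(path)
}
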