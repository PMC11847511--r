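#' Generate a labeled synthetic single-cell ATAC reference
#'
#' Builds a cell-by-peak count atlas with controllable cell-type
#' separability. Peaks are 500 bp wide, spaced 5,000 bp apart, and laid out
#' round-robin across `n_chroms` chromosomes. Each cell type owns a disjoint,
#' contiguous (in genomic peak order) marker block of
#' `floor(marker_fraction * n_peaks / n_celltypes)` peaks whose Poisson rate
#' is `base_rate * marker_fold`; all other peaks have rate `base_rate`.
#' Counts are independent Poisson draws per cell.
#'
#' @param n_celltypes number of cell types `k`.
#' @param n_peaks number of peaks.
#' @param cells_per_type cells simulated per type.
#' @param n_chroms number of chromosomes the peaks are spread over.
#' @param marker_fraction fraction of peaks reserved for marker blocks,
#'   in (0, 1).
#' @param marker_fold rate fold-change of a type's marker peaks (> 1).
#' @param base_rate background Poisson rate per peak (> 0).
#' @param seed integer seed; identical seeds give identical atlases.
#' @return An object of class `reference_atlas`: a list with `counts`
#'   (sparse cells x peaks `dgCMatrix`), `labels` (cell type per cell),
#'   `peaks` (a [peak_set()]), `celltypes`, and `marker_blocks` (peak-column
#'   indices per type).
#' @examples
#' atlas <- generate_reference(n_celltypes = 2, n_peaks = 100,
#'                             cells_per_type = 10, seed = 1)
#' dim(atlas$counts)
#' @export
generate_reference <- function(n_celltypes = 5, n_peaks = 600,
                               cells_per_type = 100, n_chroms = 3,
                               marker_fraction = 0.2, marker_fold = 10,
                               base_rate = 0.1, seed = 1) {
  stopifnot(n_celltypes >= 1, n_peaks >= 1, cells_per_type >= 1,
            n_chroms >= 1, marker_fraction > 0, marker_fraction < 1,
            marker_fold > 1 || marker_fold == 1, base_rate > 0)
  block <- floor(marker_fraction * n_peaks / n_celltypes)
  if (block < 1) {
    stop("marker_fraction * n_peaks < n_celltypes: no room for one marker ",
         "peak per cell type", call. = FALSE)
  }
  # round-robin chromosome layout: peak i -> chromosome ((i-1) mod n_chroms)+1
  i <- seq_len(n_peaks)
  chrom <- paste0("chr", ((i - 1L) %% n_chroms) + 1L)
  within <- (i - 1L) %/% n_chroms
  start <- within * 5000L
  peaks <- peak_set(chrom, start, start + 500L,
                    peak_id = sprintf("peak_%04d", i))
  # marker blocks are contiguous in the sorted genomic peak order
  celltypes <- paste0("type", seq_len(n_celltypes))
  marker_blocks <- lapply(seq_len(n_celltypes), function(t) {
    ((t - 1L) * block + 1L):(t * block)
  })
  names(marker_blocks) <- celltypes
  rates <- matrix(base_rate, nrow = n_celltypes, ncol = n_peaks)
  for (t in seq_len(n_celltypes)) {
    rates[t, marker_blocks[[t]]] <- base_rate * marker_fold
  }
  labels <- rep(celltypes, each = cells_per_type)
  counts <- with_seed(seed, {
    m <- matrix(0L, nrow = length(labels), ncol = n_peaks)
    for (t in seq_len(n_celltypes)) {
      rows <- which(labels == celltypes[t])
      m[rows, ] <- stats::rpois(length(rows) * n_peaks,
                                lambda = rep(rates[t, ], each = length(rows)))
    }
    m
  })
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(sprintf("cell_%05d", seq_along(labels)),
                           peaks$peak_id)
  structure(
    list(counts = counts, labels = labels, peaks = peaks,
         celltypes = celltypes, marker_blocks = marker_blocks),
    class = "reference_atlas"
  )
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat("<reference_atlas> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " peaks, ", length(x$celltypes), " cell types (",
      paste(x$celltypes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Ground-truth cell-type accessibility signatures
#'
#' For each cell type, averages the count profiles of its cells and min-max
#' scales the mean profile to \[0, 1\] per type (the same normalization the
#' bulk inputs receive). A constant profile maps to all zeros.
#'
#' @param atlas a `reference_atlas`.
#' @return a `k x n_peaks` numeric matrix, rows named by cell type, columns
#'   by peak_id.
#' @export
true_signatures <- function(atlas) {
  stopifnot(inherits(atlas, "reference_atlas"))
  counts <- as.matrix(atlas$counts)
  means <- rowsum(counts, group = atlas$labels) /
    as.vector(table(atlas$labels)[sort(unique(atlas$labels))])
  means <- means[atlas$celltypes, , drop = FALSE]
  sig <- minmax_normalize(means)
  dimnames(sig) <- list(atlas$celltypes, atlas$peaks$peak_id)
  sig
}

#' Write a reference atlas to disk
#'
#' Writes the sparse counts as MatrixMarket (+ sidecar label files), the cell
#' labels as a one-column text file, and the peaks as BED.
#'
#' @param atlas a `reference_atlas`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(atlas$counts, file.path(dir, "counts.mtx"))
  writeLines(atlas$labels, file.path(dir, "cell_labels.txt"))
  write_peaks(atlas$peaks, file.path(dir, "peaks.bed"))
  invisible(dir)
}

#' Read a reference atlas written by [write_reference()]
#' @param dir directory containing `counts.mtx`, `cell_labels.txt`,
#'   `peaks.bed`.
#' @return a `reference_atlas`.
#' @export
read_reference <- function(dir) {
  counts <- read_matrix(file.path(dir, "counts.mtx"),
                        orientation = "cells_by_features")
  labels <- readLines(file.path(dir, "cell_labels.txt"))
  peaks <- read_peaks(file.path(dir, "peaks.bed"))
  stopifnot(nrow(counts) == length(labels), ncol(counts) == nrow(peaks))
  structure(
    list(counts = counts, labels = labels, peaks = peaks,
         celltypes = sort(unique(labels)), marker_blocks = NULL),
    class = "reference_atlas"
  )
}
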