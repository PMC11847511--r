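#' Min-max normalize a matrix per row
#'
#' Each row (one sample's peak profile) is rescaled to \[0, 1\] by
#' `(x - min) / (max - min)`. Constant rows map to all zeros (the degenerate
#' min == max convention), which keeps the output finite and deterministic.
#' Applied per sample because it corrects sample-level differences in
#' sequencing depth.
#'
#' @param m numeric matrix (samples x peaks) or a single profile vector.
#' @return a matrix of the same shape with entries in \[0, 1\].
#' @examples
#' minmax_normalize(rbind(c(2, 4, 6), c(5, 5, 5)))
#' @export
minmax_normalize <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m <- as.matrix(m)
  stopifnot(all(is.finite(m)))
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant rows: (x - lo) is 0, divide by 1 -> zeros
  (m - lo) / rng
}

#' Intersect bulk and reference peak sets
#'
#' Keeps every reference peak that overlaps at least one bulk peak by >= 1 bp
#' (reference coordinates define the shared feature space, so the training
#' representation is unchanged). A reference peak overlapping several bulk
#' peaks is paired with the bulk peak of largest overlap; ties go to the bulk
#' peak with the smaller start.
#'
#' @param bulk_peaks,ref_peaks [peak_set()] objects.
#' @return a list with `shared` (a [peak_set()] of retained reference peaks),
#'   `ref_index` (column positions of the shared peaks in the reference
#'   matrix, i.e. in `ref_peaks` order) and `bulk_index` (column positions of
#'   the paired bulk peaks in `bulk_peaks` order).
#' @export
intersect_peaks <- function(bulk_peaks, ref_peaks) {
  gr_ref <- peaks_to_granges(ref_peaks)
  gr_bulk <- peaks_to_granges(bulk_peaks)
  hits <- GenomicRanges::findOverlaps(gr_ref, gr_bulk, minoverlap = 1L)
  if (length(hits) == 0) {
    stop("bulk and reference peak sets share no overlapping regions; ",
         "harmonize the peak sets (same genome build/peak calling) first",
         call. = FALSE)
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov_width <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_ref)[q], IRanges::ranges(gr_bulk)[s]))
  bulk_start <- bulk_peaks$start[s]
  # per reference peak: largest overlap wins, ties -> smaller bulk start
  ord <- order(q, -ov_width, bulk_start, method = "radix")
  keep <- ord[!duplicated(q[ord])]
  ref_idx <- q[keep]
  bulk_idx <- s[keep]
  o <- order(ref_idx)
  ref_idx <- ref_idx[o]
  bulk_idx <- bulk_idx[o]
  shared <- peak_set(ref_peaks$chrom[ref_idx], ref_peaks$start[ref_idx],
                     ref_peaks$end[ref_idx], ref_peaks$peak_id[ref_idx])
  list(shared = shared, ref_index = ref_idx, bulk_index = bulk_idx)
}

#' Chunk peaks into per-chromosome patches
#'
#' Peaks in genomic order are cut, chromosome by chromosome, into consecutive
#' windows of `patch_size` peaks; the final window on each chromosome may be
#' shorter and is zero-padded at model-input time. No patch ever spans a
#' chromosome boundary, so every transformer token is an intra-chromosomal
#' block of consecutive accessible regions.
#'
#' @param peaks a [peak_set()] (non-empty).
#' @param patch_size peaks per patch (default 50).
#' @return an object of class `patch_layout`: list with `patch_size`,
#'   `patches` (tibble: `chrom`, `patch_index` within chromosome, `patch`
#'   global index, `n_peaks`), `peak_cols` (list of peak column indices per
#'   patch), `peak_to_patch` (tibble: `peak_id`, `patch`, `offset`), and
#'   `n_patches`.
#' @examples
#' p <- peak_set(rep("chr1", 120), (0:119) * 1000, (0:119) * 1000 + 500)
#' build_patches(p, 50)$patches$n_peaks
#' @export
build_patches <- function(peaks, patch_size = 50) {
  stopifnot(patch_size >= 1)
  if (nrow(peaks) == 0) stop("empty peak set", call. = FALSE)
  chroms <- unique(peaks$chrom)  # peak_set is already in natural chrom order
  patch_chrom <- character()
  patch_within <- integer()
  peak_cols <- list()
  for (ch in chroms) {
    cols <- which(peaks$chrom == ch)
    n <- length(cols)
    starts <- seq(1L, n, by = patch_size)
    for (w in seq_along(starts)) {
      idx <- cols[starts[w]:min(starts[w] + patch_size - 1L, n)]
      peak_cols[[length(peak_cols) + 1L]] <- idx
      patch_chrom <- c(patch_chrom, ch)
      patch_within <- c(patch_within, w)
    }
  }
  n_patches <- length(peak_cols)
  patches <- tibble::tibble(
    chrom = patch_chrom,
    patch_index = patch_within,
    patch = seq_len(n_patches),
    n_peaks = lengths(peak_cols)
  )
  peak_to_patch <- tibble::tibble(
    peak_id = peaks$peak_id[unlist(peak_cols)],
    patch = rep(seq_len(n_patches), lengths(peak_cols)),
    offset = unlist(lapply(lengths(peak_cols), seq_len))
  )
  structure(
    list(patch_size = as.integer(patch_size), patches = patches,
         peak_cols = peak_cols, peak_to_patch = peak_to_patch,
         n_patches = n_patches, peak_ids = peaks$peak_id,
         n_peaks = nrow(peaks), peaks = peaks),
    class = "patch_layout"
  )
}

#' @export
print.patch_layout <- function(x, ...) {
  cat("<patch_layout> ", x$n_patches, " patches of size ", x$patch_size,
      " over ", x$n_peaks, " peaks on ",
      length(unique(x$patches$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}
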