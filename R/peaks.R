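#' Construct a validated peak set
#'
#' A peak set is the ordered genomic feature space shared by the single-cell
#' reference and the bulk profiles: 0-based half-open intervals (BED
#' convention), sorted by chromosome (natural order: chr1..chr22, chrX, chrY,
#' then lexicographic), start and end, with unique peak identifiers.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open interval bounds.
#' @param peak_id optional character identifiers; defaults to
#'   `"chrom:start-end"`.
#' @return A tibble of class `peak_set` with columns `chrom`, `start`, `end`,
#'   `peak_id`, sorted in genomic order.
#' @examples
#' peak_set(c("chr1", "chr1"), c(100, 50), c(300, 80))
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  if (is.null(peak_id)) {
    peak_id <- sprintf("%s:%d-%d", chrom, start, end)
  }
  peak_id <- as.character(peak_id)
  stopifnot(length(peak_id) == n)
  if (n > 0) {
    bad <- which(!is.finite(start) | !is.finite(end) | start >= end | start < 0)
    if (length(bad) > 0) {
      stop("invalid peak interval(s) (need 0 <= start < end) at record(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  ord <- order(chrom_rank(chrom), start, end, method = "radix")
  out <- tibble::tibble(
    chrom = chrom[ord], start = start[ord], end = end[ord],
    peak_id = peak_id[ord]
  )
  if (anyDuplicated(out$peak_id)) {
    stop("duplicate peak_id(s): ",
         paste(utils::head(unique(out$peak_id[duplicated(out$peak_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  class(out) <- c("peak_set", class(out))
  out
}

#' Natural chromosome ordering rank
#'
#' chr1..chr22 numerically, then chrX, chrY, then anything else
#' lexicographically.
#' @param chrom character vector.
#' @return numeric rank usable as a sort key.
#' @keywords internal
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
                 ifelse(core == "X", 1e6, ifelse(core == "Y", 1e6 + 1, NA)))
  # remaining names ordered lexicographically after X/Y
  left <- is.na(rank)
  if (any(left)) {
    lex <- match(chrom[left], sort(unique(chrom[left])))
    rank[left] <- 2e6 + lex
  }
  rank
}

#' Read a BED file of peaks
#'
#' Reads a 3+ column tab-separated BED file (0-based half-open). An optional
#' fourth column is taken as the peak identifier; missing identifiers are
#' synthesized as `"chrom:start-end"`.
#'
#' @param path path to a BED file.
#' @return A [peak_set()] tibble.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(peak_set(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED parse error: fewer than 3 columns at line ",
         which(nf < 3)[1], call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0) {
    stop("BED parse error: malformed coordinates at line ", bad[1],
         " ('", lines[bad[1]], "')", call. = FALSE)
  }
  peak_id <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                    sprintf("%s:%d-%d", chrom, start, end))
  peak_set(chrom, start, end, peak_id)
}

#' Write a peak set as BED
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- as.data.frame(peaks)[, c("chrom", "start", "end", "peak_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a peak set to a GRanges object
#' @param peaks a [peak_set()].
#' @return a `GenomicRanges::GRanges` (1-based closed, converted from BED).
#' @keywords internal
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    peak_id = peaks$peak_id
  )
}
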