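#' Read a chromatin-interaction contact list (BEDPE-like text)
#'
#' Expects seven tab-separated columns: chrom1, start1, end1, chrom2, start2,
#' end2, strength. Only intra-chromosomal pairs are kept (inter-chromosomal
#' rows are dropped with a message); each anchor is reduced to its midpoint.
#'
#' @param path path to a BEDPE-like text file.
#' @return A tibble of class `contact_list` with columns `chrom`, `start1`,
#'   `start2`, `strength` and attribute `n_dropped_interchrom`.
#' @export
read_contacts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(contact_list(character(), numeric(), numeric(), numeric(),
                        n_dropped = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7)) {
    stop("BEDPE parse error: fewer than 7 columns at line ",
         which(nf < 7)[1], call. = FALSE)
  }
  getc <- function(i) vapply(fields, `[[`, "", i)
  getn <- function(i) suppressWarnings(as.numeric(getc(i)))
  chrom1 <- getc(1); chrom2 <- getc(4)
  s1 <- getn(2); e1 <- getn(3); s2 <- getn(5); e2 <- getn(6)
  strength <- getn(7)
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2) | is.na(strength))
  if (length(bad) > 0) {
    stop("BEDPE parse error: non-numeric field at line ", bad[1], call. = FALSE)
  }
  if (any(strength < 0)) {
    stop("negative contact strength at line ", which(strength < 0)[1],
         call. = FALSE)
  }
  intra <- chrom1 == chrom2
  n_dropped <- sum(!intra)
  if (n_dropped > 0) {
    message(n_dropped, " inter-chromosomal contact(s) dropped")
  }
  contact_list(
    chrom = chrom1[intra],
    start1 = (s1[intra] + e1[intra]) / 2,
    start2 = (s2[intra] + e2[intra]) / 2,
    strength = strength[intra],
    n_dropped = n_dropped
  )
}

#' Construct a contact list
#'
#' @param chrom chromosome of both anchors (intra-chromosomal only).
#' @param start1,start2 anchor positions (bp).
#' @param strength non-negative interaction strength.
#' @param n_dropped count of inter-chromosomal records dropped upstream.
#' @return A tibble of class `contact_list`.
#' @export
contact_list <- function(chrom, start1, start2, strength, n_dropped = 0L) {
  stopifnot(all(strength >= 0))
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start1 = as.numeric(start1),
    start2 = as.numeric(start2),
    strength = as.numeric(strength)
  )
  attr(out, "n_dropped_interchrom") <- as.integer(n_dropped)
  class(out) <- c("contact_list", class(out))
  out
}
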