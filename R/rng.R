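#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state so
#' that seeded package functions do not clobber the user's random stream.
#' A `NULL` seed leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds so that stages are individually
#' reproducible without coupling their random streams. Kept below 2^31.
#'
#' @param seed global integer seed.
#' @param stage integer stage index (>= 0).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000 + stage) %% .Machine$integer.max)
}
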