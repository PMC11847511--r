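#' Simulate cell-type proportion vectors under four regimes
#'
#' Draws proportion vectors on the k-simplex from a symmetric Dirichlet and
#' shapes them into four biological scenarios:
#' * `random`: plain Dirichlet(alpha * 1_k) draw.
#' * `dominant`: one uniformly chosen type is rescaled to a uniform draw in
#'   (0.5, 0.9\]; the rest renormalized, so exactly one type exceeds 50%.
#' * `rare`: one uniformly chosen type rescaled to a uniform draw in
#'   (0, 0.05); the rest renormalized, so one type sits below 5%.
#' * `average`: all types near 1/k, with Dirichlet noise shrunk so that
#'   max - min < 0.05.
#'
#' @param k number of cell types.
#' @param n_samples number of vectors to draw.
#' @param regime one of `"random"`, `"rare"`, `"dominant"`, `"average"`.
#' @param alpha Dirichlet concentration (default 1: uniform on the simplex).
#' @param seed integer seed.
#' @return a tibble with columns `sample`, `regime`, and one proportion
#'   column per type (`p1..pk`); attribute `P` holds the `n_samples x k`
#'   matrix. Rows sum to 1 within 1e-9.
#' @export
simulate_proportions <- function(k, n_samples, regime = c("random", "rare",
                                                          "dominant",
                                                          "average"),
                                 alpha = 1, seed = 1) {
  regime <- match.arg(tolower(regime[1]), c("random", "rare", "dominant",
                                            "average"))
  stopifnot(k >= 1, n_samples >= 1, alpha > 0)
  P <- with_seed(seed, {
    P <- rdirichlet(n_samples, rep(alpha, k))
    if (k == 1) {
      P[] <- 1
    } else if (regime == "dominant") {
      pick <- sample.int(k, n_samples, replace = TRUE)
      target <- stats::runif(n_samples, 0.5, 0.9)
      P <- rescale_one(P, pick, target)
    } else if (regime == "rare") {
      pick <- sample.int(k, n_samples, replace = TRUE)
      target <- stats::runif(n_samples, 0, 0.05)
      # keep strictly below 0.05 and strictly above 0
      target <- pmin(pmax(target, 1e-6), 0.05 - 1e-9)
      P <- rescale_one(P, pick, target)
    } else if (regime == "average") {
      # shrink Dirichlet noise around 1/k until max - min < 0.05
      noise <- P - 1 / k
      spread <- apply(P, 1, max) - apply(P, 1, min)
      scale <- pmin(1, 0.04 / pmax(spread, 1e-12))
      P <- 1 / k + noise * scale
    }
    P
  })
  P <- P / rowSums(P)
  colnames(P) <- paste0("p", seq_len(k))
  out <- tibble::as_tibble(as.data.frame(P))
  out <- tibble::add_column(out,
                            sample = seq_len(n_samples),
                            regime = regime, .before = 1)
  attr(out, "P") <- P
  out
}

# set entry `pick[i]` of row i to target[i], renormalize the others to 1-target
rescale_one <- function(P, pick, target) {
  k <- ncol(P)
  n <- nrow(P)
  sel <- cbind(seq_len(n), pick)
  rest <- rowSums(P) - P[sel]
  rest[rest == 0] <- 1
  scale <- (1 - target) / rest
  P <- P * scale
  P[sel] <- target
  P
}

# symmetric-usable Dirichlet sampler via normalized gammas
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard against all-zero rows at tiny alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1
  g / rowSums(g)
}

#' Build pseudo-bulk samples with known ground truth
#'
#' For each proportion vector, `round(p_t * n_cells)` cells of type t (via
#' largest-remainder rounding, so the counts always total `n_cells`) are
#' sampled with replacement from the reference; their count rows are summed
#' and the summed profile is min-max normalized per sample. The realized
#' (post-rounding) proportions are recorded as ground truth, so `P_true` rows
#' are exact rationals over `n_cells` and sum to 1 exactly.
#'
#' @param atlas a `reference_atlas`.
#' @param proportions output of [simulate_proportions()] (its rows may mix
#'   regimes if several tibbles are bound), or a numeric matrix samples x k.
#' @param n_cells_per_sample cells aggregated per pseudo-bulk (default 500).
#' @param seed integer seed.
#' @return an object of class `pseudobulk_batch`: list with `bulk`
#'   (samples x peaks matrix in \[0,1\]), `P_true` (samples x k), `M_true`
#'   (from [true_signatures()]), `n_cells_per_sample`, `celltypes`.
#' @export
make_pseudobulk <- function(atlas, proportions, n_cells_per_sample = 500,
                            seed = 1) {
  stopifnot(inherits(atlas, "reference_atlas"), n_cells_per_sample >= 1)
  P <- if (is.matrix(proportions)) proportions else attr(proportions, "P")
  stopifnot(!is.null(P), ncol(P) == length(atlas$celltypes))
  k <- ncol(P)
  n <- nrow(P)
  cells_by_type <- lapply(atlas$celltypes,
                          function(ct) which(atlas$labels == ct))
  counts <- atlas$counts
  bulk <- matrix(0, nrow = n, ncol = ncol(counts))
  P_true <- matrix(0, nrow = n, ncol = k)
  with_seed(seed, {
    for (i in seq_len(n)) {
      n_t <- largest_remainder(P[i, ], n_cells_per_sample)
      for (t in seq_len(k)) {
        if (n_t[t] == 0) next
        pool <- cells_by_type[[t]]
        if (length(pool) == 0) {
          stop("cell type '", atlas$celltypes[t], "' has no reference cells ",
               "but nonzero proportion", call. = FALSE)
        }
        picked <- pool[sample.int(length(pool), n_t[t], replace = TRUE)]
        bulk[i, ] <- bulk[i, ] + Matrix::colSums(counts[picked, , drop = FALSE])
      }
      P_true[i, ] <- n_t / n_cells_per_sample
    }
  })
  bulk <- minmax_normalize(bulk)
  dimnames(bulk) <- list(sprintf("sample_%04d", seq_len(n)),
                         atlas$peaks$peak_id)
  dimnames(P_true) <- list(rownames(bulk), atlas$celltypes)
  structure(
    list(bulk = bulk, P_true = P_true, M_true = true_signatures(atlas),
         n_cells_per_sample = as.integer(n_cells_per_sample),
         celltypes = atlas$celltypes),
    class = "pseudobulk_batch"
  )
}

#' @export
print.pseudobulk_batch <- function(x, ...) {
  cat("<pseudobulk_batch> ", nrow(x$bulk), " samples x ", ncol(x$bulk),
      " peaks, ", length(x$celltypes), " cell types, ",
      x$n_cells_per_sample, " cells/sample\n", sep = "")
  invisible(x)
}

#' Largest-remainder apportionment of n cells to proportions
#'
#' Floors `p * n` and hands leftover cells to the largest fractional
#' remainders; remainder ties are broken by type order. The result always
#' sums to `n`.
#'
#' @param p proportion vector (sums to 1).
#' @param n total count to apportion.
#' @return integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-rem, seq_along(p), method = "radix")  # ties -> type order
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
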