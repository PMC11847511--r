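#' Extract per-chromosome patch-attention maps
#'
#' Runs the encoder on one (preprocessed) bulk profile, captures the
#' row-stochastic attention weights at every layer and head, averages over
#' heads of the last layer (or over all layers and heads), drops the
#' class-token row/column, restricts to within-chromosome patch blocks, and
#' symmetrizes each block as `(W + t(W)) / 2`.
#'
#' @param model a trained [deconv_model()] (or `deconv_fit`).
#' @param x bulk profile (length `n_peaks`, min-max normalized). Defaults in
#'   the pipeline to the mean of the training pseudo-bulk profiles.
#' @param layout the model's patch layout (defaults to `model$layout`).
#' @param aggregation `"mean_heads_last_layer"` (default) or
#'   `"mean_heads_all_layers"`.
#' @return an object of class `attention_map`: list with `per_chrom` (named
#'   list of `list(patch_ids, W)` with `W` symmetric), `layer`,
#'   `aggregation`.
#' @export
extract_attention <- function(model, x, layout = NULL,
                              aggregation = c("mean_heads_last_layer",
                                              "mean_heads_all_layers")) {
  aggregation <- match.arg(aggregation)
  if (inherits(model, "deconv_fit")) model <- model$model
  if (is.null(layout)) layout <- model$layout
  cfg <- model$config
  if (cfg$L == 0) {
    stop("cannot extract attention from a depth-0 encoder", call. = FALSE)
  }
  x <- matrix(as.numeric(x), nrow = 1)
  fw <- fwd_full(model, x, want_attention = TRUE)
  collapse <- function(Alist) {  # B=1 list [[1]][[head]] -> head mean
    Reduce(`+`, Alist[[1]]) / length(Alist[[1]])
  }
  W_full <- if (aggregation == "mean_heads_last_layer") {
    collapse(fw$attention[[cfg$L]])
  } else {
    Reduce(`+`, lapply(fw$attention, collapse)) / cfg$L
  }
  W_patch <- W_full[-1, -1, drop = FALSE]  # drop class token
  per_chrom <- list()
  for (ch in unique(layout$patches$chrom)) {
    pid <- layout$patches$patch[layout$patches$chrom == ch]
    W <- W_patch[pid, pid, drop = FALSE]
    W <- (W + t(W)) / 2
    dimnames(W) <- list(pid, pid)
    per_chrom[[ch]] <- list(patch_ids = pid, W = W)
  }
  structure(list(per_chrom = per_chrom, layer = cfg$L,
                 aggregation = aggregation),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> ", length(x$per_chrom), " chromosome(s), ",
      x$aggregation, "\n", sep = "")
  invisible(x)
}

#' Tidy an attention map into a long tibble
#' @param x an `attention_map`.
#' @param ... unused.
#' @return tibble with columns `chrom`, `patch_i`, `patch_j`, `weight`.
#' @method tidy attention_map
#' @export
tidy.attention_map <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$per_chrom), function(ch) {
    W <- x$per_chrom[[ch]]$W
    pid <- x$per_chrom[[ch]]$patch_ids
    tibble::tibble(chrom = ch,
                   patch_i = rep(pid, times = length(pid)),
                   patch_j = rep(pid, each = length(pid)),
                   weight = as.vector(W))
  }))
}

#' Categorize attention weights into High / Median / Low
#'
#' Per chromosome, the absolute off-diagonal weights are split at their
#' empirical tertiles (rank-based, so any strictly monotone transform of the
#' weights yields the same categories); ties fall into the lower category and
#' the integer-division remainder is assigned Low, then Median, then High.
#' The diagonal is excluded (`NA`). Chromosomes with fewer than 3 distinct
#' off-diagonal values are labeled all-Median with a warning.
#'
#' @param map an `attention_map`.
#' @return named list (chromosome -> character matrix in
#'   `{"High","Median","Low"}` with `NA` diagonal).
#' @export
categorize_attention <- function(map) {
  stopifnot(inherits(map, "attention_map"))
  out <- list()
  for (ch in names(map$per_chrom)) {
    W <- abs(map$per_chrom[[ch]]$W)
    p <- nrow(W)
    lab <- matrix(NA_character_, p, p, dimnames = dimnames(W))
    off <- W[upper.tri(W)]
    if (length(unique(off)) < 3) {
      warning("chromosome ", ch, ": fewer than 3 distinct off-diagonal ",
              "attention values; all labeled Median")
      lab[upper.tri(lab) | lower.tri(lab)] <- "Median"
      out[[ch]] <- lab
      next
    }
    n <- length(off)
    q <- n %/% 3L
    r <- n %% 3L
    n_low <- q + as.integer(r >= 1)
    n_med <- q + as.integer(r >= 2)
    srt <- sort(off)
    thr_low <- srt[n_low]
    thr_med <- srt[n_low + n_med]
    assign_cat <- function(v) {
      ifelse(v <= thr_low, "Low", ifelse(v <= thr_med, "Median", "High"))
    }
    ut <- upper.tri(lab)
    lab[ut] <- assign_cat(W[ut])
    lab[lower.tri(lab)] <- t(lab)[lower.tri(lab)]
    out[[ch]] <- lab
  }
  out
}

#' Map a contact list onto patch-pair strength matrices
#'
#' Each contact's two genomic positions are assigned to the patch containing
#' the nearest peak interval (positions inside a peak map to that peak;
#' positions within the chromosome's peak span map to the nearest peak;
#' positions outside the span, or on chromosomes absent from the layout, are
#' dropped and counted). Strengths of contacts hitting the same patch pair
#' accumulate by sum, symmetrically.
#'
#' @param contacts a [contact_list()].
#' @param layout a [build_patches()] layout.
#' @param peaks the [peak_set()] the layout was built from (defaults to the
#'   one stored in the layout).
#' @return named list (chromosome -> `p x p` symmetric strength matrix) with
#'   attribute `n_dropped`.
#' @export
contacts_to_patch_pairs <- function(contacts, layout, peaks = layout$peaks) {
  stopifnot(inherits(layout, "patch_layout"))
  chroms <- unique(layout$patches$chrom)
  mats <- lapply(chroms, function(ch) {
    pid <- layout$patches$patch[layout$patches$chrom == ch]
    m <- matrix(0, length(pid), length(pid), dimnames = list(pid, pid))
    m
  })
  names(mats) <- chroms
  # per chromosome: peak intervals and their local patch index
  peak_patch <- integer(nrow(peaks))
  for (i in seq_len(layout$n_patches)) peak_patch[layout$peak_cols[[i]]] <- i
  n_dropped <- 0L
  for (r in seq_len(nrow(contacts))) {
    ch <- contacts$chrom[r]
    if (!ch %in% chroms) { n_dropped <- n_dropped + 1L; next }
    rows <- which(peaks$chrom == ch)
    span_lo <- min(peaks$start[rows]); span_hi <- max(peaks$end[rows])
    pos <- c(contacts$start1[r], contacts$start2[r])
    if (any(pos < span_lo | pos >= span_hi)) {
      n_dropped <- n_dropped + 1L; next
    }
    loc <- vapply(pos, function(p) {
      dist <- pmax(peaks$start[rows] - p, p - (peaks$end[rows] - 1), 0)
      rows[which.min(dist)]
    }, 0L)
    gl <- peak_patch[loc]  # global patch indices
    pid <- layout$patches$patch[layout$patches$chrom == ch]
    li <- match(gl, pid)   # local indices within chromosome block
    mats[[ch]][li[1], li[2]] <- mats[[ch]][li[1], li[2]] + contacts$strength[r]
    if (li[1] != li[2]) {
      mats[[ch]][li[2], li[1]] <- mats[[ch]][li[2], li[1]] +
        contacts$strength[r]
    }
  }
  if (n_dropped > 0) {
    message(n_dropped, " contact(s) outside the patch layout dropped")
  }
  attr(mats, "n_dropped") <- n_dropped
  mats
}

# upper-triangle pair encoding helpers (i < j, local indices, base p)
encode_pairs <- function(i, j, p) (pmin(i, j) - 1L) * p + (pmax(i, j) - 1L)

# top-m off-diagonal pairs of a symmetric matrix by value; ties broken by
# pair index (deterministic); returns the (i, j) index matrix
top_pairs_ij <- function(W, m) {
  ut <- which(upper.tri(W), arr.ind = TRUE)
  v <- W[upper.tri(W)]
  ord <- order(-v, ut[, 1], ut[, 2], method = "radix")
  ut[ord[seq_len(min(m, length(ord)))], , drop = FALSE]
}

#' Permutation test of attention / contact-map overlap
#'
#' Per chromosome, selects the top `top_fraction` of off-diagonal patch pairs
#' by absolute attention weight and, separately, by contact strength; the
#' observed statistic is the size of the intersection of the two pair sets,
#' summed over chromosomes (selection is rank-based, so it is invariant to
#' strictly monotone transforms of either matrix). The null perturbs the
#' genomic positions of the contacts: each permutation shifts the selected
#' contact pairs by a uniformly random non-identity circular offset along the
#' patch axis per chromosome (preserving the pair-distance structure;
#' `method = "shuffle"` instead relabels patches by a random permutation) and
#' recomputes the overlap. The add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)` never returns 0.
#'
#' @param attention an `attention_map`.
#' @param contact_matrix named list of per-chromosome strength matrices from
#'   [contacts_to_patch_pairs()].
#' @param top_fraction fraction of off-diagonal pairs selected (default
#'   0.05).
#' @param n_permutations number of null draws (>= 1).
#' @param seed integer seed.
#' @param method `"circular"` (default) or `"shuffle"`.
#' @return a one-row tibble of class `overlap_result`: columns
#'   `n_attention_selected`, `n_contact_selected`, `n_overlap`, `p_value`,
#'   `n_permutations`; attribute `null` holds the null overlap counts.
#' @export
overlap_permutation_test <- function(attention, contact_matrix,
                                     top_fraction = 0.05,
                                     n_permutations = 1000, seed = 1,
                                     method = c("circular", "shuffle")) {
  method <- match.arg(method)
  stopifnot(inherits(attention, "attention_map"),
            top_fraction > 0, top_fraction < 1)
  if (n_permutations < 1) {
    stop("n_permutations must be >= 1 (p-value undefined otherwise)",
         call. = FALSE)
  }
  chroms <- intersect(names(attention$per_chrom), names(contact_matrix))
  sel <- list()
  for (ch in chroms) {
    W <- attention$per_chrom[[ch]]$W
    C <- contact_matrix[[ch]]
    stopifnot(identical(dim(W), dim(C)))
    p <- nrow(W)
    n_pairs <- p * (p - 1) %/% 2
    m <- floor(top_fraction * n_pairs)
    if (m < 1) next
    att_ij <- top_pairs_ij(abs(W), m)
    sel[[ch]] <- list(
      p = p,
      att = encode_pairs(att_ij[, 1], att_ij[, 2], p),
      con_ij = top_pairs_ij(C, m)
    )
  }
  if (length(sel) == 0) {
    stop("top_fraction selects 0 pairs on every chromosome; increase it",
         call. = FALSE)
  }
  observed <- sum(vapply(sel, function(s) {
    sum(encode_pairs(s$con_ij[, 1], s$con_ij[, 2], s$p) %in% s$att)
  }, 0))
  n_att <- sum(vapply(sel, function(s) length(s$att), 0L))
  n_con <- sum(vapply(sel, function(s) nrow(s$con_ij), 0L))
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(perm) {
      sum(vapply(sel, function(s) {
        p <- s$p
        if (method == "circular") {
          o <- sample.int(p - 1L, 1)  # non-identity offsets only
          i2 <- (s$con_ij[, 1] - 1L + o) %% p + 1L
          j2 <- (s$con_ij[, 2] - 1L + o) %% p + 1L
        } else {
          pi_ <- sample.int(p)
          i2 <- pi_[s$con_ij[, 1]]
          j2 <- pi_[s$con_ij[, 2]]
        }
        sum(encode_pairs(i2, j2, p) %in% s$att)
      }, 0))
    }, 0)
  })
  p_value <- (1 + sum(null >= observed)) / (1 + n_permutations)
  out <- tibble::tibble(
    n_attention_selected = n_att, n_contact_selected = n_con,
    n_overlap = observed, p_value = p_value,
    n_permutations = as.integer(n_permutations)
  )
  attr(out, "null") <- null
  class(out) <- c("overlap_result", class(out))
  out
}
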