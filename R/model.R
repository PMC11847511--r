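#' Model configuration
#'
#' Collects the architectural hyperparameters of the patch-transformer
#' deconvolution model. `d` must be divisible by the head count `h`;
#' `decoder_dims` gives the four hidden widths of the five-matrix factorized
#' decoder (W1: k x d1, ..., W5: d4 x n_peaks).
#'
#' @param k number of cell types.
#' @param n_peaks number of peaks in the shared feature space.
#' @param d embedding dimension (default 64).
#' @param L encoder depth (default 2).
#' @param h number of attention heads (default 4).
#' @param patch_size peaks per patch (default 50).
#' @param decoder_dims integer vector of 4 hidden widths
#'   (default `c(64, 128, 256, 512)`).
#' @param mlp_hidden hidden width of the encoder MLP blocks (default `2 * d`).
#' @param seed integer seed used for parameter initialization.
#' @return a list of class `deconv_config`.
#' @export
deconv_config <- function(k, n_peaks, d = 64, L = 2, h = 4, patch_size = 50,
                        decoder_dims = c(64, 128, 256, 512),
                        mlp_hidden = 2 * d, seed = 1) {
  stopifnot(k >= 1, n_peaks >= 1, d >= 1, L >= 0, h >= 1, patch_size >= 1)
  if (d %% h != 0) stop("d must be divisible by h", call. = FALSE)
  if (length(decoder_dims) != 4) {
    stop("decoder_dims must have exactly 4 entries (five matrices => four ",
         "hidden widths)", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), n_peaks = as.integer(n_peaks), d = as.integer(d),
         L = as.integer(L), h = as.integer(h),
         patch_size = as.integer(patch_size),
         decoder_dims = as.integer(decoder_dims),
         mlp_hidden = as.integer(mlp_hidden), seed = as.integer(seed)),
    class = "deconv_config"
  )
}

ln_eps <- 1e-5

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# add a length-ncol row vector to every row (faster than sweep in hot loops)
row_add <- function(X, v) X + rep(v, each = nrow(X))
row_mul <- function(X, v) X * rep(v, each = nrow(X))

# row-wise layer normalization with learnable gain/shift; returns cache
ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(y = row_add(row_mul(xhat, g), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- row_mul(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

#' Initialize a deconvolution model
#'
#' Creates all trainable parameters: one LayerNorm+MLP projection per patch,
#' the class token, `L` encoder layers (multi-head self-attention + MLP block,
#' each pre-LayerNorm with residual connections), the sigmoid proportion
#' head, and the five decoder matrices. Weights are drawn N(0, 0.02^2),
#' biases zero, LayerNorm gain 1; the decoder matrices start uniform
#' non-negative so the rectified signature output begins fully active.
#'
#' @param layout a [build_patches()] layout defining the patch structure.
#' @param celltypes character vector of cell-type names (defines `k` and the
#'   output order).
#' @param config optional [deconv_config()]; defaults are filled from `layout`
#'   and `celltypes`.
#' @return an object of class `deconv_model`: list with `config`, `layout`,
#'   `celltypes`, and `params` (flat named list of numeric arrays).
#' @export
deconv_model <- function(layout, celltypes, config = NULL) {
  stopifnot(inherits(layout, "patch_layout"))
  k <- length(celltypes)
  if (is.null(config)) {
    config <- deconv_config(k = k, n_peaks = layout$n_peaks,
                          patch_size = layout$patch_size)
  }
  stopifnot(config$k == k, config$n_peaks == layout$n_peaks)
  d <- config$d; s <- layout$patch_size; j <- layout$n_patches
  dm <- config$mlp_hidden
  dd <- config$decoder_dims
  params <- with_seed(config$seed, {
    rn <- function(nr, nc, sd = 0.02) {
      matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    }
    p <- list(cls = stats::rnorm(d, sd = 0.02))
    for (jj in seq_len(j)) {
      p[[sprintf("patch%d.ln_g", jj)]] <- rep(1, s)
      p[[sprintf("patch%d.ln_b", jj)]] <- rep(0, s)
      p[[sprintf("patch%d.W1", jj)]] <- rn(s, d)
      p[[sprintf("patch%d.b1", jj)]] <- rep(0, d)
      p[[sprintf("patch%d.W2", jj)]] <- rn(d, d)
      p[[sprintf("patch%d.b2", jj)]] <- rep(0, d)
    }
    for (l in seq_len(config$L)) {
      p[[sprintf("enc%d.ln1_g", l)]] <- rep(1, d)
      p[[sprintf("enc%d.ln1_b", l)]] <- rep(0, d)
      p[[sprintf("enc%d.Wq", l)]] <- rn(d, d)
      p[[sprintf("enc%d.Wk", l)]] <- rn(d, d)
      p[[sprintf("enc%d.Wv", l)]] <- rn(d, d)
      p[[sprintf("enc%d.Wo", l)]] <- rn(d, d)
      p[[sprintf("enc%d.bo", l)]] <- rep(0, d)
      p[[sprintf("enc%d.ln2_g", l)]] <- rep(1, d)
      p[[sprintf("enc%d.ln2_b", l)]] <- rep(0, d)
      p[[sprintf("enc%d.Wm1", l)]] <- rn(d, dm)
      p[[sprintf("enc%d.bm1", l)]] <- rep(0, dm)
      p[[sprintf("enc%d.Wm2", l)]] <- rn(dm, d)
      p[[sprintf("enc%d.bm2", l)]] <- rep(0, d)
    }
    p[["head.ln_g"]] <- rep(1, d)
    p[["head.ln_b"]] <- rep(0, d)
    p[["head.W1"]] <- rn(d, d)
    p[["head.b1"]] <- rep(0, d)
    p[["head.W2"]] <- rn(d, k)
    p[["head.b2"]] <- rep(0, k)
    # decoder matrices start non-negative so the final ReLU begins fully
    # active (a signed init leaves many signature entries pinned at zero);
    # scale 2/fan_in keeps the five-matrix product near mean 1/k per entry
    dims <- c(k, dd, config$n_peaks)
    for (w in 1:5) {
      p[[sprintf("dec.W%d", w)]] <- matrix(
        stats::runif(dims[w] * dims[w + 1], 0, 2 / dims[w]),
        dims[w], dims[w + 1])
    }
    p
  })
  structure(list(config = config, layout = layout,
                 celltypes = as.character(celltypes), params = params),
            class = "deconv_model")
}

#' @export
print.deconv_model <- function(x, ...) {
  cfg <- x$config
  cat("<deconv_model> ", cfg$k, " cell types, ", cfg$n_peaks, " peaks, ",
      x$layout$n_patches, " patches (size ", cfg$patch_size, "), d=", cfg$d,
      ", L=", cfg$L, ", h=", cfg$h, ", ",
      format(sum(vapply(x$params, length, 1L)), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

# --- batched forward -------------------------------------------------------

# pad a sample x patch-column slice to the layout patch width
pad_patch <- function(x, cols, s) {
  P <- x[, cols, drop = FALSE]
  if (length(cols) < s) {
    P <- cbind(P, matrix(0, nrow(P), s - length(cols)))
  }
  P
}

# patch embedding for a B x n_peaks input; returns (B*T) x d token matrix,
# sample-major (rows (b-1)*T + 1..T), token 1 = class token
embed_fwd <- function(params, layout, cfg, x, want_cache = FALSE) {
  B <- nrow(x); j <- layout$n_patches; T <- j + 1L; d <- cfg$d
  s <- layout$patch_size
  X0 <- matrix(0, B * T, d)
  idx_cls <- seq.int(1L, B * T, by = T)
  X0[idx_cls, ] <- matrix(params$cls, B, d, byrow = TRUE)
  cache <- if (want_cache) vector("list", j) else NULL
  for (jj in seq_len(j)) {
    P <- pad_patch(x, layout$peak_cols[[jj]], s)
    ln <- ln_fwd(P, params[[sprintf("patch%d.ln_g", jj)]],
                 params[[sprintf("patch%d.ln_b", jj)]])
    H <- row_add(ln$y %*% params[[sprintf("patch%d.W1", jj)]],
                 params[[sprintf("patch%d.b1", jj)]])
    A <- gelu(H)
    N <- row_add(A %*% params[[sprintf("patch%d.W2", jj)]],
                 params[[sprintf("patch%d.b2", jj)]])
    X0[idx_cls + jj, ] <- N
    if (want_cache) cache[[jj]] <- list(ln = ln, H = H, A = A)
  }
  list(X0 = X0, cache = cache, idx_cls = idx_cls, B = B, T = T)
}

# one encoder layer forward on a (B*T) x d token matrix
enc_layer_fwd <- function(params, cfg, l, X, B, want_cache = FALSE) {
  d <- cfg$d; h <- cfg$h; dh <- d %/% h
  T <- nrow(X) %/% B
  pn <- function(nm) params[[sprintf("enc%d.%s", l, nm)]]
  ln1 <- ln_fwd(X, pn("ln1_g"), pn("ln1_b"))
  Y <- ln1$y
  Q <- Y %*% pn("Wq"); K <- Y %*% pn("Wk"); V <- Y %*% pn("Wv")
  O <- matrix(0, B * T, d)
  Alist <- vector("list", B)
  sc <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * T + 1L):(b * T)
    Ab <- vector("list", h)
    for (hh in seq_len(h)) {
      ch <- ((hh - 1L) * dh + 1L):(hh * dh)
      S <- tcrossprod(Q[rb, ch, drop = FALSE], K[rb, ch, drop = FALSE]) * sc
      A <- softmax_rows(S)
      Ab[[hh]] <- A
      O[rb, ch] <- A %*% V[rb, ch, drop = FALSE]
    }
    Alist[[b]] <- Ab
  }
  Z <- row_add(O %*% pn("Wo"), pn("bo"))
  X1 <- X + Z
  ln2 <- ln_fwd(X1, pn("ln2_g"), pn("ln2_b"))
  Hm <- row_add(ln2$y %*% pn("Wm1"), pn("bm1"))
  Gm <- gelu(Hm)
  Mo <- row_add(Gm %*% pn("Wm2"), pn("bm2"))
  X2 <- X1 + Mo
  cache <- NULL
  if (want_cache) {
    cache <- list(X = X, ln1 = ln1, Q = Q, K = K, V = V, A = Alist, O = O,
                  X1 = X1, ln2 = ln2, Hm = Hm, Gm = Gm)
  }
  list(X = X2, A = Alist, cache = cache)
}

head_fwd <- function(params, cfg, C, want_cache = FALSE) {
  ln <- ln_fwd(C, params[["head.ln_g"]], params[["head.ln_b"]])
  H <- row_add(ln$y %*% params[["head.W1"]], params[["head.b1"]])
  G <- gelu(H)
  logits <- row_add(G %*% params[["head.W2"]], params[["head.b2"]])
  raw <- 1 / (1 + exp(-logits))
  S <- rowSums(raw)
  if (any(S <= 0) || any(!is.finite(S))) {
    stop("sigmoid head produced a non-positive row sum (non-finite logits?)",
         call. = FALSE)
  }
  P_hat <- raw / S
  cache <- if (want_cache) list(ln = ln, H = H, G = G, raw = raw, S = S)
  list(P_hat = P_hat, raw = raw, cache = cache)
}

decoder_fwd <- function(params) {
  M1 <- params[["dec.W1"]]
  M2 <- M1 %*% params[["dec.W2"]]
  M3 <- M2 %*% params[["dec.W3"]]
  M4 <- M3 %*% params[["dec.W4"]]
  M_pre <- M4 %*% params[["dec.W5"]]
  list(M_hat = pmax(M_pre, 0), M_pre = M_pre, M1 = M1, M2 = M2, M3 = M3,
       M4 = M4)
}

# full forward pass; x is B x n_peaks (min-max normalized)
fwd_full <- function(model, x, want_cache = FALSE, want_attention = FALSE) {
  params <- model$params; cfg <- model$config; layout <- model$layout
  stopifnot(ncol(x) == cfg$n_peaks)
  emb <- embed_fwd(params, layout, cfg, x, want_cache)
  X <- emb$X0
  B <- emb$B
  enc_caches <- if (want_cache) vector("list", cfg$L) else NULL
  attn <- if (want_attention) vector("list", max(cfg$L, 0)) else NULL
  if (cfg$L > 0) {
    for (l in seq_len(cfg$L)) {
      step <- enc_layer_fwd(params, cfg, l, X, B, want_cache)
      X <- step$X
      if (want_cache) enc_caches[[l]] <- step$cache
      if (want_attention) attn[[l]] <- step$A  # list: [[sample]][[head]]
    }
  }
  C <- X[emb$idx_cls, , drop = FALSE]
  hd <- head_fwd(params, cfg, C, want_cache)
  dec <- decoder_fwd(params)
  list(P_hat = hd$P_hat, raw = hd$raw, M_hat = dec$M_hat, X_L = X,
       attention = attn,
       cache = if (want_cache) list(emb = emb, enc = enc_caches,
                                    head = hd$cache, dec = dec,
                                    idx_cls = emb$idx_cls, B = B))
}

# --- exported single-sample operations (spec surface) ----------------------

#' Embed one bulk profile into patch tokens
#'
#' Applies each patch's own LayerNorm-then-MLP projection to its (zero-padded)
#' peak slice and prepends the learnable class token.
#'
#' @param x numeric vector (or 1 x n_peaks matrix) of a min-max normalized
#'   bulk profile.
#' @param layout the model's [build_patches()] layout.
#' @param model a [deconv_model()].
#' @return a `(1 + n_patches) x d` matrix; row 1 is the class token.
#' @export
embed_patches <- function(x, layout, model) {
  x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != layout$n_peaks) {
    stop("profile length ", ncol(x), " does not match layout (",
         layout$n_peaks, " peaks)", call. = FALSE)
  }
  emb <- embed_fwd(model$params, layout, model$config, x)
  X0 <- emb$X0
  rownames(X0) <- c("cls", paste0("patch", seq_len(layout$n_patches)))
  X0
}

#' Scaled dot-product self-attention (one head)
#'
#' Computes `softmax(q k^T / sqrt(d_head))` applied to `v`, with
#' `q, k, v = X W_{q,k,v}`.
#'
#' @param X `t x d` token matrix.
#' @param Wq,Wk,Wv `d x d_head` projection matrices.
#' @return list with `out` (`t x d_head`) and `attention` (`t x t`,
#'   row-stochastic).
#' @export
self_attention <- function(X, Wq, Wk, Wv) {
  q <- X %*% Wq; k <- X %*% Wk; v <- X %*% Wv
  A <- softmax_rows(tcrossprod(q, k) / sqrt(ncol(Wq)))
  list(out = A %*% v, attention = A)
}

#' Multi-head self-attention
#'
#' Runs `h` self-attention heads in parallel on disjoint `d/h`-wide slices of
#' the shared `d x d` projections, concatenates their outputs and applies the
#' output projection.
#'
#' @param X `t x d` token matrix.
#' @param layer_params list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d`) and `bo`
#'   (length `d`).
#' @param h number of heads.
#' @return list with `out` (`t x d`) and `attention` (`h x t x t` array).
#' @export
msa <- function(X, layer_params, h = 1) {
  d <- ncol(X)
  stopifnot(d %% h == 0)
  dh <- d %/% h
  t_ <- nrow(X)
  O <- matrix(0, t_, d)
  A <- array(0, dim = c(h, t_, t_))
  for (hh in seq_len(h)) {
    ch <- ((hh - 1L) * dh + 1L):(hh * dh)
    sa <- self_attention(X, layer_params$Wq[, ch, drop = FALSE],
                         layer_params$Wk[, ch, drop = FALSE],
                         layer_params$Wv[, ch, drop = FALSE])
    O[, ch] <- sa$out
    A[hh, , ] <- sa$attention
  }
  out <- O %*% layer_params$Wo
  out <- sweep(out, 2, layer_params$bo, `+`)
  list(out = out, attention = A)
}

#' Run the transformer encoder on a token matrix
#'
#' Applies `L` pre-LayerNorm blocks of multi-head self-attention and MLP,
#' each with a residual connection. `L = 0` is the identity.
#'
#' @param X0 `(1 + n_patches) x d` token matrix from [embed_patches()].
#' @param model a [deconv_model()].
#' @param return_attention if `TRUE`, also return the per-layer, per-head
#'   attention arrays.
#' @return the encoded token matrix, or (with attention) a list
#'   `list(X, attention)` where `attention[[l]]` is `h x t x t`.
#' @export
encoder_forward <- function(X0, model, return_attention = FALSE) {
  cfg <- model$config
  X <- as.matrix(X0)
  attn <- vector("list", max(cfg$L, 0))
  if (cfg$L > 0) {
    for (l in seq_len(cfg$L)) {
      step <- enc_layer_fwd(model$params, cfg, l, X, B = 1L)
      X <- step$X
      t_ <- nrow(X)
      attn[[l]] <- array(unlist(lapply(step$A[[1]], as.vector)),
                         dim = c(t_, t_, cfg$h))
      attn[[l]] <- aperm(attn[[l]], c(3, 1, 2))
    }
  }
  if (return_attention) list(X = X, attention = attn) else X
}

#' Predict cell-type proportions from encoded tokens
#'
#' The class-token row is LayerNormed, passed through the head MLP, squashed
#' by a sigmoid (each entry in (0,1)) and renormalized to the simplex.
#'
#' @param X_L encoded token matrix from [encoder_forward()] (class token in
#'   row 1), or a `samples x d` matrix of class-token states.
#' @param model a [deconv_model()].
#' @param cls_rows row index/indices holding class tokens (default 1).
#' @return list with `P_hat` (rows sum to 1) and `raw` (pre-normalization
#'   sigmoid outputs).
#' @export
proportion_head <- function(X_L, model, cls_rows = 1) {
  C <- as.matrix(X_L)[cls_rows, , drop = FALSE]
  hd <- head_fwd(model$params, model$config, C)
  colnames(hd$P_hat) <- model$celltypes
  colnames(hd$raw) <- model$celltypes
  hd[c("P_hat", "raw")]
}

#' Decode the cell-type signature matrix
#'
#' The decoder is the bias-free, activation-free product of five weight
#' matrices, rectified once at the end:
#' `M_hat = ReLU(W1 W2 W3 W4 W5)`, a `k x n_peaks` non-negative matrix.
#'
#' @param model a [deconv_model()].
#' @return the `k x n_peaks` signature matrix with cell types as rownames.
#' @export
decode_signature <- function(model) {
  M <- decoder_fwd(model$params)$M_hat
  dimnames(M) <- list(model$celltypes, model$layout$peak_ids)
  M
}

#' Reconstruct bulk profiles from proportions and signatures
#'
#' The mixing identity of deconvolution: `B_hat = P_hat %*% M_hat`.
#'
#' @param P_hat `samples x k` proportion matrix.
#' @param M_hat `k x n_peaks` signature matrix.
#' @return `samples x n_peaks` matrix.
#' @export
reconstruct_bulk <- function(P_hat, M_hat) {
  stopifnot(ncol(P_hat) == nrow(M_hat))
  as.matrix(P_hat) %*% as.matrix(M_hat)
}

#' Predict cell-type proportions for bulk profiles
#'
#' Runs the full forward pass in mini-batches.
#'
#' @param model a trained [deconv_model()].
#' @param bulk `samples x n_peaks` matrix (min-max normalized rows) on the
#'   model's peak space.
#' @param chunk mini-batch size for the forward pass.
#' @return a tibble (class `deconv_proportions`) in long format with columns
#'   `sample`, `celltype`, `proportion`; the wide matrix is in attribute `P`.
#' @export
predict_proportions <- function(model, bulk, chunk = 256) {
  bulk <- as.matrix(bulk)
  if (is.null(rownames(bulk))) {
    rownames(bulk) <- sprintf("sample_%04d", seq_len(nrow(bulk)))
  }
  P <- predict_P(model, bulk, chunk)
  dimnames(P) <- list(rownames(bulk), model$celltypes)
  out <- tibble::as_tibble(as.data.frame.table(P, responseName = "proportion"))
  names(out)[1:2] <- c("sample", "celltype")
  out$sample <- as.character(out$sample)
  out$celltype <- as.character(out$celltype)
  out <- dplyr::arrange(out, .data$sample, .data$celltype)
  attr(out, "P") <- P
  class(out) <- c("deconv_proportions", class(out))
  out
}

# matrix-only prediction used internally
predict_P <- function(model, bulk, chunk = 256) {
  n <- nrow(bulk)
  P <- matrix(0, n, model$config$k)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1, n)
    P[i0:i1, ] <- fwd_full(model, bulk[i0:i1, , drop = FALSE])$P_hat
  }
  P
}
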