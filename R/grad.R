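# Full backpropagation for the training loss
#
#   L = w_P * mse(P_true, P_hat) + w_M * mse(M_true, M_hat)
#     + w_recon * mse(x, P_hat %*% M_hat)
#
# Any loss weight may be 0 (terms and their gradients are skipped).
# `trainable` restricts the returned gradient to a parameter subset
# ("all", "decoder", "encoder" = everything except the decoder).
loss_and_grad <- function(model, x, P_true = NULL, M_true = NULL,
                          w_P = 1, w_M = 1, w_recon = 1,
                          trainable = c("all", "decoder", "encoder"),
                          want_grads = TRUE) {
  trainable <- match.arg(trainable)
  params <- model$params; cfg <- model$config; layout <- model$layout
  B <- nrow(x); k <- cfg$k; n_peaks <- cfg$n_peaks
  fw <- fwd_full(model, x, want_cache = want_grads)
  P_hat <- fw$P_hat; M_hat <- fw$M_hat
  dec <- if (want_grads) fw$cache$dec else decoder_fwd(params)

  parts <- c(mse_P = NA_real_, mse_M = NA_real_, mse_recon = NA_real_)
  dP_hat <- matrix(0, B, k)
  dM_hat <- matrix(0, k, n_peaks)
  loss <- 0
  if (w_P > 0 && !is.null(P_true)) {
    diffP <- P_hat - P_true
    parts["mse_P"] <- mean(diffP^2)
    loss <- loss + w_P * parts["mse_P"]
    dP_hat <- dP_hat + w_P * 2 * diffP / (B * k)
  }
  # the signature penalty acts on the pre-rectifier product: true signatures
  # are non-negative, so the optimum is unchanged, but the penalty keeps a
  # gradient alive where the rectifier is flat (entries cannot die there)
  dM_pre_direct <- NULL
  if (w_M > 0 && !is.null(M_true)) {
    diffM <- dec$M_pre - M_true
    parts["mse_M"] <- mean(diffM^2)
    loss <- loss + w_M * parts["mse_M"]
    dM_pre_direct <- w_M * 2 * diffM / (k * n_peaks)
  }
  if (w_recon > 0) {
    B_hat <- P_hat %*% M_hat
    diffR <- B_hat - x
    parts["mse_recon"] <- mean(diffR^2)
    loss <- loss + w_recon * parts["mse_recon"]
    dB <- w_recon * 2 * diffR / (B * n_peaks)
    dP_hat <- dP_hat + dB %*% t(M_hat)
    dM_hat <- dM_hat + crossprod(P_hat, dB)
  }
  if (!want_grads) {
    return(list(loss = as.numeric(loss), parts = parts, P_hat = P_hat,
                M_hat = M_hat, grads = NULL))
  }

  grads <- list()
  # ---- decoder backward ----
  if (trainable %in% c("all", "decoder")) {
    dM_pre <- dM_hat * (dec$M_pre > 0)
    if (!is.null(dM_pre_direct)) dM_pre <- dM_pre + dM_pre_direct
    dW5 <- crossprod(dec$M4, dM_pre)
    dM4 <- tcrossprod(dM_pre, params[["dec.W5"]])
    dW4 <- crossprod(dec$M3, dM4)
    dM3 <- tcrossprod(dM4, params[["dec.W4"]])
    dW3 <- crossprod(dec$M2, dM3)
    dM2 <- tcrossprod(dM3, params[["dec.W3"]])
    dW2 <- crossprod(dec$M1, dM2)
    dM1 <- tcrossprod(dM2, params[["dec.W2"]])
    grads[["dec.W1"]] <- dM1
    grads[["dec.W2"]] <- dW2
    grads[["dec.W3"]] <- dW3
    grads[["dec.W4"]] <- dW4
    grads[["dec.W5"]] <- dW5
  }
  if (trainable == "decoder") {
    return(list(loss = as.numeric(loss), parts = parts, P_hat = P_hat,
                M_hat = M_hat, grads = grads))
  }

  # ---- head backward (through the simplex renormalization) ----
  hc <- fw$cache$head
  raw <- hc$raw; S <- hc$S
  draw <- (dP_hat - rowSums(dP_hat * P_hat)) / S
  dlogits <- draw * raw * (1 - raw)
  grads[["head.W2"]] <- crossprod(hc$G, dlogits)
  grads[["head.b2"]] <- colSums(dlogits)
  dG <- tcrossprod(dlogits, params[["head.W2"]])
  dH <- dG * gelu_grad(hc$H)
  grads[["head.W1"]] <- crossprod(hc$ln$y, dH)
  grads[["head.b1"]] <- colSums(dH)
  dY <- tcrossprod(dH, params[["head.W1"]])
  lnb <- ln_bwd(dY, hc$ln, params[["head.ln_g"]])
  grads[["head.ln_g"]] <- lnb$dg
  grads[["head.ln_b"]] <- lnb$db
  dC <- lnb$dx

  # ---- encoder backward ----
  idx_cls <- fw$cache$idx_cls
  T <- layout$n_patches + 1L
  d <- cfg$d; h <- cfg$h; dh <- d %/% h
  dX <- matrix(0, B * T, d)
  dX[idx_cls, ] <- dC
  if (cfg$L > 0) {
    for (l in rev(seq_len(cfg$L))) {
      ec <- fw$cache$enc[[l]]
      pn <- function(nm) params[[sprintf("enc%d.%s", l, nm)]]
      gn <- function(nm) sprintf("enc%d.%s", l, nm)
      # MLP block: X2 = X1 + MLP(LN2(X1))
      dMo <- dX
      grads[[gn("Wm2")]] <- crossprod(ec$Gm, dMo)
      grads[[gn("bm2")]] <- colSums(dMo)
      dGm <- tcrossprod(dMo, pn("Wm2"))
      dHm <- dGm * gelu_grad(ec$Hm)
      grads[[gn("Wm1")]] <- crossprod(ec$ln2$y, dHm)
      grads[[gn("bm1")]] <- colSums(dHm)
      dY2 <- tcrossprod(dHm, pn("Wm1"))
      lnb2 <- ln_bwd(dY2, ec$ln2, pn("ln2_g"))
      grads[[gn("ln2_g")]] <- lnb2$dg
      grads[[gn("ln2_b")]] <- lnb2$db
      dX1 <- dX + lnb2$dx
      # MSA block: X1 = X + MSA(LN1(X))
      dZ <- dX1
      grads[[gn("Wo")]] <- crossprod(ec$O, dZ)
      grads[[gn("bo")]] <- colSums(dZ)
      dO <- tcrossprod(dZ, pn("Wo"))
      dQ <- matrix(0, B * T, d)
      dK <- matrix(0, B * T, d)
      dV <- matrix(0, B * T, d)
      sc <- 1 / sqrt(dh)
      for (b in seq_len(B)) {
        rb <- ((b - 1L) * T + 1L):(b * T)
        for (hh in seq_len(h)) {
          ch <- ((hh - 1L) * dh + 1L):(hh * dh)
          A <- ec$A[[b]][[hh]]
          dOb <- dO[rb, ch, drop = FALSE]
          Vb <- ec$V[rb, ch, drop = FALSE]
          dA <- tcrossprod(dOb, Vb)
          dV[rb, ch] <- crossprod(A, dOb)
          dS <- A * (dA - rowSums(dA * A))
          dQ[rb, ch] <- dS %*% ec$K[rb, ch, drop = FALSE] * sc
          dK[rb, ch] <- crossprod(dS, ec$Q[rb, ch, drop = FALSE]) * sc
        }
      }
      Y <- ec$ln1$y
      grads[[gn("Wq")]] <- crossprod(Y, dQ)
      grads[[gn("Wk")]] <- crossprod(Y, dK)
      grads[[gn("Wv")]] <- crossprod(Y, dV)
      dY <- tcrossprod(dQ, pn("Wq")) + tcrossprod(dK, pn("Wk")) +
        tcrossprod(dV, pn("Wv"))
      lnb1 <- ln_bwd(dY, ec$ln1, pn("ln1_g"))
      grads[[gn("ln1_g")]] <- lnb1$dg
      grads[[gn("ln1_b")]] <- lnb1$db
      dX <- dX1 + lnb1$dx
    }
  }

  # ---- patch embedding backward ----
  grads[["cls"]] <- colSums(dX[idx_cls, , drop = FALSE])
  s <- layout$patch_size
  x_pad_cache <- fw$cache$emb$cache
  for (jj in seq_len(layout$n_patches)) {
    pc <- x_pad_cache[[jj]]
    pn <- function(nm) params[[sprintf("patch%d.%s", jj, nm)]]
    gn <- function(nm) sprintf("patch%d.%s", jj, nm)
    dN <- dX[idx_cls + jj, , drop = FALSE]
    grads[[gn("W2")]] <- crossprod(pc$A, dN)
    grads[[gn("b2")]] <- colSums(dN)
    dA <- tcrossprod(dN, pn("W2"))
    dH <- dA * gelu_grad(pc$H)
    grads[[gn("W1")]] <- crossprod(pc$ln$y, dH)
    grads[[gn("b1")]] <- colSums(dH)
    dy <- tcrossprod(dH, pn("W1"))
    lnb <- ln_bwd(dy, pc$ln, pn("ln_g"))
    grads[[gn("ln_g")]] <- lnb$dg
    grads[[gn("ln_b")]] <- lnb$db
  }
  if (trainable == "encoder") {
    grads[grep("^dec\\.", names(grads))] <- NULL
  }
  list(loss = as.numeric(loss), parts = parts, P_hat = P_hat, M_hat = M_hat,
       grads = grads)
}

# numerical loss-only evaluation used by the finite-difference oracle in tests
loss_only <- function(model, x, P_true = NULL, M_true = NULL,
                      w_P = 1, w_M = 1, w_recon = 1) {
  loss_and_grad(model, x, P_true, M_true, w_P, w_M, w_recon,
                want_grads = FALSE)$loss
}
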