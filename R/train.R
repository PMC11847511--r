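#' Mean squared error between two equally shaped arrays
#'
#' @param A,B numeric vectors or matrices of identical shape.
#' @return mean of squared elementwise differences (a scalar, >= 0).
#' @examples
#' mse(c(1, 2), c(3, 2))  # 2
#' @export
mse <- function(A, B) {
  if (!identical(dim(A), dim(B)) || length(A) != length(B)) {
    stop("shape mismatch in mse()", call. = FALSE)
  }
  mean((A - B)^2)
}

#' Plateau detection on a loss history
#'
#' `TRUE` iff the best (minimum) value seen before the last `patience`
#' entries has not been improved by more than `tol` within those entries.
#' Histories no longer than `patience` never plateau (not enough evidence).
#'
#' @param history numeric vector of loss values (most recent last).
#' @param patience number of trailing entries that must fail to improve.
#' @param tol minimum decrease that counts as an improvement.
#' @return logical.
#' @examples
#' plateau(c(1, 0.5, 0.5, 0.5), patience = 2)  # TRUE
#' @export
plateau <- function(history, patience = 5, tol = 1e-6) {
  stopifnot(length(history) >= 1, patience >= 1)
  n <- length(history)
  if (n <= patience) return(FALSE)
  best_before <- min(history[seq_len(n - patience)])
  best_recent <- min(history[(n - patience + 1):n])
  (best_before - best_recent) <= tol
}

# --- Adam optimizer over a flat named parameter list -----------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Supervised initial training on pseudo-bulk batches
#'
#' Minimizes
#' `mse(P_true, P_hat) + w_M * mse(M_true, M_hat) + w_recon * mse(bulk, P_hat M_hat)`
#' jointly over all parameters by mini-batch Adam. After the final epoch the
#' training-set predictions are snapshotted as the anchors `P_tilde` /
#' `M_tilde` used by [adapt()].
#'
#' @param model a freshly initialized [deconv_model()].
#' @param batch a `pseudobulk_batch` whose peak space matches the model.
#' @param epochs training epochs (0 returns the model unchanged).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling shuffling (reproducible histories).
#' @param w_M,w_recon loss weights of the signature and reconstruction terms.
#' @param verbose print per-epoch losses.
#' @return an object of class `deconv_fit`: list with `model` (trained) and
#'   `state` (class `train_state`: `loss_history` tibble with per-epoch mean
#'   mini-batch losses, anchors `P_tilde`/`M_tilde`, `patience`, `tol`).
#' @export
train_initial <- function(model, batch, epochs = 22, lr = 1e-3,
                          batch_size = 32, seed = 1, w_M = 5, w_recon = 1,
                          verbose = FALSE) {
  stopifnot(inherits(model, "deconv_model"),
            inherits(batch, "pseudobulk_batch"),
            ncol(batch$bulk) == model$config$n_peaks,
            ncol(batch$P_true) == model$config$k)
  x <- batch$bulk; P_true <- batch$P_true; M_true <- batch$M_true
  n <- nrow(x)
  opt <- adam_init(model$params)
  history <- vector("list", epochs)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      acc <- c(loss = 0, mse_P = 0, mse_M = 0, mse_recon = 0)
      for (i0 in starts) {
        idx <- ord[i0:min(i0 + batch_size - 1, n)]
        lg <- loss_and_grad(model, x[idx, , drop = FALSE],
                            P_true[idx, , drop = FALSE], M_true,
                            w_P = 1, w_M = w_M, w_recon = w_recon)
        if (!is.finite(lg$loss)) {
          stop("non-finite training loss at epoch ", e,
               "; try a lower learning rate", call. = FALSE)
        }
        st <- adam_step(model$params, lg$grads, opt, lr = lr)
        model$params <- st$params
        opt <- st$state
        acc <- acc + c(lg$loss, lg$parts)
      }
      acc <- acc / length(starts)
      history[[e]] <- tibble::tibble(epoch = e, loss = acc[1],
                                     mse_P = acc[2], mse_M = acc[3],
                                     mse_recon = acc[4])
      if (verbose) {
        message(sprintf("epoch %d: loss %.5f (P %.5f, M %.5f, recon %.5f)",
                        e, acc[1], acc[2], acc[3], acc[4]))
      }
    }
  })
  loss_history <- if (epochs > 0) dplyr::bind_rows(history) else
    tibble::tibble(epoch = integer(), loss = numeric(), mse_P = numeric(),
                   mse_M = numeric(), mse_recon = numeric())
  P_tilde <- if (epochs > 0) predict_P(model, x) else NULL
  if (!is.null(P_tilde)) dimnames(P_tilde) <- dimnames(P_true)
  state <- structure(
    list(epochs = epochs, loss_history = loss_history,
         P_tilde = P_tilde,
         M_tilde = if (epochs > 0) decode_signature(model) else NULL,
         patience = 5L, tol = 1e-6),
    class = "train_state"
  )
  structure(list(model = model, state = state), class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  h <- x$state$loss_history
  cat("<deconv_fit> ", x$state$epochs, " epochs", sep = "")
  if (nrow(h) > 0) {
    cat(sprintf("; final loss %.5f (P %.5f, M %.5f, recon %.5f)",
                h$loss[nrow(h)], h$mse_P[nrow(h)], h$mse_M[nrow(h)],
                h$mse_recon[nrow(h)]))
  }
  cat("\n")
  invisible(x)
}

# optimize a parameter subset until plateau, restoring the best-seen
# parameters (an accepted plateau can never be worse than step entry)
optimize_until_plateau <- function(model, step_fn, lr = 1e-4, patience = 5,
                                   tol = 1e-6, max_steps = 200) {
  opt <- adam_init(model$params)
  history <- numeric()
  best <- Inf
  best_params <- model$params
  for (it in seq_len(max_steps + 1L)) {
    lg <- step_fn(model)  # tracked loss and gradients at current parameters
    history <- c(history, lg$track)
    if (lg$track < best) {
      best <- lg$track
      best_params <- model$params
    }
    if (plateau(history, patience, tol) || it > max_steps) break
    st <- adam_step(model$params, lg$grads, opt, lr = lr)
    model$params <- st$params
    opt <- st$state
  }
  model$params <- best_params
  list(model = model, history = history, best = best)
}

#' Per-sample adaptive refinement (two-step greedy optimization)
#'
#' Refines a trained model on one unlabeled bulk profile by alternating two
#' greedy steps until plateau:
#' * Step 1 — freeze encoder and head; optimize the decoder matrices against
#'   `mse(bulk, P_hat M_hat)` until the reconstruction MSE no longer
#'   decreases.
#' * Step 2 — freeze the decoder; optimize encoder, patch projections and
#'   head against `mse(P_hat, P_tilde) + mse(bulk, P_hat M_hat)` until the
#'   proportion term no longer decreases.
#'
#' The anchors `P_tilde` (proportions) and `M_tilde` (signatures) are the
#' supplied model's own outputs on this bulk sample at entry — the
#' post-initial-training solution — which regularizes adaptation toward the
#' supervised fit; pass `state` to override them. Each step keeps the best
#' parameters seen, so an accepted plateau is never worse than step entry;
#' if the final reconstruction MSE exceeds the entry value (or the loss
#' diverges above 10x entry), the pre-adaptation model is returned with a
#' warning.
#'
#' @param model a trained [deconv_model()] (or a `deconv_fit`).
#' @param bulk_sample length-`n_peaks` vector or `1 x n_peaks` matrix,
#'   min-max normalized on the model's peak space.
#' @param state optional `train_state` supplying anchor `P_tilde` for this
#'   sample (matrix `1 x k`) and `M_tilde`.
#' @param max_rounds maximum Step-1/Step-2 pairs (0 returns the input model's
#'   predictions unchanged).
#' @param lr Adam learning rate for adaptation.
#' @param patience,tol plateau parameters.
#' @param max_steps cap on iterations within each step.
#' @return list with `model` (adapted), `P_hat` (`1 x k`), `M_hat`
#'   (`k x n_peaks`), and `history` (outer objective per round, entry first).
#' @export
adapt <- function(model, bulk_sample, state = NULL, max_rounds = 3,
                  lr = 1e-4, patience = 5, tol = 1e-6, max_steps = 100) {
  if (inherits(model, "deconv_fit")) {
    if (is.null(state)) state <- model$state
    model <- model$model
  }
  x <- matrix(as.numeric(bulk_sample), nrow = 1)
  stopifnot(ncol(x) == model$config$n_peaks)
  entry_model <- model
  # anchors: the post-initial-training solution on this sample
  P_anchor <- fwd_full(model, x)$P_hat
  M_anchor <- decoder_fwd(model$params)$M_hat
  if (!is.null(state) && !is.null(state$P_tilde) &&
      nrow(state$P_tilde) == 1) {
    P_anchor <- state$P_tilde
  }
  if (!is.null(state) && !is.null(state$M_tilde)) M_anchor <- state$M_tilde
  outer_obj <- function(m) {
    lg <- loss_and_grad(m, x, P_true = P_anchor, M_true = NULL,
                        w_P = 1, w_M = 0, w_recon = 1, want_grads = FALSE)
    list(total = lg$loss, recon = unname(lg$parts["mse_recon"]),
         prop = unname(lg$parts["mse_P"]))
  }
  entry <- outer_obj(model)
  history <- entry$total
  recon_history <- entry$recon
  if (max_rounds > 0) {
    for (round in seq_len(max_rounds)) {
      # Step 1: decoder only, reconstruction loss
      step1 <- optimize_until_plateau(
        model,
        step_fn = function(m) {
          lg <- loss_and_grad(m, x, w_P = 0, w_M = 0, w_recon = 1,
                              trainable = "decoder")
          list(grads = lg$grads, track = lg$loss)
        },
        lr = lr, patience = patience, tol = tol, max_steps = max_steps)
      model <- step1$model
      # Step 2: encoder/head only; plateau on the proportion anchor term
      step2 <- optimize_until_plateau(
        model,
        step_fn = function(m) {
          lg <- loss_and_grad(m, x, P_true = P_anchor, M_true = NULL,
                              w_P = 1, w_M = 0, w_recon = 1,
                              trainable = "encoder")
          list(grads = lg$grads, track = unname(lg$parts["mse_P"]))
        },
        lr = lr, patience = patience, tol = tol, max_steps = max_steps)
      model <- step2$model
      cur <- outer_obj(model)
      history <- c(history, cur$total)
      recon_history <- c(recon_history, cur$recon)
      if (!is.finite(cur$total) || cur$total > 10 * max(entry$total, 1e-12)) {
        warning("adaptation diverged; reverting to the pre-adaptation model")
        model <- entry_model
        history <- history[1]
        break
      }
      if (plateau(history, patience = 1, tol = tol)) break
    }
    # never accept an adaptation that worsened the reconstruction
    if (outer_obj(model)$recon > entry$recon + 1e-12) {
      model <- entry_model
    }
  }
  fin <- fwd_full(model, x)
  P_hat <- fin$P_hat
  colnames(P_hat) <- model$celltypes
  M_hat <- fin$M_hat
  dimnames(M_hat) <- list(model$celltypes, model$layout$peak_ids)
  list(model = model, P_hat = P_hat, M_hat = M_hat, history = history)
}
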