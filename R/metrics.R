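#' Lin's concordance correlation coefficient
#'
#' `2 cov(X, Y) / (var(X) + var(Y) + (mean(X) - mean(Y))^2)` with population
#' (1/n) moments, following Lin's original definition. Measures agreement:
#' it penalizes both decorrelation and location/scale shift. Returns 0 when
#' the denominator is 0 (both vectors constant and equal means).
#'
#' @param X,Y numeric vectors of equal length >= 2.
#' @return a scalar in \[-1, 1\].
#' @examples
#' ccc(c(1, 2, 3), c(3, 2, 1))  # -1
#' @export
ccc <- function(X, Y) {
  if (length(X) != length(Y)) stop("length mismatch in ccc()", call. = FALSE)
  stopifnot(length(X) >= 2)
  n <- length(X)
  mx <- mean(X); my <- mean(Y)
  covp <- mean((X - mx) * (Y - my))
  vx <- mean((X - mx)^2)
  vy <- mean((Y - my)^2)
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(0)
  2 * covp / den
}

#' Mean absolute error
#'
#' `sum(|X - X_tilde|) / (n * k)` over all entries of two equally shaped
#' matrices (or vectors).
#'
#' @param X,X_tilde numeric matrices/vectors of identical shape.
#' @return a scalar >= 0.
#' @examples
#' mae(matrix(0.5), matrix(0.3))  # 0.2
#' @export
mae <- function(X, X_tilde) {
  if (!identical(dim(X), dim(X_tilde)) || length(X) != length(X_tilde)) {
    stop("shape mismatch in mae()", call. = FALSE)
  }
  mean(abs(X - X_tilde))
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of the rank transforms, with average ranks for ties.
#' A constant input vector has no defined rank correlation; 0 is returned
#' with a warning.
#'
#' @param y,y_hat numeric vectors of equal length >= 2.
#' @return a scalar in \[-1, 1\].
#' @examples
#' spearman(c(1, 2, 3), c(10, 20, 15))  # 0.5
#' @export
spearman <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("length mismatch in spearman()", call. = FALSE)
  }
  stopifnot(length(y) >= 2)
  ry <- rank(y, ties.method = "average")
  rh <- rank(y_hat, ties.method = "average")
  sy <- stats::sd(ry); sh <- stats::sd(rh)
  if (sy == 0 || sh == 0) {
    warning("constant vector: Spearman correlation undefined, returning 0")
    return(0)
  }
  as.numeric(stats::cov(ry, rh) / (sy * sh))
}

#' Evaluate predicted against true cell-type proportions
#'
#' Computes, from two `samples x k` proportion matrices:
#' * per-sample CCC and MAE over each k-vector;
#' * per-cell-type CCC and MAE over the sample axis (`NA` when only one
#'   sample is available — undefined, not zero);
#' * overall CCC, MAE and Spearman over all flattened entries, plus the mean
#'   per-sample Spearman.
#'
#' @param P_true,P_hat `samples x k` matrices on the simplex (same shape).
#' @return an object of class `metric_report`: list of tibbles `per_sample`,
#'   `per_celltype`, `overall`.
#' @export
evaluate <- function(P_true, P_hat) {
  P_true <- as.matrix(P_true); P_hat <- as.matrix(P_hat)
  if (!identical(dim(P_true), dim(P_hat))) {
    stop("shape mismatch in evaluate()", call. = FALSE)
  }
  n <- nrow(P_true); k <- ncol(P_true)
  samples <- rownames(P_true) %||% sprintf("sample_%04d", seq_len(n))
  celltypes <- colnames(P_true) %||% paste0("type", seq_len(k))
  per_sample <- tibble::tibble(
    sample = samples,
    ccc = vapply(seq_len(n), function(i) ccc(P_true[i, ], P_hat[i, ]), 0),
    mae = vapply(seq_len(n), function(i) mae(P_true[i, ], P_hat[i, ]), 0),
    spearman = vapply(seq_len(n), function(i)
      suppressWarnings(spearman(P_true[i, ], P_hat[i, ])), 0)
  )
  per_celltype <- tibble::tibble(
    celltype = celltypes,
    ccc = if (n >= 2) vapply(seq_len(k), function(j)
      ccc(P_true[, j], P_hat[, j]), 0) else rep(NA_real_, k),
    mae = if (n >= 2) vapply(seq_len(k), function(j)
      mae(P_true[, j], P_hat[, j]), 0) else rep(NA_real_, k)
  )
  overall <- tibble::tibble(
    ccc = ccc(as.vector(P_true), as.vector(P_hat)),
    mae = mae(P_true, P_hat),
    spearman = spearman(as.vector(P_true), as.vector(P_hat)),
    spearman_per_sample = mean(per_sample$spearman)
  )
  structure(list(per_sample = per_sample, per_celltype = per_celltype,
                 overall = overall),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<metric_report> overall: CCC %.3f, MAE %.4f, Spearman %.3f (%d samples, %d cell types)\n",
    o$ccc, o$mae, o$spearman, nrow(x$per_sample), nrow(x$per_celltype)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metric report into one long tibble
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return tibble with columns `level` (overall/sample/celltype), `unit`,
#'   `metric`, `value`.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::mutate(x$overall, level = "overall", unit = "all"),
      cols = c("ccc", "mae", "spearman", "spearman_per_sample"),
      names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(
      dplyr::mutate(dplyr::rename(x$per_sample, unit = "sample"),
                    level = "sample"),
      cols = c("ccc", "mae", "spearman"),
      names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(
      dplyr::mutate(dplyr::rename(x$per_celltype, unit = "celltype"),
                    level = "celltype"),
      cols = c("ccc", "mae"),
      names_to = "metric", values_to = "value")
  )[, c("level", "unit", "metric", "value")]
}

#' One-row summary of a metric report
#' @param x a `metric_report`.
#' @param ... unused.
#' @return one-row tibble with the overall metrics.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) x$overall

#' Tidy a fitted deconvolution model (per-epoch loss history)
#' @param x a `deconv_fit` from [train_initial()].
#' @param ... unused.
#' @return the per-epoch loss history tibble.
#' @method tidy deconv_fit
#' @export
tidy.deconv_fit <- function(x, ...) x$state$loss_history

#' One-row summary of a fitted deconvolution model
#' @param x a `deconv_fit`.
#' @param ... unused.
#' @return one-row tibble: epochs, final loss and its components.
#' @method glance deconv_fit
#' @export
glance.deconv_fit <- function(x, ...) {
  h <- x$state$loss_history
  if (nrow(h) == 0) {
    return(tibble::tibble(epochs = 0L, loss = NA_real_, mse_P = NA_real_,
                          mse_M = NA_real_, mse_recon = NA_real_))
  }
  tibble::tibble(epochs = nrow(h), loss = h$loss[nrow(h)],
                 mse_P = h$mse_P[nrow(h)], mse_M = h$mse_M[nrow(h)],
                 mse_recon = h$mse_recon[nrow(h)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
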