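#' Build and validate a run configuration
#'
#' A flat key-value document holding every tunable of the end-to-end
#' pipeline. Unknown keys are rejected outright so typos never silently fall
#' back to defaults.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_celltypes = 5L, n_peaks = 600L, cells_per_type = 100L, n_chroms = 3L,
    marker_fraction = 0.2, marker_fold = 10, base_rate = 0.1,
    regimes = c("random", "rare", "dominant", "average"),
    n_samples_per_regime = 1000L, n_heldout = 50L, alpha = 1,
    n_cells_per_sample = 500L,
    patch_size = 50L, d = 64L, L = 2L, h = 4L,
    decoder_dims = c(64L, 128L, 256L, 512L),
    epochs = 22L, lr = 1e-3, batch_size = 32L, w_M = 5, w_recon = 1,
    adaptive = TRUE, adapt_lr = 1e-4, adapt_max_rounds = 2L,
    patience = 5L, tol = 1e-6,
    top_fraction = 0.05, n_permutations = 1000L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Read a flat key=value config file
#'
#' Lines of the form `key = value` (comments with `#`); comma-separated
#' values become vectors.
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- lapply(kv, function(x) {
    v <- trimws(strsplit(paste(x[-1], collapse = "="), ",")[[1]])
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- keys
  do.call(run_config, vals)
}

#' Run the full deconvolution workflow
#'
#' Executes every stage in order — synthetic reference, pseudo-bulk
#' simulation under the four proportion regimes, supervised training,
#' (optionally adaptive) prediction on held-out samples, evaluation, and
#' attention extraction — writing each artifact plus a checksum manifest
#' under `out_dir`. One global seed fans out to per-stage derived seeds.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param verbose log stage progress to stderr.
#' @return (invisibly) a list with the in-memory results: `atlas`, `fit`,
#'   `heldout`, `P_hat`, `report`, `attention`, `manifest`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = tempdir(),
                           verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  artifacts <- character()
  put <- function(path) artifacts <<- c(artifacts, path)

  say("stage 1/6: synthetic reference")
  atlas <- generate_reference(
    n_celltypes = config$n_celltypes, n_peaks = config$n_peaks,
    cells_per_type = config$cells_per_type, n_chroms = config$n_chroms,
    marker_fraction = config$marker_fraction,
    marker_fold = config$marker_fold, base_rate = config$base_rate,
    seed = derive_seed(config$seed, 1))
  write_reference(atlas, file.path(out_dir, "reference"))
  put(file.path(out_dir, "reference", "counts.mtx"))

  say("stage 2/6: pseudo-bulk simulation")
  k <- length(atlas$celltypes)
  P_list <- lapply(seq_along(config$regimes), function(i) {
    attr(simulate_proportions(k, config$n_samples_per_regime,
                              regime = config$regimes[i],
                              alpha = config$alpha,
                              seed = derive_seed(config$seed, 10 + i)), "P")
  })
  P_train <- do.call(rbind, P_list)
  train_batch <- make_pseudobulk(atlas, P_train,
                                 n_cells_per_sample = config$n_cells_per_sample,
                                 seed = derive_seed(config$seed, 2))
  P_test <- attr(simulate_proportions(k, config$n_heldout, regime = "random",
                                      alpha = config$alpha,
                                      seed = derive_seed(config$seed, 3)),
                 "P")
  heldout <- make_pseudobulk(atlas, P_test,
                             n_cells_per_sample = config$n_cells_per_sample,
                             seed = derive_seed(config$seed, 4))
  write_matrix(train_batch$P_true, file.path(out_dir, "P_train_true.csv"))
  put(file.path(out_dir, "P_train_true.csv"))

  say("stage 3/6: training (", nrow(train_batch$bulk), " pseudo-bulks, ",
      config$epochs, " epochs)")
  layout <- build_patches(atlas$peaks, config$patch_size)
  cfg <- deconv_config(k = k, n_peaks = config$n_peaks, d = config$d,
                     L = config$L, h = config$h,
                     patch_size = config$patch_size,
                     decoder_dims = config$decoder_dims,
                     seed = derive_seed(config$seed, 5))
  model <- deconv_model(layout, atlas$celltypes, cfg)
  fit <- train_initial(model, train_batch, epochs = config$epochs,
                       lr = config$lr, batch_size = config$batch_size,
                       seed = derive_seed(config$seed, 6),
                       w_M = config$w_M, w_recon = config$w_recon)
  utils::write.csv(fit$state$loss_history,
                   file.path(out_dir, "loss_history.csv"), row.names = FALSE)
  put(file.path(out_dir, "loss_history.csv"))

  say("stage 4/6: prediction on ", nrow(heldout$bulk), " held-out samples",
      if (config$adaptive) " (adaptive)")
  if (config$adaptive) {
    P_hat <- matrix(0, nrow(heldout$bulk), k)
    for (i in seq_len(nrow(heldout$bulk))) {
      P_hat[i, ] <- adapt(fit$model, heldout$bulk[i, ],
                          max_rounds = config$adapt_max_rounds,
                          lr = config$adapt_lr, patience = config$patience,
                          tol = config$tol)$P_hat
    }
  } else {
    P_hat <- predict_P(fit$model, heldout$bulk)
  }
  dimnames(P_hat) <- dimnames(heldout$P_true)
  write_matrix(P_hat, file.path(out_dir, "proportions.csv"))
  put(file.path(out_dir, "proportions.csv"))
  M_hat <- decode_signature(fit$model)
  write_matrix(M_hat, file.path(out_dir, "signatures.tsv"))
  put(file.path(out_dir, "signatures.tsv"))

  say("stage 5/6: evaluation")
  report <- evaluate(heldout$P_true, P_hat)
  utils::write.csv(tidy(report), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  put(file.path(out_dir, "report.csv"))

  say("stage 6/6: attention extraction")
  probe <- colMeans(train_batch$bulk)
  amap <- extract_attention(fit$model, probe)
  utils::write.table(tidy.attention_map(amap),
                     file.path(out_dir, "attention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  put(file.path(out_dir, "attention.tsv"))

  manifest <- tibble::tibble(path = artifacts,
                             md5 = unname(tools::md5sum(artifacts)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  say("done: overall Spearman ",
      sprintf("%.3f", report$overall$spearman), ", MAE ",
      sprintf("%.4f", report$overall$mae))
  invisible(list(atlas = atlas, fit = fit, heldout = heldout, P_hat = P_hat,
                 report = report, attention = amap, manifest = manifest))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the parameters with the
#' configuration and patch layout embedded, so prediction needs no other
#' inputs beyond a bulk matrix on the same peak space.
#'
#' @param model a [deconv_model()] or `deconv_fit`.
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly (`save_model`); the restored object
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("deconv_model", "deconv_fit")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, c("deconv_model", "deconv_fit")))
  obj
}
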