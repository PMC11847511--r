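# shared in-code fixtures for the unit tests

# a small peak set spread over two chromosomes
tiny_peaks <- function(n1 = 8, n2 = 4, width = 500, gap = 1000) {
  starts <- c((seq_len(n1) - 1) * gap, (seq_len(n2) - 1) * gap)
  peak_set(rep(c("chr1", "chr2"), c(n1, n2)), starts, starts + width)
}

# a tiny but structurally complete model (j = 3 patches, d = 8, L = 1, h = 2)
tiny_model <- function(L = 1, seed = 7) {
  layout <- build_patches(tiny_peaks(), 4)
  cfg <- deconv_config(k = 3, n_peaks = 12, d = 8, L = L, h = 2,
                     patch_size = 4, decoder_dims = c(4, 5, 6, 7),
                     mlp_hidden = 16, seed = seed)
  deconv_model(layout, paste0("t", 1:3), cfg)
}

tiny_batch <- function(n = 4, seed = 5) {
  set.seed(seed)
  x <- minmax_normalize(matrix(runif(n * 12), n, 12))
  P <- matrix(rgamma(n * 3, 1), n, 3)
  P <- P / rowSums(P)
  M <- matrix(runif(3 * 12), 3, 12)
  list(x = x, P = P, M = M)
}

# a small trained reference/model pair reused across training-related tests
small_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    atlas <- generate_reference(n_celltypes = 3, n_peaks = 120,
                                cells_per_type = 40, n_chroms = 2,
                                marker_fraction = 0.3, marker_fold = 10,
                                base_rate = 0.2, seed = 101)
    P <- attr(simulate_proportions(3, 150, "random", seed = 102), "P")
    batch <- make_pseudobulk(atlas, P, n_cells_per_sample = 200, seed = 103)
    layout <- build_patches(atlas$peaks, 20)
    model <- deconv_model(layout, atlas$celltypes,
                        deconv_config(k = 3, n_peaks = 120, d = 16, L = 1,
                                    h = 2, patch_size = 20,
                                    decoder_dims = c(8, 12, 16, 24),
                                    mlp_hidden = 32, seed = 104))
    fit <- train_initial(model, batch, epochs = 8, seed = 105)
    cache <<- list(atlas = atlas, batch = batch, layout = layout, fit = fit)
    cache
  }
})
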