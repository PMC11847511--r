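test_that("attention maps are symmetric per chromosome with aligned patches", {
  ex <- small_experiment()
  probe <- colMeans(ex$batch$bulk)
  amap <- extract_attention(ex$fit, probe)
  expect_named(amap$per_chrom, c("chr1", "chr2"))
  for (ch in names(amap$per_chrom)) {
    W <- amap$per_chrom[[ch]]$W
    expect_lt(max(abs(W - t(W))), 1e-9)
    expect_true(all(is.finite(W)))
    expect_equal(amap$per_chrom[[ch]]$patch_ids,
                 ex$layout$patches$patch[ex$layout$patches$chrom == ch])
  }
  # head-averaged pre-symmetrization rows (with the class column) sum to 1
  fw <- atacdeconv:::fwd_full(ex$fit$model,
                              matrix(probe, 1), want_attention = TRUE)
  Ahm <- Reduce(`+`, fw$attention[[1]][[1]]) / length(fw$attention[[1]][[1]])
  expect_equal(unname(rowSums(Ahm)), rep(1, nrow(Ahm)), tolerance = 1e-6)
})

test_that("a single-patch chromosome yields a 1x1 attention map", {
  pk <- peak_set(rep(c("chr1", "chr2"), c(8, 4)),
                 c((0:7) * 1000, (0:3) * 1000),
                 c((0:7) * 1000 + 500, (0:3) * 1000 + 500))
  layout <- build_patches(pk, 4)
  m <- deconv_model(layout, paste0("t", 1:3),
                  deconv_config(k = 3, n_peaks = 12, d = 8, L = 1, h = 2,
                              patch_size = 4, decoder_dims = c(4, 5, 6, 7),
                              mlp_hidden = 16, seed = 1))
  amap <- extract_attention(m, runif(12))
  expect_equal(dim(amap$per_chrom$chr2$W), c(1L, 1L))
})

test_that("attention cannot be extracted from a depth-0 encoder", {
  m <- tiny_model(L = 0)
  expect_error(extract_attention(m, runif(12)), "depth-0")
})

test_that("tertile categorization is balanced, tie-aware and rank-based", {
  # craft a map with 9 distinct off-diagonal values
  W <- matrix(0, 4, 4)
  vals <- c(5, 9, 1, 3, 7, 2)  # 6 upper-tri cells for p = 4
  W[upper.tri(W)] <- vals
  W <- W + t(W)
  amap <- structure(list(per_chrom = list(chr1 = list(patch_ids = 1:4,
                                                      W = W)),
                         layer = 1, aggregation = "mean_heads_last_layer"),
                    class = "attention_map")
  cats <- categorize_attention(amap)$chr1
  expect_equal(sum(cats == "Low", na.rm = TRUE), 4)     # symmetric pairs
  expect_equal(sum(cats == "Median", na.rm = TRUE), 4)
  expect_equal(sum(cats == "High", na.rm = TRUE), 4)
  expect_true(all(is.na(diag(cats))))

  # monotone relabeling leaves categories unchanged
  W2 <- W; W2[upper.tri(W2)] <- exp(vals / 3); W2 <- W2 + t(W2) - diag(diag(W2))
  amap2 <- amap; amap2$per_chrom$chr1$W <- W2
  expect_equal(categorize_attention(amap2)$chr1, cats)

  # all-equal weights: everything Median with a warning
  amap3 <- amap; amap3$per_chrom$chr1$W <- matrix(1, 4, 4)
  expect_warning(c3 <- categorize_attention(amap3), "fewer than 3 distinct")
  expect_true(all(c3$chr1[!is.na(c3$chr1)] == "Median"))
})

test_that("contacts accumulate into symmetric patch-pair matrices", {
  pk <- tiny_peaks()  # chr1: 8 peaks (2 patches of 4), chr2: 4 peaks
  layout <- build_patches(pk, 4)
  # midpoints of chr1 peak 1 (patch 1) and peak 6 (patch 2)
  ctc <- contact_list(chrom = c("chr1", "chr1", "chr3"),
                      start1 = c(250, 250, 100),
                      start2 = c(5250, 5250, 500),
                      strength = c(2, 3, 9))
  expect_message(mats <- contacts_to_patch_pairs(ctc, layout, pk), "dropped")
  expect_equal(mats$chr1[1, 2], 5)  # 2 + 3 summed
  expect_equal(mats$chr1[2, 1], 5)
  expect_equal(attr(mats, "n_dropped"), 1L)
  expect_true(all(mats$chr2 == 0))
})

test_that("planted overlap attains the minimal permutation p-value", {
  p <- 12
  set.seed(5)
  W <- matrix(0, p, p)
  W[upper.tri(W)] <- runif(p * (p - 1) / 2, 0, 0.1)
  # plant the same three pairs as both attention and contact top sets, and
  # make all other circular shifts produce strictly smaller overlaps
  top <- rbind(c(1, 2), c(3, 7), c(5, 6))
  for (r in 1:3) W[top[r, 1], top[r, 2]] <- 1 + r
  W <- W + t(W)
  C <- matrix(0, p, p)
  for (r in 1:3) C[top[r, 1], top[r, 2]] <- 10 + r
  C <- C + t(C)
  amap <- structure(list(per_chrom = list(chr1 = list(patch_ids = 1:p,
                                                      W = W)),
                         layer = 1, aggregation = "mean_heads_last_layer"),
                    class = "attention_map")
  res <- overlap_permutation_test(amap, list(chr1 = C), top_fraction = 0.05,
                                  n_permutations = 200, seed = 1)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$p_value, 1 / 201)

  # the null preserves the number of selected contact pairs: overlap can
  # never exceed the selection size
  expect_true(all(attr(res, "null") <= res$n_contact_selected))
})

test_that("overlap statistic is invariant to monotone transforms", {
  p <- 10
  set.seed(6)
  W <- matrix(0, p, p); W[upper.tri(W)] <- runif(45); W <- W + t(W)
  C <- matrix(0, p, p); C[upper.tri(C)] <- runif(45); C <- C + t(C)
  amap <- structure(list(per_chrom = list(chr1 = list(patch_ids = 1:p,
                                                      W = W)),
                         layer = 1, aggregation = "mean_heads_last_layer"),
                    class = "attention_map")
  r1 <- overlap_permutation_test(amap, list(chr1 = C), 0.1, 50, seed = 2)
  amap2 <- amap
  amap2$per_chrom$chr1$W <- W^3
  r2 <- overlap_permutation_test(amap2, list(chr1 = exp(C)), 0.1, 50,
                                 seed = 2)
  expect_equal(r1$n_overlap, r2$n_overlap)
  expect_identical(attr(r1, "null"), attr(r2, "null"))
})

test_that("degenerate permutation-test inputs error out", {
  p <- 6
  W <- matrix(runif(36), p, p); W <- W + t(W)
  amap <- structure(list(per_chrom = list(chr1 = list(patch_ids = 1:p,
                                                      W = W)),
                         layer = 1, aggregation = "mean_heads_last_layer"),
                    class = "attention_map")
  C <- W
  expect_error(overlap_permutation_test(amap, list(chr1 = C), 0.05, 100),
               "selects 0 pairs")  # 15 pairs * 0.05 < 1
  expect_error(overlap_permutation_test(amap, list(chr1 = C), 0.2, 0),
               "n_permutations")
})
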