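test_that("k = 1 always yields the single-vertex simplex", {
  for (rg in c("random", "rare", "dominant", "average")) {
    P <- attr(simulate_proportions(1, 5, rg, seed = 1), "P")
    expect_equal(unname(P[, 1]), rep(1, 5))
  }
})

test_that("dominant draws have exactly one type above 50%", {
  P <- attr(simulate_proportions(3, 200, "dominant", seed = 2), "P")
  expect_true(all(rowSums(P > 0.5) == 1))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("symmetric Dirichlet(1) is uniform on the simplex (mean 1/k)", {
  P <- attr(simulate_proportions(2, 10000, "random", alpha = 1, seed = 3),
            "P")
  expect_lt(abs(mean(P[, 1]) - 0.5), 0.01)
})

test_that("regime invariants hold across many draws", {
  n <- 2000
  for (k in c(2, 5)) {
    dom <- attr(simulate_proportions(k, n, "dominant", seed = 11), "P")
    rare <- attr(simulate_proportions(k, n, "rare", seed = 12), "P")
    avg <- attr(simulate_proportions(k, n, "average", seed = 13), "P")
    rnd <- attr(simulate_proportions(k, n, "random", seed = 14), "P")
    expect_true(all(apply(dom, 1, max) > 0.5))
    expect_true(all(apply(rare, 1, min) < 0.05))
    expect_true(all(apply(avg, 1, max) - apply(avg, 1, min) < 0.05))
    for (P in list(dom, rare, avg, rnd)) {
      expect_true(all(P >= 0))
      expect_true(all(abs(rowSums(P) - 1) < 1e-9))
    }
  }
})

test_that("largest-remainder rounding preserves totals and breaks ties by order", {
  expect_equal(largest_remainder(c(0.5, 0.5), 3), c(2L, 1L))
  expect_equal(largest_remainder(c(1, 0), 10), c(10L, 0L))
  set.seed(4)
  for (i in 1:50) {
    p <- rgamma(4, 1); p <- p / sum(p)
    n <- sample(1:500, 1)
    cnt <- largest_remainder(p, n)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - p * n) < 1))
  }
})

test_that("single-type mixtures reproduce sums of own-type cells", {
  atlas <- generate_reference(n_celltypes = 2, n_peaks = 40,
                              cells_per_type = 6, seed = 21)
  batch <- make_pseudobulk(atlas, matrix(c(1, 0), 1), 10, seed = 22)
  expect_equal(unname(batch$P_true[1, ]), c(1, 0))
  expect_true(all(batch$bulk >= 0 & batch$bulk <= 1))
  # realized proportions are exact rationals over n_cells
  batch2 <- make_pseudobulk(atlas, matrix(c(0.5, 0.5), 1), 3, seed = 23)
  expect_equal(unname(batch2$P_true[1, ]), c(2 / 3, 1 / 3))
})

test_that("pseudo-bulk generation is seed-deterministic", {
  atlas <- generate_reference(n_celltypes = 2, n_peaks = 40,
                              cells_per_type = 6, seed = 21)
  P <- attr(simulate_proportions(2, 5, "random", seed = 24), "P")
  b1 <- make_pseudobulk(atlas, P, 50, seed = 25)
  b2 <- make_pseudobulk(atlas, P, 50, seed = 25)
  expect_identical(b1$bulk, b2$bulk)
  expect_identical(b1$P_true, b2$P_true)
})

test_that("unnormalized pseudo-bulk expectation is linear in proportions", {
  atlas <- generate_reference(n_celltypes = 2, n_peaks = 60,
                              cells_per_type = 200, marker_fold = 8,
                              base_rate = 0.5, seed = 26)
  counts <- as.matrix(atlas$counts)
  mean_profiles <- rowsum(counts, atlas$labels) /
    as.vector(table(atlas$labels))
  p <- c(0.3, 0.7)
  n_cells <- 2000
  # many replicate samples at the same p; average their unnormalized sums
  cells_by_type <- split(seq_len(nrow(counts)), atlas$labels)
  set.seed(27)
  reps <- replicate(30, {
    n_t <- largest_remainder(p, n_cells)
    idx <- c(sample(cells_by_type[[1]], n_t[1], replace = TRUE),
             sample(cells_by_type[[2]], n_t[2], replace = TRUE))
    colSums(counts[idx, ])
  })
  expected <- n_cells * (p[1] * mean_profiles[1, ] + p[2] * mean_profiles[2, ])
  expect_lt(max(abs(rowMeans(reps) - expected) / expected), 0.05)
})

test_that("a proportion on a type with no reference cells errors", {
  atlas <- generate_reference(n_celltypes = 2, n_peaks = 40,
                              cells_per_type = 6, seed = 21)
  atlas$labels[atlas$labels == "type2"] <- "type1"
  expect_error(make_pseudobulk(atlas, matrix(c(0.5, 0.5), 1), 10, seed = 1),
               "type2")
})
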