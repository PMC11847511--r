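test_that("patch embedding produces (1 + j) x d tokens, class token first", {
  m <- tiny_model()
  x <- runif(12)
  X0 <- embed_patches(x, m$layout, m)
  expect_equal(dim(X0), c(4L, 8L))  # 3 patches + cls, d = 8
  expect_equal(unname(X0[1, ]), m$params$cls)
})

test_that("identical patch vectors embed identically only at the same index", {
  m <- tiny_model()
  x <- rep(runif(4), 3)  # all three patches carry the same values
  X0 <- embed_patches(x, m$layout, m)
  x2 <- x; x2[5:8] <- x[1:4]
  expect_equal(embed_patches(x2, m$layout, m)[2, ], X0[2, ])
  # distinct per-patch projections: same input, different patch -> different
  expect_false(isTRUE(all.equal(unname(X0[2, ]), unname(X0[3, ]))))
})

test_that("self-attention is row-stochastic and exact on hand cases", {
  set.seed(1)
  X <- matrix(rnorm(5 * 8), 5, 8)
  W <- matrix(rnorm(8 * 4, sd = 0.5), 8, 4)
  sa <- self_attention(X, W, W, W)
  expect_equal(unname(rowSums(sa$attention)), rep(1, 5), tolerance = 1e-6)

  # single token: weight 1, output equals v
  sa1 <- self_attention(X[1, , drop = FALSE], W, W, W)
  expect_equal(sa1$attention[1, 1], 1)
  expect_equal(sa1$out, X[1, , drop = FALSE] %*% W)

  # 2-token closed form including the sqrt(d/h) temperature
  Xs <- matrix(c(1, 0, 0, 1), 2, 2)
  I2 <- diag(2)
  sa2 <- self_attention(Xs, I2, I2, I2)
  z <- 1 / sqrt(2)  # q k^T entries are 1 or 0, scaled by 1/sqrt(d_head)
  expA <- exp(c(z, 0)) / sum(exp(c(z, 0)))
  expect_equal(unname(sa2$attention[1, ]), expA, tolerance = 1e-12)
})

test_that("msa with one head reduces to projected self-attention", {
  set.seed(2)
  X <- matrix(rnorm(4 * 8), 4, 8)
  lp <- list(Wq = matrix(rnorm(64, sd = .3), 8, 8),
             Wk = matrix(rnorm(64, sd = .3), 8, 8),
             Wv = matrix(rnorm(64, sd = .3), 8, 8),
             Wo = matrix(rnorm(64, sd = .3), 8, 8), bo = rnorm(8))
  out1 <- msa(X, lp, h = 1)
  sa <- self_attention(X, lp$Wq, lp$Wk, lp$Wv)
  expect_equal(out1$out, sweep(sa$out %*% lp$Wo, 2, lp$bo, `+`))
  out4 <- msa(X, lp, h = 4)
  expect_equal(dim(out4$out), dim(X))
})

test_that("msa is permutation-equivariant over tokens", {
  set.seed(3)
  X <- matrix(rnorm(6 * 8), 6, 8)
  lp <- list(Wq = matrix(rnorm(64, sd = .3), 8, 8),
             Wk = matrix(rnorm(64, sd = .3), 8, 8),
             Wv = matrix(rnorm(64, sd = .3), 8, 8),
             Wo = matrix(rnorm(64, sd = .3), 8, 8), bo = rnorm(8))
  perm <- sample(6)
  expect_equal(msa(X[perm, ], lp, h = 2)$out, msa(X, lp, h = 2)$out[perm, ])
})

test_that("encoder is the identity at depth 0 and with zero weights", {
  m0 <- tiny_model(L = 0)
  X0 <- matrix(rnorm(4 * 8), 4, 8)
  expect_equal(encoder_forward(X0, m0), X0)

  m1 <- tiny_model(L = 1)
  for (nm in grep("^enc1\\.(W|b)", names(m1$params), value = TRUE)) {
    m1$params[[nm]][] <- 0
  }
  expect_equal(encoder_forward(X0, m1), X0)
})

test_that("encoder outputs and attention stay finite and row-stochastic", {
  m <- tiny_model(L = 2)
  for (seed in 1:20) {
    set.seed(seed)
    X0 <- matrix(rnorm(4 * 8, sd = 2), 4, 8)
    ef <- encoder_forward(X0, m, return_attention = TRUE)
    expect_true(all(is.finite(ef$X)))
    for (l in 1:2) {
      for (hh in 1:2) {
        expect_equal(unname(rowSums(ef$attention[[l]][hh, , ])), rep(1, 4),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("proportion head renormalizes sigmoid outputs onto the simplex", {
  m <- tiny_model()
  # zero head weights -> logits 0 -> raw 0.5 each -> uniform proportions
  mz <- m
  for (nm in c("head.W1", "head.b1", "head.W2", "head.b2")) {
    mz$params[[nm]][] <- 0
  }
  ph <- proportion_head(matrix(rnorm(4 * 8), 4, 8), mz)
  expect_equal(unname(ph$raw[1, ]), rep(0.5, 3))
  expect_equal(unname(ph$P_hat[1, ]), rep(1 / 3, 3))

  ph2 <- proportion_head(matrix(rnorm(4 * 8, sd = 5), 4, 8), m)
  expect_true(all(ph2$raw > 0 & ph2$raw < 1))
  expect_equal(unname(rowSums(ph2$P_hat)), 1, tolerance = 1e-6)
})

test_that("k = 1 head always returns proportion 1", {
  layout <- build_patches(tiny_peaks(), 4)
  m <- deconv_model(layout, "only",
                  deconv_config(k = 1, n_peaks = 12, d = 8, L = 0, h = 2,
                              patch_size = 4, decoder_dims = c(4, 5, 6, 7),
                              seed = 1))
  ph <- proportion_head(matrix(rnorm(8), 1, 8), m)
  expect_equal(unname(ph$P_hat[1, 1]), 1)
})

test_that("decoded signatures are non-negative with bounded rank", {
  m <- tiny_model()
  M <- decode_signature(m)
  expect_true(all(M >= 0))
  expect_equal(dim(M), c(3L, 12L))
  # rank of the pre-ReLU product is bounded by the smallest factor dimension
  pre <- with(m$params,
              dec.W1 %*% dec.W2 %*% dec.W3 %*% dec.W4 %*% dec.W5)
  expect_lte(qr(pre)$rank, min(3, 4, 5, 6, 7))
  # ReLU is the identity when the product is non-negative
  m2 <- m
  for (w in 1:5) m2$params[[paste0("dec.W", w)]] <- abs(m2$params[[paste0("dec.W", w)]])
  pre2 <- with(m2$params,
               dec.W1 %*% dec.W2 %*% dec.W3 %*% dec.W4 %*% dec.W5)
  expect_equal(unname(decode_signature(m2)), unname(pre2))
})

test_that("bulk reconstruction is the convex mixing identity", {
  M <- rbind(a = c(1, 0, 2), b = c(0, 1, 4))
  expect_equal(unname(reconstruct_bulk(matrix(c(1, 0), 1), M)[1, ]),
               c(1, 0, 2))
  expect_equal(unname(reconstruct_bulk(matrix(c(0.5, 0.5), 1), M)[1, ]),
               c(0.5, 0.5, 3))
  expect_true(all(reconstruct_bulk(matrix(c(0.3, 0.7), 1), M) >= 0))
})

test_that("the full forward pass is deterministic given the seed", {
  m1 <- tiny_model(seed = 5)
  m2 <- tiny_model(seed = 5)
  x <- matrix(runif(2 * 12), 2, 12)
  f1 <- atacdeconv:::fwd_full(m1, x)
  f2 <- atacdeconv:::fwd_full(m2, x)
  expect_identical(f1$P_hat, f2$P_hat)
  expect_identical(f1$M_hat, f2$M_hat)
})

test_that("backpropagated gradients match central finite differences", {
  m <- tiny_model(L = 1, seed = 7)
  b <- tiny_batch()
  lg <- atacdeconv:::loss_and_grad(m, b$x, b$P, b$M)
  f <- function(model) atacdeconv:::loss_only(model, b$x, b$P, b$M)
  hstep <- 1e-4
  set.seed(9)
  worst <- 0
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (ii in sample(length(p), min(3, length(p)))) {
      mp <- m; mp$params[[nm]][ii] <- p[ii] + hstep
      mm <- m; mm$params[[nm]][ii] <- p[ii] - hstep
      fd <- (f(mp) - f(mm)) / (2 * hstep)
      an <- lg$grads[[nm]][ii]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-5))
    }
  }
  expect_lt(worst, 1e-4)
})
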