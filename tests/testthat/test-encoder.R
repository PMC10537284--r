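test_that("linear projection applies each weight matrix to the tokens", {
  X <- matrix(rnorm(8), 4, 2)
  idp <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2),
              Wqg = diag(2), Wkg = diag(2), Wvg = diag(2))
  pr <- linear_projection(X, idp)
  for (m in pr) expect_equal(m, X)

  idp$Wq <- 2 * diag(2)
  expect_equal(linear_projection(matrix(c(1, 1), 1, 2), idp)$Q,
               matrix(c(2, 2), 1, 2))

  set.seed(14)
  p <- list(Wq = matrix(rnorm(4), 2, 2), Wk = matrix(rnorm(4), 2, 2),
            Wv = matrix(rnorm(4), 2, 2), Wqg = matrix(rnorm(4), 2, 2),
            Wkg = matrix(rnorm(4), 2, 2), Wvg = matrix(rnorm(4), 2, 2))
  X <- matrix(rnorm(6), 3, 2)
  pr <- linear_projection(X, p)
  expect_equal(pr$Q, X %*% t(p$Wq))
  expect_equal(pr$Vg, X %*% t(p$Wvg))
  expect_error(linear_projection(matrix(0, 2, 3), p), class = "nutrinet_dimension_error")
})

test_that("focused attention reproduces closed-form cases", {
  # a single token attends only to itself
  Q <- matrix(rnorm(3), 1, 3); K <- matrix(rnorm(3), 1, 3); V <- matrix(rnorm(3), 1, 3)
  expect_equal(focused_attention(Q, K, V, dk = 3), V)

  # 2x2 identity case: off/on logits 0 and 1/sqrt(2)
  I2 <- diag(2)
  out <- focused_attention(I2, I2, I2, dk = 2)
  p <- exp(1 / sqrt(2)) / (1 + exp(1 / sqrt(2)))
  expect_equal(out, matrix(c(p, 1 - p, 1 - p, p), 2, 2), tolerance = 1e-12)
  expect_equal(out[1, ], c(0.6698, 0.3302), tolerance = 1e-4)

  # identical keys -> uniform attention -> every row is the column mean of V
  K_same <- matrix(1, 4, 2)
  V4 <- matrix(rnorm(8), 4, 2)
  out <- focused_attention(matrix(rnorm(8), 4, 2), K_same, V4, dk = 2)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V4), tolerance = 1e-12)

  # independent attention is the same functional form
  expect_equal(independent_attention(I2, I2, I2, 2),
               focused_attention(I2, I2, I2, 2))
})

test_that("attention weights are row-stochastic and permutation equivariant", {
  set.seed(15)
  for (i in 1:50) {
    T_ <- sample(2:10, 1); d <- sample(2:6, 1)
    X <- matrix(rnorm(T_ * d), T_, d)
    # with V = identity, the output *is* the attention weight matrix
    A <- focused_attention(X, matrix(rnorm(T_ * d), T_, d), diag(T_), d)
    expect_equal(rowSums(A), rep(1, T_), tolerance = 1e-6)
    expect_true(all(A >= 0 & A <= 1))
  }
  # permuting the tokens permutes the output rows identically
  X <- matrix(rnorm(12), 4, 3)
  perm <- c(3, 1, 4, 2)
  out <- focused_attention(X, X, X, 3)
  out_p <- focused_attention(X[perm, ], X[perm, ], X[perm, ], 3)
  expect_equal(out_p, out[perm, ], tolerance = 1e-12)
})

test_that("MHSA fusion is the weighted linear combination it claims", {
  C <- matrix(c(2), 1, 1); I <- matrix(c(4), 1, 1)
  expect_equal(mhsa_fuse(C, I, list(Wo = diag(1), alpha = 1, beta = 0)), C)
  expect_equal(mhsa_fuse(C, I, list(Wo = diag(1), alpha = 0.5, beta = 0.5)),
               matrix(3, 1, 1))
  set.seed(16)
  C <- matrix(rnorm(6), 2, 3); I <- matrix(rnorm(6), 2, 3)
  p <- list(Wo = matrix(rnorm(9), 3, 3), alpha = 0.7, beta = 0.2)
  expect_equal(mhsa_fuse(3 * C, 3 * I, p), 3 * mhsa_fuse(C, I, p), tolerance = 1e-12)
  expect_error(mhsa_fuse(C, matrix(0, 3, 2), p), class = "nutrinet_dimension_error")
})

test_that("ASPP preserves spatial dims and matches a direct convolution", {
  d <- 3L; ca <- 2L
  t <- array(rnorm(5 * 5 * d), c(5, 5, d))
  zero_w <- list(br0_W = matrix(0, ca, d), br0_b = numeric(ca),
                 rates = list(list(W = matrix(0, 9 * d, ca), b = numeric(ca))),
                 fuse_W = matrix(0, d, 2 * ca), fuse_b = numeric(d))
  expect_true(all(aspp(t, 1L, zero_w) == 0))

  # one rate-1 branch routed through an identity fuse = a plain 3x3 conv
  set.seed(17)
  conv_W <- matrix(rnorm(9 * d * ca), 9 * d, ca)
  w <- list(br0_W = matrix(0, ca, d), br0_b = numeric(ca),
            rates = list(list(W = conv_W, b = numeric(ca))),
            fuse_W = cbind(matrix(0, ca, ca), diag(ca)), fuse_b = numeric(ca))
  out <- aspp(t, 1L, w)
  direct <- nutrinet:::conv2d_forward(nutrinet:::tensor_to_tokens(t), 5L, 5L,
                                      conv_W, numeric(ca), 3L)$Y
  expect_equal(out, nutrinet:::tokens_to_tensor(direct, 5L, 5L), tolerance = 1e-12)

  # arbitrary rate sets keep the spatial dims
  cfgw <- list(br0_W = matrix(rnorm(ca * d), ca, d), br0_b = rnorm(ca),
               rates = list(list(W = matrix(rnorm(9 * d * ca), 9 * d, ca), b = rnorm(ca)),
                            list(W = matrix(rnorm(9 * d * ca), 9 * d, ca), b = rnorm(ca))),
               fuse_W = matrix(rnorm(d * 3 * ca), d, 3 * ca), fuse_b = rnorm(d))
  expect_equal(dim(aspp(t, c(2L, 6L), cfgw)), dim(t))
})

test_that("the encoder collapses to identity when every stage is neutral", {
  d <- 3L
  cfg <- encoder_config(layers = 0L, width = d, n_heads = 1L,
                        aspp_rates = 1L, aspp_channels = d)
  W <- nutrinet:::with_seed(18, nutrinet:::encoder_init(cfg))
  # ASPP: 1x1 branch identity, conv branch zero, fuse selects the 1x1 branch
  W$aspp$br0_W <- diag(d); W$aspp$br0_b <- numeric(d)
  W$aspp$rates[[1]]$W <- matrix(0, 9 * d, d); W$aspp$rates[[1]]$b <- numeric(d)
  W$aspp$fuse_W <- cbind(diag(d), matrix(0, d, d)); W$aspp$fuse_b <- numeric(d)
  W$res_W <- matrix(0, d, 3); W$res_b <- numeric(d)
  img <- random_preprocessed(6, 16L)
  t_in <- array(rnorm(4 * 4 * d), c(4, 4, d))
  expect_equal(encoder_forward(t_in, img, cfg, W), t_in, tolerance = 1e-12)

  # the residual path adds exactly the projected pooled image
  W2 <- W
  W2$res_W <- matrix(rnorm(d * 3), d, 3)
  diff <- encoder_forward(t_in, img, cfg, W2) - encoder_forward(t_in, img, cfg, W)
  proj <- nutrinet:::tensor_to_tokens(nutrinet:::pool_to_grid(unclass(img), 4L)) %*% t(W2$res_W)
  expect_equal(diff, nutrinet:::tokens_to_tensor(proj, 4L, 4L), tolerance = 1e-12)
})

test_that("the full encoder matches a stagewise single-head reference", {
  d <- 4L
  cfg <- encoder_config(layers = 1L, width = d, n_heads = 1L,
                        aspp_rates = 1L, aspp_channels = 3L)
  W <- nutrinet:::with_seed(19, nutrinet:::encoder_init(cfg))
  img <- random_preprocessed(7, 16L)
  t_in <- array(rnorm(2 * 2 * d), c(2, 2, d))

  # reference: compose the printed formulas step by step
  X <- nutrinet:::tensor_to_tokens(t_in)
  p <- W$layers[[1]]
  pr <- linear_projection(X, p)
  C <- focused_attention(pr$Q, pr$K, pr$V, d)
  I <- independent_attention(pr$Qg, pr$Kg, pr$Vg, d)
  X1 <- X + mhsa_fuse(C, I, p)
  ff <- gelu(sweep(X1 %*% t(p$ff_W1), 2, p$ff_b1, `+`))
  X2 <- X1 + sweep(ff %*% t(p$ff_W2), 2, p$ff_b2, `+`)
  t_mid <- nutrinet:::tokens_to_tensor(X2, 2L, 2L)
  t_aspp <- aspp(t_mid, cfg$aspp_rates, W$aspp)
  resid <- nutrinet:::tensor_to_tokens(nutrinet:::pool_to_grid(unclass(img), 2L)) %*% t(W$res_W)
  resid <- sweep(resid, 2, W$res_b, `+`)
  expected <- t_aspp + nutrinet:::tokens_to_tensor(resid, 2L, 2L)

  expect_equal(encoder_forward(t_in, img, cfg, W), expected, tolerance = 1e-12)
})
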