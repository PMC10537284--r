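# Dual-attention transformer encoder. Each layer projects the token matrix
# into a local (Q, K, V) triple and a separately parameterised global triple,
# runs scaled dot-product attention on both paths ("focused" C and
# "independent" I), fuses them as Wo (alpha C + beta I), and applies a GELU
# feed-forward sublayer. The stack is followed by atrous spatial pyramid
# pooling and a residual path carrying a 1x1 projection of the original
# image back into the features.

encoder_config <- function(layers = 2L, width = 16L, n_heads = 4L,
                           aspp_rates = c(1L, 6L, 12L, 18L),
                           aspp_channels = 8L) {
  if (width %% n_heads != 0L)
    config_error("encoder width must be divisible by n_heads")
  list(layers = as.integer(layers), width = as.integer(width),
       n_heads = as.integer(n_heads), aspp_rates = as.integer(aspp_rates),
       aspp_channels = as.integer(aspp_channels))
}

encoder_init <- function(cfg) {
  d <- cfg$width
  layer_init <- function() list(
    Wq = init_weight(d, d), Wk = init_weight(d, d), Wv = init_weight(d, d),
    Wqg = init_weight(d, d), Wkg = init_weight(d, d), Wvg = init_weight(d, d),
    Wo = init_weight(d, d),
    alpha = 0.5, beta = 0.5,
    ff_W1 = init_weight(4L * d, d), ff_b1 = numeric(4L * d),
    ff_W2 = init_weight(d, 4L * d), ff_b2 = numeric(d)
  )
  ca <- cfg$aspp_channels; nr <- length(cfg$aspp_rates)
  list(
    layers = lapply(seq_len(cfg$layers), function(i) layer_init()),
    aspp = list(
      br0_W = init_weight(ca, d), br0_b = numeric(ca),
      rates = lapply(cfg$aspp_rates, function(r)
        list(W = init_conv_weight(3L, d, ca), b = numeric(ca))),
      fuse_W = init_weight(d, ca * (nr + 1L)), fuse_b = numeric(d)
    ),
    res_W = init_weight(d, 3L), res_b = numeric(d)
  )
}

#' Project a token matrix into local and global Q/K/V matrices
#'
#' Applies the seven-way linear map of the dual-attention layer: each output
#' is its weight matrix applied to the tokens (`Q = X Wq'`, row-token
#' convention).
#'
#' @param X A `T x d` token matrix.
#' @param p Parameter list with square matrices `Wq, Wk, Wv, Wqg, Wkg, Wvg`.
#' @return A list of six `T x d` matrices: `Q, K, V, Qg, Kg, Vg`.
#' @export
linear_projection <- function(X, p) {
  if (ncol(X) != ncol(p$Wq))
    dimension_error(sprintf("token width %d does not match projection width %d",
                            ncol(X), ncol(p$Wq)))
  list(Q = tcrossprod(X, p$Wq), K = tcrossprod(X, p$Wk), V = tcrossprod(X, p$Wv),
       Qg = tcrossprod(X, p$Wqg), Kg = tcrossprod(X, p$Wkg), Vg = tcrossprod(X, p$Wvg))
}

#' Focused (local) scaled dot-product attention
#'
#' \eqn{C = \mathrm{softmax}(Q K^T / \sqrt{d_k})\,V}; the softmax is row-wise,
#' so every attention weight matrix is row-stochastic.
#'
#' @param Q,K,V Conformable token matrices.
#' @param dk Key width used in the temperature (at least 1).
#' @return A matrix the shape of `V`'s row space: `nrow(Q) x ncol(V)`.
#' @export
focused_attention <- function(Q, K, V, dk) {
  if (dk < 1) config_error("dk must be at least 1")
  A <- row_softmax(tcrossprod(Q, K) / sqrt(dk))
  A %*% V
}

#' Independent (global) scaled dot-product attention
#'
#' Identical functional form to [focused_attention()], applied to the
#' separately projected global matrices.
#'
#' @param Qg,Kg,Vg Global token matrices.
#' @param dk Key width.
#' @return Attention output matrix `I`.
#' @export
independent_attention <- function(Qg, Kg, Vg, dk) focused_attention(Qg, Kg, Vg, dk)

#' Fuse the focused and independent attention outputs
#'
#' \eqn{\mathrm{MHSA}_{out} = W_o(\alpha C + \beta I)} — a weighted sum of the
#' two attention paths followed by a linear output transform.
#'
#' @param C,I Same-shape attention outputs.
#' @param p Parameter list with `Wo`, `alpha`, `beta`.
#' @return Fused token matrix.
#' @export
mhsa_fuse <- function(C, I, p) {
  if (!all(dim(C) == dim(I))) dimension_error("C and I must have identical shapes")
  tcrossprod(p$alpha * C + p$beta * I, p$Wo)
}

.head_slices <- function(d, n_heads) {
  dk <- d %/% n_heads
  lapply(seq_len(n_heads), function(h) ((h - 1L) * dk + 1L):(h * dk))
}

# One encoder layer with cache for backprop.
.enc_layer_forward <- function(X, p, n_heads, keep_cache = FALSE) {
  d <- ncol(X)
  pr <- linear_projection(X, p)
  slices <- .head_slices(d, n_heads)
  dk <- d %/% n_heads
  C <- matrix(0, nrow(X), d); I <- matrix(0, nrow(X), d)
  A_loc <- vector("list", n_heads); A_glo <- vector("list", n_heads)
  for (h in seq_along(slices)) {
    s <- slices[[h]]
    A_loc[[h]] <- row_softmax(tcrossprod(pr$Q[, s, drop = FALSE], pr$K[, s, drop = FALSE]) / sqrt(dk))
    C[, s] <- A_loc[[h]] %*% pr$V[, s, drop = FALSE]
    A_glo[[h]] <- row_softmax(tcrossprod(pr$Qg[, s, drop = FALSE], pr$Kg[, s, drop = FALSE]) / sqrt(dk))
    I[, s] <- A_glo[[h]] %*% pr$Vg[, s, drop = FALSE]
  }
  P <- p$alpha * C + p$beta * I
  M <- tcrossprod(P, p$Wo)
  X1 <- X + M
  Z1 <- sweep(tcrossprod(X1, p$ff_W1), 2, p$ff_b1, `+`)
  G <- gelu(Z1)
  Z2 <- sweep(tcrossprod(G, p$ff_W2), 2, p$ff_b2, `+`)
  Y <- X1 + Z2
  cache <- NULL
  if (keep_cache)
    cache <- list(X = X, pr = pr, A_loc = A_loc, A_glo = A_glo, C = C, I = I,
                  P = P, X1 = X1, Z1 = Z1, G = G, slices = slices, dk = dk)
  list(Y = Y, cache = cache)
}

.attn_bwd <- function(dO, A, Q, K, V, dk) {
  dV <- crossprod(A, dO)
  dA <- tcrossprod(dO, V)
  dS <- A * (dA - rowSums(dA * A))
  sc <- 1 / sqrt(dk)
  list(dQ = dS %*% K * sc, dK = crossprod(dS, Q) * sc, dV = dV)
}

.enc_layer_backward <- function(dY, cache, p) {
  g <- list()
  # feed-forward sublayer
  dZ2 <- dY
  g$ff_W2 <- crossprod(dZ2, cache$G); g$ff_b2 <- colSums(dZ2)
  dG <- dZ2 %*% p$ff_W2
  dZ1 <- dG * gelu_grad(cache$Z1)
  g$ff_W1 <- crossprod(dZ1, cache$X1); g$ff_b1 <- colSums(dZ1)
  dX1 <- dY + dZ1 %*% p$ff_W1
  # attention sublayer
  dM <- dX1
  g$Wo <- crossprod(dM, cache$P)
  dP <- dM %*% p$Wo
  g$alpha <- sum(dP * cache$C); g$beta <- sum(dP * cache$I)
  dC <- p$alpha * dP; dI <- p$beta * dP
  pr <- cache$pr
  dQ <- matrix(0, nrow(dY), ncol(dY)); dK <- dQ; dV <- dQ
  dQg <- dQ; dKg <- dQ; dVg <- dQ
  for (h in seq_along(cache$slices)) {
    s <- cache$slices[[h]]
    bl <- .attn_bwd(dC[, s, drop = FALSE], cache$A_loc[[h]],
                    pr$Q[, s, drop = FALSE], pr$K[, s, drop = FALSE],
                    pr$V[, s, drop = FALSE], cache$dk)
    dQ[, s] <- bl$dQ; dK[, s] <- bl$dK; dV[, s] <- bl$dV
    bg <- .attn_bwd(dI[, s, drop = FALSE], cache$A_glo[[h]],
                    pr$Qg[, s, drop = FALSE], pr$Kg[, s, drop = FALSE],
                    pr$Vg[, s, drop = FALSE], cache$dk)
    dQg[, s] <- bg$dQ; dKg[, s] <- bg$dK; dVg[, s] <- bg$dV
  }
  X <- cache$X
  g$Wq <- crossprod(dQ, X); g$Wk <- crossprod(dK, X); g$Wv <- crossprod(dV, X)
  g$Wqg <- crossprod(dQg, X); g$Wkg <- crossprod(dKg, X); g$Wvg <- crossprod(dVg, X)
  dX <- dX1 +
    dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv +
    dQg %*% p$Wqg + dKg %*% p$Wkg + dVg %*% p$Wvg
  list(dX = dX, grads = g)
}

#' Atrous spatial pyramid pooling
#'
#' Parallel 3x3 dilated convolutions at the given rates plus a 1x1 branch,
#' concatenated along channels and fused by a final 1x1 convolution. Spatial
#' dimensions are preserved (same padding).
#'
#' @param t An `H x W x C` feature tensor.
#' @param rates Dilation rates for the 3x3 branches (nonempty).
#' @param weights List with `br0_W`, `br0_b` (the 1x1 branch), `rates` (one
#'   `list(W, b)` per rate) and `fuse_W`, `fuse_b`.
#' @return An `H x W x C_out` tensor.
#' @export
aspp <- function(t, rates, weights) {
  if (length(rates) < 1L) config_error("ASPP needs at least one dilation rate")
  h <- dim(t)[1]; w <- dim(t)[2]
  out <- .aspp_forward(tensor_to_tokens(t), h, w, as.integer(rates), weights)
  tokens_to_tensor(out$Y, h, w)
}

.aspp_forward <- function(X, h, w, rates, W, keep_cache = FALSE) {
  b0 <- sweep(tcrossprod(X, W$br0_W), 2, W$br0_b, `+`)
  convs <- vector("list", length(rates))
  outs <- vector("list", length(rates) + 1L)
  outs[[1L]] <- b0
  for (i in seq_along(rates)) {
    cv <- conv2d_forward(X, h, w, W$rates[[i]]$W, W$rates[[i]]$b, 3L, dilation = rates[i])
    convs[[i]] <- cv
    outs[[i + 1L]] <- cv$Y
  }
  cat_ <- do.call(cbind, outs)
  Y <- sweep(tcrossprod(cat_, W$fuse_W), 2, W$fuse_b, `+`)
  cache <- if (keep_cache) list(X = X, convs = convs, cat_ = cat_, rates = rates) else NULL
  list(Y = Y, cache = cache)
}

.aspp_backward <- function(dY, cache, W) {
  g <- list()
  g$fuse_W <- crossprod(dY, cache$cat_); g$fuse_b <- colSums(dY)
  dcat <- dY %*% W$fuse_W
  ca <- nrow(W$br0_W)
  db0 <- dcat[, 1:ca, drop = FALSE]
  g$br0_W <- crossprod(db0, cache$X); g$br0_b <- colSums(db0)
  dX <- db0 %*% W$br0_W
  g$rates <- vector("list", length(cache$rates))
  for (i in seq_along(cache$rates)) {
    dYi <- dcat[, (i * ca + 1L):((i + 1L) * ca), drop = FALSE]
    bw <- conv2d_backward(dYi, cache$convs[[i]], W$rates[[i]]$W)
    g$rates[[i]] <- list(W = bw$dW, b = bw$db)
    dX <- dX + bw$dX
  }
  list(dX = dX, grads = g)
}

.encoder_forward <- function(X, h, w, orig_small, cfg, W, keep_cache = FALSE) {
  layer_caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    st <- .enc_layer_forward(X, W$layers[[l]], cfg$n_heads, keep_cache)
    layer_caches[[l]] <- st$cache
    X <- st$Y
  }
  asp <- .aspp_forward(X, h, w, cfg$aspp_rates, W$aspp, keep_cache)
  R <- sweep(tcrossprod(orig_small, W$res_W), 2, W$res_b, `+`)
  Y <- asp$Y + R
  cache <- if (keep_cache)
    list(layers = layer_caches, aspp = asp$cache, orig_small = orig_small) else NULL
  list(Y = Y, cache = cache)
}

.encoder_backward <- function(dY, cache, cfg, W) {
  g <- list()
  g$res_W <- crossprod(dY, cache$orig_small); g$res_b <- colSums(dY)
  asp <- .aspp_backward(dY, cache$aspp, W$aspp)
  g$aspp <- asp$grads
  dX <- asp$dX
  g$layers <- vector("list", cfg$layers)
  for (l in rev(seq_len(cfg$layers))) {
    bl <- .enc_layer_backward(dX, cache$layers[[l]], W$layers[[l]])
    g$layers[[l]] <- bl$grads
    dX <- bl$dX
  }
  list(dX = dX, grads = g)
}

#' Run the dual-attention encoder
#'
#' Stacks `cfg$layers` dual-attention layers over the EFE output tokens,
#' applies atrous spatial pyramid pooling, and adds a residual path: the
#' original image is pooled to the encoder's spatial grid and 1x1-projected
#' to the feature width.
#'
#' @param efe_out `H x W x C` feature tensor from [efe_forward()].
#' @param original The `preprocessed_image` the features came from.
#' @param cfg Encoder configuration block (see [model_config()]).
#' @param weights Encoder weights, e.g. from [init_model()]'s `$enc`.
#' @return An `H x W x C` feature tensor on the same grid.
#' @export
encoder_forward <- function(efe_out, original, cfg, weights) {
  h <- dim(efe_out)[1]; w <- dim(efe_out)[2]
  if (dim(efe_out)[3] != cfg$width)
    config_error(sprintf("encoder width %d does not match feature channels %d",
                         cfg$width, dim(efe_out)[3]))
  orig_small <- tensor_to_tokens(pool_to_grid(unclass(original), h))
  out <- .encoder_forward(tensor_to_tokens(efe_out), h, w, orig_small, cfg, weights)
  tokens_to_tensor(out$Y, h, w)
}
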