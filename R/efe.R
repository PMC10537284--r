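# Environment feature extraction (EFE) backbone:
# HSI conversion -> pointwise linear embedding -> parallel convolutions with
# different kernel sizes -> channel recombination -> 1x1 conv -> MDN -> 1x1
# conv. The front end is meant to damp background clutter before the encoder
# ever sees the image.

efe_config <- function(kernel_sizes = c(1L, 3L, 5L, 7L),
                       channels_per_branch = 8L,
                       mid_channels = 16L,
                       out_channels = 16L,
                       embed_dim = 16L,
                       hsi_mode = c("replace", "concat"),
                       mdn_k = 2L,
                       mdn_bins = 32L) {
  hsi_mode <- match.arg(hsi_mode)
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(kernel_sizes) < 1L) config_error("at least one convolution branch is required")
  if (any(kernel_sizes %% 2L == 0L)) config_error("all kernel sizes must be odd")
  list(kernel_sizes = kernel_sizes,
       channels_per_branch = as.integer(channels_per_branch),
       mid_channels = as.integer(mid_channels),
       out_channels = as.integer(out_channels),
       embed_dim = as.integer(embed_dim),
       hsi_mode = hsi_mode,
       mdn_k = as.integer(mdn_k),
       mdn_bins = as.integer(mdn_bins))
}

efe_input_channels <- function(cfg) if (cfg$hsi_mode == "concat") 6L else 3L

efe_init <- function(cfg) {
  cin <- efe_input_channels(cfg)
  de <- cfg$embed_dim; cb <- cfg$channels_per_branch
  nb <- length(cfg$kernel_sizes)
  w <- list(
    embed_W = init_weight(de, cin), embed_b = numeric(de),
    branches = lapply(cfg$kernel_sizes, function(k)
      list(W = init_conv_weight(k, de, cb), b = numeric(cb))),
    comb1_W = init_weight(cfg$mid_channels, nb * cb), comb1_b = numeric(cfg$mid_channels),
    comb2_W = init_weight(cfg$out_channels, cfg$mid_channels), comb2_b = numeric(cfg$out_channels)
  )
  w
}

# X: npix x cin token matrix of (scaled) HSI planes.
.efe_forward <- function(X, h, w, cfg, W, keep_cache = FALSE) {
  if (ncol(X) != ncol(W$embed_W))
    config_error(sprintf("EFE input has %d channels but weights expect %d",
                         ncol(X), ncol(W$embed_W)))
  E <- tcrossprod(X, W$embed_W)
  E <- sweep(E, 2, W$embed_b, `+`)
  convs <- vector("list", length(cfg$kernel_sizes))
  outs <- vector("list", length(cfg$kernel_sizes))
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]
    cv <- conv2d_forward(E, h, w, W$branches[[i]]$W, W$branches[[i]]$b, k)
    convs[[i]] <- cv
    outs[[i]] <- cv$Y
  }
  Ycat <- do.call(cbind, outs)
  Z1 <- sweep(tcrossprod(Ycat, W$comb1_W), 2, W$comb1_b, `+`)
  pm <- .partition_cols(Z1, min(cfg$mdn_k, ncol(Z1)), cfg$mdn_bins)
  md <- .mdn_forward(Z1, pm$assignment)
  Z2 <- sweep(tcrossprod(md$Y, W$comb2_W), 2, W$comb2_b, `+`)
  cache <- NULL
  if (keep_cache)
    cache <- list(X = X, E = E, convs = convs, Ycat = Ycat, Z1 = Z1,
                  pm = pm, norms = md$norms, Zn = md$Y)
  list(Y = Z2, cache = cache)
}

.efe_backward <- function(dZ2, cache, cfg, W) {
  g <- list()
  g$comb2_W <- crossprod(dZ2, cache$Zn)
  g$comb2_b <- colSums(dZ2)
  dZn <- dZ2 %*% W$comb2_W
  dZ1 <- .mdn_backward(dZn, cache$Z1, cache$pm$assignment, cache$norms)
  g$comb1_W <- crossprod(dZ1, cache$Ycat)
  g$comb1_b <- colSums(dZ1)
  dYcat <- dZ1 %*% W$comb1_W
  cb <- cfg$channels_per_branch
  dE <- 0
  g$branches <- vector("list", length(cfg$kernel_sizes))
  for (i in seq_along(cfg$kernel_sizes)) {
    dYi <- dYcat[, ((i - 1L) * cb + 1L):(i * cb), drop = FALSE]
    bw <- conv2d_backward(dYi, cache$convs[[i]], W$branches[[i]]$W)
    g$branches[[i]] <- list(W = bw$dW, b = bw$db)
    dE <- dE + bw$dX
  }
  g$embed_W <- crossprod(dE, cache$X)
  g$embed_b <- colSums(dE)
  dX <- dE %*% W$embed_W
  list(dX = dX, grads = g)
}

#' Run the environment feature extraction backbone on one image
#'
#' Pipeline: HSI conversion (planes rescaled to `[0, 1]`), block-mean pooling
#' to the working grid, a pointwise linear embedding, parallel same-padding
#' convolutions at each configured kernel size, channel recombination, a 1x1
#' convolution, distribution-partition normalisation (MDN), and a final 1x1
#' convolution. Deterministic given weights.
#'
#' @param img A `preprocessed_image` (or any `H x W x 3` array in `[0, 1]`).
#' @param cfg An EFE configuration block (see [model_config()]).
#' @param weights EFE weights, e.g. from [init_model()]'s `$efe`.
#' @param grid Working grid side length (tokens per side).
#' @return A `grid x grid x out_channels` feature tensor.
#' @export
efe_forward <- function(img, cfg, weights, grid = 8L) {
  hsi <- hsi_unit_scale(rgb_to_hsi(img))
  Xh <- pool_to_grid(hsi, grid)
  if (cfg$hsi_mode == "concat") {
    Xr <- pool_to_grid(unclass(img), grid)
    Xh <- array(c(Xh, Xr), c(grid, grid, 6L))
  }
  out <- .efe_forward(tensor_to_tokens(Xh), grid, grid, cfg, weights)
  tokens_to_tensor(out$Y, grid, grid)
}
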