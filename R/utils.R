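# Internal helpers shared across modules.

.nn_error <- function(msg, class) {
  stop(structure(
    class = c(class, "nutrinet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error    <- function(msg) .nn_error(msg, "nutrinet_config_error")
dimension_error <- function(msg) .nn_error(msg, "nutrinet_dimension_error")
decode_error    <- function(msg) .nn_error(msg, "nutrinet_decode_error")
validation_error<- function(msg) .nn_error(msg, "nutrinet_validation_error")
metric_error    <- function(msg) .nn_error(msg, "nutrinet_metric_error")
io_error        <- function(msg) .nn_error(msg, "nutrinet_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Hashes a master seed together with one or more stream labels into a new
#' integer seed (always below 2^31), so independent random streams — data
#' draws, splits, renders — can be derived from a single seed without
#' interfering.
#'
#' @param seed Integer master seed.
#' @param ... Stream labels (coerced to character).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  x <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) {
      x <- (x * 31 + ch) %% 2147483647
    }
  }
  as.integer(x)
}

# Run an expression under a local RNG state so library code never clobbers
# the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## ---- bilinear sampling -----------------------------------------------------
## Centre-aligned inverse mapping: output pixel centre (j - 0.5) in output
## units maps to (j - 0.5) * in/out in input units. Edge handling is either
## clamp (resize) or reflect (rotation fill).

.reflect_index <- function(v, n) {
  if (n == 1L) return(rep(1, length(v)))
  period <- 2 * (n - 1)
  p <- (v - 1) %% period
  ifelse(p > (n - 1), period - p, p) + 1
}

# img: H x W x C array (or H x W matrix); returns out_h x out_w x C
resize_bilinear <- function(img, out_h, out_w) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  sy <- clamp((seq_len(out_h) - 0.5) * h / out_h + 0.5, 1, h)
  sx <- clamp((seq_len(out_w) - 0.5) * w / out_w + 0.5, 1, w)
  y0 <- pmin(floor(sy), h); y1 <- pmin(y0 + 1, h); fy <- sy - y0
  x0 <- pmin(floor(sx), w); x1 <- pmin(x0 + 1, w); fx <- sx - x0
  wyx00 <- (1 - fy) %o% (1 - fx); wyx10 <- fy %o% (1 - fx)
  wyx01 <- (1 - fy) %o% fx;       wyx11 <- fy %o% fx
  out <- array(0, c(out_h, out_w, nc))
  for (c in seq_len(nc)) {
    M <- img[, , c]
    out[, , c] <- M[y0, x0, drop = FALSE] * wyx00 + M[y1, x0, drop = FALSE] * wyx10 +
      M[y0, x1, drop = FALSE] * wyx01 + M[y1, x1, drop = FALSE] * wyx11
  }
  out
}

# Sample img at arbitrary (ys, xs) coordinates with reflect padding.
sample_bilinear_reflect <- function(img, ys, xs) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  ry0 <- .reflect_index(y0, h); ry1 <- .reflect_index(y0 + 1, h)
  rx0 <- .reflect_index(x0, w); rx1 <- .reflect_index(x0 + 1, w)
  out <- matrix(0, length(ys), nc)
  for (c in seq_len(nc)) {
    M <- img[, , c]
    out[, c] <- M[cbind(ry0, rx0)] * (1 - fy) * (1 - fx) +
      M[cbind(ry1, rx0)] * fy * (1 - fx) +
      M[cbind(ry0, rx1)] * (1 - fy) * fx +
      M[cbind(ry1, rx1)] * fy * fx
  }
  out
}

# Block-mean pooling of an H x W x C array down to grid x grid.
# Falls back to a bilinear resize to a divisible size first.
pool_to_grid <- function(img, grid) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  if (h %% grid != 0 || w %% grid != 0) {
    side <- grid * max(1L, floor(min(h, w) / grid))
    img <- resize_bilinear(img, side, side)
    h <- w <- side
  }
  fy <- h %/% grid; fx <- w %/% grid
  out <- array(0, c(grid, grid, nc))
  for (c in seq_len(nc)) {
    M <- img[, , c]
    dim(M) <- c(fy, grid, fx, grid)
    out[, , c] <- apply(M, c(2, 4), mean)
  }
  out
}

## ---- tensor <-> token layout ----------------------------------------------
## Feature maps travel as (H*W) x C matrices in column-major pixel order;
## module boundaries expose H x W x C arrays.

tensor_to_tokens <- function(t) {
  stopifnot(length(dim(t)) == 3L)
  matrix(t, nrow = dim(t)[1] * dim(t)[2])
}

tokens_to_tensor <- function(m, h, w) {
  array(m, c(h, w, ncol(m)))
}

## ---- im2col convolution geometry -------------------------------------------
## Neighbour index tables are cached per (h, w, k, dilation); index 0 marks an
## out-of-frame tap (zero padding).

.geom_cache <- new.env(parent = emptyenv())

conv_geometry <- function(h, w, k, dilation = 1L) {
  key <- paste(h, w, k, dilation, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  half <- (k - 1L) %/% 2L
  offs <- (-half:half) * dilation
  yy <- rep(seq_len(h), times = w)
  xx <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k)
  o <- 0L
  for (dx in offs) for (dy in offs) {
    o <- o + 1L
    ny <- yy + dy; nx <- xx + dx
    ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
    col <- integer(h * w)
    col[ok] <- (nx[ok] - 1L) * h + ny[ok]
    idx[, o] <- col
  }
  .geom_cache[[key]] <- idx
  idx
}

# X: npix x Cin. W: (k*k*Cin) x Cout, offset-major blocks of Cin columns.
im2col <- function(X, idx) {
  npix <- nrow(X); cin <- ncol(X); k2 <- ncol(idx)
  Xp <- rbind(0, X)                    # row 1 = zero pad target
  cols <- matrix(0, npix, k2 * cin)
  for (o in seq_len(k2)) {
    cols[, ((o - 1L) * cin + 1L):(o * cin)] <- Xp[idx[, o] + 1L, , drop = FALSE]
  }
  cols
}

conv2d_forward <- function(X, h, w, W, b, k, dilation = 1L) {
  cin <- ncol(X)
  if (nrow(W) != k * k * cin)
    config_error(sprintf("conv weight rows %d != k^2 * Cin = %d", nrow(W), k * k * cin))
  idx <- conv_geometry(h, w, k, dilation)
  cols <- im2col(X, idx)
  Y <- cols %*% W
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, cols = cols, idx = idx, cin = cin)
}

conv2d_backward <- function(dY, cache, W) {
  cols <- cache$cols; idx <- cache$idx; cin <- cache$cin
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, W)
  dX <- matrix(0, nrow(dY), cin)
  k2 <- ncol(idx)
  for (o in seq_len(k2)) {
    rows <- idx[, o]; ok <- rows > 0L
    block <- dcols[ok, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
    dX[rows[ok], ] <- dX[rows[ok], ] + block
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- softmax / layer norm ----------------------------------------------------

row_softmax <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

## Fan-in-scaled uniform weight init (out x in convention).
init_weight <- function(n_out, n_in) {
  lim <- sqrt(1 / n_in)
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

init_conv_weight <- function(k, cin, cout) {
  lim <- sqrt(1 / (k * k * cin))
  matrix(stats::runif(k * k * cin * cout, -lim, lim), k * k * cin, cout)
}
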