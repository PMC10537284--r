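# Sup-HeadAttention decoder. A supervision layer watches per-token activity
# during training; tokens whose running mean absolute activation falls below
# a threshold are "slept" for a fixed number of epochs — frozen at their
# current value and excluded from the attention matmul — which shrinks the
# token set passed onward. Attention is followed by dropout, layer
# normalisation, a residual fully connected stack, and mean pooling over the
# awake tokens into the decoder's feature vector.

decoder_config <- function(fc_layers = 2L, dropout = 0.1, tau = 1e-3,
                           sleep_epochs = 2L, window = 50L, d_out = NULL) {
  if (sleep_epochs < 1L) config_error("sleep_epochs must be at least 1")
  if (window < 1L) config_error("window must be at least 1")
  if (tau < 0) config_error("tau must be nonnegative")
  list(fc_layers = as.integer(fc_layers), dropout = dropout, tau = tau,
       sleep_epochs = as.integer(sleep_epochs), window = as.integer(window),
       d_out = d_out)
}

decoder_init <- function(cfg, d) {
  d_out <- as.integer(cfg$d_out %||% d)
  list(
    Wq = init_weight(d, d), Wk = init_weight(d, d), Wv = init_weight(d, d),
    ln_g = rep(1, d), ln_b = numeric(d),
    fc = lapply(seq_len(cfg$fc_layers), function(i)
      list(W = init_weight(d, d), b = numeric(d))),
    out_W = init_weight(d_out, d), out_b = numeric(d_out)
  )
}

#' Create a sleep state for a token set
#'
#' @param n_tokens Number of tokens tracked.
#' @param d Token width (for the frozen-value store).
#' @return A list of class `sleep_state` with `asleep` (logical), `remaining`
#'   (integer epochs of sleep left) and `frozen` (`n_tokens x d` matrix of
#'   stored activations), plus the running activation statistics.
#' @export
sleep_state <- function(n_tokens, d) {
  structure(list(
    asleep = rep(FALSE, n_tokens),
    remaining = integer(n_tokens),
    frozen = matrix(0, n_tokens, d),
    mean_abs = numeric(n_tokens),
    steps_seen = 0L
  ), class = "sleep_state")
}

.check_sleep_state <- function(state) {
  if (!all((state$remaining > 0L) == state$asleep))
    validation_error("sleep-state invariant violated: asleep <=> remaining > 0")
  if (any(state$remaining < 0L))
    validation_error("sleep-state invariant violated: negative remaining counter")
  invisible(state)
}

#' Flag inactive tokens
#'
#' A token is flagged if and only if its running mean absolute activation is
#' strictly below `tau`; with `tau = 0` nothing is ever flagged. Flags are
#' only meaningful once the statistics window has filled.
#'
#' @param stats A list with `mean_abs` and `steps_seen` (e.g. a
#'   `sleep_state`).
#' @param tau Nonnegative inactivity threshold.
#' @param window Required number of observed steps before flagging.
#' @return A logical mask over tokens.
#' @export
detect_inactive <- function(stats, tau, window = 1L) {
  if (tau < 0) config_error("tau must be nonnegative")
  if (stats$steps_seen < window) return(rep(FALSE, length(stats$mean_abs)))
  stats$mean_abs < tau
}

# Exponential-window running mean of |activation| per token.
.update_stats <- function(state, X, window) {
  a <- rowMeans(abs(X))
  n <- min(state$steps_seen + 1L, window)
  state$mean_abs <- state$mean_abs + (a - state$mean_abs) / n
  state$steps_seen <- state$steps_seen + 1L
  state
}

#' Advance the sleep bookkeeping
#'
#' Newly flagged awake tokens fall asleep with `remaining = sleep_epochs`
#' and their current activation frozen; an already-asleep token that is
#' flagged again is not re-armed. At an epoch boundary every sleeper's
#' counter decrements, and tokens wake when it reaches zero.
#'
#' @param state A `sleep_state`.
#' @param flags Logical mask from [detect_inactive()].
#' @param sleep_epochs Epochs a newly slept token stays asleep (>= 1).
#' @param epoch_boundary Whether this call closes an epoch.
#' @param values Optional `n_tokens x d` activation matrix to freeze for
#'   newly slept tokens.
#' @return The updated `sleep_state`.
#' @export
update_sleep <- function(state, flags, sleep_epochs, epoch_boundary = FALSE,
                         values = NULL) {
  if (sleep_epochs < 1L) config_error("sleep_epochs must be at least 1")
  if (length(flags) != length(state$asleep))
    dimension_error("flag mask does not match the token count")
  newly <- flags & !state$asleep
  if (any(newly)) {
    state$asleep[newly] <- TRUE
    state$remaining[newly] <- as.integer(sleep_epochs)
    if (!is.null(values)) state$frozen[newly, ] <- values[newly, , drop = FALSE]
  }
  if (epoch_boundary && any(state$asleep)) {
    state$remaining[state$asleep] <- state$remaining[state$asleep] - 1L
    wake <- state$asleep & state$remaining == 0L
    state$asleep[wake] <- FALSE
  }
  .check_sleep_state(state)
  state
}

#' Attention over the awake token subset
#'
#' Computes scaled dot-product attention restricted to awake tokens; the
#' output rows of asleep tokens are their frozen values. With an empty sleep
#' mask this is exactly [focused_attention()] on the full token matrix.
#'
#' @param X `T x d` token matrix.
#' @param state A `sleep_state` sized to `X`.
#' @param weights List with `Wq`, `Wk`, `Wv`.
#' @param dk Key width for the attention temperature.
#' @return A `T x d` matrix.
#' @export
sup_head_attention <- function(X, state, weights, dk) {
  out <- .sup_attn_forward(X, state, weights, dk)
  out$Y
}

.sup_attn_forward <- function(X, state, weights, dk, keep_cache = FALSE) {
  if (length(state$asleep) != nrow(X))
    dimension_error("sleep state does not match the token count")
  awake <- which(!state$asleep)
  if (length(awake) == 0L)
    validation_error("degenerate input: every token is asleep")
  Xa <- X[awake, , drop = FALSE]
  Q <- tcrossprod(Xa, weights$Wq)
  K <- tcrossprod(Xa, weights$Wk)
  V <- tcrossprod(Xa, weights$Wv)
  A <- row_softmax(tcrossprod(Q, K) / sqrt(dk))
  Oa <- A %*% V
  Y <- state$frozen
  if (ncol(Y) != ncol(Oa)) Y <- matrix(0, nrow(X), ncol(Oa))
  Y[awake, ] <- Oa
  cache <- if (keep_cache) list(X = X, awake = awake, Q = Q, K = K, V = V, A = A) else NULL
  list(Y = Y, awake = awake, cache = cache)
}

.sup_attn_backward <- function(dY, cache, weights, dk) {
  awake <- cache$awake
  dOa <- dY[awake, , drop = FALSE]
  bl <- .attn_bwd(dOa, cache$A, cache$Q, cache$K, cache$V, dk)
  Xa <- cache$X[awake, , drop = FALSE]
  g <- list(Wq = crossprod(bl$dQ, Xa), Wk = crossprod(bl$dK, Xa),
            Wv = crossprod(bl$dV, Xa))
  dXa <- bl$dQ %*% weights$Wq + bl$dK %*% weights$Wk + bl$dV %*% weights$Wv
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  dX[awake, ] <- dXa
  list(dX = dX, grads = g)
}

.decoder_forward <- function(X, state, cfg, W, mode = "eval", keep_cache = FALSE) {
  d <- ncol(X)
  dk <- d
  # sleeping is a training-time mechanism; evaluation uses every token
  eff_state <- if (mode == "train") state else sleep_state(nrow(X), d)
  at <- .sup_attn_forward(X, eff_state, W, dk, keep_cache)
  O <- at$Y
  drop_mask <- NULL
  if (mode == "train" && cfg$dropout > 0) {
    drop_mask <- matrix((stats::runif(length(O)) >= cfg$dropout) / (1 - cfg$dropout),
                        nrow(O), ncol(O))
    O <- O * drop_mask
  }
  ln <- layernorm_forward(O, W$ln_g, W$ln_b)
  Xf <- ln$Y
  fc_caches <- vector("list", length(W$fc))
  for (i in seq_along(W$fc)) {
    Z <- sweep(tcrossprod(Xf, W$fc[[i]]$W), 2, W$fc[[i]]$b, `+`)
    G <- gelu(Z)
    fc_caches[[i]] <- list(X = Xf, Z = Z)
    Xf <- Xf + G
  }
  awake <- at$awake
  pooled <- colMeans(Xf[awake, , drop = FALSE])
  f <- as.numeric(W$out_W %*% pooled + W$out_b)
  cache <- NULL
  if (keep_cache)
    cache <- list(attn = at$cache, awake = awake, drop_mask = drop_mask,
                  ln = ln, fc = fc_caches, Xf = Xf, pooled = pooled,
                  O_postdrop = O)
  list(f = f, cache = cache, attn_out = at$Y, awake = awake)
}

.decoder_backward <- function(df, cache, cfg, W) {
  g <- list()
  g$out_W <- tcrossprod(df, cache$pooled)
  g$out_b <- df
  dpooled <- as.numeric(crossprod(W$out_W, df))
  n_awake <- length(cache$awake)
  dXf <- matrix(0, nrow(cache$ln$Y), length(dpooled))
  dXf[cache$awake, ] <- matrix(dpooled / n_awake, n_awake, length(dpooled), byrow = TRUE)
  g$fc <- vector("list", length(W$fc))
  for (i in rev(seq_along(W$fc))) {
    cc <- cache$fc[[i]]
    dG <- dXf
    dZ <- dG * gelu_grad(cc$Z)
    g$fc[[i]] <- list(W = crossprod(dZ, cc$X), b = colSums(dZ))
    dXf <- dXf + dZ %*% W$fc[[i]]$W
  }
  ln_b <- layernorm_backward(dXf, cache$ln, W$ln_g)
  g$ln_g <- ln_b$dg; g$ln_b <- ln_b$db
  dO <- ln_b$dX
  if (!is.null(cache$drop_mask)) dO <- dO * cache$drop_mask
  at <- .sup_attn_backward(dO, cache$attn, W, ncol(dO))
  g$Wq <- at$grads$Wq; g$Wk <- at$grads$Wk; g$Wv <- at$grads$Wv
  list(dX = at$dX, grads = g)
}

#' Run the decoder on an encoder output tensor
#'
#' Flattens the tensor to tokens, applies Sup-HeadAttention under the given
#' sleep state, dropout (train mode only), layer normalisation, a residual
#' GELU fully connected stack, mean pooling over awake tokens, and a final
#' linear map to the feature vector. Eval mode is deterministic and uses all
#' tokens.
#'
#' @param enc_out `H x W x C` tensor from [encoder_forward()].
#' @param state A `sleep_state` over the `H*W` tokens (used in train mode).
#' @param cfg Decoder configuration block (see [model_config()]).
#' @param weights Decoder weights, e.g. from [init_model()]'s `$dec`.
#' @param mode `"eval"` or `"train"`.
#' @return A numeric feature vector.
#' @export
decoder_forward <- function(enc_out, state, cfg, weights, mode = "eval") {
  X <- tensor_to_tokens(enc_out)
  .decoder_forward(X, state, cfg, weights, mode)$f
}
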