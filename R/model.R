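# End-to-end model assembly and the WMAE training loop.

## ---- nested parameter-list helpers ----------------------------------------

nested_zero <- function(w) rapply(w, function(x) x * 0, how = "replace")

# Reorder a gradient list to the exact field order of the weight list, so
# positional walks (Adam, unlist comparisons) line up leaf by leaf.
nested_align <- function(g, ref) {
  if (!is.list(ref)) return(g)
  keys <- names(ref)
  if (is.null(keys) || any(keys == "")) {
    return(lapply(seq_along(ref), function(i) nested_align(g[[i]], ref[[i]])))
  }
  out <- lapply(keys, function(k) nested_align(g[[k]], ref[[k]]))
  names(out) <- keys
  out
}

nested_add <- function(a, b) {
  if (is.list(a)) return(mapply(nested_add, a, b, SIMPLIFY = FALSE))
  a + b
}

nested_scale <- function(a, s) rapply(a, function(x) x * s, how = "replace")

count_params <- function(w) {
  sum(rapply(w, length, how = "unlist"))
}

adam_state <- function(weights) {
  list(m = nested_zero(weights), v = nested_zero(weights), t = 0L)
}

adam_update <- function(weights, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  t <- st$t
  step <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- mapply(step, w, g, m, v, SIMPLIFY = FALSE)
      return(list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- step(weights, grads, st$m, st$v)
  st$m <- out$m; st$v <- out$v
  list(weights = out$w, state = st)
}

## ---- configuration ----------------------------------------------------------

#' Build a model configuration
#'
#' Collects the hyperparameters of every stage: the EFE backbone, the
#' dual-attention encoder, the token-sleeping decoder, the nutrient head, the
#' loss weights, the working grid, and the seed. All values have CPU-friendly
#' defaults; the published formulas leave nearly all of them free.
#'
#' @param grid Working grid side length: the image is block-mean pooled to
#'   `grid x grid` tokens after HSI conversion.
#' @param efe,encoder,decoder,head Per-stage option lists; entries override
#'   the stage defaults (see the vignette for the full table).
#' @param loss_weights Positive WMAE weight per nutrient class.
#' @param use_efe If `FALSE`, the EFE backbone is replaced by a plain
#'   convolutional stem of matched parameter budget (the ablation arm).
#' @param seed Integer seed used for weight initialisation.
#' @return A list of class `nutrinet_config`.
#' @export
model_config <- function(grid = 8L, efe = list(), encoder = list(),
                         decoder = list(), head = list(),
                         loss_weights = NULL, use_efe = TRUE, seed = 0L) {
  .check_keys(efe, names(formals(efe_config)), "efe")
  .check_keys(encoder, names(formals(encoder_config)), "encoder")
  .check_keys(decoder, names(formals(decoder_config)), "decoder")
  .check_keys(head, c("hidden", "dropout", "n_classes"), "head")
  cfg <- list(
    grid = as.integer(grid),
    efe = do.call(efe_config, efe),
    encoder = do.call(encoder_config, encoder),
    decoder = do.call(decoder_config, decoder),
    head = utils::modifyList(list(hidden = 32L, dropout = 0.3,
                                  n_classes = length(nutrient_classes())), head),
    use_efe = isTRUE(use_efe),
    seed = as.integer(seed)
  )
  if (cfg$efe$out_channels != cfg$encoder$width)
    config_error("efe out_channels must equal encoder width")
  n_class <- cfg$head$n_classes
  cfg$loss_weights <- loss_weights %||% rep(1, n_class)
  if (length(cfg$loss_weights) != n_class || any(cfg$loss_weights <= 0))
    config_error("loss_weights must be positive and one per nutrient class")
  cfg$decoder$supervise <- cfg$decoder$supervise %||% TRUE
  structure(cfg, class = "nutrinet_config")
}

#' The package's reference small configuration
#'
#' A CPU-friendly configuration (roughly 1e5 parameters on an 8 x 8 working
#' grid) used by the worked examples, the evaluation scripts and the
#' ablations: all four EFE kernel sizes, a two-layer dual-attention encoder
#' of width 24 with 4 heads, a two-layer decoder with a 64-wide feature
#' vector, and a 768-unit head.
#'
#' @param seed Initialisation seed.
#' @param use_efe Passed through to [model_config()].
#' @return A `nutrinet_config`.
#' @export
small_config <- function(seed = 0L, use_efe = TRUE) {
  model_config(
    grid = 8L,
    efe = list(kernel_sizes = c(1L, 3L, 5L, 7L), channels_per_branch = 8L,
               mid_channels = 24L, out_channels = 24L, embed_dim = 12L),
    encoder = list(layers = 2L, width = 24L, n_heads = 4L,
                   aspp_rates = c(1L, 2L, 4L), aspp_channels = 12L),
    decoder = list(fc_layers = 2L, dropout = 0.05, d_out = 64L),
    head = list(hidden = 768L),
    use_efe = use_efe,
    seed = as.integer(seed)
  )
}

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), c(allowed, "supervise"))
  if (length(bad) > 0L)
    config_error(sprintf("unknown %s option(s): %s", where, paste(bad, collapse = ", ")))
}

# Plain convolutional stem used by the no-EFE ablation arm: pointwise embed,
# one 3x3 convolution with GELU, and a 1x1 projection, with the hidden width
# chosen so the parameter count approximately matches the EFE backbone.
stem_init <- function(cfg) {
  cin <- efe_input_channels(cfg$efe)
  de <- cfg$efe$embed_dim; out <- cfg$efe$out_channels
  target <- count_params(with_seed(1L, efe_init(cfg$efe)))
  cs <- max(1L, round((target - de * (cin + 1) - out) / (9 * de + 1 + out)))
  list(
    embed_W = init_weight(de, cin), embed_b = numeric(de),
    conv_W = init_conv_weight(3L, de, cs), conv_b = numeric(cs),
    proj_W = init_weight(out, cs), proj_b = numeric(out)
  )
}

.stem_forward <- function(X, h, w, W, keep_cache = FALSE) {
  E <- sweep(tcrossprod(X, W$embed_W), 2, W$embed_b, `+`)
  cv <- conv2d_forward(E, h, w, W$conv_W, W$conv_b, 3L)
  G <- gelu(cv$Y)
  Y <- sweep(tcrossprod(G, W$proj_W), 2, W$proj_b, `+`)
  cache <- if (keep_cache) list(X = X, E = E, cv = cv, G = G) else NULL
  list(Y = Y, cache = cache)
}

.stem_backward <- function(dY, cache, W) {
  g <- list()
  g$proj_W <- crossprod(dY, cache$G); g$proj_b <- colSums(dY)
  dG <- dY %*% W$proj_W
  dZ <- dG * gelu_grad(cache$cv$Y)
  bw <- conv2d_backward(dZ, cache$cv, W$conv_W)
  g$conv_W <- bw$dW; g$conv_b <- bw$db
  dE <- bw$dX
  g$embed_W <- crossprod(dE, cache$X); g$embed_b <- colSums(dE)
  list(dX = dE %*% W$embed_W, grads = g)
}

#' Initialise model weights
#'
#' Fan-in-scaled uniform initialisation of every stage, fully determined by
#' `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return A nested weight list with components `efe` (or `stem`), `enc`,
#'   `dec`, `head`.
#' @export
init_model <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "init"), {
    front <- if (cfg$use_efe) list(efe = efe_init(cfg$efe)) else list(stem = stem_init(cfg))
    d <- cfg$encoder$width
    d_out <- as.integer(cfg$decoder$d_out %||% d)
    c(front, list(
      enc = encoder_init(cfg$encoder),
      dec = decoder_init(cfg$decoder, d),
      head = list(
        W1 = init_weight(cfg$head$hidden, d_out), b1 = numeric(cfg$head$hidden),
        W2 = init_weight(cfg$head$n_classes, cfg$head$hidden),
        b2 = numeric(cfg$head$n_classes)
      )
    ))
  })
}

## ---- forward / backward through the whole network ---------------------------

# Precompute the deterministic image-dependent inputs once per sample: the
# pooled unit-scaled HSI tokens (network input) and pooled RGB tokens
# (residual path source).
prepare_inputs <- function(img, cfg) {
  x <- unclass(img)
  if (max(x) > 1) x <- x / 255
  hsi <- hsi_unit_scale(rgb_to_hsi(x))
  Xh <- pool_to_grid(hsi, cfg$grid)
  if (cfg$efe$hsi_mode == "concat") {
    Xh <- array(c(Xh, pool_to_grid(x, cfg$grid)), c(cfg$grid, cfg$grid, 6L))
  }
  list(X = tensor_to_tokens(Xh),
       orig = tensor_to_tokens(pool_to_grid(x, cfg$grid)))
}

.net_forward <- function(inp, cfg, W, state, mode = "eval", keep_cache = FALSE) {
  g <- cfg$grid
  if (cfg$use_efe) {
    fr <- .efe_forward(inp$X, g, g, cfg$efe, W$efe, keep_cache)
  } else {
    fr <- .stem_forward(inp$X, g, g, W$stem, keep_cache)
  }
  en <- .encoder_forward(fr$Y, g, g, inp$orig, cfg$encoder, W$enc, keep_cache)
  de <- .decoder_forward(en$Y, state, cfg$decoder, W$dec, mode, keep_cache)
  hd <- .head_forward(de$f, W$head, mode, cfg$head$dropout)
  list(p = hd$p, front = fr, enc = en, dec = de, head = hd)
}

.net_backward <- function(dp, fw, cfg, W) {
  hb <- .head_backward(dp, fw$head, W$head)
  db <- .decoder_backward(hb$df, fw$dec$cache, cfg$decoder, W$dec)
  eb <- .encoder_backward(db$dX, fw$enc$cache, cfg$encoder, W$enc)
  if (cfg$use_efe) {
    fb <- .efe_backward(eb$dX, fw$front$cache, cfg$efe, W$efe)
    front <- list(efe = fb$grads)
  } else {
    fb <- .stem_backward(eb$dX, fw$front$cache, W$stem)
    front <- list(stem = fb$grads)
  }
  nested_align(c(front, list(enc = eb$grads, dec = db$grads, head = hb$grads)), W)
}

#' Run the full model on one image
#'
#' Composes the four stages — environment feature extraction (or the plain
#' stem), dual-attention encoder, token-sleeping decoder, and nutrient head —
#' and returns the predicted nutrient distribution.
#'
#' @param img A `preprocessed_image`, `rgb_image`, or `H x W x 3` array.
#' @param cfg A [model_config()].
#' @param weights Weights from [init_model()] or a trained model.
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @param state Optional `sleep_state` (train mode only).
#' @return A named nutrient probability vector summing to 1.
#' @export
model_forward <- function(img, cfg, weights, mode = "eval", state = NULL) {
  inp <- prepare_inputs(img, cfg)
  if (is.null(state)) state <- sleep_state(cfg$grid^2, cfg$encoder$width)
  p <- .net_forward(inp, cfg, weights, state, mode)$p
  stats::setNames(p, nutrient_classes()[seq_along(p)])
}

## ---- training ----------------------------------------------------------------

.as_sample_list <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$samples)) dataset <- dataset$samples
  if (length(dataset) == 0L) metric_error("empty dataset")
  dataset
}

#' Train the network with the WMAE objective
#'
#' First-order stochastic optimisation (Adam) of every stage against the
#' weighted mean absolute error between the predicted and reference nutrient
#' vectors. The decoder's supervision layer updates per-token activity
#' statistics at every step, puts inactive tokens to sleep, and decrements
#' sleep counters at epoch boundaries. Fully seeded: data order, weight
#' initialisation and dropout reproduce exactly for a fixed seed.
#'
#' @param dataset A list of samples (each with `$image` and `$nutrients`),
#'   e.g. from [generate_dataset()].
#' @param cfg A [model_config()].
#' @param epochs Number of passes over the training split.
#' @param seed Integer master seed.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param val_frac Fraction held out for per-epoch validation (0 disables).
#' @param weights Optional warm-start weights.
#' @return A `nutrinet_model`: list with `weights`, `cfg`, `state`, `record`
#'   (per-epoch losses, sleep events, config hash) and `seed`.
#' @export
train_model <- function(dataset, cfg, epochs = 30L, seed = 0L, lr = 1e-3,
                        batch_size = 25L, val_frac = 0.2, weights = NULL) {
  samples <- .as_sample_list(dataset)
  n <- length(samples)
  inputs <- lapply(samples, function(s) prepare_inputs(s$image, cfg))
  targets <- lapply(samples, function(s) as.numeric(s$nutrients))
  w_loss <- cfg$loss_weights
  split_seed <- derive_seed(seed, "split")
  idx <- with_seed(split_seed, sample.int(n))
  n_val <- floor(n * val_frac)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  if (length(tr_idx) == 0L) metric_error("training split is empty")

  if (is.null(weights)) weights <- init_model(cfg)
  opt <- adam_state(weights)
  d <- cfg$encoder$width
  state <- sleep_state(cfg$grid^2, d)
  supervise <- isTRUE(cfg$decoder$supervise) && cfg$decoder$tau > 0
  sleep_events <- list()
  epoch_rows <- vector("list", epochs)
  step <- 0L

  eval_wmae <- function(ids) {
    if (length(ids) == 0L) return(NA_real_)
    mean(vapply(ids, function(i) {
      p <- .net_forward(inputs[[i]], cfg, weights, state, "eval")$p
      wmae(w_loss, p, targets[[i]])
    }, numeric(1)))
  }

  set.seed(derive_seed(seed, "train"))
  for (ep in seq_len(epochs)) {
    order_ep <- sample(tr_idx)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / batch_size))
    ep_loss <- 0
    for (bt in batches) {
      step <- step + 1L
      acc <- NULL
      last_attn <- NULL
      for (i in bt) {
        fw <- .net_forward(inputs[[i]], cfg, weights, state, "train", keep_cache = TRUE)
        loss_i <- wmae(w_loss, fw$p, targets[[i]])
        if (!is.finite(loss_i))
          .nn_error(sprintf("non-finite loss at epoch %d step %d", ep, step),
                    "nutrinet_numeric_error")
        ep_loss <- ep_loss + loss_i
        dp <- wmae_grad(w_loss, fw$p, targets[[i]])
        gr <- .net_backward(dp, fw, cfg, weights)
        acc <- if (is.null(acc)) gr else nested_add(acc, gr)
        last_attn <- fw$dec$attn_out
        if (supervise) state <- .update_stats(state, fw$dec$attn_out, cfg$decoder$window)
      }
      acc <- nested_scale(acc, 1 / length(bt))
      up <- adam_update(weights, acc, opt, lr)
      weights <- up$weights; opt <- up$state
      if (supervise) {
        flags <- detect_inactive(state, cfg$decoder$tau, cfg$decoder$window)
        # attention needs at least one token: the most active awake token
        # is never allowed to sleep
        if (all(flags | state$asleep)) {
          aw <- which(!state$asleep)
          flags[aw[which.max(state$mean_abs[aw])]] <- FALSE
        }
        newly <- which(flags & !state$asleep)
        if (length(newly) > 0L)
          sleep_events[[length(sleep_events) + 1L]] <- tibble::tibble(
            epoch = ep, step = step, token = newly,
            mean_abs = state$mean_abs[newly])
        state <- update_sleep(state, flags, cfg$decoder$sleep_epochs,
                              epoch_boundary = FALSE, values = last_attn)
      }
    }
    if (supervise)
      state <- update_sleep(state, rep(FALSE, length(state$asleep)),
                            cfg$decoder$sleep_epochs, epoch_boundary = TRUE)
    epoch_rows[[ep]] <- tibble::tibble(
      epoch = ep,
      train_wmae = ep_loss / length(tr_idx),
      val_wmae = eval_wmae(val_idx),
      n_asleep = sum(state$asleep)
    )
  }
  record <- list(
    epochs = dplyr::bind_rows(epoch_rows),
    sleep_events = if (length(sleep_events) > 0) dplyr::bind_rows(sleep_events)
      else tibble::tibble(epoch = integer(), step = integer(),
                          token = integer(), mean_abs = numeric()),
    config_hash = rlang::hash(unclass(cfg)),
    seed = as.integer(seed),
    n_params = count_params(weights)
  )
  structure(list(weights = weights, cfg = cfg, state = state,
                 record = record, seed = as.integer(seed)),
            class = "nutrinet_model")
}

#' @export
print.nutrinet_model <- function(x, ...) {
  ep <- x$record$epochs
  cat(sprintf("<nutrinet_model> %d parameters, %d epochs (seed %d)\n",
              x$record$n_params, nrow(ep), x$seed))
  if (nrow(ep) > 0)
    cat(sprintf("  final train WMAE %.5f | val WMAE %s | %d token(s) asleep\n",
                ep$train_wmae[nrow(ep)],
                ifelse(is.na(ep$val_wmae[nrow(ep)]), "-",
                       sprintf("%.5f", ep$val_wmae[nrow(ep)])),
                ep$n_asleep[nrow(ep)]))
  invisible(x)
}

#' Predict the nutrient composition of an image
#'
#' @param object A `nutrinet_model`.
#' @param image A `preprocessed_image`, `rgb_image`, array, or file path.
#' @param ... Unused.
#' @return A tibble with columns `nutrient`, `fraction` and `nrv_pct`
#'   (the fraction expressed on the percent scale of published
#'   nutrient-reference tables).
#' @export
predict.nutrinet_model <- function(object, image, ...) {
  if (is.character(image)) image <- preprocess(load_image(image))
  p <- model_forward(image, object$cfg, object$weights, "eval")
  tibble::tibble(nutrient = names(p), fraction = as.numeric(p),
                 nrv_pct = 100 * as.numeric(p))
}

#' Evaluate a model on a dataset
#'
#' Runs the model in eval mode over every sample and scores the predictions
#' with the regression top-1 / top-5 accuracies and WMAE.
#'
#' @param dataset A list of samples with `$image` and `$nutrients`.
#' @param weights Model weights (or pass a `nutrinet_model` as `weights` and
#'   omit `cfg`).
#' @param cfg The matching [model_config()].
#' @return A [metrics_report()] list (`summary`, `per_sample`,
#'   `per_nutrient`).
#' @export
evaluate_model <- function(dataset, weights, cfg = NULL) {
  if (inherits(weights, "nutrinet_model")) {
    cfg <- weights$cfg; weights <- weights$weights
  }
  samples <- .as_sample_list(dataset)
  preds <- t(vapply(samples, function(s)
    model_forward(s$image, cfg, weights, "eval"), numeric(cfg$head$n_classes)))
  truths <- t(vapply(samples, function(s) as.numeric(s$nutrients),
                     numeric(cfg$head$n_classes)))
  colnames(preds) <- colnames(truths) <- nutrient_classes()[seq_len(ncol(preds))]
  metrics_report(preds, truths, cfg$loss_weights)
}

## ---- ablations ----------------------------------------------------------------

.pair_stability <- function(pairs, weights, cfg) {
  groups <- split(pairs, vapply(pairs, function(p) p$pair_id, numeric(1)))
  vars <- lapply(groups, function(gr) {
    preds <- lapply(gr, function(s) model_forward(s$image, cfg, weights, "eval"))
    stability_variance(preds)
  })
  do.call(rbind, vars)
}

#' Background-stability ablation of the EFE backbone
#'
#' Trains two matched models on the same data and seed — one with the EFE
#' backbone, one with a plain convolutional stem of equal parameter budget —
#' then renders each foreground over different backgrounds and compares the
#' per-nutrient population variance of the predictions. Lower variance means
#' the front end is doing its denoising job.
#'
#' @param train_data Training samples (list with `$image`, `$nutrients`).
#' @param pairs Same-foreground/different-background samples from
#'   [generate_background_pairs()].
#' @param cfg A [model_config()] (the `use_efe` flag is set per arm).
#' @param seed Master seed shared by both arms.
#' @param epochs,lr,batch_size Training-loop settings per arm.
#' @return A list of class `efe_ablation`: `report` (tibble: arm, nutrient,
#'   median_variance), `per_pair` variance matrices, and the two fitted
#'   models.
#' @export
ablate_efe <- function(train_data, pairs, cfg, seed = 0L, epochs = 15L,
                       lr = 1e-3, batch_size = 25L) {
  arms <- list(with_efe = TRUE, without_efe = FALSE)
  fits <- lapply(arms, function(use) {
    cfg_a <- cfg
    cfg_a$use_efe <- use
    train_model(train_data, cfg_a, epochs = epochs, seed = seed, lr = lr,
                batch_size = batch_size, val_frac = 0)
  })
  var_mats <- lapply(fits, function(m) .pair_stability(pairs, m$weights, m$cfg))
  report <- dplyr::bind_rows(lapply(names(var_mats), function(arm) {
    vm <- var_mats[[arm]]
    tibble::tibble(arm = arm, nutrient = colnames(vm),
                   median_variance = apply(vm, 2, stats::median))
  }))
  structure(list(report = report, per_pair = var_mats, models = fits,
                 seed = as.integer(seed)),
            class = "efe_ablation")
}

#' Decoder-depth ablation
#'
#' Trains one model per requested decoder depth (number of fully connected
#' residual layers), reports each model's predictions on the paired samples
#' and the background-stability variances, mirroring a depth-comparison
#' table.
#'
#' @param train_data Training samples.
#' @param pairs Background pairs for the stability readout.
#' @param cfg Base [model_config()].
#' @param depths Integer vector of decoder depths (at least two).
#' @param seed Master seed shared across depths.
#' @param epochs,lr,batch_size Training-loop settings per depth.
#' @return A list of class `depth_ablation`: `report` (tibble: depth,
#'   nutrient, median_variance, mean_wmae) and `predictions` (tibble of
#'   per-sample predicted fractions by depth).
#' @export
ablate_depth <- function(train_data, pairs, cfg, depths, seed = 0L,
                         epochs = 15L, lr = 1e-3, batch_size = 25L) {
  depths <- as.integer(depths)
  if (length(depths) < 2L) config_error("ablate_depth() needs at least two depths")
  rows <- list(); pred_rows <- list()
  for (dep in depths) {
    cfg_d <- cfg
    cfg_d$decoder$fc_layers <- dep
    fit <- train_model(train_data, cfg_d, epochs = epochs, seed = seed, lr = lr,
                       batch_size = batch_size, val_frac = 0)
    vm <- .pair_stability(pairs, fit$weights, fit$cfg)
    ev <- evaluate_model(pairs, fit$weights, fit$cfg)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      depth = dep, nutrient = colnames(vm),
      median_variance = apply(vm, 2, stats::median),
      mean_wmae = ev$summary$wmae)
    pred_rows[[length(pred_rows) + 1L]] <- dplyr::bind_rows(lapply(
      seq_along(pairs), function(i) {
        p <- model_forward(pairs[[i]]$image, fit$cfg, fit$weights, "eval")
        tibble::tibble(depth = dep, sample = i, nutrient = names(p),
                       fraction = as.numeric(p))
      }))
  }
  structure(list(report = dplyr::bind_rows(rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 seed = as.integer(seed)),
            class = "depth_ablation")
}

## ---- checkpoints --------------------------------------------------------------

#' Save a trained model to a checkpoint file
#'
#' The checkpoint is a single serialised archive holding the weights (named
#' by module path), the configuration, the sleep state and the seed.
#'
#' @param model A `nutrinet_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path A file written by [save_checkpoint()].
#' @return A `nutrinet_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) io_error(sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  if (!all(c("weights", "cfg") %in% names(obj)))
    validation_error(sprintf("'%s' is not a model checkpoint", path))
  structure(obj, class = "nutrinet_model")
}
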