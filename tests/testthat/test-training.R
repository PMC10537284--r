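test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config(seed = 3L)
  W <- init_model(cfg)
  img <- random_preprocessed(41, 12L)
  inp <- nutrinet:::prepare_inputs(img, cfg)
  st <- sleep_state(cfg$grid^2, cfg$encoder$width)
  y <- c(0.1, 0.1, 0.05, 0.3, 0.05, 0.2, 0.2)  # offset from any prediction
  loss_of <- function(w) wmae(cfg$loss_weights,
                              nutrinet:::.net_forward(inp, cfg, w, st, "train")$p, y)
  fw <- nutrinet:::.net_forward(inp, cfg, W, st, "train", keep_cache = TRUE)
  gr <- nutrinet:::.net_backward(wmae_grad(cfg$loss_weights, fw$p, y), fw, cfg, W)

  # nutrient-head weights: every leaf, tight tolerance
  eps <- 1e-5
  for (leaf in c("W1", "b1", "W2", "b2")) {
    g_an <- gr$head[[leaf]]
    idx <- seq_along(g_an)
    if (length(idx) > 20) { set.seed(1); idx <- sample(idx, 20) }
    for (i in idx) {
      Wp <- W; Wp$head[[leaf]][i] <- Wp$head[[leaf]][i] + eps
      Wm <- W; Wm$head[[leaf]][i] <- Wm$head[[leaf]][i] - eps
      num <- (loss_of(Wp) - loss_of(Wm)) / (2 * eps)
      expect_equal(as.numeric(g_an[i]), num,
                   tolerance = 1e-4 * max(1, abs(num)))
    }
  }

  # a sampled sweep across every other stage
  flat <- unlist(W); gflat <- unlist(gr)
  expect_identical(names(flat), names(gflat))
  set.seed(2)
  idx <- sample(length(flat), 120)
  for (i in idx) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    num <- (loss_of(utils::relist(vp, W)) - loss_of(utils::relist(vm, W))) / (2 * eps)
    an <- gflat[i]
    expect_lt(abs(num - an) / max(abs(num), abs(an), 1e-6), 1e-3)
  }
})

test_that("a zero learning rate freezes the weights and the loss", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 8, seed = 1)
  cfg <- tiny_config()
  fit <- train_model(ds$samples, cfg, epochs = 3, seed = 5, lr = 0, val_frac = 0,
                     batch_size = 4)
  expect_equal(fit$weights, init_model(cfg), tolerance = 1e-12)
  expect_equal(length(unique(round(fit$record$epochs$train_wmae, 12))), 1L)
})

test_that("training is bit-reproducible for a fixed seed", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 10, seed = 2)
  cfg <- tiny_config()
  f1 <- train_model(ds$samples, cfg, epochs = 2, seed = 7, batch_size = 5)
  f2 <- train_model(ds$samples, cfg, epochs = 2, seed = 7, batch_size = 5)
  expect_identical(f1$record$epochs, f2$record$epochs)
  expect_identical(f1$weights, f2$weights)
})

test_that("a single sample is memorised and the loss trace decreases", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 1, seed = 3)
  fit <- train_model(ds$samples, tiny_config(), epochs = 200, seed = 0,
                     lr = 3e-3, val_frac = 0, batch_size = 1)
  tr <- fit$record$epochs$train_wmae
  expect_lt(tr[length(tr)], 0.01)
  expect_lt(median(utils::tail(tr, 10)), median(utils::head(tr, 10)))
})

test_that("the composed forward pass equals its stagewise composition", {
  cfg <- tiny_config(seed = 9L)
  W <- init_model(cfg)
  img <- random_preprocessed(55, 16L)
  p <- model_forward(img, cfg, W)
  t_efe <- efe_forward(img, cfg$efe, W$efe, grid = cfg$grid)
  t_enc <- encoder_forward(t_efe, img, cfg$encoder, W$enc)
  f <- decoder_forward(t_enc, sleep_state(cfg$grid^2, cfg$encoder$width),
                       cfg$decoder, W$dec)
  p_ref <- semantic_output(f, W$head)
  expect_equal(as.numeric(p), as.numeric(p_ref), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_identical(p, model_forward(img, cfg, W))
})

test_that("tau = 0 yields a decoder identical to one without supervision", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 12, seed = 4)
  base <- tiny_config()
  cfg_tau0 <- base; cfg_tau0$decoder$tau <- 0
  cfg_off <- base; cfg_off$decoder$tau <- 0.5; cfg_off$decoder$supervise <- FALSE
  cfg_off$decoder$window <- 2L; cfg_tau0$decoder$window <- 2L
  f_tau0 <- train_model(ds$samples, cfg_tau0, epochs = 10, seed = 11, batch_size = 6,
                        val_frac = 0)
  f_off <- train_model(ds$samples, cfg_off, epochs = 10, seed = 11, batch_size = 6,
                       val_frac = 0)
  expect_identical(f_tau0$weights, f_off$weights)
  expect_equal(f_tau0$record$epochs$train_wmae, f_off$record$epochs$train_wmae)
  expect_equal(nrow(f_tau0$record$sleep_events), 0L)

  # whereas an aggressive threshold actually sleeps tokens and changes the fit
  cfg_hot <- base; cfg_hot$decoder$tau <- 10; cfg_hot$decoder$window <- 2L
  f_hot <- train_model(ds$samples, cfg_hot, epochs = 10, seed = 11, batch_size = 6,
                       val_frac = 0)
  expect_gt(nrow(f_hot$record$sleep_events), 0L)
  expect_false(identical(f_hot$weights, f_tau0$weights))
})

test_that("evaluation aggregates per-sample metrics over the model", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 6, seed = 5)
  cfg <- tiny_config()
  W <- init_model(cfg)
  ev <- evaluate_model(ds$samples, W, cfg)
  expect_equal(ev$summary$n, 6L)
  expect_equal(ev$summary$wmae, mean(ev$per_sample$wmae), tolerance = 1e-12)
  expect_equal(nrow(ev$per_nutrient), 7L)
  expect_error(evaluate_model(list(), W, cfg), class = "nutrinet_metric_error")
})

test_that("checkpoints round-trip and drive prediction", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 6, seed = 6)
  fit <- train_model(ds$samples, tiny_config(), epochs = 1, seed = 1, batch_size = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_identical(back$weights, fit$weights)
  pred <- predict(back, ds$samples[[1]]$image)
  expect_s3_class(pred, "tbl_df")
  expect_equal(sum(pred$fraction), 1, tolerance = 1e-9)
  expect_equal(pred$nrv_pct, 100 * pred$fraction)
})

test_that("ablation reports carry both arms and are reproducible", {
  spec <- synthetic_spec(image_size = 16L)
  ds <- generate_dataset(spec, 16, seed = 7)
  pairs <- generate_background_pairs(spec, food = 1, n_pairs = 2, seed = 7)
  cfg <- tiny_config()
  ab <- ablate_efe(ds$samples, pairs, cfg, seed = 3, epochs = 2, batch_size = 8)
  expect_setequal(unique(ab$report$arm), c("with_efe", "without_efe"))
  expect_equal(nrow(ab$report), 14L)  # 2 arms x 7 nutrients
  expect_true(all(ab$report$median_variance >= 0))
  # parameter budgets of the two arms are matched within a few percent
  n_with <- ab$models$with_efe$record$n_params
  n_without <- ab$models$without_efe$record$n_params
  expect_lt(abs(n_with - n_without) / n_with, 0.05)
  ab2 <- ablate_efe(ds$samples, pairs, cfg, seed = 3, epochs = 2, batch_size = 8)
  expect_equal(ab$report, ab2$report)

  dep <- ablate_depth(ds$samples, pairs, cfg, depths = c(1L, 2L), seed = 3,
                      epochs = 2, batch_size = 8)
  expect_setequal(unique(dep$report$depth), c(1L, 2L))
  expect_equal(nrow(dep$report), 14L)
  expect_s3_class(dep$predictions, "tbl_df")
  expect_error(ablate_depth(ds$samples, pairs, cfg, depths = 2L),
               class = "nutrinet_config_error")
})
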