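test_that("WMAE matches its closed form and metric properties", {
  expect_equal(wmae(c(1, 1), c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(wmae(c(2, 1), c(1, 0), c(0, 2)), 4 / 3, tolerance = 1e-12)
  # uniform weights reduce to the plain MAE
  set.seed(31)
  a <- runif(5); b <- runif(5)
  expect_equal(wmae(rep(3, 5), a, b), mean(abs(a - b)), tolerance = 1e-12)
  # symmetry and the triangle inequality of the weighted l1 metric
  for (i in 1:25) {
    w <- runif(4, 0.1, 3); x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
    expect_equal(wmae(w, x, y), wmae(w, y, x), tolerance = 1e-12)
    expect_lte(wmae(w, x, z), wmae(w, x, y) + wmae(w, y, z) + 1e-12)
  }
  expect_error(wmae(c(1, 1), c(1, 2, 3), c(1, 2, 3)), class = "nutrinet_dimension_error")
  expect_error(wmae(c(0, 1), c(1, 2), c(1, 2)), class = "nutrinet_validation_error")
})

test_that("GELU is x * Phi(x) with the exact normal CDF", {
  expect_equal(gelu(0), 0)
  expect_equal(gelu(1), pnorm(1), tolerance = 1e-12)
  expect_equal(gelu(1), 0.841345, tolerance = 1e-6)
  expect_equal(gelu(10) / 10, 1, tolerance = 1e-6)
  # numerically integrated CDF as the oracle
  xs <- seq(-5, 5, length.out = 100)
  phi <- vapply(xs, function(x)
    stats::integrate(stats::dnorm, -Inf, x, rel.tol = 1e-12)$value, numeric(1))
  expect_lt(max(abs(gelu(xs) - xs * phi)), 1e-8)
  # shape preservation
  m <- matrix(rnorm(6), 2, 3)
  expect_equal(dim(gelu(m)), dim(m))
})

test_that("regression top-1 scores clamp at zero and peak at exactness", {
  expect_equal(top1_acc(7.28, 7.28), 1)
  expect_equal(top1_acc(6.090, 7.280), 1 - 1.19 / 7.28, tolerance = 1e-12)
  expect_equal(top1_acc(6.090, 7.280), 0.83654, tolerance = 1e-5)
  # an unpredicted nutrient scores zero
  expect_equal(top1_acc(0, 5), 0)
  expect_equal(top1_acc(12, 5), 0)  # overshoot beyond 2x clamps too
  expect_error(top1_acc(1, 0), class = "nutrinet_metric_error")
  set.seed(32)
  for (i in 1:50) {
    s <- top1_acc(runif(1, 0, 3), runif(1, 0.1, 3))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("top-5 averages the five clamped per-class scores", {
  expect_equal(top5_acc(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
  expect_equal(top5_acc(c(1, 0, 0, 0, 0), c(1, 2, 3, 4, 5)), 0.2)
  expect_equal(top5_acc(c(2, 1.5, 3, 1, 0.5), c(2, 3, 2, 2, 1)), mean(c(1, 0.5, 0.5, 0.5, 0.5)))
  expect_error(top5_acc(c(1, 2, 3), c(1, 2, 3)), class = "nutrinet_metric_error")
  expect_error(top5_acc(1:5, c(1, 2, 0, 4, 5)), class = "nutrinet_metric_error")
})

test_that("stability variance is the per-class population variance", {
  same <- list(c(a = 0.2, b = 0.8), c(a = 0.2, b = 0.8))
  expect_equal(unname(stability_variance(same)), c(0, 0))
  two <- list(c(0.3, 0.5), c(0.4, 0.5))
  expect_equal(unname(stability_variance(two)), c(0.0025, 0), tolerance = 1e-12)
  # shift invariance
  set.seed(33)
  preds <- matrix(runif(12), 4, 3)
  shifted <- sweep(preds, 2, c(1, 2, 3), `+`)
  expect_equal(stability_variance(preds), stability_variance(shifted), tolerance = 1e-12)
  expect_error(stability_variance(list(c(1, 2))), class = "nutrinet_metric_error")
})

test_that("dataset-level metrics are the mean of per-sample metrics", {
  set.seed(34)
  truths <- t(replicate(8, random_simplex(7)))
  colnames(truths) <- nutrient_classes()
  # a perfect oracle scores 1 / 1 / 0
  rep_ <- metrics_report(truths, truths)
  expect_equal(rep_$summary$top1, 1)
  expect_equal(rep_$summary$top5, 1)
  expect_equal(rep_$summary$wmae, 0)
  # an all-remainder predictor triggers the zero-score rule when the true
  # remainder is at most half the predicted mass
  truths0 <- matrix(rep(c(0.15, 0.1, 0.05, 0.2, 0.05, 0.05, 0.4), 3),
                    3, 7, byrow = TRUE)
  colnames(truths0) <- nutrient_classes()
  preds0 <- matrix(rep(c(0, 0, 0, 0, 0, 0, 1), 3), 3, 7, byrow = TRUE)
  colnames(preds0) <- nutrient_classes()
  expect_equal(metrics_report(preds0, truths0)$summary$top1, 0)
  # aggregate equals mean of the per-sample table
  preds <- t(replicate(8, random_simplex(7)))
  colnames(preds) <- nutrient_classes()
  rep2 <- metrics_report(preds, truths)
  expect_equal(rep2$summary$top1, mean(rep2$per_sample$top1), tolerance = 1e-12)
  expect_equal(rep2$summary$wmae, mean(rep2$per_sample$wmae), tolerance = 1e-12)
  expect_error(metrics_report(matrix(0, 0, 7), matrix(0, 0, 7)),
               class = "nutrinet_metric_error")
})
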